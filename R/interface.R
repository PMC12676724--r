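# Shared I/O, configuration and the end-to-end pipeline. Internal
# coordinates are 0-based half-open everywhere; 1-based inclusive appears
# only in the BLAST-like hits TSV. Logging goes to stderr; results go to
# files.

#' Read sequence records
#'
#' Reads FASTA (via Biostrings, wrapped records accepted) or FASTQ
#' (4-line records, Phred+33). Duplicate ids are rejected; a malformed
#' FASTQ record raises a parse error naming the offending line.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return named character vector of sequences; FASTQ qualities are
#'   attached as attribute `"qualities"`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop("FASTQ parse error: truncated record at line ", length(lines))
    if (!length(lines)) {
      seqs <- setNames(character(0), character(0))
      attr(seqs, "qualities") <- character(0)
      return(seqs)
    }
    idx <- seq.int(1L, length(lines), by = 4L)
    bad_at <- !startsWith(lines[idx], "@")
    if (any(bad_at))
      stop("FASTQ parse error: expected '@' at line ", idx[which(bad_at)[1L]])
    bad_plus <- !startsWith(lines[idx + 2L], "+")
    if (any(bad_plus))
      stop("FASTQ parse error: expected '+' at line ", idx[which(bad_plus)[1L]] + 2L)
    seqs <- lines[idx + 1L]
    quals <- lines[idx + 3L]
    bad_len <- nchar(seqs) != nchar(quals)
    if (any(bad_len))
      stop("FASTQ parse error: sequence/quality length mismatch at line ",
           idx[which(bad_len)[1L]] + 3L)
    names(seqs) <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
    attr(seqs, "qualities") <- quals
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ","))
  seqs
}

#' Write sequence records
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param format `"fasta"` (wrapped at 70 columns) or `"fastq"`.
#' @param qualities quality strings for FASTQ (recycled; default constant
#'   Q40 `I`).
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq"),
                            qualities = NULL) {
  format <- match.arg(format)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  if (format == "fasta") {
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = 70L)
  } else {
    if (is.null(qualities))
      qualities <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    qualities <- rep_len(qualities, length(seqs))
    out <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs),
                           "+", qualities))
    writeLines(out, path)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the thresholds of every stage in one validated object that
#' serializes losslessly to and from YAML. Defaults carry the published
#' constants: BSR coverage gate 5, contig rule >3 kb, species identity
#' 98.7%, breadth model `1 - exp(-0.883 d)` with a 15% band, fall-winter
#' window 21 September to 21 March.
#'
#' @param reads,markers,references,contigs,tables,rrna_refs input paths
#'   (optional; stages without inputs are skipped by [run_pipeline()]).
#' @param outdir output directory.
#' @param seed integer seed flowing to every stochastic stage.
#' @param bsr_min,coverage_min prescreen thresholds.
#' @param min_contig_len,min_hit_columns,min_identity recruitment thresholds.
#' @param marker_bsr_min completeness marker BSR threshold.
#' @param species_identity strict 16S species-assignment threshold.
#' @param model_k,model_tolerance,model_sidedness detection-model fields.
#' @param bloom_k_mad,bloom_min_peak bloom-calling parameters.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads = NULL, markers = NULL, references = NULL,
                            contigs = NULL, tables = NULL, rrna_refs = NULL,
                            outdir = "endotrawl_out", seed = 1L,
                            bsr_min = 0.4, coverage_min = 5,
                            min_contig_len = 3000L, min_hit_columns = 1000L,
                            min_identity = 0.80, marker_bsr_min = 0.4,
                            species_identity = 0.987,
                            model_k = 0.883, model_tolerance = 0.15,
                            model_sidedness = "one_sided_lower",
                            bloom_k_mad = 5, bloom_min_peak = 1e-4) {
  cfg <- list(reads = reads, markers = markers, references = references,
              contigs = contigs, tables = tables, rrna_refs = rrna_refs,
              outdir = outdir, seed = as.integer(seed),
              bsr_min = bsr_min, coverage_min = coverage_min,
              min_contig_len = as.integer(min_contig_len),
              min_hit_columns = as.integer(min_hit_columns),
              min_identity = min_identity, marker_bsr_min = marker_bsr_min,
              species_identity = species_identity,
              model_k = model_k, model_tolerance = model_tolerance,
              model_sidedness = model_sidedness,
              bloom_k_mad = bloom_k_mad, bloom_min_peak = bloom_min_peak)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$bsr_min >= 0, cfg$bsr_min <= 1,
            cfg$coverage_min >= 0,
            cfg$min_contig_len > 0, cfg$min_hit_columns > 0,
            cfg$min_identity > 0, cfg$min_identity <= 1,
            cfg$species_identity > 0, cfg$species_identity < 1,
            cfg$model_k > 0,
            cfg$model_tolerance > 0, cfg$model_tolerance < 1,
            cfg$model_sidedness %in% c("one_sided_lower", "two_sided"),
            cfg$bloom_k_mad > 0, cfg$bloom_min_peak >= 0)
  invisible(cfg)
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_config()].
#' @return a validated [pipeline_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[!vapply(cfg, is.null, TRUE)])
}

log_msg <- function(...) {
  message("[endotrawl] ", ...)
}

# serialize an S3 report to plain lists for JSON
report_to_list <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) {
    if (inherits(v, "Date")) as.character(v)
    else if (is.data.frame(v) || is.list(v)) v
    else v
  })
}

#' Write stage reports as JSON and TSV
#'
#' Each named report is written as `<name>.json` (full structure, schema
#' versioned) and `<name>.tsv` (scalar fields as one row).
#'
#' @param reports named list of stage report objects.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(reports, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character(0)
  for (nm in names(reports)) {
    obj <- report_to_list(reports[[nm]])
    obj$schema_version <- "1.0"
    jp <- file.path(outdir, paste0(nm, ".json"))
    jsonlite::write_json(obj, jp, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    scalars <- obj[vapply(obj, function(v)
      is.atomic(v) && length(v) == 1L, TRUE)]
    tp <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(as.data.frame(scalars, stringsAsFactors = FALSE), tp,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, jp, tp)
  }
  invisible(paths)
}

#' Run the discovery funnel end to end
#'
#' Executes prescreen, recruitment, quality control and detection in order
#' on the files named in the configuration, mirroring the dataset-selection
#' funnel: a dataset failing the prescreen short-circuits all later stages.
#' Every report is written to the output directory together with a run
#' manifest of stages, file digests and the seed.
#'
#' @param config a [pipeline_config()] with at least `reads`, `markers` and
#'   (for recruitment) `references` and `contigs` paths set.
#' @return an object of class `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  reports <- list()

  run_stage <- function(name, expr) {
    log_msg("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (is.null(config$reads) || is.null(config$markers))
    stop("config must name 'reads' and 'markers' inputs")
  reads <- run_stage("load", read_sequences(config$reads))
  markers <- run_stage("load", read_sequences(config$markers, "fasta"))

  scheme_p <- scoring_scheme("protein")
  scheme_n <- scoring_scheme()

  screen <- run_stage("screen", screen_dataset(
    unname(reads), markers, bsr_min = config$bsr_min,
    coverage_min = config$coverage_min, scheme = scheme_p,
    dataset_id = basename(config$reads)))
  stages <- c(stages, "screen")
  reports$screen <- screen

  bins <- list()
  if (screen$verdict == "pass" &&
      !is.null(config$references) && !is.null(config$contigs)) {
    refs <- read_sequences(config$references, "fasta")
    contigs <- read_sequences(config$contigs, "fasta")
    rc <- recruit_config(min_contig_len = config$min_contig_len,
                         min_hit_columns = config$min_hit_columns,
                         min_identity = config$min_identity)
    recruited <- run_stage("recruit",
                           recruit_contigs(contigs, refs, rc, scheme_n))
    stages <- c(stages, "recruit")
    for (rid in names(recruited)) {
      if (!length(recruited[[rid]])) next
      b <- build_bin(recruited[[rid]], rid, paste0("bin_", rid))
      b <- detect_circularity(b, rc)
      bins[[b$bin_id]] <- b
      write_sequences(b$contigs,
                      file.path(config$outdir, paste0(b$bin_id, ".fasta")))
    }
    reports$recruit <- list(
      n_contigs_in = length(contigs),
      bins = lapply(bins, function(b)
        b[c("bin_id", "best_reference", "total_length", "n_contigs",
            "largest_contig", "N50", "circular")]))

    completeness_set <- markers[setdiff(names(markers), c("tlcA", "nosZ"))]
    rrna <- NULL
    if (!is.null(config$rrna_refs))
      rrna <- read_sequences(config$rrna_refs, "fasta")
    for (b in bins) {
      qr <- run_stage("qc", {
        orfs <- find_orfs(b$contigs, circular = b$circular)
        counts <- score_markers(orfs$protein, completeness_set, scheme_p,
                                bsr_min = config$marker_bsr_min)
        flags <- if (is.null(rrna))
          c("5S" = FALSE, "16S" = FALSE, "23S" = FALSE)
        else detect_rrna(b$contigs, rrna, scheme_n)
        completeness_report(counts, completeness_set, flags, bin = b)
      })
      reports[[paste0("qc_", b$bin_id)]] <- qr
      stages <- c(stages, paste0("qc_", b$bin_id))

      det <- run_stage("detect", {
        genome <- paste(b$contigs, collapse = "")
        hits <- seeded_map(unname(reads), genome, scheme = scheme_n,
                           circular = b$circular)
        prof <- coverage_profile(hits, nchar(genome), b$bin_id,
                                 circular = b$circular)
        call_presence(prof, detection_model(config$model_k,
                                            config$model_tolerance,
                                            config$model_sidedness))
      })
      reports[[paste0("detect_", b$bin_id)]] <- det
      stages <- c(stages, paste0("detect_", b$bin_id))
    }
  }

  write_reports(reports, config$outdir)
  outfiles <- list.files(config$outdir, full.names = TRUE)
  manifest <- structure(list(
    stages = stages,
    verdict = screen$verdict,
    bins = names(bins),
    digests = as.list(tools::md5sum(sort(outfiles))),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$verdict, "| stages:",
      paste(x$stages, collapse = " > "), "\n")
  invisible(x)
}
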