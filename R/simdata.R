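# Synthetic-data generators with known ground truth. They emulate the study
# system: tiny (234-375 kb) circular endosymbiont genomes carrying marker
# genes in conserved order, shotgun read sets over a background community,
# fragmented "assemblies", and multi-year amplicon count tables with seasonal
# blooms. Every generator is a pure function of its arguments and seed.

# run code under a temporary RNG state seeded with `seed`; NULL seed uses the
# current RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# short sequence with a stop codon in all six reading frames and no start
# codon on either strand; placed immediately upstream of every planted gene
# so maximal ORFs cannot begin before the recorded coordinates
STOP_CASSETTE <- "TAACTAACTAATTAGTTAGTTA"

#' Default marker-protein catalog
#'
#' Random marker proteins standing in for the family-specific single-copy
#' marker set: the two prescreen markers `tlcA` (ATP/ADP translocase) and
#' `nosZ` (nitrous oxide reductase) plus `n_markers` completeness markers
#' `marker_001 ...`. The default completeness-set size of 55 makes single
#' markers worth 1/55 of completeness (so 30/55 = 54.55%).
#'
#' @param n_markers number of completeness markers (default 55).
#' @param seed RNG seed.
#' @param len_range amino-acid length range for completeness markers.
#' @param screen_len amino-acid length of tlcA and nosZ (default 500,
#'   about the size of the real ATP/ADP translocase).
#' @return named character vector of protein sequences.
#' @export
default_marker_catalog <- function(n_markers = 55L, seed = 1L,
                                   len_range = c(120L, 250L), screen_len = 500L) {
  with_seed(seed, {
    lens <- sample(seq.int(len_range[1], len_range[2]), n_markers, replace = TRUE)
    cat_names <- sprintf("marker_%03d", seq_len(n_markers))
    markers <- vapply(lens, random_protein, character(1))
    names(markers) <- cat_names
    c(tlcA = random_protein(screen_len), nosZ = random_protein(screen_len), markers)
  })
}

#' Generate a circular symbiont genome with planted marker genes
#'
#' Reverse-translates each catalog protein (bacterial code 11, seeded
#' synonymous codon choice), appends a stop codon, and plants the genes in
#' catalog order on the forward strand, separated by seeded random spacers.
#' Each gene is preceded by a cassette containing stop codons in all six
#' frames, so an ORF caller recovers the genes at exactly the recorded
#' coordinates. The sequence is flagged circular.
#'
#' @param marker_catalog named character vector of proteins to plant.
#' @param genome_length total length in bases (tiny symbiont range
#'   234,000-375,000; default 300,000).
#' @param seed RNG seed.
#' @param min_spacer minimum random spacer between gene blocks.
#' @return list with `sequence`, `genes` (data.frame `gene,start,end,strand`,
#'   0-based half-open, stop codon included), `genes_nt` (planted nucleotide
#'   sequences) and `circular = TRUE`.
#' @export
generate_symbiont_genome <- function(marker_catalog,
                                     genome_length = 300000L,
                                     seed = 1L, min_spacer = 30L) {
  if (!length(marker_catalog)) stop("marker catalog must be non-empty")
  if (is.null(names(marker_catalog)) || anyNA(names(marker_catalog)))
    stop("marker catalog must be named")
  with_seed(seed, {
    genes_nt <- vapply(marker_catalog, reverse_translate, character(1),
                       add_stop = TRUE)
    n <- length(genes_nt)
    block_len <- nchar(genes_nt) + nchar(STOP_CASSETTE)
    spare <- genome_length - sum(block_len)
    n_spacer <- n # one random spacer before each block; cassette abuts gene
    if (spare < n_spacer * min_spacer + 1L)
      stop("genome_length too short for the marker catalog (need > ",
           sum(block_len) + n_spacer * min_spacer, " bases)")
    extra <- as.vector(stats::rmultinom(1L, spare - n_spacer * min_spacer,
                                        rep(1 / (n_spacer + 1L), n_spacer + 1L)))
    spacer_len <- min_spacer + extra[seq_len(n_spacer)]
    tail_len <- extra[n_spacer + 1L]

    pieces <- character(0)
    genes <- vector("list", n)
    pos <- 0L
    for (i in seq_len(n)) {
      sp <- random_dna(spacer_len[i])
      pieces <- c(pieces, sp, STOP_CASSETTE, genes_nt[[i]])
      gstart <- pos + spacer_len[i] + nchar(STOP_CASSETTE)
      gend <- gstart + nchar(genes_nt[[i]])
      genes[[i]] <- data.frame(gene = names(genes_nt)[i], start = gstart,
                               end = gend, strand = "+",
                               stringsAsFactors = FALSE)
      pos <- gend
    }
    if (tail_len > 0L) pieces <- c(pieces, random_dna(tail_len))
    sequence <- paste(pieces, collapse = "")
    stopifnot(nchar(sequence) == genome_length)
    list(sequence = sequence, genes = do.call(rbind, genes),
         genes_nt = genes_nt, circular = TRUE)
  })
}

#' Derive a related species by seeded substitution
#'
#' Applies substitutions at seeded random positions at the given expected
#' per-base divergence; gene order and length are unchanged, emulating the
#' conserved genome structure of related symbiont species.
#'
#' @param genome sequence.
#' @param divergence expected substituted fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return sequence of equal length; the 0-based substitution positions are
#'   attached as attribute `"substitutions"`.
#' @export
derive_species <- function(genome, divergence, seed = 1L) {
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  with_seed(seed, {
    r <- cpp_mutate(toupper(genome), divergence)
    structure(r$seq, substitutions = r$positions)
  })
}

#' Simulate shotgun reads over a community
#'
#' Draws each read's genome of origin from a multinomial on `abundances`,
#' its start uniformly (wrapping across the origin for circular genomes),
#' and its strand uniformly; substitution errors are applied at `error_rate`
#' (no indels, keeping mapping oracles exact). Qualities are constant
#' Phred+33 `I` (Q40).
#'
#' @param genomes named character vector of genome sequences.
#' @param abundances relative abundances (recycled to sum 1).
#' @param total_reads number of reads to emit.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution probability.
#' @param circular logical, recycled over genomes.
#' @param seed RNG seed.
#' @return list with `reads` (named character vector), `quality` (constant
#'   string) and `origin` (data.frame `read_id, genome, start, strand`,
#'   start 0-based on the forward strand).
#' @export
simulate_reads <- function(genomes, abundances = rep(1, length(genomes)),
                           total_reads, read_length = 150L,
                           error_rate = 0.01, circular = FALSE, seed = 1L) {
  if (total_reads > 0 && !length(genomes)) stop("no genomes to sample reads from")
  if (total_reads < 0) stop("total_reads must be >= 0")
  stopifnot(length(abundances) == length(genomes), all(abundances >= 0))
  circular <- rep_len(circular, length(genomes))
  ids <- names(genomes) %||% paste0("genome_", seq_along(genomes))
  qual <- strrep("I", read_length)
  if (total_reads == 0) {
    return(list(reads = setNames(character(0), character(0)), quality = qual,
                origin = data.frame(read_id = character(0), genome = character(0),
                                    start = integer(0), strand = character(0),
                                    stringsAsFactors = FALSE)))
  }
  lens <- nchar(genomes)
  if (any(!circular & lens < read_length))
    stop("linear genome shorter than the read length")
  with_seed(seed, {
    gi <- sample.int(length(genomes), total_reads, replace = TRUE,
                     prob = abundances / sum(abundances))
    starts <- integer(total_reads)
    for (g in unique(gi)) {
      sel <- gi == g
      hi <- if (circular[g]) lens[g] else lens[g] - read_length + 1L
      starts[sel] <- sample.int(hi, sum(sel), replace = TRUE) - 1L
    }
    strands <- sample(c("+", "-"), total_reads, replace = TRUE)
    doubled <- ifelse(circular, paste0(genomes, genomes), genomes)
    reads <- substring(doubled[gi], starts + 1L, starts + read_length)
    flip <- strands == "-"
    if (any(flip)) reads[flip] <- vapply(reads[flip], revcomp, character(1))
    if (error_rate > 0)
      reads <- vapply(reads, function(s) cpp_mutate(s, error_rate)$seq,
                      character(1), USE.NAMES = FALSE)
    read_ids <- sprintf("read_%06d", seq_len(total_reads))
    names(reads) <- read_ids
    list(reads = reads, quality = qual,
         origin = data.frame(read_id = read_ids, genome = ids[gi],
                             start = starts, strand = strands,
                             stringsAsFactors = FALSE))
  })
}

#' Fragment a genome into contigs
#'
#' Cuts the genome into `n_fragments` non-overlapping tiles of at least
#' `min_len` bases (seeded random cut points). In circular mode the last
#' fragment is extended by `overlap` bases wrapped from the genome start, so
#' a single-fragment contig carries the terminal repeat used by circularity
#' detection; concatenating the fragments minus the declared overlap
#' reconstructs the genome.
#'
#' @param genome sequence.
#' @param n_fragments number of contigs (>= 1).
#' @param min_len minimum fragment length.
#' @param circular add the wrapped terminal overlap?
#' @param overlap terminal overlap length in circular mode.
#' @param seed RNG seed.
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame `contig, start, end, overlap`).
#' @export
fragment_genome <- function(genome, n_fragments, min_len = 1000L,
                            circular = FALSE, overlap = 50L, seed = 1L) {
  L <- nchar(genome)
  if (n_fragments < 1L) stop("n_fragments must be >= 1")
  spare <- L - n_fragments * min_len
  if (spare < 0L)
    stop("cannot cut ", L, " bases into ", n_fragments,
         " fragments of >= ", min_len)
  if (circular && overlap > L) stop("overlap longer than the genome")
  with_seed(seed, {
    extra <- as.vector(stats::rmultinom(1L, spare,
                                        rep(1 / n_fragments, n_fragments)))
    lens <- min_len + extra
    ends <- cumsum(lens)
    starts <- c(0L, ends[-n_fragments])
    contigs <- substring(genome, starts + 1L, ends)
    ov <- integer(n_fragments)
    if (circular) {
      wrap <- substring(paste0(genome, genome), L + 1L, L + overlap)
      contigs[n_fragments] <- paste0(contigs[n_fragments], wrap)
      ov[n_fragments] <- overlap
    }
    ids <- sprintf("contig_%03d", seq_len(n_fragments))
    names(contigs) <- ids
    list(contigs = contigs,
         truth = data.frame(contig = ids, start = starts, end = ends,
                            overlap = ov, stringsAsFactors = FALSE))
  })
}

#' Simulate a dated taxon count table with seasonal blooms
#'
#' Counts are drawn per sample around per-taxon baselines from a negative
#' binomial parameterized by mean and dispersion (`variance =
#' mu + dispersion * mu^2`); inside a bloom interval a taxon's mean is
#' multiplied by its fold increase. Zero dispersion gives deterministic
#' rounded baselines.
#'
#' @param taxa named numeric vector of baseline mean counts per taxon.
#' @param dates strictly increasing `Date` vector (one sample per date).
#' @param blooms data.frame with columns `taxon, start, end, fold`
#'   (dates within range), or `NULL`.
#' @param dispersion negative-binomial dispersion (default 0.3).
#' @param plant plant/site label for all samples.
#' @param seed RNG seed.
#' @return list with `table` (data.frame `sample_id, date, plant`, one count
#'   column per taxon) and `truth` (the bloom data.frame).
#' @export
simulate_timeseries <- function(taxa, dates, blooms = NULL, dispersion = 0.3,
                                plant = "plant_A", seed = 1L) {
  dates <- as.Date(dates)
  if (any(diff(dates) <= 0)) stop("dates must be strictly increasing")
  if (is.null(names(taxa))) stop("taxa must be a named numeric vector")
  if (!is.null(blooms) && nrow(blooms)) {
    blooms$start <- as.Date(blooms$start); blooms$end <- as.Date(blooms$end)
    if (any(blooms$start > blooms$end)) stop("bloom start after end")
    if (any(blooms$start < min(dates)) || any(blooms$end > max(dates)))
      stop("bloom interval outside the sampled date range")
    if (!all(blooms$taxon %in% names(taxa))) stop("bloom taxon not in taxa")
  }
  n <- length(dates)
  with_seed(seed, {
    mu <- matrix(rep(taxa, each = n), nrow = n,
                 dimnames = list(NULL, names(taxa)))
    if (!is.null(blooms) && nrow(blooms)) {
      for (b in seq_len(nrow(blooms))) {
        sel <- dates >= blooms$start[b] & dates <= blooms$end[b]
        mu[sel, blooms$taxon[b]] <- mu[sel, blooms$taxon[b]] * blooms$fold[b]
      }
    }
    counts <- if (dispersion == 0) {
      round(mu)
    } else {
      matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
             nrow = n, dimnames = dimnames(mu))
    }
    tab <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                      date = dates, plant = plant, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(counts))
    list(table = tab, truth = blooms)
  })
}
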