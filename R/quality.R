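# Bin quality assessment: a minimal ORF caller, single-copy marker
# completeness/contamination against a family-specific marker set, rRNA
# presence, MIMAG quality tiers, and 16S identity-based species assignment.

ORF_STARTS <- c("ATG", "GTG", "TTG") # bacterial code 11 initiators

orfs_one_frame <- function(seq_id, codons, offset, L, strand, frame,
                           min_aa, wrap_limit) {
  gc <- genetic_code_11()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (!length(stops)) return(NULL)
  starts_all <- which(codons %in% ORF_STARTS)
  if (!length(starts_all)) return(NULL)
  seg_begin <- c(1L, stops[-length(stops)] + 1L)
  # first start codon at or after each segment begin
  pos <- findInterval(seg_begin - 0.5, starts_all) + 1L
  keep <- pos <= length(starts_all)
  seg_begin <- seg_begin[keep]; stops_k <- stops[keep]; pos <- pos[keep]
  first_start <- starts_all[pos]
  ok <- first_start < stops_k & (stops_k - first_start) >= min_aa
  first_start <- first_start[ok]; stops_k <- stops_k[ok]
  if (!length(first_start)) return(NULL)

  out <- vector("list", length(first_start))
  for (i in seq_along(first_start)) {
    cs <- first_start[i]; ce <- stops_k[i] # codon indices, stop included
    nt_start <- offset + (cs - 1L) * 3L    # 0-based on the scanned strand
    nt_end <- offset + ce * 3L
    if (strand == "+") { fs <- nt_start; fe <- nt_end }
    else { fs <- L - nt_end; fe <- L - nt_start } # forward-strand coords
    out[[i]] <- data.frame(
      contig = seq_id, start = fs, end = fe, strand = strand, frame = frame,
      protein = paste(aa[cs:(ce - 1L)], collapse = ""),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call open reading frames
#'
#' Reports all maximal ORFs (first ATG/GTG/TTG after the previous in-frame
#' stop, through the stop codon) of at least `min_aa` residues on all six
#' frames, bacterial genetic code 11. Coordinates are 0-based half-open on
#' the forward strand and include the stop codon. Circular sequences are
#' scanned across the origin on the doubled sequence; a wrapped ORF has
#' `start < length <= end`.
#'
#' @param seqs named character vector of contig sequences (or one sequence).
#' @param min_aa minimum ORF length in residues, excluding the stop
#'   (default 100; must be >= 10).
#' @param circular scan across the origin?
#' @return data.frame `contig, start, end, strand, frame, protein`.
#' @export
find_orfs <- function(seqs, min_aa = 100L, circular = FALSE) {
  if (min_aa < 10L) stop("min_aa must be >= 10")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  res <- list()
  for (id in names(seqs)) {
    s <- toupper(seqs[[id]])
    L0 <- nchar(s)
    scan <- if (circular) paste0(s, s) else s
    L <- nchar(scan)
    rc <- revcomp(scan)
    for (strand in c("+", "-")) {
      src <- if (strand == "+") scan else rc
      for (f in 0:2) {
        n_codon <- (nchar(src) - f) %/% 3L
        if (n_codon < 1L) next
        st <- f + seq.int(1L, by = 3L, length.out = n_codon)
        codons <- substring(src, st, st + 2L)
        o <- orfs_one_frame(id, codons, f, L, strand, f + 1L, min_aa, L0)
        if (!is.null(o)) res[[length(res) + 1L]] <- o
      }
    }
  }
  if (!length(res)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, res)
  if (circular) {
    # map to [0, L0) starts and drop duplicates from the doubled scan
    L0s <- nchar(seqs)[orfs$contig]
    shift <- ifelse(orfs$start >= L0s, L0s, 0L)
    orfs$start <- orfs$start - shift
    orfs$end <- orfs$end - shift
    keep <- orfs$start < L0s & orfs$end <= 2L * L0s &
      (orfs$end - orfs$start) <= L0s
    orfs <- orfs[keep, , drop = FALSE]
    orfs <- orfs[!duplicated(orfs[c("contig", "start", "end", "strand")]), ,
                 drop = FALSE]
  }
  orfs <- orfs[order(orfs$contig, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs$orf_id <- sprintf("%s_orf_%04d", orfs$contig, seq_len(nrow(orfs)))
  orfs[c("orf_id", "contig", "start", "end", "strand", "frame", "protein")]
}

#' Count marker hits among bin proteins
#'
#' A bin protein counts for marker `m` iff `m` is the protein's best-scoring
#' marker and the BSR of the protein against `m` is at least `bsr_min`.
#'
#' @param proteins character vector of bin protein sequences.
#' @param marker_set named character vector of marker proteins.
#' @param scheme protein [scoring_scheme()].
#' @param bsr_min BSR threshold (default 0.4).
#' @return named integer vector of per-marker hit counts.
#' @export
score_markers <- function(proteins, marker_set,
                          scheme = scoring_scheme("protein"), bsr_min = 0.4) {
  if (!length(marker_set)) stop("marker set must be non-empty")
  if (anyDuplicated(names(marker_set))) stop("marker ids must be unique")
  counts <- setNames(integer(length(marker_set)), names(marker_set))
  if (!length(proteins)) return(counts)
  proteins <- toupper(proteins)
  score <- matrix(0L, length(proteins), length(marker_set))
  for (j in seq_along(marker_set))
    score[, j] <- cpp_sw_score_batch(proteins, toupper(marker_set[[j]]),
                                     scheme$lut, scheme$gap_open, scheme$gap_extend)
  self <- cpp_self_scores(proteins, scheme$lut)
  best <- max.col(score, ties.method = "first")
  bsr_best <- score[cbind(seq_along(proteins), best)] / pmax(self, 1L)
  hit <- self > 0L & bsr_best >= bsr_min
  tab <- table(factor(names(marker_set)[best[hit]], levels = names(marker_set)))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Completeness, contamination and MIMAG tier of a bin
#'
#' Completeness is the percentage of markers found at least once (multi-copy
#' markers count as present, CheckM-like); contamination is the percentage
#' found in two or more copies. Both are reported to 2 decimals, rounding
#' half away from zero. The MIMAG tier is `high` iff completeness > 90,
#' contamination < 5, all three rRNAs present and at least 18 tRNAs;
#' `medium` iff completeness >= 50 and contamination < 10; else `low`.
#'
#' @param counts named integer vector of per-marker hit counts covering the
#'   whole marker set (from [score_markers()]).
#' @param marker_set the marker set the counts refer to.
#' @param rrna named logical vector `c("5S"=,"16S"=,"23S"=)`.
#' @param trna_count number of tRNAs (supplied by external annotation;
#'   default 0, which blocks the high tier).
#' @param bin optional [build_bin()] object whose assembly statistics are
#'   carried into the report.
#' @return an object of class `quality_report`.
#' @export
completeness_report <- function(counts, marker_set,
                                rrna = c("5S" = FALSE, "16S" = FALSE, "23S" = FALSE),
                                trna_count = 0L, bin = NULL) {
  ids <- names(marker_set)
  if (!all(ids %in% names(counts)))
    stop("counts must cover every marker in the set")
  counts <- counts[ids]
  n <- length(ids)
  found_single <- ids[counts == 1L]
  found_multi <- ids[counts >= 2L]
  missing <- ids[counts == 0L]
  completeness <- round_half_away(100 * (length(found_single) + length(found_multi)) / n, 2L)
  contamination <- round_half_away(100 * length(found_multi) / n, 2L)
  rrna <- rrna[c("5S", "16S", "23S")]
  tier <- if (completeness > 90 && contamination < 5 &&
              all(rrna) && trna_count >= 18L) {
    "high"
  } else if (completeness >= 50 && contamination < 10) {
    "medium"
  } else "low"
  structure(list(found_single = found_single, found_multi = found_multi,
                 missing = missing, n_markers = n,
                 completeness = completeness, contamination = contamination,
                 rrna = as.list(rrna), trna_count = as.integer(trna_count),
                 tier = tier,
                 bin_stats = if (is.null(bin)) NULL else
                   bin[c("bin_id", "total_length", "n_contigs",
                         "largest_contig", "N50", "circular")]),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> completeness %.2f%%, contamination %.2f%%, tier %s\n",
              x$completeness, x$contamination, x$tier))
  cat(sprintf("  markers: %d single, %d multi, %d missing of %d; rRNA %s; tRNAs %d\n",
              length(x$found_single), length(x$found_multi),
              length(x$missing), x$n_markers,
              paste(names(which(unlist(x$rrna))), collapse = ","),
              x$trna_count))
  invisible(x)
}

#' Detect rRNA genes in a bin
#'
#' Each reference rRNA (ids `5S`, `16S`, `23S`) is searched against every
#' bin contig; the flag is true iff some hit reaches identity at least
#' `min_identity` over at least `min_cov` of the reference length.
#'
#' @param bin_seqs named character vector of bin contig sequences.
#' @param rrna_refs named character vector with elements `5S`, `16S`, `23S`.
#' @param scheme nucleotide [scoring_scheme()].
#' @param min_identity identity floor (default 0.80).
#' @param min_cov reference-length coverage floor (default 0.80).
#' @param k seed length.
#' @return named logical vector (`5S`, `16S`, `23S`).
#' @export
detect_rrna <- function(bin_seqs, rrna_refs, scheme = scoring_scheme(),
                        min_identity = 0.80, min_cov = 0.80, k = 13L) {
  need <- c("5S", "16S", "23S")
  if (!all(need %in% names(rrna_refs)))
    stop("rrna_refs must contain genes named '5S', '16S' and '23S'")
  flags <- setNames(rep(FALSE, 3L), need)
  for (g in need) {
    ref <- rrna_refs[[g]]
    for (contig in bin_seqs) {
      h <- seeded_map(setNames(ref, g), contig, k = k, scheme = scheme,
                      refine_max_len = 2000L)
      if (nrow(h) && any(h$identity >= min_identity &
                           h$columns >= min_cov * nchar(ref))) {
        flags[g] <- TRUE
        break
      }
    }
  }
  flags
}

#' Assign a species from a 16S sequence
#'
#' Returns the taxonomy of the best-scoring reference iff its identity is
#' strictly above `min_identity` (default 0.987); otherwise
#' `"unclassified"`. Ties are broken by identity, then lexicographic
#' reference id.
#'
#' @param query_16s query 16S sequence.
#' @param ref_db named character vector of reference 16S sequences.
#' @param taxonomy named character vector mapping reference ids to taxa
#'   (defaults to the reference ids themselves).
#' @param scheme nucleotide [scoring_scheme()].
#' @param min_identity strict identity threshold.
#' @return list with `taxon`, `ref_id`, `identity`, `score`.
#' @export
assign_species <- function(query_16s, ref_db,
                           taxonomy = setNames(names(ref_db), names(ref_db)),
                           scheme = scoring_scheme(), min_identity = 0.987) {
  if (!length(ref_db)) stop("reference 16S database is empty")
  if (!nzchar(query_16s)) stop("query must be non-empty")
  hits <- lapply(names(ref_db), function(rid)
    smith_waterman(query_16s, ref_db[[rid]], scheme, ref_id = rid))
  score <- vapply(hits, `[[`, 0L, "score")
  ident <- vapply(hits, `[[`, 0, "identity")
  ids <- names(ref_db)
  ord <- order(-score, -ident, ids)
  best <- hits[[ord[1L]]]
  assigned <- best$identity > min_identity
  list(taxon = if (assigned) unname(taxonomy[[best$ref_id]]) else "unclassified",
       ref_id = best$ref_id, identity = best$identity, score = best$score)
}
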