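# Sequential marker-gene triage of read sets with the BLAST Score Ratio
# (BSR). Datasets are screened first for tlcA (ATP/ADP translocase); only
# datasets whose estimated tlcA coverage clears the gate are screened for
# nosZ (nitrous oxide reductase). The gate reproduces the "marker coverage
# above 5" dataset-selection funnel.

# codon-index -> amino-acid table for the C++ translator, derived from the
# same genetic code used everywhere else
code64_cache <- new.env(parent = emptyenv())
code64 <- function() {
  if (is.null(code64_cache$v)) {
    gc <- genetic_code_11()
    bases <- DNA_BASES
    # index order 16*b1 + 4*b2 + b3: first base varies slowest
    codons <- sapply(0:63, function(i)
      paste0(bases[i %/% 16 + 1], bases[(i %/% 4) %% 4 + 1], bases[i %% 4 + 1]))
    code64_cache$v <- paste(gc[codons], collapse = "")
  }
  code64_cache$v
}

# vectorized frame translation (offset 0..2) of many reads
translate_many <- function(reads, offset = 0L) {
  cpp_translate_many(reads, as.integer(offset), code64())
}

# six-frame translations of a read set, cached so sequential screening
# stages translate only once
six_frame_batch <- function(reads) {
  rc <- cpp_revcomp_many(reads)
  lapply(FRAME_ORDER, function(f)
    translate_many(if (f > 0) reads else rc, abs(f) - 1L))
}

# per-read protein-space BSR against one marker: for each of the six frame
# translations, raw = best local score vs the marker and self = the frame's
# self-alignment score; the frame with the highest raw/self ratio is kept.
# Pairing raw and self within a frame guarantees bsr <= 1 and bsr = 1 for an
# exact reverse-translated marker fragment.
bsr_batch <- function(reads, marker, scheme, frames = NULL) {
  n <- length(reads)
  best_bsr <- rep(0, n); best_raw <- rep(0L, n); best_self <- rep(NA_integer_, n)
  best_frame <- rep(NA_integer_, n)
  if (is.null(frames)) frames <- six_frame_batch(reads)
  for (i in seq_along(FRAME_ORDER)) {
    f <- FRAME_ORDER[i]
    prot <- frames[[i]]
    ok <- nzchar(prot)
    if (!any(ok)) next
    raw <- integer(n); self <- integer(n)
    raw[ok] <- cpp_sw_score_batch(prot[ok], marker, scheme$lut,
                                  scheme$gap_open, scheme$gap_extend)
    self[ok] <- cpp_self_scores(prot[ok], scheme$lut)
    usable <- ok & self > 0L
    b <- ifelse(usable, raw / pmax(self, 1L), 0)
    take <- b > best_bsr | (is.na(best_frame) & usable)
    best_bsr[take] <- b[take]; best_raw[take] <- raw[take]
    best_self[take] <- self[take]; best_frame[take] <- f
  }
  data.frame(raw_score = best_raw, self_score = best_self,
             bsr = best_bsr, frame = best_frame)
}

#' BLAST Score Ratio of a read against a marker
#'
#' The BSR is the read's best local alignment score against the marker
#' divided by the read's self-alignment score, a length-normalized
#' similarity in `[0, 1]` under a diagonal-dominant scheme. In protein mode
#' the read is translated in six frames; raw and self scores are paired
#' within each frame and the best ratio is reported.
#'
#' @param read nucleotide read (protein mode) or sequence in the scheme
#'   alphabet (nucleotide mode).
#' @param marker marker sequence (protein in protein mode).
#' @param scheme a [scoring_scheme()]; default protein/BLOSUM62.
#' @param query_id,marker_id identifiers carried into the record.
#' @return an object of class `bsr_record` with fields `query_id, marker_id,
#'   raw_score, self_score, bsr` (and `frame` in protein mode).
#' @export
bsr <- function(read, marker, scheme = scoring_scheme("protein"),
                query_id = NA_character_, marker_id = NA_character_) {
  if (!nzchar(read) || !nzchar(marker)) stop("read and marker must be non-empty")
  if (scheme$mode == "protein") {
    r <- bsr_batch(toupper(read), toupper(marker), scheme)
    if (is.na(r$frame[1]) || is.na(r$self_score[1]) || r$self_score[1] <= 0)
      stop("degenerate read: zero self-alignment score in every frame")
    rec <- list(query_id = query_id, marker_id = marker_id,
                raw_score = r$raw_score[1], self_score = r$self_score[1],
                bsr = r$bsr[1], frame = r$frame[1])
  } else {
    raw <- smith_waterman(read, marker, scheme)$score
    self <- self_score(read, scheme)
    if (self <= 0) stop("degenerate read: zero self-alignment score")
    rec <- list(query_id = query_id, marker_id = marker_id,
                raw_score = raw, self_score = self,
                bsr = raw / self, frame = NA_integer_)
  }
  structure(rec, class = "bsr_record")
}

#' @export
print.bsr_record <- function(x, ...) {
  cat(sprintf("<bsr_record> raw %d / self %d = %.3f\n",
              x$raw_score, x$self_score, x$bsr))
  invisible(x)
}

#' Estimate marker coverage from passing reads
#'
#' Coverage (fold) is the total length of reads passing the BSR threshold
#' divided by the marker's nucleotide length (3x its protein length for
#' protein markers).
#'
#' @param n_passing number of reads passing the threshold.
#' @param marker_nt_length marker length in nucleotides (> 0).
#' @param read_length read length in bases.
#' @return coverage as a fold value; 0 when no reads pass.
#' @export
estimate_marker_coverage <- function(n_passing, marker_nt_length, read_length) {
  if (marker_nt_length <= 0) stop("marker_nt_length must be > 0")
  (n_passing * read_length) / marker_nt_length
}

#' Sequentially screen a read set for symbiont markers
#'
#' Stage 1 computes the BSR of every read against `tlcA` and estimates the
#' marker's coverage from the passing reads; if that coverage does not
#' exceed `coverage_min` the dataset fails stage 1 and stage 2 is never
#' evaluated. Otherwise stage 2 repeats the computation for `nosZ`; the
#' dataset passes only when both coverages are strictly above
#' `coverage_min` (default 5).
#'
#' @param reads character vector of nucleotide reads.
#' @param marker_db named character vector of marker proteins; must contain
#'   `tlcA` and `nosZ`.
#' @param bsr_min BSR threshold for a read to count as a marker hit
#'   (default 0.4).
#' @param coverage_min marker coverage gate, strict (default 5).
#' @param scheme protein [scoring_scheme()].
#' @param dataset_id label carried into the report.
#' @param pooled if `TRUE`, the final gate uses reads and lengths pooled
#'   over both markers instead of per-marker coverages.
#' @return an object of class `screen_report`.
#' @export
screen_dataset <- function(reads, marker_db, bsr_min = 0.4, coverage_min = 5,
                           scheme = scoring_scheme("protein"),
                           dataset_id = "dataset", pooled = FALSE) {
  need <- c("tlcA", "nosZ")
  if (!all(need %in% names(marker_db)))
    stop("marker_db must contain markers named 'tlcA' and 'nosZ'")
  read_length <- if (length(reads)) stats::median(nchar(reads)) else 0
  reads <- toupper(reads)
  frames <- if (length(reads)) six_frame_batch(reads) else NULL

  stage <- function(marker_name) {
    marker <- toupper(marker_db[[marker_name]])
    nt_len <- 3L * nchar(marker)
    if (!length(reads))
      return(list(n_hits = 0L, coverage = 0, nt_len = nt_len, scored = 0L))
    b <- bsr_batch(reads, marker, scheme, frames = frames)
    n_hits <- sum(b$bsr >= bsr_min)
    list(n_hits = n_hits,
         coverage = estimate_marker_coverage(n_hits, nt_len, read_length),
         nt_len = nt_len, scored = length(reads))
  }

  s1 <- stage("tlcA")
  s2 <- NULL
  if (s1$coverage > coverage_min) {
    s2 <- stage("nosZ")
    if (pooled) {
      pooled_cov <- estimate_marker_coverage(
        s1$n_hits + s2$n_hits, s1$nt_len + s2$nt_len, read_length)
      verdict <- if (pooled_cov > coverage_min) "pass" else "fail_stage2"
    } else {
      verdict <- if (s2$coverage > coverage_min) "pass" else "fail_stage2"
    }
  } else {
    verdict <- "fail_stage1"
  }

  structure(list(
    dataset_id = dataset_id,
    stage1_marker = "tlcA", stage2_marker = "nosZ",
    n_reads = length(reads), read_length = read_length,
    stage1_hits = s1$n_hits, stage1_coverage = s1$coverage,
    stage2_hits = if (is.null(s2)) NA_integer_ else s2$n_hits,
    stage2_coverage = if (is.null(s2)) NA_real_ else s2$coverage,
    stage2_reads_scored = if (is.null(s2)) 0L else s2$scored,
    bsr_min = bsr_min, coverage_min = coverage_min,
    verdict = verdict), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s: %s\n", x$dataset_id, x$verdict))
  cat(sprintf("  stage 1 (tlcA): %d hits, coverage %.2f\n",
              x$stage1_hits, x$stage1_coverage))
  if (!is.na(x$stage2_hits))
    cat(sprintf("  stage 2 (nosZ): %d hits, coverage %.2f\n",
                x$stage2_hits, x$stage2_coverage))
  else cat("  stage 2 (nosZ): not evaluated\n")
  invisible(x)
}
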