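# Reference-guided recovery of symbiont bins: contigs aligning to a known
# complete genome are recruited under a strict >3 kb length rule, assembled
# into a bin with MIMAG-style assembly statistics, checked for circularity
# by terminal exact repeat, and audited for conserved gene order (synteny)
# to flag putative binning errors.

#' Recruitment configuration
#'
#' @param min_contig_len minimum contig length in bases, exclusive
#'   (default 3000: "contigs > 3 kb" read strictly, so a 3000-base contig
#'   is discarded and a 3001-base contig retained).
#' @param min_hit_columns minimum aligned columns of the best hit
#'   (default 1000).
#' @param min_identity minimum identity of the best hit (default 0.80).
#' @param circular_overlap_min minimum terminal repeat length declaring a
#'   single-contig bin circular (default 50).
#' @param circular_overlap_max longest terminal repeat searched for
#'   (default 5000).
#' @return an object of class `recruit_config`.
#' @export
recruit_config <- function(min_contig_len = 3000L, min_hit_columns = 1000L,
                           min_identity = 0.80, circular_overlap_min = 50L,
                           circular_overlap_max = 5000L) {
  stopifnot(min_contig_len > 0, min_hit_columns > 0,
            min_identity > 0, min_identity <= 1,
            circular_overlap_min > 0,
            circular_overlap_max >= circular_overlap_min)
  structure(list(min_contig_len = as.integer(min_contig_len),
                 min_hit_columns = as.integer(min_hit_columns),
                 min_identity = min_identity,
                 circular_overlap_min = as.integer(circular_overlap_min),
                 circular_overlap_max = as.integer(circular_overlap_max)),
            class = "recruit_config")
}

#' Recruit contigs to reference genomes
#'
#' A contig is retained for its best-scoring reference iff its length is
#' strictly greater than `min_contig_len` and its best hit spans at least
#' `min_hit_columns` aligned columns at identity at least `min_identity`.
#' Each contig is assigned to at most one reference (highest score; ties
#' broken by lexicographic reference id), preventing double-binning when
#' references are congeneric.
#'
#' @param contigs named character vector of contig sequences.
#' @param references named character vector of reference genome sequences.
#' @param config a [recruit_config()].
#' @param scheme nucleotide [scoring_scheme()].
#' @param k seed length for the alignment search.
#' @return named list mapping each reference id to the character vector of
#'   retained contig sequences (named by contig id); the underlying hits
#'   are attached as attribute `"hits"`.
#' @export
recruit_contigs <- function(contigs, references, config = recruit_config(),
                            scheme = scoring_scheme(), k = 21L) {
  if (!length(references)) stop("at least one reference genome is required")
  if (is.null(names(references))) stop("references must be named")
  out <- setNames(vector("list", length(references)), names(references))
  if (!length(contigs)) {
    out[] <- list(setNames(character(0), character(0)))
    attr(out, "hits") <- NULL
    return(out)
  }
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_", seq_along(contigs))
  long <- contigs[nchar(contigs) > config$min_contig_len]

  hits <- NULL
  if (length(long)) {
    per_ref <- lapply(names(references), function(rid) {
      h <- seeded_map(long, references[[rid]], k = k, scheme = scheme,
                      circular = FALSE, refine_max_len = 2000L)
      if (nrow(h)) h$ref_id <- rid
      h
    })
    hits <- do.call(rbind, per_ref[vapply(per_ref, nrow, 1L) > 0])
  }
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$columns >= config$min_hit_columns &
                   hits$identity >= config$min_identity, , drop = FALSE]
  }
  if (!is.null(hits) && nrow(hits)) {
    # best reference per contig: highest score, ties lexicographic ref id
    hits <- hits[order(hits$query_id, -hits$score, hits$ref_id), , drop = FALSE]
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]
    for (rid in names(references)) {
      ids <- best$query_id[best$ref_id == rid]
      out[[rid]] <- long[ids]
    }
  }
  for (rid in names(references))
    if (is.null(out[[rid]])) out[[rid]] <- setNames(character(0), character(0))
  attr(out, "hits") <- hits
  out
}

#' Assemble recruited contigs into a bin with assembly statistics
#'
#' @param contigs named character vector of retained contig sequences
#'   (at least one).
#' @param reference_id id of the recruiting reference.
#' @param bin_id bin label.
#' @return an object of class `bin` with `total_length`, `n_contigs`,
#'   `largest_contig` and `N50` (the largest length L such that contigs of
#'   length >= L sum to at least half the total).
#' @export
build_bin <- function(contigs, reference_id = NA_character_, bin_id = "bin_1") {
  if (!length(contigs)) stop("a bin needs at least one contig")
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_", seq_along(contigs))
  lens <- sort(nchar(contigs), decreasing = TRUE)
  total <- sum(lens)
  n50 <- unname(lens[which(cumsum(lens) >= total / 2)[1L]])
  structure(list(bin_id = bin_id, contigs = contigs,
                 best_reference = reference_id,
                 total_length = total, n_contigs = length(contigs),
                 largest_contig = max(lens), N50 = n50,
                 circular = FALSE, circular_overlap = 0L),
            class = "bin")
}

#' @export
print.bin <- function(x, ...) {
  cat(sprintf("<bin> %s: %d contig(s), %d bp, largest %d, N50 %d%s\n",
              x$bin_id, x$n_contigs, x$total_length, x$largest_contig, x$N50,
              if (x$circular) sprintf(", circular (overlap %d)", x$circular_overlap)
              else ""))
  invisible(x)
}

#' Detect circularity by terminal exact repeat
#'
#' A bin is flagged circular iff it consists of a single contig whose prefix
#' of length at least `circular_overlap_min` exactly equals its suffix of
#' the same length (a proxy for a closed assembly-graph loop). The longest
#' such overlap (searched up to `circular_overlap_max`) is reported and the
#' duplicated suffix is trimmed from the stored sequence.
#'
#' @param bin a [build_bin()] object.
#' @param config a [recruit_config()].
#' @return the bin, updated with `circular`, `circular_overlap` and (when
#'   circular) the trimmed single contig and statistics.
#' @export
detect_circularity <- function(bin, config = recruit_config()) {
  stopifnot(inherits(bin, "bin"))
  bin$circular <- FALSE
  bin$circular_overlap <- 0L
  if (bin$n_contigs != 1L) return(bin)
  s <- bin$contigs[[1L]]
  L <- nchar(s)
  cap <- min(config$circular_overlap_max, L %/% 2L)
  if (cap < config$circular_overlap_min) return(bin)
  for (ov in seq.int(cap, config$circular_overlap_min)) {
    if (substr(s, 1L, ov) == substr(s, L - ov + 1L, L)) {
      bin$circular <- TRUE
      bin$circular_overlap <- ov
      trimmed <- substr(s, 1L, L - ov)
      bin$contigs[[1L]] <- trimmed
      bin$total_length <- bin$largest_contig <- bin$N50 <- nchar(trimmed)
      break
    }
  }
  bin
}

# longest strictly increasing subsequence: returns indices of one optimal
# chain (O(n^2), anchor counts are small)
lis_chain <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  chain <- integer(0)
  while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
  chain
}

#' Audit bin-versus-reference gene order (synteny)
#'
#' Anchors bin genes to reference genes by best reciprocal protein hits
#' (BSR at least `bsr_min` in both directions), then measures collinearity
#' as the longest strictly order-preserving anchor chain over reference
#' order (computed for both orientations, the better taken) divided by the
#' number of anchors. Contigs with no anchor on the chosen chain are flagged
#' as putative binning errors.
#'
#' @param bin_genes data.frame with columns `gene`, `protein`, `start` and
#'   optionally `contig` (one row per bin gene, ordered coordinates).
#' @param ref_genes data.frame with columns `gene`, `protein`, `start`.
#' @param scheme protein [scoring_scheme()].
#' @param bsr_min reciprocal-hit BSR threshold (default 0.4).
#' @return an object of class `synteny_audit` with `anchors`,
#'   `collinear_fraction` and `flagged_contigs`.
#' @export
audit_synteny <- function(bin_genes, ref_genes,
                          scheme = scoring_scheme("protein"), bsr_min = 0.4) {
  if (!nrow(bin_genes) || !nrow(ref_genes))
    stop("audit requires genes on both the bin and the reference")
  if (is.null(bin_genes$contig)) bin_genes$contig <- "contig_1"
  bin_genes <- bin_genes[order(bin_genes$contig, bin_genes$start), , drop = FALSE]
  ref_genes <- ref_genes[order(ref_genes$start), , drop = FALSE]
  bp <- toupper(bin_genes$protein); rp <- toupper(ref_genes$protein)

  score <- matrix(0L, nrow(bin_genes), nrow(ref_genes))
  for (j in seq_len(nrow(ref_genes)))
    score[, j] <- cpp_sw_score_batch(bp, rp[j], scheme$lut,
                                     scheme$gap_open, scheme$gap_extend)
  self_b <- cpp_self_scores(bp, scheme$lut)
  self_r <- cpp_self_scores(rp, scheme$lut)

  best_for_bin <- apply(score, 1L, which.max)
  best_for_ref <- apply(score, 2L, which.max)
  anchors <- data.frame(bin_idx = integer(0), ref_idx = integer(0))
  for (i in seq_len(nrow(bin_genes))) {
    j <- best_for_bin[i]
    if (best_for_ref[j] != i) next
    if (score[i, j] / self_b[i] < bsr_min) next
    if (score[i, j] / self_r[j] < bsr_min) next
    anchors <- rbind(anchors, data.frame(bin_idx = i, ref_idx = j))
  }

  if (!nrow(anchors)) {
    return(structure(list(anchors = anchors, collinear_fraction = 0,
                          chain = integer(0),
                          flagged_contigs = unique(bin_genes$contig)),
                     class = "synteny_audit"))
  }
  anchors <- anchors[order(anchors$bin_idx), , drop = FALSE]
  fwd <- lis_chain(anchors$ref_idx)
  rev_ <- lis_chain(-anchors$ref_idx)
  chain <- if (length(fwd) >= length(rev_)) fwd else rev_
  frac <- length(chain) / nrow(anchors)

  on_chain_contigs <- unique(bin_genes$contig[anchors$bin_idx[chain]])
  flagged <- setdiff(unique(bin_genes$contig), on_chain_contigs)

  structure(list(anchors = cbind(anchors,
                                 bin_gene = bin_genes$gene[anchors$bin_idx],
                                 ref_gene = ref_genes$gene[anchors$ref_idx],
                                 contig = bin_genes$contig[anchors$bin_idx]),
                 collinear_fraction = frac, chain = chain,
                 flagged_contigs = flagged),
            class = "synteny_audit")
}

#' @export
print.synteny_audit <- function(x, ...) {
  cat(sprintf("<synteny_audit> %d anchors, collinear fraction %.3f, %d flagged contig(s)\n",
              nrow(x$anchors), x$collinear_fraction, length(x$flagged_contigs)))
  invisible(x)
}
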