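# Local alignment engine: affine-gap Smith-Waterman (Gotoh) in nucleotide or
# translated-protein mode, six-frame translation, and exact k-mer seeded
# mapping. These scores are the substrate of the BSR prescreen, contig
# recruitment, rRNA detection and coverage mapping.

#' Alignment scoring scheme
#'
#' Builds a scoring scheme for local alignment. Nucleotide defaults are
#' BLAST-like (match +2, mismatch -3, gap open 5, gap extend 2); protein
#' mode defaults to BLOSUM62 with gap open 11, extend 1. A gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide match/mismatch scores (`match > 0 > mismatch`).
#' @param gap_open,gap_extend nonnegative affine gap penalties,
#'   `gap_open >= gap_extend >= 0`.
#' @param matrix protein substitution matrix (named square matrix); defaults
#'   to BLOSUM62. Diagonal entries must be row maxima (checked at load).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 2L, mismatch = -3L,
                           gap_open = NULL, gap_extend = NULL,
                           matrix = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    gap_open <- gap_open %||% 5L
    gap_extend <- gap_extend %||% 2L
    if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
    lut <- matrix(0L, 128, 128)
    for (a in DNA_BASES) for (b in DNA_BASES) {
      lut[utf8ToInt(a) + 1L, utf8ToInt(b) + 1L] <-
        if (a == b) as.integer(match) else as.integer(mismatch)
    }
    alphabet <- DNA_BASES
    submat <- NULL
  } else {
    gap_open <- gap_open %||% 11L
    gap_extend <- gap_extend %||% 1L
    if (is.null(matrix)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      matrix <- e$BLOSUM62
    }
    if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
      stop("protein matrix must be square with identical row/col names")
    d <- diag(matrix)
    if (any(d < apply(matrix, 1L, max)))
      stop("protein matrix diagonal entries must be row maxima")
    lut <- matrix(0L, 128, 128)
    chars <- rownames(matrix)
    idx <- utf8ToInt(paste(chars, collapse = "")) + 1L
    lut[idx, idx] <- as.integer(matrix)
    alphabet <- chars
    submat <- matrix
  }
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 matrix = submat, alphabet = alphabet, lut = lut),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme>", x$mode,
      if (x$mode == "nucleotide")
        sprintf("match %d mismatch %d", x$match, x$mismatch)
      else "substitution matrix",
      sprintf("gap %d/%d\n", x$gap_open, x$gap_extend))
  invisible(x)
}

check_alphabet <- function(seq, scheme, what = "sequence") {
  chars <- unique(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, scheme$alphabet)
  if (length(bad))
    stop(what, " contains characters outside the scheme alphabet: ",
         paste(bad, collapse = ","))
  invisible(TRUE)
}

local_hit <- function(query_id = NA_character_, ref_id = NA_character_,
                      qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
                      strand = "+", frame = NA_integer_,
                      score = 0L, identity = 0, columns = 0L, matches = 0L) {
  structure(list(query_id = query_id, ref_id = ref_id,
                 qstart = qstart, qend = qend, sstart = sstart, send = send,
                 strand = strand, frame = frame, score = score,
                 identity = identity, columns = columns, matches = matches),
            class = "local_hit")
}

#' @export
print.local_hit <- function(x, ...) {
  cat(sprintf("<local_hit> score %d  q[%d,%d) s[%d,%d) %s  identity %.3f over %d cols\n",
              x$score, x$qstart, x$qend, x$sstart, x$send,
              if (is.na(x$frame)) x$strand else paste0("frame ", x$frame),
              x$identity, x$columns))
  invisible(x)
}

#' Affine-gap local alignment (Smith-Waterman / Gotoh)
#'
#' Returns the maximum-score local alignment of `query` against `ref`.
#' When no positive-scoring cell exists the hit has score 0 and empty
#' intervals. Coordinates are 0-based half-open. Ties are broken by
#' preferring diagonal, then vertical, then horizontal moves, and by
#' reporting the first maximal cell in row-major order.
#'
#' @param query,ref sequences over the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @param query_id,ref_id optional identifiers carried into the hit.
#' @return a `local_hit`.
#' @export
smith_waterman <- function(query, ref, scheme = scoring_scheme(),
                           query_id = NA_character_, ref_id = NA_character_) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!nzchar(query) || !nzchar(ref)) stop("sequences must be non-empty")
  query <- toupper(query); ref <- toupper(ref)
  check_alphabet(query, scheme, "query")
  check_alphabet(ref, scheme, "ref")
  r <- cpp_sw_align(query, ref, scheme$lut, scheme$gap_open, scheme$gap_extend)
  local_hit(query_id = query_id, ref_id = ref_id,
            qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
            score = r$score, identity = r$identity, columns = r$columns,
            matches = r$matches)
}

# score-only batch interface used by the prescreen and marker scoring
sw_score_batch <- function(queries, ref, scheme) {
  cpp_sw_score_batch(toupper(queries), toupper(ref), scheme$lut,
                     scheme$gap_open, scheme$gap_extend)
}

# best possible self-alignment score of a sequence: sum of diagonal scores
# (exact for diagonal-dominant schemes, where aligning a sequence to itself
# position-by-position is optimal)
self_score <- function(seq, scheme) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- utf8ToInt(paste(chars, collapse = "")) + 1L
  sum(scheme$lut[cbind(idx, idx)])
}

FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' bacterial genetic code (translation table 11). Stops are rendered `*`;
#' trailing partial codons are dropped. Frames `+1,+2,+3` read the forward
#' strand at offsets 0,1,2; `-1,-2,-3` read the reverse complement likewise.
#'
#' @param nt nucleotide sequence of length >= 3.
#' @return named character vector of six proteins
#'   (`"+1","+2","+3","-1","-2","-3"`).
#' @export
translate_six_frames <- function(nt) {
  if (nchar(nt) < 3L) stop("sequence shorter than one codon")
  nt <- toupper(nt)
  rc <- revcomp(nt)
  out <- c(translate_frame(nt, 0L), translate_frame(nt, 1L), translate_frame(nt, 2L),
           translate_frame(rc, 0L), translate_frame(rc, 1L), translate_frame(rc, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Best translated hit of a read against a marker protein
#'
#' Translates the read in six frames and returns the best-scoring local
#' alignment against the marker; ties are broken by the lowest frame index
#' in the order +1, +2, +3, -1, -2, -3.
#'
#' @param read_nt nucleotide read (length >= 3).
#' @param marker_protein amino-acid sequence.
#' @param scheme a protein-mode [scoring_scheme()].
#' @return a `local_hit` with the `frame` field set.
#' @export
translated_best_hit <- function(read_nt, marker_protein,
                                scheme = scoring_scheme("protein")) {
  if (scheme$mode != "protein") stop("scheme must be in protein mode")
  if (nchar(read_nt) < 3L) stop("read shorter than one codon")
  frames <- translate_six_frames(read_nt)
  best <- NULL
  for (i in seq_along(FRAME_ORDER)) {
    p <- frames[[i]]
    if (!nzchar(p)) next
    h <- smith_waterman(p, marker_protein, scheme)
    if (is.null(best) || h$score > best$score) {
      best <- h
      best$frame <- FRAME_ORDER[i]
    }
  }
  if (is.null(best)) best <- local_hit(frame = 1L)
  best
}

#' Seeded read mapping onto a genome
#'
#' Maps reads by exact k-mer seeding followed by ungapped diagonal extension
#' and gapped Smith-Waterman refinement on a bounded window around the seed
#' diagonal. Both strands are searched; hits are reported in forward-strand
#' reference coordinates with a strand flag. Circular genomes are indexed on
#' the doubled sequence; a wrapped hit has `sstart < length <= send`.
#' A reported score never exceeds the full dynamic-programming score for the
#' same pair.
#'
#' @param reads character vector of reads (names used as ids if present).
#' @param genome reference sequence.
#' @param k exact seed length, `8 <= k <= 31` and no longer than the reads.
#' @param scheme nucleotide [scoring_scheme()].
#' @param circular is the genome circular?
#' @param refine_max_len maximum query length for gapped refinement; longer
#'   queries keep the ungapped extension (exact under a substitution-only
#'   error model).
#' @return data.frame with one row per mapped read: `query_id, qstart, qend,
#'   sstart, send, strand, score, identity, columns` (0-based half-open).
#' @export
seeded_map <- function(reads, genome, k = 15L, scheme = scoring_scheme(),
                       circular = FALSE, refine_max_len = 2000L) {
  if (scheme$mode != "nucleotide") stop("seeded_map requires a nucleotide scheme")
  if (k < 8L) stop("seed length k must be >= 8")
  if (length(reads) && any(nchar(reads) < k))
    stop("seed length k exceeds the shortest read")
  ids <- names(reads) %||% as.character(seq_along(reads))
  df <- cpp_seeded_map(toupper(unname(reads)), toupper(genome), as.integer(k),
                       as.integer(scheme$match), as.integer(scheme$mismatch),
                       scheme$gap_open, scheme$gap_extend,
                       isTRUE(circular), as.integer(refine_max_len), TRUE)
  data.frame(query_id = ids[df$query],
             qstart = df$qstart, qend = df$qend,
             sstart = df$sstart, send = df$send,
             strand = ifelse(df$strand > 0, "+", "-"),
             score = df$score, identity = df$identity, columns = df$columns,
             stringsAsFactors = FALSE)
}

#' Write hits in BLAST-like 12-column tabular format
#'
#' Mirrors BLAST `outfmt 6` field order (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) with 1-based inclusive
#' coordinates in this file only; `evalue` is `NA` and `bitscore` carries the
#' raw alignment score.
#'
#' @param hits data.frame from [seeded_map()] (plus a `ref_id` column, or one
#'   is supplied via `ref_id`).
#' @param path output TSV path.
#' @param ref_id subject id used when `hits` lacks a `ref_id` column.
#' @export
write_hits_tsv <- function(hits, path, ref_id = "ref") {
  sid <- if ("ref_id" %in% names(hits)) hits$ref_id else rep(ref_id, nrow(hits))
  out <- data.frame(
    qseqid = hits$query_id, sseqid = sid,
    pident = round_half_away(100 * hits$identity, 2L),
    length = hits$columns,
    mismatch = hits$columns - round(hits$identity * hits$columns),
    gapopen = NA_integer_,
    qstart = hits$qstart + 1L, qend = hits$qend,
    sstart = hits$sstart + 1L, send = hits$send,
    evalue = NA, bitscore = hits$score,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
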