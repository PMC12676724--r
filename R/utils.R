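# Shared sequence helpers. All internal coordinates are 0-based half-open;
# 1-based inclusive coordinates appear only in the BLAST-like TSV and GFF3
# interfaces.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param seq character scalar over A/C/G/T.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTacgt", "TGCAtgca", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# bacterial/archaeal genetic code (NCBI translation table 11)
genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

# codon -> amino acid translation of one frame, trailing partial codon dropped
translate_frame <- function(seq, offset = 0L) {
  n <- nchar(seq)
  usable <- n - offset
  n_codon <- usable %/% 3L
  if (n_codon < 1L) return("")
  starts <- offset + seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(seq, starts, starts + 2L)
  gc <- genetic_code_11()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# synonymous codon list per amino acid, for seeded reverse translation
codons_by_aa <- function() {
  gc <- genetic_code_11()
  split(names(gc), gc)
}

# reverse-translate a protein to DNA, sampling synonymous codons with the
# current RNG state; optionally append a stop codon
reverse_translate <- function(protein, add_stop = TRUE) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  tab <- codons_by_aa()
  bad <- setdiff(aa, names(tab))
  bad <- setdiff(bad, "*")
  if (length(bad)) stop("cannot reverse-translate residues: ", paste(bad, collapse = ","))
  codons <- vapply(aa, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  if (add_stop) {
    stops <- tab[["*"]]
    codons <- c(codons, stops[sample.int(length(stops), 1L)])
  }
  paste(codons, collapse = "")
}

# round half away from zero to `digits` decimals (matches printed percentages)
round_half_away <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# random DNA of length n from the current RNG state
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# random protein (no stops) starting with methionine
random_protein <- function(n_aa) {
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  body <- sample(aa20, n_aa - 1L, replace = TRUE)
  paste(c("M", body), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty character scalar")
}
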