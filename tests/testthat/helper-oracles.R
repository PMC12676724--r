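# Independent oracles used across the suite. These deliberately re-derive
# results by brute force, separately from the package's own code paths.

# full Gotoh local-alignment score in pure R: three explicit matrices,
# gap of length L costs open + L*ext
sw_oracle <- function(q, s, scheme) {
  lut <- scheme$lut
  qi <- utf8ToInt(q) + 1L
  si <- utf8ToInt(s) + 1L
  n <- length(qi); m <- length(si)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F <- matrix(NEG, n + 1L, m + 1L)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - go - ge, E[i, j - 1L] - ge)
      F[i, j] <- max(H[i - 1L, j] - go - ge, F[i - 1L, j] - ge)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + lut[qi[i - 1L], si[j - 1L]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# brute-force longest strictly monotone subsequence over all subsequences
lis_oracle <- function(x) {
  n <- length(x)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0) || all(diff(v) < 0)) best <- length(idx)
  }
  best
}

# high-precision 1 - exp(-k*d) via scaling-and-squaring of a short Taylor
# series at a tiny argument (method error far below double precision)
expected_breadth_oracle <- function(d, k = 0.883) {
  x <- -k * d / 1024
  term <- 1; acc <- 1
  for (i in 1:25) {
    term <- term * x / i
    acc <- acc + term
  }
  for (i in 1:10) acc <- acc * acc
  1 - acc
}

# independent reverse translation: first codon per residue in the
# Biostrings table for genetic code 11 (no stop appended)
reverse_translate_test <- function(protein) {
  gc <- Biostrings::getGeneticCode("11")
  first <- vapply(split(names(gc), gc), `[`, "", 1L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(first[aa], collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_aa <- function(n) {
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa20, n, TRUE), collapse = "")
}

# plant a given number of substitutions at interior positions (>= 3 from
# either end, pairwise spaced) so a local alignment cannot trim them away
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- alt[1L]
  }
  paste(chars, collapse = "")
}

# small reusable synthetic world for cross-module tests
tiny_world <- function(n_markers = 8L, genome_length = 40000L, seed = 42L) {
  catalog <- default_marker_catalog(n_markers = n_markers, seed = seed,
                                    screen_len = 300L)
  genome <- generate_symbiont_genome(catalog, genome_length = genome_length,
                                     seed = seed)
  list(catalog = catalog, genome = genome)
}
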