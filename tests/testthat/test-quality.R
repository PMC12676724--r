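# Quality module: ORF recovery at ground-truth coordinates, marker
# counting, the completeness/contamination formulas with their printed
# worked examples, MIMAG tiers, rRNA detection and species assignment.

test_that("find_orfs handles minimal constructions", {
  # M + 10 lysines, then stop: one ORF at min_aa 10
  seq1 <- paste0("CCC", "ATG", strrep("AAA", 10), "TAG", "CCC")
  o <- find_orfs(c(s = seq1), min_aa = 10)
  fwd <- o[o$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$protein, paste0("M", strrep("K", 10)))
  expect_equal(c(fwd$start, fwd$end), c(3L, 3L + 36L))

  # no start codon anywhere: nothing
  no_start <- strrep("CCT", 30)
  expect_equal(nrow(find_orfs(c(s = no_start), min_aa = 10)), 0L)
  expect_error(find_orfs(c(s = seq1), min_aa = 5), "min_aa")
})

test_that("find_orfs recovers every planted gene at its ground-truth coordinates", {
  w <- tiny_world()
  orfs <- find_orfs(c(genome = w$genome$sequence), min_aa = 100,
                    circular = TRUE)
  found <- paste(orfs$start, orfs$end, orfs$strand)
  want <- paste(w$genome$genes$start, w$genome$genes$end, "+")
  expect_true(all(want %in% found))
  # and the recovered proteins equal the catalog entries
  m <- match(want, found)
  expect_equal(unname(orfs$protein[m]), unname(w$catalog))
})

test_that("score_markers counts single and duplicated markers", {
  set.seed(51)
  markers <- setNames(vapply(1:8, function(i) rand_aa(100), ""),
                      paste0("m", 1:8))
  counts <- score_markers(unname(markers), markers)
  expect_equal(unname(counts), rep(1L, 8))

  dup <- c(unname(markers), markers[["m3"]])
  counts2 <- score_markers(dup, markers)
  expect_equal(unname(counts2[c("m3")]), 2L)
  expect_equal(unname(counts2[setdiff(names(markers), "m3")]), rep(1L, 7))

  some <- score_markers(unname(markers[1:3]), markers)
  expect_equal(unname(some), c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))

  # permutation invariance
  perm <- sample(8)
  expect_equal(score_markers(unname(markers)[perm], markers), counts)
})

test_that("completeness reproduces the printed worked examples", {
  markers <- setNames(replicate(55, rand_aa(50)), sprintf("m%02d", 1:55))
  mk_counts <- function(n_single, n_multi = 0) {
    counts <- setNames(integer(55), names(markers))
    if (n_single > 0) counts[seq_len(n_single)] <- 1L
    if (n_multi > 0) counts[n_single + seq_len(n_multi)] <- 2L
    counts
  }
  r30 <- completeness_report(mk_counts(30), markers)
  expect_identical(r30$completeness, 54.55)
  r49 <- completeness_report(mk_counts(49), markers)
  expect_identical(r49$completeness, 89.09)

  all2 <- completeness_report(mk_counts(0, 55), markers)
  expect_identical(all2$completeness, 100)
  expect_identical(all2$contamination, 100)
  expect_equal(all2$tier, "low")
})

test_that("completeness sweep is exact for every m in 0..N", {
  n <- 55L
  markers <- setNames(replicate(n, rand_aa(40)), sprintf("m%02d", 1:n))
  for (m in 0:n) {
    counts <- setNames(c(rep(1L, m), rep(0L, n - m)), names(markers))
    rep_ <- completeness_report(counts, markers)
    want <- sign(m) * floor(abs(100 * m / n) * 100 + 0.5) / 100
    expect_identical(rep_$completeness, want)
    expect_identical(rep_$contamination, 0)
  }
})

test_that("MIMAG tier boundaries behave as specified", {
  markers <- setNames(replicate(100, rand_aa(30)), sprintf("m%03d", 1:100))
  counts_n <- function(n_single, n_multi = 0) {
    counts <- setNames(integer(100), names(markers))
    counts[seq_len(n_single)] <- 1L
    if (n_multi) counts[n_single + seq_len(n_multi)] <- 2L
    counts
  }
  rrna_all <- c("5S" = TRUE, "16S" = TRUE, "23S" = TRUE)

  # completeness 91, contamination 0, everything else satisfied -> high
  expect_equal(completeness_report(counts_n(91), markers, rrna_all, 18)$tier,
               "high")
  # completeness exactly 90 is not > 90 -> medium
  expect_equal(completeness_report(counts_n(90), markers, rrna_all, 18)$tier,
               "medium")
  # missing rRNA blocks high
  expect_equal(completeness_report(counts_n(91), markers,
                                   c("5S" = TRUE, "16S" = FALSE, "23S" = TRUE),
                                   18)$tier, "medium")
  # too few tRNAs blocks high (default 0)
  expect_equal(completeness_report(counts_n(91), markers, rrna_all)$tier,
               "medium")
  # contamination 5 is not < 5 -> medium
  expect_equal(completeness_report(counts_n(86, 5), markers, rrna_all, 18)$tier,
               "medium")
  # completeness exactly 50 -> medium; 49 -> low
  expect_equal(completeness_report(counts_n(50), markers)$tier, "medium")
  expect_equal(completeness_report(counts_n(49), markers)$tier, "low")
  # contamination 10 is not < 10 -> low
  expect_equal(completeness_report(counts_n(50, 10), markers)$tier, "low")
})

test_that("raising completeness never lowers the tier", {
  markers <- setNames(replicate(20, rand_aa(30)), sprintf("m%02d", 1:20))
  rrna_all <- c("5S" = TRUE, "16S" = TRUE, "23S" = TRUE)
  rank <- c(low = 1L, medium = 2L, high = 3L)
  prev <- 0L
  for (m in 0:20) {
    counts <- setNames(c(rep(1L, m), rep(0L, 20 - m)), names(markers))
    tier <- completeness_report(counts, markers, rrna_all, 18)$tier
    expect_gte(rank[[tier]], prev)
    prev <- rank[[tier]]
  }
})

test_that("rRNA detection respects identity and coverage floors", {
  set.seed(61)
  refs <- c("5S" = rand_dna(120), "16S" = rand_dna(1500), "23S" = rand_dna(2900))
  flank <- rand_dna(2000)
  bin <- c(c1 = paste0(flank, refs[["16S"]], rand_dna(1000)))
  flags <- detect_rrna(bin, refs)
  expect_true(flags[["16S"]])
  expect_false(flags[["5S"]])
  expect_false(flags[["23S"]])

  none <- detect_rrna(c(c1 = rand_dna(5000)), refs)
  expect_false(any(none))

  div10 <- as.character(derive_species(refs[["16S"]], 0.10, seed = 3))
  div30 <- as.character(derive_species(refs[["16S"]], 0.30, seed = 3))
  f10 <- detect_rrna(c(c1 = paste0(flank, div10)), refs)
  f30 <- detect_rrna(c(c1 = paste0(flank, div30)), refs)
  expect_true(f10[["16S"]])
  expect_false(f30[["16S"]])

  expect_error(detect_rrna(bin, refs[c("5S", "16S")]), "23S")
})

test_that("species assignment applies the strict 98.7% identity rule", {
  set.seed(71)
  db <- c(sp_a = rand_dna(1000), sp_b = rand_dna(1000))
  taxonomy <- c(sp_a = "midas_s_0001", sp_b = "midas_s_0002")

  exact <- assign_species(db[["sp_a"]], db, taxonomy)
  expect_equal(exact$taxon, "midas_s_0001")
  expect_equal(exact$identity, 1.0)

  # exactly 13 interior substitutions in 1000 nt = 98.70%: not above 98.7%
  q13 <- substitute_at(db[["sp_a"]], seq(50, by = 70, length.out = 13))
  r13 <- assign_species(q13, db, taxonomy)
  expect_equal(r13$identity, 0.987)
  expect_equal(r13$taxon, "unclassified")

  q50 <- substitute_at(db[["sp_a"]], seq(10, by = 19, length.out = 50))
  expect_equal(assign_species(q50, db, taxonomy)$taxon, "unclassified")

  expect_error(assign_species(db[["sp_a"]], character(0)), "empty")
})
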