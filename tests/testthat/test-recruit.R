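# Recruitment: the strict >3 kb boundary, ground-truth recovery against a
# background, N50 arithmetic, terminal-repeat circularity, synteny audit
# against an exhaustive LIS oracle.

test_that("the >3 kb rule is strict at the boundary", {
  w <- tiny_world()
  ref <- c(refA = w$genome$sequence)
  contigs <- c(keep = substr(w$genome$sequence, 1001, 1000 + 3001),
               drop = substr(w$genome$sequence, 5001, 5000 + 3000))
  rec <- recruit_contigs(contigs, ref)
  expect_equal(names(rec$refA), "keep")
})

test_that("unrelated contigs are never recruited", {
  w <- tiny_world()
  set.seed(5)
  junk <- setNames(vapply(1:3, function(i) rand_dna(8000), ""),
                   paste0("junk", 1:3))
  rec <- recruit_contigs(junk, c(refA = w$genome$sequence))
  expect_length(rec$refA, 0L)
  empty <- recruit_contigs(character(0), c(refA = w$genome$sequence))
  expect_length(empty$refA, 0L)
})

test_that("recruitment recovers exactly the true fragments against a background", {
  w <- tiny_world()
  frags <- fragment_genome(w$genome$sequence, 6, min_len = 5000, seed = 7)
  set.seed(8)
  bg <- setNames(vapply(1:20, function(i) rand_dna(sample(4000:9000, 1)), ""),
                 paste0("bg_", sprintf("%02d", 1:20)))
  ref <- derive_species(w$genome$sequence, 0.03, seed = 9) # diverged reference
  rec <- recruit_contigs(c(frags$contigs, bg), c(refA = as.character(ref)))
  expect_setequal(names(rec$refA), names(frags$contigs))
})

test_that("contigs go to their best reference with lexicographic ties", {
  w <- tiny_world()
  near <- derive_species(w$genome$sequence, 0.01, seed = 2)
  far <- derive_species(w$genome$sequence, 0.10, seed = 3)
  contig <- c(c1 = substr(w$genome$sequence, 1, 10000))
  rec <- recruit_contigs(contig, c(zz_near = as.character(near),
                                   aa_far = as.character(far)))
  expect_equal(names(rec$zz_near), "c1") # higher score wins over lexicographic
  expect_length(rec$aa_far, 0L)
})

test_that("build_bin computes N50 and friends correctly", {
  set.seed(4)
  contigs <- setNames(c(rand_dna(100), rand_dna(200), rand_dna(300)),
                      c("a", "b", "c"))
  b <- build_bin(contigs, "ref")
  expect_equal(b$total_length, 600L)
  expect_equal(b$N50, 300L)
  expect_equal(b$largest_contig, 300L)

  one <- build_bin(contigs["c"], "ref")
  expect_equal(one$N50, 300L)
  expect_equal(one$total_length, one$largest_contig)

  two <- build_bin(setNames(c(rand_dna(100), rand_dna(100)), c("a", "b")), "r")
  expect_equal(two$N50, 100L)

  # brute-force oracle: N50 is the largest length L among the contigs such
  # that contigs >= L sum to at least half the total
  for (i in 1:10) {
    lens <- sample(50:500, sample(2:8, 1))
    ctgs <- setNames(vapply(lens, rand_dna, ""), paste0("c", seq_along(lens)))
    want <- max(Filter(function(L) sum(lens[lens >= L]) >= sum(lens) / 2,
                       sort(unique(lens))))
    expect_equal(build_bin(ctgs, "r")$N50, want)
  }
  expect_error(build_bin(character(0), "r"), "at least one")
})

test_that("circularity detection finds planted terminal repeats and nothing else", {
  w <- tiny_world()
  frag <- fragment_genome(w$genome$sequence, 1, circular = TRUE,
                          overlap = 50, seed = 3)
  b <- detect_circularity(build_bin(frag$contigs, "refA"))
  expect_true(b$circular)
  expect_equal(b$circular_overlap, 50L)
  expect_equal(b$total_length, nchar(w$genome$sequence))
  expect_equal(b$contigs[[1]], w$genome$sequence)

  two <- fragment_genome(w$genome$sequence, 2, min_len = 10000, seed = 4)
  b2 <- detect_circularity(build_bin(two$contigs, "refA"))
  expect_false(b2$circular)
})

test_that("circularity is invariant under rotation of the circular genome", {
  w <- tiny_world()
  g <- w$genome$sequence
  L <- nchar(g)
  for (shift in c(1000L, 17000L, L - 500L)) {
    rot <- paste0(substr(g, shift + 1, L), substr(g, 1, shift))
    ctg <- paste0(rot, substr(rot, 1, 50)) # re-add the terminal repeat
    b <- detect_circularity(build_bin(c(c1 = ctg), "refA"))
    expect_true(b$circular)
    expect_equal(b$circular_overlap, 50L)
  }
})

test_that("random linear contigs are not called circular (Monte-Carlo null)", {
  set.seed(9)
  hits <- 0L
  for (i in 1:200) {
    b <- detect_circularity(build_bin(c(c1 = rand_dna(20000)), "r"))
    hits <- hits + b$circular
  }
  expect_equal(hits, 0L)
})

test_that("synteny audit scores collinearity and flags foreign contigs", {
  set.seed(12)
  prots <- vapply(1:10, function(i) rand_aa(80), "")
  ref <- data.frame(gene = paste0("g", 1:10), protein = prots,
                    start = seq(0, by = 1000, length.out = 10))
  bin <- data.frame(gene = paste0("b", 1:10), protein = prots,
                    start = seq(0, by = 900, length.out = 10),
                    contig = "contig_1")
  a <- audit_synteny(bin, ref)
  expect_equal(a$collinear_fraction, 1.0)
  expect_length(a$flagged_contigs, 0L)

  foreign <- data.frame(gene = c("x1", "x2"),
                        protein = vapply(1:2, function(i) rand_aa(80), ""),
                        start = c(0, 500), contig = "contig_alien")
  a2 <- audit_synteny(rbind(bin, foreign), ref)
  expect_true("contig_alien" %in% a2$flagged_contigs)
  expect_false("contig_1" %in% a2$flagged_contigs)

  expect_error(audit_synteny(bin[0, ], ref), "both")
})

test_that("collinear fraction equals the exhaustive LIS oracle on permutations", {
  set.seed(14)
  prots <- vapply(1:12, function(i) rand_aa(60), "")
  ref <- data.frame(gene = paste0("g", 1:12), protein = prots,
                    start = seq(0, by = 500, length.out = 12))
  for (trial in 1:5) {
    perm <- sample(12)
    bin <- data.frame(gene = paste0("b", 1:12), protein = prots[perm],
                      start = seq(0, by = 500, length.out = 12),
                      contig = "c1")
    a <- audit_synteny(bin, ref)
    expect_equal(a$collinear_fraction, lis_oracle(perm) / 12,
                 info = paste("perm", paste(perm, collapse = ",")))
  }
})

test_that("collinear fraction is orientation-aware (reverse complement invariant)", {
  set.seed(15)
  prots <- vapply(1:8, function(i) rand_aa(70), "")
  ref <- data.frame(gene = paste0("g", 1:8), protein = prots,
                    start = seq(0, by = 400, length.out = 8))
  bin_rev <- data.frame(gene = paste0("b", 1:8), protein = rev(prots),
                        start = seq(0, by = 400, length.out = 8),
                        contig = "c1")
  expect_equal(audit_synteny(bin_rev, ref)$collinear_fraction, 1.0)
})
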