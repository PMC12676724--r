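# I/O, configuration and the end-to-end funnel: format round-trips, parse
# errors with line numbers, YAML config losslessness, report round-trips,
# pipeline short-circuit and digest determinism.

test_that("FASTA fixtures read back verbatim", {
  fix <- test_path("fixtures", "two_records.fasta")
  seqs <- read_sequences(fix)
  expect_length(seqs, 2L)
  expect_named(seqs, c("contig_a", "contig_b"))
  expect_equal(unname(seqs[["contig_a"]]), "ACGTACGTACGTACGT")
})

test_that("FASTQ parse errors name the offending line", {
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad) # quality too short
  expect_error(read_sequences(bad), "line 4")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), bad)
  expect_error(read_sequences(bad), "truncated")
  writeLines(c("r1", "ACGT", "+", "IIII"), bad)
  expect_error(read_sequences(bad), "line 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r1", "TTTT", "+", "IIII"), bad)
  expect_error(read_sequences(bad), "duplicate")
})

test_that("sequence round-trips are lossless", {
  set.seed(105)
  for (i in 1:20) {
    n <- sample(1:20, 1)
    seqs <- setNames(vapply(seq_len(n), function(j)
      rand_dna(sample(30:200, 1)), ""), paste0("s", seq_len(n)))
    fa <- withr::local_tempfile(fileext = ".fasta")
    write_sequences(seqs, fa)
    expect_equal(read_sequences(fa), seqs)
    fq <- withr::local_tempfile(fileext = ".fastq")
    write_sequences(seqs, fq, "fastq")
    back <- read_sequences(fq)
    expect_equal(unname(unclass(back))[seq_len(n)], unname(seqs),
                 ignore_attr = TRUE)
    expect_equal(names(back), names(seqs))
    expect_equal(nchar(attr(back, "qualities")), unname(nchar(seqs)))
  }
})

test_that("pipeline configuration survives a YAML round-trip", {
  cfg <- pipeline_config(reads = "r.fastq", markers = "m.faa", seed = 42,
                         bsr_min = 0.35, coverage_min = 6,
                         model_sidedness = "two_sided")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
  expect_error(pipeline_config(model_tolerance = 1.5), "model_tolerance")
  expect_error(pipeline_config(min_contig_len = -1), "min_contig_len")
})

test_that("reports round-trip through JSON with their field names", {
  markers <- setNames(replicate(10, rand_aa(30)), sprintf("m%02d", 1:10))
  counts <- setNames(c(rep(1L, 7), 2L, 0L, 0L), names(markers))
  qr <- completeness_report(counts, markers,
                            c("5S" = TRUE, "16S" = TRUE, "23S" = FALSE), 12)
  outdir <- withr::local_tempdir()
  write_reports(list(qc = qr), outdir)
  back <- jsonlite::read_json(file.path(outdir, "qc.json"), simplifyVector = TRUE)
  expect_equal(back$completeness, qr$completeness)
  expect_equal(back$contamination, qr$contamination)
  expect_equal(back$tier, qr$tier)
  expect_setequal(back$found_single, qr$found_single)
  expect_equal(back$trna_count, qr$trna_count)
  expect_true(file.exists(file.path(outdir, "qc.tsv")))

  empty_dir <- withr::local_tempdir()
  expect_silent(write_reports(list(), empty_dir))
})

test_that("the pipeline runs the funnel end to end and short-circuits failures", {
  w <- tiny_world(n_markers = 6L, genome_length = 30000L, seed = 77L)
  dir <- withr::local_tempdir()
  reads <- simulate_reads(setNames(w$genome$sequence, "sym"),
                          total_reads = 2000, error_rate = 0.01,
                          circular = TRUE, seed = 78)
  frag <- fragment_genome(w$genome$sequence, 1, circular = TRUE, seed = 79)
  ref <- derive_species(w$genome$sequence, 0.02, seed = 80)
  paths <- list(reads = file.path(dir, "reads.fastq"),
                markers = file.path(dir, "markers.faa"),
                contigs = file.path(dir, "contigs.fasta"),
                refs = file.path(dir, "refs.fasta"))
  write_sequences(reads$reads, paths$reads, "fastq")
  write_sequences(w$catalog, paths$markers)
  write_sequences(frag$contigs, paths$contigs)
  write_sequences(c(refA = as.character(ref)), paths$refs)

  cfg <- pipeline_config(reads = paths$reads, markers = paths$markers,
                         references = paths$refs, contigs = paths$contigs,
                         outdir = file.path(dir, "out1"), seed = 5)
  man <- run_pipeline(cfg)
  expect_equal(man$verdict, "pass")
  expect_true(any(grepl("^qc_", man$stages)))
  expect_true(any(grepl("^detect_", man$stages)))
  qc <- jsonlite::read_json(file.path(dir, "out1", "qc_bin_refA.json"))
  expect_equal(qc$completeness, 100)
  expect_true(qc$bin_stats$circular)
  det <- jsonlite::read_json(file.path(dir, "out1", "detect_bin_refA.json"))
  expect_true(det$detected)

  # identical config + seed -> identical digests (fresh outdirs)
  cfg2 <- cfg; cfg2$outdir <- file.path(dir, "out2")
  man2 <- run_pipeline(cfg2)
  expect_equal(unname(unlist(man$digests)), unname(unlist(man2$digests)))

  # no symbiont: fail at stage 1, later stages skipped
  set.seed(81)
  junk <- setNames(vapply(1:300, function(i) rand_dna(150), ""),
                   sprintf("read_%06d", 1:300))
  write_sequences(junk, file.path(dir, "junk.fastq"), "fastq")
  cfg3 <- pipeline_config(reads = file.path(dir, "junk.fastq"),
                          markers = paths$markers,
                          references = paths$refs, contigs = paths$contigs,
                          outdir = file.path(dir, "out3"), seed = 5)
  man3 <- run_pipeline(cfg3)
  expect_equal(man3$verdict, "fail_stage1")
  expect_equal(man3$stages, "screen")
})

test_that("the CLI screens a packaged-style fixture", {
  w <- tiny_world(n_markers = 5L, genome_length = 25000L, seed = 88L)
  dir <- withr::local_tempdir()
  reads <- simulate_reads(setNames(w$genome$sequence, "sym"),
                          total_reads = 1500, error_rate = 0.01,
                          circular = TRUE, seed = 89)
  write_sequences(reads$reads, file.path(dir, "reads.fastq"), "fastq")
  write_sequences(w$catalog, file.path(dir, "markers.faa"))
  out <- file.path(dir, "cli_out")
  status <- endotrawl_cli(c("screen", "--reads", file.path(dir, "reads.fastq"),
                            "--markers", file.path(dir, "markers.faa"),
                            "--bsr-min", "0.4", "--cov-min", "5",
                            "--outdir", out))
  expect_equal(status, 0L)
  rep <- jsonlite::read_json(file.path(out, "screen.json"))
  expect_equal(rep$verdict, "pass")
})
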