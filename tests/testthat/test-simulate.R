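test_that("the reference generator is seeded and balanced", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1e6)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  r3 <- simulate_reference(sim_config(seed = 4, n_chroms = 1,
                                      chrom_length = 1e6))
  expect_false(as.character(r1[[1]]) == as.character(r3[[1]]))
  gc_frac <- Biostrings::letterFrequency(r1[[1]], "GC", as.prob = TRUE)
  expect_equal(unname(gc_frac), 0.5, tolerance = 0.02)
})

test_that("a config without a seed is rejected", {
  expect_error(sim_config(), "seed")
})

test_that("implanted SVs respect spacing and class counts", {
  cfg <- sim_config(seed = 5, n_chroms = 2, chrom_length = 5e5,
                    n_svs_per_class = 6)
  truth <- implant_svs(simulate_reference(cfg), cfg)
  expect_equal(nrow(truth), 24L)
  expect_equal(as.integer(table(truth$sv_class)), rep(6L, 4))
  expect_true(all(truth$size >= 50))
  # pairwise separation on each chromosome (span intervals + donors)
  spans <- dplyr::bind_rows(
    truth[, c("chrom", "start", "end")],
    stats::setNames(truth[!is.na(truth$donor_chrom),
                          c("donor_chrom", "donor_start", "donor_end")],
                    c("chrom", "start", "end")))
  for (cn in unique(spans$chrom)) {
    s <- spans[spans$chrom == cn, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) {
      expect_true(all(s$start[-1] - s$end[-nrow(s)] >= 1000))
    }
  }
})

test_that("an overloaded genome is a fatal error", {
  cfg <- sim_config(seed = 6, n_chroms = 1, chrom_length = 2e4,
                    n_svs_per_class = 50)
  expect_error(implant_svs(simulate_reference(cfg), cfg), "too small")
})

test_that("zero requested SVs give an empty truth set", {
  cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 1e5,
                    n_svs_per_class = 0)
  truth <- implant_svs(simulate_reference(cfg), cfg)
  expect_equal(nrow(truth), 0L)
})

test_that("truth intervals pad 25 bp around each breakpoint", {
  truth <- tibble::tibble(
    sv_id = "sv0001", sv_class = "DEL", chrom = "chr01",
    start = 10000L, end = 10500L, size = 500L,
    donor_chrom = NA_character_, donor_start = NA_integer_,
    donor_end = NA_integer_,
    zygosity = list(c(s1 = "hom")), het_hap = list(c(s1 = 1)))
  ti <- truth_intervals(truth)
  expect_equal(ti$start, c(9975L, 10475L))
  expect_equal(ti$end, c(10025L, 10525L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_truth_bed(truth, path)
  back <- read_truth_bed(path)
  expect_equal(back$start, ti$start)
  expect_equal(back$end, ti$end)
  expect_equal(back$sv_class, c("DEL", "DEL"))
  expect_equal(back$size, c(500L, 500L))
})

test_that("insertion truth records the donor interval", {
  cfg <- sim_config(seed = 8, n_chroms = 2, chrom_length = 2e5,
                    n_svs_per_class = 3, sv_classes = "INS")
  truth <- implant_svs(simulate_reference(cfg), cfg)
  expect_true(all(!is.na(truth$donor_chrom)))
  expect_true(all(truth$donor_chrom != truth$chrom))
  expect_equal(truth$donor_end - truth$donor_start, truth$size)
  ti <- truth_intervals(truth)
  expect_equal(nrow(ti), 9L)  # recipient point + both donor edges
})

test_that("truth tables round-trip through TSV", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 3e5,
                    n_svs_per_class = 4, n_samples = 2)
  truth <- implant_svs(simulate_reference(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(truth, path)
  back <- read_truth_tsv(path)
  expect_equal(back$sv_id, truth$sv_id)
  expect_equal(back$start, truth$start)
  expect_identical(back$zygosity, truth$zygosity)
})

test_that("emitted alignments are deterministic and at target coverage", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 10, n_chroms = 1, chrom_length = 2e5,
                    n_svs_per_class = 0, coverage = 50,
                    spurious_clip_rate = 0)
  ref <- simulate_reference(cfg)
  truth <- implant_svs(ref, cfg)
  b1 <- emit_alignments(ref, truth, cfg, "s1", file.path(dir, "a"))
  b2 <- emit_alignments(ref, truth, cfg, "s1", file.path(dir, "b"))
  r1 <- read_alignments(b1)
  r2 <- read_alignments(b2)
  expect_identical(r1, r2)

  # mean depth within 5% of the configured coverage
  depth <- nrow(r1) * cfg$read_length / cfg$chrom_length
  expect_equal(depth, 50, tolerance = 0.05)

  # an SV-free genome has no clip evidence at all
  expect_equal(sum(r1$clip_left_len > 0 | r1$clip_right_len > 0), 0L)

  # proper pairs dominate and tlen is centred on the configured insert
  expect_gt(mean(r1$proper_pair), 0.95)
  expect_equal(median(abs(r1$tlen)), 400, tolerance = 0.05)
})

test_that("a heterozygous deletion clips about half the junction reads", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 11, n_chroms = 1, chrom_length = 1e5,
                    n_svs_per_class = 0, coverage = 60,
                    spurious_clip_rate = 0)
  ref <- simulate_reference(cfg)
  truth <- tibble::tibble(
    sv_id = "sv0001", sv_class = "DEL", chrom = "chr01",
    start = 40000L, end = 42000L, size = 2000L,
    donor_chrom = NA_character_, donor_start = NA_integer_,
    donor_end = NA_integer_,
    zygosity = list(c(s1 = "het")), het_hap = list(c(s1 = 1)))
  bam <- emit_alignments(ref, truth, cfg, "s1", file.path(dir, "het"))
  reads <- read_alignments(bam)
  # at the left breakpoint: carrier-haplotype junction reads are clipped
  # exactly there, the other haplotype spans cleanly
  sigs <- clip_signatures(reads)
  clipped <- sum(sigs$break_pos %in% c(40000L, 42000L))
  spanning <- sum(reads$pos < 40000 & reads$pos + reads$ref_span > 40000 &
                    reads$clip_left_len == 0 & reads$clip_right_len == 0)
  # hap1 junction-crossing reads split between the two clip boundaries;
  # hap2 spans: expect clips ~= spanning coverage (loose binomial bounds)
  expect_gt(clipped, 0.4 * spanning)
  expect_lt(clipped, 2.5 * spanning)
  # clip boundaries sit exactly on the breakpoints
  expect_true(40000 %in% sigs$break_pos)
  expect_true(42000 %in% sigs$break_pos)
  expect_true(all(sigs$break_pos %in% c(40000L, 42000L)))
})

test_that("FASTQ emission writes paired reads for every fragment", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 12, n_chroms = 1, chrom_length = 5e4,
                    n_svs_per_class = 0, coverage = 10)
  ref <- simulate_reference(cfg)
  truth <- implant_svs(ref, cfg)
  fq <- write_sim_fastq(ref, truth, cfg, "s1", file.path(dir, "sim"))
  l1 <- readLines(fq[["r1"]]); l2 <- readLines(fq[["r2"]])
  expect_equal(length(l1), length(l2))
  expect_equal(length(l1) %% 4, 0)
  expect_gt(length(l1), 0)
  expect_true(all(nchar(l1[seq(2, length(l1), 4)]) == cfg$read_length))
})
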