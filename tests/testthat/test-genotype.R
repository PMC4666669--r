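ev_row <- function(allele, mapq = 60L, n = 1L, sample_id = "s1") {
  tibble::tibble(read_ref = seq_len(n), sample_id = sample_id,
                 allele = allele, mapq = as.integer(mapq),
                 basis = ifelse(allele == "alt", "clipped_at_breakpoint",
                                "reference_spanning"))
}

# independent oracle: per-read mixture likelihood evaluated in plain
# linear space with prod()
brute_gl <- function(allele, mapq) {
  e <- pmin(10^(-mapq / 10), 0.5)
  L <- vapply(c(0, 1, 2), function(g) {
    p_alt <- g / 2
    prod(ifelse(allele == "alt",
                p_alt * (1 - e) + (1 - p_alt) * e,
                p_alt * e + (1 - p_alt) * (1 - e)))
  }, numeric(1))
  log10(L) - max(log10(L))
}

test_that("unanimous reference evidence yields 0/0", {
  g <- genotype_likelihoods(ev_row(rep("ref", 10)))
  expect_equal(g$gt, "0/0")
  expect_equal(g$dp, 10L)
  expect_equal(g$alt_count, 0L)
})

test_that("two clean alt reads give the closed-form likelihoods", {
  g <- genotype_likelihoods(ev_row(rep("alt", 2)))
  expect_equal(g$gt, "1/1")
  gl <- g$gl[[1]]
  expect_equal(gl[1], -12, tolerance = 1e-4)
  expect_equal(gl[2], log10(0.25), tolerance = 1e-4)
  expect_equal(gl[3], 0)
})

test_that("balanced evidence is heterozygous and matches brute force", {
  ev <- ev_row(c(rep("ref", 5), rep("alt", 5)))
  g <- genotype_likelihoods(ev)
  expect_equal(g$gt, "0/1")
  expect_equal(g$gl[[1]], brute_gl(ev$allele, ev$mapq), tolerance = 1e-10)
})

test_that("likelihoods equal brute-force products on random pileups", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(1:20, 1)
    ev <- ev_row(sample(c("ref", "alt"), n, replace = TRUE),
                 mapq = sample(c(0L, 5L, 20L, 40L, 60L), n,
                               replace = TRUE))
    g <- genotype_likelihoods(ev)
    expect_equal(g$gl[[1]], brute_gl(ev$allele, ev$mapq),
                 tolerance = 1e-9)
    expect_equal(max(g$gl[[1]]), 0)
  }
})

test_that("swapping ref and alt labels mirrors the likelihood triple", {
  set.seed(18)
  ev <- ev_row(sample(c("ref", "alt"), 12, replace = TRUE),
               mapq = sample(10:60, 12, replace = TRUE))
  g1 <- genotype_likelihoods(ev)$gl[[1]]
  ev2 <- ev
  ev2$allele <- ifelse(ev$allele == "alt", "ref", "alt")
  g2 <- genotype_likelihoods(ev2)$gl[[1]]
  expect_equal(g1, rev(g2), tolerance = 1e-9)
})

test_that("MAPQ 0 reads are uninformative", {
  ev <- ev_row(c(rep("alt", 4), rep("ref", 3)))
  base <- genotype_likelihoods(ev)$gl[[1]]
  with0 <- genotype_likelihoods(dplyr::bind_rows(
    ev, ev_row(sample(c("ref", "alt"), 5, replace = TRUE), mapq = 0L)))
  expect_equal(with0$gl[[1]], base, tolerance = 1e-9)
})

test_that("empty evidence gives a missing genotype", {
  g <- genotype_likelihoods(ev_row(character(0), n = 0L))
  expect_equal(g$gt, "./.")
  expect_equal(g$gl[[1]], c(0, 0, 0))
  expect_equal(g$dp, 0L)
})

test_that("error-free trio evidence is Mendelian-consistent", {
  # plant parental genotypes, draw the child's alleles by inheritance,
  # genotype everyone from clean depth-20 evidence
  gt_ev <- function(copies) {
    ev_row(c(rep("alt", copies * 10), rep("ref", (2 - copies) * 10)))
  }
  inherit <- function(g) if (g == 2) 1L else if (g == 0) 0L else
    stats::rbinom(1, 1, 0.5)
  set.seed(19)
  for (i in 1:25) {
    mum <- sample(0:2, 1); dad <- sample(0:2, 1)
    child <- inherit(mum) + inherit(dad)
    gts <- vapply(c(mum, dad, child), function(g)
      genotype_likelihoods(gt_ev(g))$gt, character(1))
    copies <- c(`0/0` = 0L, `0/1` = 1L, `1/1` = 2L)[gts]
    # called copies must equal the planted ones -> no violations possible
    expect_equal(unname(copies), c(mum, dad, child))
  }
})

test_that("read evidence is classified by breakpoint signature", {
  # soft-clipped exactly at the call position
  r <- make_read(pos = 100L, cigar = "90M10S", seq = random_seq(100))
  ev <- classify_read_evidence(r, "chr1", 190L)
  expect_equal(ev$allele, "alt")
  expect_equal(ev$basis, "clipped_at_breakpoint")

  # clean proper pair spanning the breakpoint
  r <- make_read(pos = 150L, cigar = "100M")
  ev <- classify_read_evidence(r, "chr1", 190L)
  expect_equal(ev$allele, "ref")
  expect_equal(ev$basis, "reference_spanning")

  # both mates on the forward strand: inversion signature
  r <- make_read(pos = 150L, cigar = "100M", mate_reverse = FALSE,
                 proper_pair = FALSE)
  ev <- classify_read_evidence(r, "chr1", 190L)
  expect_equal(ev$basis, "same_strand_pair")
  expect_equal(ev$allele, "alt")

  # long-insert discordant pair near the breakpoint
  r <- make_read(pos = 150L, cigar = "100M", tlen = 2000L,
                 mate_pos = 2050L, proper_pair = FALSE)
  ev <- classify_read_evidence(r, "chr1", 190L,
                               insert_stats = c(mu = 400, sigma = 50))
  expect_equal(ev$basis, "discordant_pair")

  # a >= 10 bp deletion op spanning the call is internal evidence
  r <- make_read(pos = 150L, cigar = "40M20D60M")
  ev <- classify_read_evidence(r, "chr1", 195L)
  expect_equal(ev$basis, "internal_breakpoint")

  # reads that neither span nor touch the breakpoint contribute nothing
  r <- make_read(pos = 2000L, cigar = "100M", mate_pos = 2300L)
  expect_equal(nrow(classify_read_evidence(r, "chr1", 190L)), 0L)
})

test_that("each read is counted once with its strongest basis", {
  # clipped at the breakpoint AND discordant: clip wins
  r <- make_read(pos = 100L, cigar = "90M10S", seq = random_seq(100),
                 tlen = 3000L, mate_pos = 3000L, proper_pair = FALSE)
  ev <- classify_read_evidence(r, "chr1", 190L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$basis, "clipped_at_breakpoint")
})

test_that("joint site filter needs three alt reads in one individual", {
  expect_false(joint_site_filter(c(A = 2L, B = 2L, C = 2L)))
  expect_true(joint_site_filter(c(A = 3L, B = 0L)))
  expect_false(joint_site_filter(integer(0)))
})

test_that("insert statistics are robust to SV outliers", {
  set.seed(20)
  tl <- c(round(rnorm(1000, 400, 50)), rep(5000L, 30))
  reads <- tibble::tibble(proper_pair = c(rep(TRUE, 1000), rep(FALSE, 30)),
                          tlen = as.integer(tl))
  st <- estimate_insert_stats(reads)
  expect_equal(unname(st["mu"]), 400, tolerance = 0.02)
  expect_lt(abs(st["sigma"] - 50), 10)
})
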