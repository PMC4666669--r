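sig_at <- function(pos = 500L, side = "left", n = 1L, primary = TRUE,
                   dup = FALSE, chrom = "chr1") {
  tibble::tibble(chrom = chrom, break_pos = as.integer(pos), side = side,
                 clip_len = 10L, clip_seq = strrep("A", 10),
                 read_ref = seq_len(n), sample_id = "s1",
                 is_primary = primary, mapq = 60L, duplicate = dup)
}

test_that("shared clip positions hash to one key, duplicates are dropped", {
  sigs <- dplyr::bind_rows(sig_at(500, n = 3), sig_at(500, n = 1,
                                                      dup = TRUE))
  idx <- build_clip_index(sigs)
  expect_equal(nrow(idx), 3L)   # the duplicate-flagged read is excluded
  cands <- find_candidates(idx)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$support, 3L)
})

test_that("nearby but distinct positions are distinct keys", {
  sigs <- dplyr::bind_rows(sig_at(500, n = 3), sig_at(501, n = 3))
  cands <- find_candidates(build_clip_index(sigs))
  expect_equal(cands$pos, c(500L, 501L))
})

test_that("only primary reads count toward the support threshold", {
  sigs <- dplyr::bind_rows(sig_at(500, n = 2, primary = TRUE),
                           sig_at(500, n = 5, primary = FALSE))
  expect_equal(nrow(find_candidates(build_clip_index(sigs))), 0L)
  sigs3 <- sig_at(700, n = 3, primary = TRUE)
  cands <- find_candidates(build_clip_index(sigs3))
  expect_equal(cands$support, 3L)
  expect_equal(nrow(find_candidates(tibble::tibble(
    chrom = character(), break_pos = integer(), side = character(),
    clip_len = integer(), clip_seq = character(), read_ref = integer(),
    sample_id = character(), is_primary = logical(),
    mapq = integer(), duplicate = logical()))), 0L)
})

test_that("overlapping alleles with different breakpoints stay separate", {
  sigs <- dplyr::bind_rows(sig_at(500, side = "right", n = 3),
                           sig_at(510, side = "right", n = 4))
  cands <- find_candidates(build_clip_index(sigs))
  expect_equal(nrow(cands), 2L)
})

test_that("raising min_support never increases the candidate count", {
  set.seed(21)
  sigs <- dplyr::bind_rows(lapply(1:30, function(i) {
    sig_at(sample(100:120, 1), n = sample(1:6, 1),
           primary = runif(1) < 0.8)
  }))
  idx <- build_clip_index(sigs)
  counts <- vapply(1:6, function(m)
    nrow(find_candidates(idx, min_support = m)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("candidates match exhaustive enumeration on small pileups", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:20, 1)
    sigs <- tibble::tibble(
      chrom = "chr1",
      break_pos = sample(1000:1005, n, replace = TRUE),
      side = sample(c("left", "right"), n, replace = TRUE),
      clip_len = 10L, clip_seq = strrep("A", 10),
      read_ref = seq_len(n), sample_id = "s1",
      is_primary = runif(n) < 0.7, mapq = 60L, duplicate = FALSE)
    got <- find_candidates(build_clip_index(sigs), min_support = 3L)
    # oracle: brute-force count over every (pos, side) pair
    want <- 0L
    for (p in unique(sigs$break_pos)) for (sd in c("left", "right")) {
      k <- sum(sigs$is_primary & sigs$break_pos == p & sigs$side == sd)
      if (k >= 3) {
        want <- want + 1L
        expect_equal(got$support[got$pos == p & got$side == sd], k)
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("identical clip sequences give a perfect consensus", {
  cons <- build_consensus(rep("ACGTACGTACGT", 3), "right")
  expect_equal(cons$sequence, "ACGTACGTACGT")
  expect_equal(cons$mismatch_fraction, 0)
  expect_equal(cons$n_input, 3L)
})

test_that("a single disagreeing base gives mismatch 1/36", {
  cons <- build_consensus(c("ACGTACGTACGT", "ACGTACGTACGT",
                            "ACGTACGAACGT"), "right")
  expect_equal(cons$mismatch_fraction, 1 / 36)
  expect_equal(cons$sequence, "ACGTACGTACGT")
})

test_that("consensus mismatch equals an independent column tally", {
  # oracle: explicit column-majority count over the padded stack
  oracle <- function(seqs, side) {
    L <- max(nchar(seqs))
    pad <- strrep(" ", L - nchar(seqs))
    padded <- if (side == "left") paste0(pad, seqs) else paste0(seqs, pad)
    mat <- do.call(rbind, strsplit(padded, ""))
    bad <- 0; tot <- 0
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j][mat[, j] != " "]
      if (!length(col)) next
      tot <- tot + length(col)
      bad <- bad + length(col) - max(table(col))
    }
    bad / tot
  }
  set.seed(99)
  for (rep in 1:20) {
    seqs <- vapply(1:4, function(i) random_seq(20), character(1))
    side <- sample(c("left", "right"), 1)
    expect_equal(build_consensus(seqs, side)$mismatch_fraction,
                 oracle(seqs, side))
  }
  # mutually random 20-mers disagree in roughly half their positions
  set.seed(100)
  mm <- replicate(50, build_consensus(
    vapply(1:4, function(i) random_seq(20), character(1)),
    "right")$mismatch_fraction)
  expect_gt(mean(mm), 0.45)
  expect_lt(mean(mm), 0.65)
})

test_that("left-side clips are anchored at their right edge", {
  # clips of different lengths must line up at the breakpoint
  cons <- build_consensus(c("TTGACGT", "ACGT", "GACGT"), "left")
  expect_equal(cons$mismatch_fraction, 0)
  expect_equal(cons$sequence, "GACGT")  # columns with >= 2 sequences
})

test_that("hard-clip-only candidates yield an empty consensus", {
  cons <- build_consensus(c("", "", ""), "right")
  expect_equal(cons$sequence, "")
  expect_false(filter_consensus(cons$sequence,
                                cons$mismatch_fraction)$keep)
})

test_that("consensus filters apply strict thresholds", {
  f <- filter_consensus(strrep("A", 9), 0)
  expect_false(f$keep); expect_equal(f$reason, "too_short")
  f <- filter_consensus(strrep("A", 10), 0.5)   # exactly 50% passes
  expect_true(f$keep); expect_equal(f$reason, "ok")
  f <- filter_consensus(strrep("A", 40), 0.51)
  expect_false(f$keep); expect_equal(f$reason, "too_divergent")
})
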