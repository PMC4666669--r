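test_that("SA tags imply the clip-adjacent partner boundary", {
  # right clip at chr1:190; the SA alignment's leading clip mirrors the
  # anchored segment, so the partner breakpoint is the SA start
  r <- make_read(pos = 100L, cigar = "90M10S", seq = random_seq(100),
                 sa = "chr1,1001,+,10S90M,60,0;")
  ep <- candidate_endpoints(r, "right")
  expect_equal(ep$chrom, "chr1")
  expect_equal(ep$pos, 1000L)
  expect_true(ep$precise)

  # opposite strand (inversion geometry): boundary swaps to the SA end
  r2 <- make_read(pos = 100L, cigar = "90M10S", seq = random_seq(100),
                  sa = "chr1,1001,-,90M10S,60,0;")
  ep2 <- candidate_endpoints(r2, "right")
  expect_equal(ep2$pos, 1000L + 90L)

  # left clip, same strand: partner breakpoint is the SA end
  r3 <- make_read(pos = 100L, cigar = "10S90M", seq = random_seq(100),
                  sa = "chr1,1001,+,90M10S,60,0;")
  ep3 <- candidate_endpoints(r3, "left")
  expect_equal(ep3$pos, 1090L)
})

test_that("SA endpoint rule is consistent with a planted deletion", {
  # brute-force check on a toy genome: delete [300, 800) from a 1 kb
  # reference, realign a junction-crossing read by exact string search
  set.seed(77)
  ref <- random_seq(1000)
  hap <- paste0(substr(ref, 1, 300), substr(ref, 801, 1000))
  read <- substr(hap, 281, 380)  # 20 bp before junction + 80 after
  anchored <- substr(read, 1, 20)
  clipped <- substr(read, 21, 100)
  # oracle: where does the clipped part land on the reference?
  oracle_pos <- as.integer(regexpr(clipped, ref, fixed = TRUE)) - 1L
  expect_equal(oracle_pos, 800L)
  r <- make_read(pos = 280L, cigar = "20M80S", seq = read,
                 sa = sprintf("chr1,%d,+,20S80M,60,0;", oracle_pos + 1L))
  ep <- candidate_endpoints(r, "right")
  expect_equal(ep$pos, 800L)
})

test_that("discordant mates give a flagged low-precision fallback", {
  r <- make_read(pos = 100L, cigar = "90M10S", seq = random_seq(100),
                 mate_pos = 5100L, tlen = 5100L, mate_reverse = TRUE)
  ep <- candidate_endpoints(r, "right",
                            insert_stats = c(mu = 400, sigma = 50))
  expect_equal(nrow(ep), 1L)
  expect_false(ep$precise)
  expect_equal(ep$source, "mate")
  expect_equal(ep$pos, 5200L)  # far edge of the mate
})

test_that("endpoints cluster on a 10 bp half-up grid", {
  eps <- tibble::tibble(chrom = "chr1",
                        pos = c(1003L, 1004L, 1008L, 1102L),
                        precise = TRUE, source = "SA")
  cl <- cluster_endpoints(eps)
  expect_equal(cl$rounded_pos, c(1000L, 1010L, 1100L))
  expect_equal(cl$support, c(2L, 1L, 1L))
  expect_equal(cl$rounded_pos[1], 1000L)        # winner first
  expect_equal(sort(cl$member_positions[[1]]), c(1003L, 1004L))
})

test_that("half-up rounding sends 1005 to 1010", {
  cl <- cluster_endpoints(tibble::tibble(chrom = "chr1", pos = 1005L,
                                         precise = TRUE, source = "SA"))
  expect_equal(cl$rounded_pos, 1010L)
})

test_that("cluster ties break to the leftmost position", {
  eps <- tibble::tibble(chrom = "chr1",
                        pos = c(1001L, 1002L, 1003L, 2001L, 2002L, 2003L),
                        precise = TRUE, source = "SA")
  cl <- cluster_endpoints(eps)
  expect_equal(cl$rounded_pos[1], 1000L)
})

test_that("clustering is idempotent on its own output", {
  set.seed(8)
  eps <- tibble::tibble(chrom = "chr1",
                        pos = sample(1000:1100, 20, replace = TRUE),
                        precise = TRUE, source = "SA")
  cl <- cluster_endpoints(eps)
  cl2 <- cluster_endpoints(tibble::tibble(chrom = cl$chrom,
                                          pos = cl$rounded_pos,
                                          precise = TRUE, source = "SA"))
  expect_setequal(cl2$rounded_pos, cl$rounded_pos)
})

test_that("single endpoint forms its own winning cluster", {
  cl <- cluster_endpoints(tibble::tibble(chrom = "chr2", pos = 57L,
                                         precise = TRUE, source = "SA"))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 1L)
  expect_equal(nrow(cluster_endpoints(tibble::tibble(
    chrom = character(), pos = integer(), precise = logical(),
    source = character()))), 0L)
})

with_toy_ref <- function(code) {
  set.seed(123)
  ref <- random_seq(3000)
  fetch <- function(chrom, start, end) substr(ref, start + 1, end)
  attr(fetch, "lengths") <- c(chr1 = 3000L)
  list(ref = ref, fetch = fetch)
}

test_that("Smith-Waterman refinement recovers exact and offset matches", {
  toy <- with_toy_ref()
  cons <- substr(toy$ref, 1401, 1430)   # reference [1400, 1430)
  expect_equal(refine_with_sw(cons, toy$fetch, "chr1", 1400L, "right",
                              3000L), 1400L)
  # planted 7 bp offset inside the 1400 cluster window
  cons7 <- substr(toy$ref, 1408, 1437)  # starts at 0-based 1407
  expect_equal(refine_with_sw(cons7, toy$fetch, "chr1", 1400L, "right",
                              3000L), 1407L)
  # left-side clips anchor at the alignment's end
  consL <- substr(toy$ref, 1371, 1400)  # ends at 0-based 1400
  expect_equal(refine_with_sw(consL, toy$fetch, "chr1", 1400L, "left",
                              3000L), 1400L)
  # reverse-complement (inversion) matches anchor at the opposite end
  consR <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(toy$ref, 1401, 1430))))
  expect_equal(refine_with_sw(consR, toy$fetch, "chr1", 1400L, "right",
                              3000L), 1430L)
})

test_that("random consensus sequences are rejected by SW thresholds", {
  toy <- with_toy_ref()
  set.seed(9)
  hits <- vapply(1:200, function(i) {
    !is.na(refine_with_sw(random_seq(30), toy$fetch, "chr1", 1400L,
                          "right", 3000L))
  }, logical(1))
  expect_lt(mean(hits), 0.02)
})

test_that("refinement never moves a breakpoint beyond the window", {
  toy <- with_toy_ref()
  set.seed(10)
  for (i in 1:20) {
    at <- sample(300:2500, 1)
    cons <- substr(toy$ref, at + 1, at + 25)
    centre <- clipsv:::round_to(at, 10L)
    got <- refine_with_sw(cons, toy$fetch, "chr1", centre, "right", 3000L,
                          sw_params())
    if (!is.na(got)) expect_lte(abs(got - centre), 200L)
  }
})

test_that("window truncation at contig edges is not an error", {
  toy <- with_toy_ref()
  cons <- substr(toy$ref, 51, 80)
  expect_equal(refine_with_sw(cons, toy$fetch, "chr1", 50L, "right",
                              3000L), 50L)
})

test_that("distance filters demand exact mate support for large events", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(1000L, 1000L, 1000L),
    be_chrom = c("chr1", "chr2", "chr1"),
    be_pos = c(1000999L, 5000L, 500000L),
    mate_exact_support = c(1L, 1L, 1L),
    n_split_chroms = c(1L, 2L, 1L))
  f <- apply_distance_filters(calls)
  expect_true(f$keep[1])    # 999,999 bp: below the 1 Mb threshold
  expect_false(f$keep[2])   # translocation with weak exact support
  expect_true(f$keep[3])    # ordinary intra-chromosomal call

  big <- tibble::tibble(chrom = "chr1", pos = 0L, be_chrom = "chr1",
                        be_pos = 1500000L, mate_exact_support = 2L,
                        n_split_chroms = 1L)
  expect_true(apply_distance_filters(big)$keep)

  multi <- tibble::tibble(chrom = "chr1", pos = 0L, be_chrom = "chr1",
                          be_pos = 100L, mate_exact_support = 5L,
                          n_split_chroms = 4L)
  expect_false(apply_distance_filters(multi)$keep)
  expect_equal(apply_distance_filters(multi)$reason,
               "multi_chrom_splits")
})

test_that("more mate support never turns a kept small call into a drop", {
  for (ms in 0:5) {
    call <- tibble::tibble(chrom = "chr1", pos = 1000L, be_chrom = "chr1",
                           be_pos = 5000L,
                           mate_exact_support = ms, n_split_chroms = 1L)
    expect_true(apply_distance_filters(call)$keep)
  }
})
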