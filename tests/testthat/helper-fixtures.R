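# In-code fixtures shared across the suite: single-read builders, a tiny
# SAM/BAM writer, and a memoised small simulated dataset.

make_read <- function(chrom = "chr1", pos = 100L, cigar = "100M",
                      mapq = 60L, seq = NA_character_, sample_id = "s1",
                      qname = "r1", paired = TRUE, proper_pair = TRUE,
                      unmapped = FALSE, mate_unmapped = FALSE,
                      reverse = FALSE, mate_reverse = TRUE,
                      secondary = FALSE, duplicate = FALSE,
                      supplementary = FALSE, mate_chrom = chrom,
                      mate_pos = pos + 300L, tlen = 400L,
                      sa = NA_character_, xa = NA_character_) {
  clipsv::add_cigar_info(tibble::tibble(
    qname = qname, sample_id = sample_id, chrom = chrom,
    pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
    paired = paired, proper_pair = proper_pair, unmapped = unmapped,
    mate_unmapped = mate_unmapped, reverse = reverse,
    mate_reverse = mate_reverse, secondary = secondary,
    duplicate = duplicate, supplementary = supplementary,
    mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
    tlen = as.integer(tlen), sa = sa, xa = xa, seq = seq))
}

make_reads <- function(...) dplyr::bind_rows(...)

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Write a BAM from SAM body lines (already coordinate-sorted).
write_test_bam <- function(body, prefix,
                           contigs = c(chr1 = 10000L),
                           sample_id = "s1",
                           so = "coordinate") {
  sam <- paste0(prefix, ".sam")
  writeLines(c(paste0("@HD\tVN:1.6\tSO:", so),
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
               sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id),
               body), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

sam_line <- function(qname = "r1", flag = 99L, chrom = "chr1",
                     pos1 = 101L, mapq = 60L, cigar = "100M",
                     rnext = "=", pnext1 = 401L, tlen = 400L,
                     seq = "*", tags = "RG:Z:s1") {
  paste(qname, flag, chrom, pos1, mapq, cigar, rnext, pnext1, tlen, seq,
        "*", tags, sep = "\t")
}

within_slop <- function(ints, slop) {
  ints$start <- ints$start - slop
  ints$end <- ints$end + slop
  ints
}

# Small end-to-end simulated dataset, built once per test session.
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    dir <- file.path(tempdir(), "clipsv_small_sim")
    cfg <- clipsv::sim_config(seed = 42, n_chroms = 2,
                              chrom_length = 3e5, n_svs_per_class = 5,
                              coverage = 50)
    ds <- clipsv::simulate_sv_dataset(cfg, dir)
    ds$calls <- clipsv::sv_call(ds$bams, ds$reference,
                                out_vcf = file.path(dir, "calls.vcf"))
    ds$vcf <- file.path(dir, "calls.vcf")
    .sim_cache$small <- ds
  }
  .sim_cache$small
}
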