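#' Names of the fourteen pileup attributes, in canonical order
#'
#' Each attribute is the fraction of reads at the pileup position showing
#' one mapping property, normalised by the read depth there. The set spans
#' every mapping signal an SV leaves in short-read data: clipping on
#' either side, split (`SA`) and alternative (`XA`) alignments, stretched
#' and compressed inserts, same-strand (inversion) and everted
#' (tandem-duplication) pair orientations, unmapped or trans-chromosomal
#' mates, large internal indels, supplementary records, low mapping
#' quality and duplicate flags. The vector is ordered and named here once;
#' the `AT` INFO field and the classifier training format both follow this
#' order, so models trained on these attributes are stable across runs.
#'
#' @return character vector of length 14.
#' @export
attribute_names <- function() {
  c("f_clip_left", "f_clip_right", "f_split", "f_alt_aln",
    "f_discordant_insert_long", "f_discordant_insert_short",
    "f_same_strand", "f_everted_pair", "f_mate_unmapped",
    "f_mate_other_chrom", "f_internal_indel", "f_supplementary",
    "f_low_mapq", "f_duplicate_flagged")
}

#' Extract the fourteen depth-normalised attributes of a pileup position
#'
#' @param reads reads tibble of the records overlapping the pileup
#'   position (combined across samples).
#' @param insert_stats named numeric `c(mu, sigma)` of the insert-size
#'   distribution, used for the long/short discordant-insert fractions.
#' @param low_mapq mapping-quality cutoff for `f_low_mapq` (default 20).
#' @return one-row tibble with the 14 fractions in [attribute_names()]
#'   order plus `depth`. Zero depth yields an all-zero vector.
#' @export
extract_attributes <- function(reads, insert_stats = c(mu = 400, sigma = 50),
                               low_mapq = 20L) {
  nm <- attribute_names()
  depth <- nrow(reads)
  if (!depth) {
    out <- tibble::as_tibble(as.list(stats::setNames(rep(0, 14), nm)))
    out$depth <- 0L
    return(out)
  }
  if (!"ref_span" %in% names(reads)) reads <- add_cigar_info(reads)
  mu <- insert_stats[["mu"]]; sigma <- insert_stats[["sigma"]]
  hi <- mu + 3 * sigma; lo <- mu - 3 * sigma

  mate_ok <- reads$paired & !reads$mate_unmapped
  same_chrom <- mate_ok & !is.na(reads$mate_chrom) &
    reads$mate_chrom == reads$chrom
  tl <- abs(reads$tlen)
  everted <- same_chrom &
    ((reads$reverse & !reads$mate_reverse & reads$mate_pos > reads$pos) |
       (!reads$reverse & reads$mate_reverse & reads$mate_pos < reads$pos))

  frac <- function(x) sum(x, na.rm = TRUE) / depth
  vals <- c(
    frac(reads$clip_left_len > 0L),
    frac(reads$clip_right_len > 0L),
    frac(!is.na(reads$sa)),
    frac(!is.na(reads$xa)),
    frac(same_chrom & !is.na(tl) & tl != 0 & tl > hi),
    frac(same_chrom & !is.na(tl) & tl != 0 & tl < lo),
    frac(mate_ok & reads$reverse == reads$mate_reverse),
    frac(everted),
    frac(reads$paired & reads$mate_unmapped),
    frac(mate_ok & !is.na(reads$mate_chrom) &
           reads$mate_chrom != reads$chrom),
    frac(has_big_indel(reads$cigar)),
    frac(reads$supplementary),
    frac(reads$mapq < low_mapq),
    frac(reads$duplicate))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, nm)))
  out$depth <- depth
  out
}
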