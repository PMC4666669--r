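#' Robust insert-size statistics for one sample
#'
#' Location/scale of the template-length distribution from properly paired
#' reads with positive `tlen`, using the median and MAD so that SV-driven
#' outliers do not inflate the estimate. At most `max_pairs` pairs are
#' used, taken from the head of the file.
#'
#' @param reads reads tibble for one sample.
#' @param max_pairs cap on pairs used (default 1e5).
#' @return named numeric `c(mu, sigma)`.
#' @export
estimate_insert_stats <- function(reads, max_pairs = 1e5) {
  tl <- reads$tlen[reads$proper_pair & !is.na(reads$tlen) & reads$tlen > 0]
  tl <- utils::head(tl, max_pairs)
  if (!length(tl)) return(c(mu = 400, sigma = 50))
  c(mu = stats::median(tl), sigma = max(stats::mad(tl), 1))
}

#' Classify reads overlapping a call as reference or alternative evidence
#'
#' A read supports the alternative allele when it is clipped exactly at a
#' call breakpoint, carries a large (>= 10 bp) internal insertion or
#' deletion spanning the breakpoint, is discordantly mapped (template
#' length beyond mu + 3 sigma, or mate on another chromosome), or shows
#' the inversion signature of a same-strand mate pair. A read that spans
#' the breakpoint cleanly is reference evidence. Each read is counted at
#' most once; when several bases of support apply, the strongest
#' (most breakpoint-specific) basis wins, in the order listed above.
#' Reads that neither span nor touch either breakpoint contribute
#' nothing.
#'
#' @param reads reads tibble of records near the call (any samples).
#' @param chrom,pos primary breakpoint (0-based).
#' @param be_chrom,be_pos optional partner breakpoint.
#' @param insert_stats named numeric `c(mu, sigma)`.
#' @return evidence tibble: `read_ref` (row in `reads`), `sample_id`,
#'   `allele` (`"ref"`/`"alt"`), `mapq`, `basis`.
#' @export
classify_read_evidence <- function(reads, chrom, pos,
                                   be_chrom = NA, be_pos = NA,
                                   insert_stats = c(mu = 400, sigma = 50)) {
  if (!"ref_span" %in% names(reads)) reads <- add_cigar_info(reads)
  n <- nrow(reads)
  if (!n) {
    return(tibble::tibble(read_ref = integer(), sample_id = character(),
                          allele = character(), mapq = integer(),
                          basis = character()))
  }
  end <- reads$pos + reads$ref_span
  at_bp1 <- reads$chrom == chrom &
    ((reads$clip_left_len > 0L & reads$pos == pos) |
       (reads$clip_right_len > 0L & end == pos))
  at_bp2 <- !is.na(be_chrom) & reads$chrom == be_chrom &
    ((reads$clip_left_len > 0L & reads$pos == be_pos) |
       (reads$clip_right_len > 0L & end == be_pos))
  clipped <- at_bp1 | at_bp2

  spans1 <- reads$chrom == chrom & reads$pos <= pos & end > pos
  spans2 <- !is.na(be_chrom) & reads$chrom == be_chrom &
    reads$pos <= be_pos & end > be_pos
  spans <- spans1 | (!is.na(spans2) & spans2)

  internal <- has_big_indel(reads$cigar) & spans

  mu <- insert_stats[["mu"]]; sigma <- insert_stats[["sigma"]]
  discordant <- reads$paired & !reads$mate_unmapped &
    (reads$mate_chrom != reads$chrom |
       (!is.na(reads$tlen) & reads$tlen != 0L &
          abs(reads$tlen) > mu + 3 * sigma))
  discordant[is.na(discordant)] <- FALSE
  same_strand <- reads$paired & !reads$mate_unmapped &
    reads$reverse == reads$mate_reverse

  touches <- clipped | spans
  near1 <- reads$chrom == chrom & abs(reads$pos - pos) <= 2L * 100L
  considered <- touches | (near1 & (discordant | same_strand))

  basis <- dplyr::case_when(
    clipped ~ "clipped_at_breakpoint",
    internal ~ "internal_breakpoint",
    discordant & considered ~ "discordant_pair",
    same_strand & considered ~ "same_strand_pair",
    spans ~ "reference_spanning",
    TRUE ~ NA_character_)
  keep <- !is.na(basis)
  tibble::tibble(
    read_ref = which(keep),
    sample_id = reads$sample_id[keep],
    allele = ifelse(basis[keep] == "reference_spanning", "ref", "alt"),
    mapq = reads$mapq[keep],
    basis = basis[keep])
}

# >=10 bp internal I or D operation; computed over unique CIGARs
has_big_indel <- function(cigars) {
  u <- unique(cigars)
  hit <- vapply(stringr::str_match_all(u, "(\\d+)([ID])"), function(m) {
    nrow(m) > 0 && any(as.integer(m[, 2]) >= 10L)
  }, logical(1))
  hit[match(cigars, u)]
}

#' Bi-allelic genotype likelihoods from mapping qualities
#'
#' Implements the standard per-read mixture likelihood for a diploid
#' bi-allelic site, with the read's mapping quality standing in for base
#' quality: the probability that a read's allele assignment is wrong is
#' `e = min(10^(-mapq/10), 0.5)` (so MAPQ 0 reads are uninformative rather
#' than anti-informative). For genotype `g` alternative copies,
#' each read contributes `(g/2) P(obs|alt) + (1-g/2) P(obs|ref)` with
#' `P(obs = alt | alt) = 1 - e`, `P(obs = alt | ref) = e` (and
#' symmetrically for reference observations); the site likelihood is the
#' product over reads. The genotype is the maximum-likelihood class under
#' a flat prior, GQ is the phred-scaled probability that it is wrong.
#'
#' @param evidence evidence tibble for one sample (from
#'   [classify_read_evidence()], subset to the sample).
#' @return one-row tibble: `gt` (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`),
#'   `gl` (list column, log10 likelihoods normalised so the maximum is 0),
#'   `dp`, `alt_count`, `gq`.
#' @export
genotype_likelihoods <- function(evidence) {
  if (!nrow(evidence)) {
    return(tibble::tibble(gt = "./.", gl = list(c(0, 0, 0)),
                          dp = 0L, alt_count = 0L, gq = 0L))
  }
  e <- pmin(10^(-evidence$mapq / 10), 0.5)
  is_alt <- evidence$allele == "alt"
  p_obs_alt <- ifelse(is_alt, 1 - e, e)   # P(obs | read from alt allele)
  p_obs_ref <- ifelse(is_alt, e, 1 - e)   # P(obs | read from ref allele)
  ll <- vapply(c(0, 1, 2), function(g) {
    sum(log10((g / 2) * p_obs_alt + (1 - g / 2) * p_obs_ref))
  }, numeric(1))
  gl <- ll - max(ll)
  post <- 10^gl / sum(10^gl)
  gidx <- which.max(gl)
  tibble::tibble(
    gt = c("0/0", "0/1", "1/1")[gidx],
    gl = list(gl),
    dp = nrow(evidence),
    alt_count = sum(is_alt),
    gq = phred(1 - post[gidx]))
}

#' Joint-calling site filter
#'
#' During joint calling a site is kept only when at least one individual
#' has `min_alt` (default 3) reads supporting the alternative allele;
#' weakly shared clipping scattered across many individuals does not by
#' itself trigger a call.
#'
#' @param per_sample_alt_counts named integer vector (or list) of
#'   alternative-evidence read counts per sample.
#' @param min_alt threshold (default 3).
#' @return logical scalar.
#' @export
joint_site_filter <- function(per_sample_alt_counts, min_alt = 3L) {
  counts <- unlist(per_sample_alt_counts, use.names = FALSE)
  length(counts) > 0 && max(counts) >= min_alt
}
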