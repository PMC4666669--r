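#' Candidate partner-breakpoint positions from SA/XA tags
#'
#' For each supplementary (`SA`) or alternative (`XA`) alignment attached
#' to a read supporting the candidate, the implied partner breakpoint is
#' the clip-adjacent boundary of that tag alignment. With the read's clip
#' on its right side, the clipped bases continue the sequence *past* the
#' breakpoint: on the same strand they begin at the tag alignment's start,
#' so the partner breakpoint is the tag start; on the opposite strand
#' (inversion geometry) the boundary swaps to the tag alignment's end.
#' Left-side clips mirror this rule.
#'
#' Reads with no SA/XA but a discordantly placed mate contribute a
#' low-precision fallback endpoint at the mate's far edge, marked
#' `precise = FALSE`; these are used only when no tag-derived cluster
#' exists and never trigger Smith-Waterman refinement.
#'
#' @param support_reads reads tibble for the reads supporting the
#'   candidate (must carry `sa`, `xa`, mate columns and derived CIGAR
#'   columns).
#' @param side clip side of the candidate (`"left"` or `"right"`).
#' @param insert_stats optional `c(mu, sigma)` used to recognise
#'   discordant mates for the fallback path.
#' @return tibble of endpoints: `chrom`, `pos`, `precise`, `source`
#'   (`"SA"`, `"XA"`, `"mate"`).
#' @export
candidate_endpoints <- function(support_reads, side,
                                insert_stats = c(mu = 400, sigma = 50)) {
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          precise = logical(), source = character())
  out <- empty
  for (tagcol in c("sa", "xa")) {
    tags <- support_reads[[tagcol]]
    parsed <- parse_tags_many(tags)
    if (!nrow(parsed)) next
    read_rev <- support_reads$reverse[parsed$tag_idx]
    read_strand <- ifelse(read_rev, "-", "+")
    same <- parsed$strand == read_strand
    use_start <- (side == "right") == same
    pos <- ifelse(use_start, parsed$pos, parsed$pos + parsed$ref_span)
    out <- dplyr::bind_rows(out, tibble::tibble(
      chrom = parsed$chrom, pos = as.integer(pos), precise = TRUE,
      source = toupper(tagcol)))
  }
  # mate-pair fallback: discordant mates of reads that carry no tags
  no_tag <- is.na(support_reads$sa) & is.na(support_reads$xa)
  disc <- no_tag & support_reads$paired & !support_reads$mate_unmapped &
    (support_reads$mate_chrom != support_reads$chrom |
       (!is.na(support_reads$tlen) &
          abs(support_reads$tlen) >
          insert_stats[["mu"]] + 3 * insert_stats[["sigma"]]))
  disc[is.na(disc)] <- FALSE
  if (any(disc)) {
    md <- support_reads[disc, ]
    # far edge of the mate: its end if it points back toward us, else start
    far <- ifelse(md$mate_reverse, md$mate_pos + 100L, md$mate_pos)
    out <- dplyr::bind_rows(out, tibble::tibble(
      chrom = md$mate_chrom, pos = as.integer(far), precise = FALSE,
      source = "mate"))
  }
  out
}

#' Cluster candidate endpoints on a 10 bp grid
#'
#' Endpoint positions are rounded to the nearest multiple of 10 bp (halves
#' rounded up) and grouped by `(chrom, rounded_pos)`. The cluster with the
#' highest read support wins; ties break to the smallest
#' `(chrom, rounded_pos)` for determinism.
#'
#' @param endpoints tibble from [candidate_endpoints()] (tag-derived
#'   endpoints take precedence: imprecise mate-pair endpoints are only
#'   clustered when no precise endpoint exists).
#' @return tibble of clusters sorted winner-first: `chrom`, `rounded_pos`,
#'   `support`, `member_positions` (list column), `precise`. Zero rows for
#'   empty input.
#' @export
cluster_endpoints <- function(endpoints) {
  if (!nrow(endpoints)) {
    return(tibble::tibble(chrom = character(), rounded_pos = integer(),
                          support = integer(), member_positions = list(),
                          precise = logical()))
  }
  if (any(endpoints$precise)) {
    endpoints <- endpoints[endpoints$precise, , drop = FALSE]
  }
  endpoints %>%
    dplyr::mutate(rounded_pos = round_to(.data$pos, 10L)) %>%
    dplyr::group_by(.data$chrom, .data$rounded_pos) %>%
    dplyr::summarise(support = dplyr::n(),
                     member_positions = list(.data$pos),
                     precise = any(.data$precise), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$support), .data$chrom,
                   .data$rounded_pos)
}

#' Default Smith-Waterman refinement parameters
#'
#' Local-alignment scoring and acceptance thresholds used when re-anchoring
#' a clip consensus inside the partner-breakpoint window: match +2,
#' mismatch -2, gap open -3, gap extend -1, a 200 bp window each side of
#' the clustered position, and acceptance only when at least 90% of the
#' consensus aligns at 80% identity or better. Chosen to accept true
#' breakpoint matches carrying a couple of sequencing errors in a
#' 10-30 bp consensus while rejecting random sequence.
#'
#' @return named list of parameters.
#' @export
sw_params <- function(match = 2, mismatch = -2, gap_open = 3,
                      gap_extend = 1, window = 200L,
                      min_coverage = 0.90, min_identity = 0.80) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, window = as.integer(window),
       min_coverage = min_coverage, min_identity = min_identity)
}

#' Refine a clustered partner breakpoint with Smith-Waterman alignment
#'
#' Aligns the clip consensus (and its reverse complement, to catch
#' inversion geometry) against the reference window around the winning
#' endpoint cluster. When the best local alignment covers at least
#' `min_coverage` of the consensus at `min_identity` or better, the
#' breakpoint is refined to the breakpoint-proximal end of the alignment:
#' the alignment start for a right-side clip matched in forward
#' orientation (the clip sequence *begins* at the partner breakpoint),
#' the alignment end in the mirrored cases.
#'
#' @param consensus consensus sequence (>= 10 bp).
#' @param ref_fetch reference accessor `function(chrom, start, end)`
#'   returning the sequence over a 0-based half-open range (see
#'   [fasta_accessor()]).
#' @param chrom,rounded_pos the winning cluster.
#' @param side clip side of the originating candidate.
#' @param contig_length length of `chrom`, used to truncate the window.
#' @param params list from [sw_params()].
#' @return refined 0-based position (integer) or `NA` when no acceptable
#'   alignment exists (the rounded cluster position then stands).
#' @export
refine_with_sw <- function(consensus, ref_fetch, chrom, rounded_pos, side,
                           contig_length = NULL, params = sw_params()) {
  if (is.na(consensus) || nchar(consensus) < 10L) return(NA_integer_)
  w0 <- max(0L, rounded_pos - params$window)
  w1 <- rounded_pos + params$window
  if (!is.null(contig_length)) w1 <- min(w1, contig_length)
  if (w1 - w0 < nchar(consensus)) return(NA_integer_)
  window_seq <- ref_fetch(chrom, w0, w1)

  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln_for <- Biostrings::pairwiseAlignment(
    consensus, window_seq, type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  aln_rev <- Biostrings::pairwiseAlignment(
    revcomp(consensus), window_seq, type = "local",
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  forward <- Biostrings::score(aln_for) >= Biostrings::score(aln_rev)
  aln <- if (forward) aln_for else aln_rev

  pat_w <- IRanges::width(Biostrings::pattern(aln))
  cov <- pat_w / nchar(consensus)
  # identity over the full gapped alignment length: gapped random matches
  # are penalised, true substitution-only matches are unaffected
  aln_len <- nchar(as.character(Biostrings::pattern(aln)))
  ident <- Biostrings::nmatch(aln) / max(aln_len, 1L)
  if (cov < params$min_coverage || ident < params$min_identity) {
    return(NA_integer_)
  }
  sub_r <- Biostrings::subject(aln)
  ref_start <- w0 + IRanges::start(sub_r) - 1L   # back to 0-based
  ref_end <- w0 + IRanges::end(sub_r)            # half-open end
  # breakpoint-proximal end: where the clip abuts the partner locus
  use_start <- (side == "right") == forward
  as.integer(if (use_start) ref_start else ref_end)
}

#' Large-SV and translocation filters
#'
#' Inter-chromosomal calls and intra-chromosomal calls spanning more than
#' `max_span` (default 1 Mb) are kept only when the partner breakpoint has
#' at least two reads supporting its exact (refined, un-rounded) position.
#' Independently, a candidate whose split reads map to more than
#' `max_chroms` (default 3) distinct chromosomes is discarded as a likely
#' repeat-driven mapping artefact. Only `SA` entries count as split reads
#' for the chromosome-count filter.
#'
#' @param calls calls tibble with `chrom`, `pos`, `be_chrom`, `be_pos`,
#'   `mate_exact_support`, `n_split_chroms`.
#' @param max_span intra-chromosomal span above which the extra mate
#'   support is required (default 1e6).
#' @param max_chroms maximum distinct chromosomes split reads may hit.
#' @return tibble with `keep` and `reason` (`"ok"`, `"weak_distal_mate"`,
#'   `"multi_chrom_splits"`).
#' @export
apply_distance_filters <- function(calls, max_span = 1e6, max_chroms = 3L) {
  has_mate <- !is.na(calls$be_chrom)
  inter <- has_mate & calls$be_chrom != calls$chrom
  big <- has_mate & !inter & abs(calls$be_pos - calls$pos) > max_span
  weak <- (inter | big) & calls$mate_exact_support < 2L
  multi <- calls$n_split_chroms > max_chroms
  tibble::tibble(
    keep = !weak & !multi,
    reason = dplyr::case_when(multi ~ "multi_chrom_splits",
                              weak ~ "weak_distal_mate",
                              TRUE ~ "ok"))
}
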