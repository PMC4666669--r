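#' Build the joint multi-sample clip index
#'
#' Pools clip signatures from all samples and drops records that cannot
#' support a breakpoint: duplicate-flagged reads (PCR/optical duplicates
#' re-report the same molecule and would inflate support into false
#' positives) and unmapped records (already excluded upstream). Secondary
#' and supplementary signatures are retained but keep `is_primary = FALSE`,
#' so they never count toward the support threshold.
#'
#' The index is keyed exactly by `(chrom, break_pos, side)` — no positional
#' fuzzing happens at this stage; nearby-but-distinct clip positions are
#' distinct keys.
#'
#' @param signatures a clip-signature tibble from [clip_signatures()],
#'   possibly row-bound across samples.
#' @return the filtered signature tibble, sorted by key.
#' @export
build_clip_index <- function(signatures) {
  out <- signatures[!signatures$duplicate, , drop = FALSE]
  dplyr::arrange(out, .data$chrom, .data$break_pos, .data$side)
}

#' Find breakpoint candidates from the clip index
#'
#' A position is interrogated as a putative SV breakpoint when at least
#' `min_support` primary reads (neither secondary- nor
#' supplementary-flagged) share the same clip boundary on the same side.
#'
#' @param index signature tibble from [build_clip_index()].
#' @param min_support minimum number of primary clipped reads sharing the
#'   breakpoint (default 3).
#' @return a candidate tibble sorted by `(chrom, pos, side)` with columns
#'   `chrom`, `pos`, `side`, `support` (primary signature count, reported
#'   later as `SP`) and `n_signatures` (all signatures at the key).
#' @export
find_candidates <- function(index, min_support = 3L) {
  if (!nrow(index)) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          side = character(), support = integer(),
                          n_signatures = integer()))
  }
  out <- index %>%
    dplyr::group_by(.data$chrom, pos = .data$break_pos, .data$side) %>%
    dplyr::summarise(support = sum(.data$is_primary),
                     n_signatures = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$support >= min_support) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$side)
  out
}

#' Collapse clip sequences into a breakpoint consensus
#'
#' Clipped overhangs sharing a breakpoint are stacked with the clip
#' boundary as a common anchor: left-side clips (bases preceding the
#' aligned segment) are right-aligned so their final bases line up at the
#' breakpoint; right-side clips are left-aligned. Shorter sequences are
#' padded. Each column's consensus base is the majority among non-pad
#' characters, ties resolved to the lexicographically smallest base so the
#' result is deterministic. The mismatch fraction is the share of non-pad
#' characters that disagree with their column consensus, over all columns.
#' The reported consensus sequence is trimmed to columns backed by at least
#' two sequences.
#'
#' This is deliberately an anchored, gap-free column vote rather than a
#' full multiple sequence alignment: the clip sequences share a fixed
#' anchor, so a gapped MSA adds little, and the column vote is
#' deterministic and linear in total bases.
#'
#' @param clip_seqs character vector of clip sequences (empty strings, e.g.
#'   from hard clips, are ignored for sequence but the candidate keeps
#'   their support).
#' @param side `"left"` or `"right"`: which side of the breakpoint the
#'   clips hang over (controls the anchoring direction).
#' @return one-row tibble: `sequence`, `n_input`, `aligned_columns`,
#'   `mismatch_fraction`.
#' @export
build_consensus <- function(clip_seqs, side = c("right", "left")) {
  side <- match.arg(side)
  seqs <- clip_seqs[!is.na(clip_seqs) & nzchar(clip_seqs)]
  if (!length(seqs)) {
    return(tibble::tibble(sequence = "", n_input = 0L,
                          aligned_columns = 0L, mismatch_fraction = 0))
  }
  L <- max(nchar(seqs))
  pad <- strrep(".", L - nchar(seqs))
  padded <- if (side == "left") paste0(pad, seqs) else paste0(seqs, pad)
  m <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)

  cons <- character(L)
  n_nonpad <- integer(L)
  n_agree <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col != "."]
    n_nonpad[j] <- length(col)
    if (!length(col)) { cons[j] <- ""; next }
    tab <- table(col)
    best <- sort(names(tab)[tab == max(tab)])[1]  # tie -> smallest base
    cons[j] <- best
    n_agree[j] <- tab[[best]]
  }
  total <- sum(n_nonpad)
  mism <- if (total > 0) (total - sum(n_agree)) / total else 0
  keep <- n_nonpad >= 2L
  tibble::tibble(sequence = paste(cons[keep], collapse = ""),
                 n_input = length(seqs), aligned_columns = L,
                 mismatch_fraction = mism)
}

#' Filter breakpoint consensus sequences
#'
#' Consensus sequences shorter than `min_len` bases or with more than
#' `max_mismatch` column disagreement are more likely mapping noise than
#' allelic signal and their candidates are discarded. Both comparisons
#' follow the stated rule strictly: length 10 passes, mismatch fraction
#' exactly 0.5 passes.
#'
#' @param sequence consensus sequence(s) (character).
#' @param mismatch_fraction matching mismatch fraction(s).
#' @param min_len minimum consensus length in bp (default 10).
#' @param max_mismatch maximum tolerated mismatch fraction (default 0.5,
#'   strict inequality).
#' @return tibble with `keep` (logical) and `reason`
#'   (`"ok"`, `"too_short"`, `"too_divergent"`).
#' @export
filter_consensus <- function(sequence, mismatch_fraction,
                             min_len = 10L, max_mismatch = 0.5) {
  too_short <- nchar(sequence) < min_len
  too_div <- !too_short & mismatch_fraction > max_mismatch
  tibble::tibble(
    keep = !too_short & !too_div,
    reason = dplyr::case_when(too_short ~ "too_short",
                              too_div ~ "too_divergent",
                              TRUE ~ "ok"))
}
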