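size_bin_labels <- c("50bp-1kb", "1kb-10kb", "10kb-100kb", "100kb-1Mb")

size_bin <- function(size) {
  cut(size, breaks = c(0, 1e3, 1e4, 1e5, Inf), labels = size_bin_labels,
      right = FALSE)
}

#' Truth intervals around simulated breakpoints
#'
#' One interval per breakpoint of each truth SV, `pad` bp up- and
#' downstream (half-open; a 500 bp deletion at `[10000, 10500)` with the
#' default pad yields `[9975, 10025)` and `[10475, 10525)`). Deletions,
#' duplications and inversions contribute their two reference breakpoints;
#' insertions contribute the recipient point plus both donor-interval
#' boundaries, since calls legitimately anchor on either side of the
#' copied sequence.
#'
#' @param truth truth tibble from [implant_svs()].
#' @param pad bp each side of the breakpoint (default 25).
#' @return interval tibble: `sv_id`, `sv_class`, `size`, `chrom`,
#'   `start`, `end`.
#' @export
truth_intervals <- function(truth, pad = 25L) {
  if (!nrow(truth)) {
    return(tibble::tibble(sv_id = character(), sv_class = character(),
                          size = integer(), chrom = character(),
                          start = integer(), end = integer()))
  }
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    if (r$sv_class == "INS") {
      bp <- tibble::tibble(chrom = c(r$chrom, r$donor_chrom,
                                     r$donor_chrom),
                           at = c(r$start, r$donor_start, r$donor_end))
    } else {
      bp <- tibble::tibble(chrom = r$chrom, at = c(r$start, r$end))
    }
    tibble::tibble(sv_id = r$sv_id, sv_class = r$sv_class, size = r$size,
                   chrom = bp$chrom, start = bp$at - pad, end = bp$at + pad)
  })
  dplyr::bind_rows(rows)
}

#' Write / read truth intervals as BED
#'
#' Columns: chrom, start, end, sv_id, class, size (the size column is an
#' extension over minimal BED so size-stratified benchmarking works from
#' the file alone; readers tolerate its absence).
#'
#' @param truth truth tibble.
#' @param path BED path.
#' @param pad interval padding passed to [truth_intervals()].
#' @export
write_truth_bed <- function(truth, path, pad = 25L) {
  ti <- truth_intervals(truth, pad = pad)
  utils::write.table(
    ti[, c("chrom", "start", "end", "sv_id", "sv_class", "size")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  tibble::tibble(sv_id = b[[4]],
                 sv_class = if (ncol(b) >= 5) b[[5]] else "UNK",
                 size = if (ncol(b) >= 6) as.integer(b[[6]]) else
                   NA_integer_,
                 chrom = b[[1]], start = as.integer(b[[2]]),
                 end = as.integer(b[[3]]))
}

# Greedy truth matching, best-supported call first. A call is a true
# positive only when both of its breakpoints fall inside (possibly
# different) intervals of the same truth SV; each truth SV can be
# recalled by at most one call, and further calls matching an
# already-recalled SV are redundant (neither TP nor FP). Calls matching
# no SV at all are false positives, one per emitted record.
match_calls <- function(calls, ints) {
  n <- nrow(calls)
  status <- rep("fp", n)
  matched_sv <- rep(NA_character_, n)
  if (!n) return(tibble::tibble(status = status, sv_id = matched_sv))
  supp <- calls$support
  supp[is.na(supp)] <- 0L
  ord <- order(-supp, calls$chrom, calls$pos)
  claimed <- character()
  for (i in ord) {
    in1 <- ints$chrom == calls$chrom[i] & calls$pos[i] >= ints$start &
      calls$pos[i] < ints$end
    if (is.na(calls$be_chrom[i]) || is.na(calls$be_pos[i])) next
    in2 <- ints$chrom == calls$be_chrom[i] & calls$be_pos[i] >= ints$start &
      calls$be_pos[i] < ints$end
    cand <- sort(intersect(ints$sv_id[in1], ints$sv_id[in2]))
    if (!length(cand)) next
    free <- setdiff(cand, claimed)
    if (length(free)) {
      status[i] <- "tp"
      matched_sv[i] <- free[1]
      claimed <- c(claimed, free[1])
    } else {
      status[i] <- "redundant"
      matched_sv[i] <- cand[1]
    }
  }
  tibble::tibble(status = status, sv_id = matched_sv)
}

#' Score a call set against truth intervals
#'
#' Extends every truth interval by `slop` bp in both directions, matches
#' calls greedily (see details in the source of `match_calls`), and
#' tabulates true positives, false positives and false negatives per SV
#' class and size bin, plus an `overall` row. Sensitivity is
#' `tp / (tp + fn)` over truth SVs; FDR is `fp / (tp + fp)` over emitted
#' records (0 when no positive calls exist). False positives are
#' stratified by their called class (`wc`, `UNK` when unclassified) and
#' called span.
#'
#' @param calls calls tibble (from [sv_call()] or [read_sv_vcf()]).
#' @param ints truth interval tibble from [truth_intervals()] /
#'   [read_truth_bed()].
#' @param slop extra bp added to both ends of every truth interval.
#' @return a `clipsv_bench` tibble: `sv_class`, `size_bin`, `slop`,
#'   `tp`, `fp`, `fn`, `sensitivity`, `fdr`.
#' @export
evaluate_calls <- function(calls, ints, slop = 0L) {
  ext <- ints
  ext$start <- ext$start - slop
  ext$end <- ext$end + slop
  m <- match_calls(calls, ext)

  truth_sv <- dplyr::distinct(ints[, c("sv_id", "sv_class", "size")])
  truth_sv$size_bin <- as.character(size_bin(truth_sv$size))
  truth_sv$recalled <- truth_sv$sv_id %in% m$sv_id[m$status == "tp"]

  tp_fn <- truth_sv %>%
    dplyr::group_by(.data$sv_class, .data$size_bin) %>%
    dplyr::summarise(tp = sum(.data$recalled),
                     fn = sum(!.data$recalled), .groups = "drop")

  fp_calls <- calls[m$status == "fp", , drop = FALSE]
  if (nrow(fp_calls)) {
    wc <- if ("wc" %in% names(fp_calls)) fp_calls$wc else
      rep(NA_character_, nrow(fp_calls))
    wc[is.na(wc)] <- "UNK"
    span <- ifelse(!is.na(fp_calls$be_chrom) &
                     fp_calls$be_chrom == fp_calls$chrom,
                   as.numeric(abs(fp_calls$be_pos - fp_calls$pos)),
                   NA_real_)
    fp_tab <- tibble::tibble(sv_class = wc,
                             size_bin = as.character(size_bin(span))) %>%
      dplyr::mutate(size_bin = ifelse(is.na(.data$size_bin), "unknown",
                                      .data$size_bin)) %>%
      dplyr::count(.data$sv_class, .data$size_bin, name = "fp")
  } else {
    fp_tab <- tibble::tibble(sv_class = character(),
                             size_bin = character(), fp = integer())
  }

  strata <- dplyr::full_join(tp_fn, fp_tab,
                             by = c("sv_class", "size_bin")) %>%
    dplyr::mutate(dplyr::across(c("tp", "fn", "fp"),
                                ~ifelse(is.na(.x), 0L, .x)))
  overall <- tibble::tibble(
    sv_class = "overall", size_bin = "overall",
    tp = sum(strata$tp), fn = sum(strata$fn),
    fp = sum(m$status == "fp"))
  out <- dplyr::bind_rows(strata, overall) %>%
    dplyr::mutate(
      slop = as.integer(slop),
      sensitivity = ifelse(.data$tp + .data$fn > 0,
                           .data$tp / (.data$tp + .data$fn), NA_real_),
      fdr = ifelse(.data$tp + .data$fp > 0,
                   .data$fp / (.data$tp + .data$fp), 0)) %>%
    dplyr::select("sv_class", "size_bin", "slop", "tp", "fp", "fn",
                  "sensitivity", "fdr")
  class(out) <- c("clipsv_bench", class(out))
  out
}

#' Breakpoint-accuracy sensitivity curve
#'
#' Ignores truth confidence intervals entirely: each truth breakpoint
#' becomes a point, `slop` bp of bi-directional tolerance is added to the
#' predicted breakpoints (equivalently, to the truth points), and the
#' usual both-breakpoints matching is applied. Sensitivity is
#' non-decreasing in slop by construction.
#'
#' @param calls calls tibble.
#' @param truth truth tibble (raw breakpoints, not a padded BED).
#' @param slops slop values in bp.
#' @param sv_class optional class filter applied to the truth set (e.g.
#'   `"DEL"` for the deletion accuracy assay).
#' @return a `clipsv_bpcurve` tibble: `slop`, `tp`, `fn`, `sensitivity`.
#' @export
breakpoint_accuracy_curve <- function(calls, truth,
                                      slops = c(1, 5, 10, 25, 50, 100, 500),
                                      sv_class = NULL) {
  if (!is.null(sv_class)) {
    truth <- truth[truth$sv_class %in% sv_class, , drop = FALSE]
  }
  pts <- truth_intervals(truth, pad = 0L)  # zero-width at the breakpoint
  n_truth <- dplyr::n_distinct(pts$sv_id)
  out <- purrr::map_dfr(slops, function(s) {
    ext <- pts
    ext$start <- ext$start - s
    ext$end <- ext$end + s + 1L   # inclusive +/- s around the point
    m <- match_calls(calls, ext)
    tp <- sum(m$status == "tp")
    tibble::tibble(slop = s, tp = tp, fn = n_truth - tp,
                   sensitivity = ifelse(n_truth > 0, tp / n_truth,
                                        NA_real_))
  })
  class(out) <- c("clipsv_bpcurve", class(out))
  out
}
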