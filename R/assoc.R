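#' Allele counts for the target/background association test
#'
#' Each called diploid genotype contributes two alleles to its cohort's
#' total `k` and 0/1/2 non-reference alleles to `n` for `0/0`, `0/1`,
#' `1/1` respectively; missing genotypes (`./.`) contribute nothing.
#'
#' @param genotypes tibble with `sample_id` and `gt` columns for one site.
#' @param target_samples,background_samples disjoint character vectors of
#'   sample ids.
#' @return one-row tibble: `n_t`, `k_t`, `n_b`, `k_b`, `n_c`, `k_c`,
#'   `af_t`, `af_b`, `af_c`. `NA` frequencies when a cohort has no called
#'   alleles (no LRT is emitted for such sites).
#' @export
assoc_counts <- function(genotypes, target_samples, background_samples) {
  if (length(intersect(target_samples, background_samples))) {
    stop("target and background sample sets overlap", call. = FALSE)
  }
  alt_copies <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  count_cohort <- function(samples) {
    gt <- genotypes$gt[genotypes$sample_id %in% samples]
    copies <- alt_copies[gt]
    called <- !is.na(copies)
    c(n = sum(copies[called]), k = 2L * sum(called))
  }
  t <- count_cohort(target_samples)
  b <- count_cohort(background_samples)
  tibble::tibble(
    n_t = t[["n"]], k_t = t[["k"]], n_b = b[["n"]], k_b = b[["k"]],
    n_c = t[["n"]] + b[["n"]], k_c = t[["k"]] + b[["k"]],
    af_t = ifelse(t[["k"]] > 0, t[["n"]] / t[["k"]], NA_real_),
    af_b = ifelse(b[["k"]] > 0, b[["n"]] / b[["k"]], NA_real_),
    af_c = ifelse(t[["k"]] + b[["k"]] > 0,
                  (t[["n"]] + b[["n"]]) / (t[["k"]] + b[["k"]]), NA_real_))
}

# binomial log-kernel n*ln(p) + (k-n)*ln(1-p) at the MLE p = n/k,
# with the 0*ln(0) := 0 convention
binom_log_kernel <- function(n, k) {
  p <- n / k
  term1 <- ifelse(n > 0, n * log(p), 0)
  term2 <- ifelse(k - n > 0, (k - n) * log(1 - p), 0)
  term1 + term2
}

#' Binomial likelihood-ratio statistic D between two cohorts
#'
#' `D = -2 ln[ B(n_c, k_c, af_c) / (B(n_t, k_t, af_t) B(n_b, k_b, af_b)) ]`
#' where `B` is the binomial kernel `p^n (1-p)^(k-n)` evaluated at each
#' group's own allele frequency, `0 ln 0 := 0`. The binomial coefficients
#' cancel from the ratio as implemented, making this the standard
#' two-sample binomial likelihood-ratio test: `D >= 0` always, `D = 0`
#' exactly when the two cohort frequencies are equal, and `D` is
#' asymptotically chi-squared with 1 df under the null.
#'
#' Inputs are vectorised; supply columns of an [assoc_counts()]-style
#' tibble to score many sites at once.
#'
#' @param n_t,k_t non-reference and total allele counts in the target.
#' @param n_b,k_b the same for the background.
#' @return numeric vector of D statistics (`NA` when either cohort has no
#'   alleles).
#' @export
lrt_statistic <- function(n_t, k_t, n_b, k_b) {
  d <- rep(NA_real_, length(n_t))
  ok <- k_t >= 1 & k_b >= 1
  d[ok] <- -2 * (binom_log_kernel(n_t[ok] + n_b[ok], k_t[ok] + k_b[ok]) -
                   binom_log_kernel(n_t[ok], k_t[ok]) -
                   binom_log_kernel(n_b[ok], k_b[ok]))
  pmax(d, 0)  # clamp floating-point negatives at the D = 0 fixed point
}

#' Convert the D statistic to a p-value
#'
#' Upper-tail chi-squared probability with one degree of freedom.
#'
#' @param d D statistic(s), must be non-negative.
#' @return p-value(s) in (0, 1].
#' @export
chi2_pvalue <- function(d) {
  if (any(d < 0, na.rm = TRUE)) {
    stop("negative D statistic: the likelihood-ratio model is violated",
         call. = FALSE)
  }
  stats::pchisq(d, df = 1, lower.tail = FALSE)
}

#' Association test across sites
#'
#' Convenience wrapper: computes cohort allele counts, the D statistic and
#' its chi-squared p-value for every site in a per-site genotype table.
#' Sites where either cohort ends up with zero called alleles get `NA`
#' (no LRT is written for them).
#'
#' @param genotypes tibble with `site_id`, `sample_id`, `gt`.
#' @param target_samples,background_samples disjoint sample id vectors.
#' @return tibble: `site_id`, the count columns, `D`, `p_value`.
#' @export
sv_association <- function(genotypes, target_samples, background_samples) {
  genotypes %>%
    dplyr::group_by(.data$site_id) %>%
    dplyr::group_modify(~assoc_counts(.x, target_samples,
                                      background_samples)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      D = lrt_statistic(.data$n_t, .data$k_t, .data$n_b, .data$k_b),
      p_value = ifelse(is.na(.data$D), NA_real_, chi2_pvalue(.data$D)))
}
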