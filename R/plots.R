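#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a benchmark result
#'
#' Sensitivity per SV class and size bin as a faceted bar chart; the
#' overall row is shown as a dashed reference line.
#'
#' @param object a `clipsv_bench` tibble from [evaluate_calls()].
#' @param metric `"sensitivity"` or `"fdr"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.clipsv_bench <- function(object, metric = c("sensitivity", "fdr"),
                                  ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  overall <- df[df$sv_class == "overall", , drop = FALSE]
  df <- df[df$sv_class != "overall" & df$sv_class != "UNK" &
             df$size_bin %in% size_bin_labels, , drop = FALSE]
  df$size_bin <- factor(df$size_bin, levels = size_bin_labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size_bin,
                                        y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sv_class)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "SV size", y = metric,
                  title = sprintf("%s at %d bp slop", metric,
                                  object$slop[1])) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (nrow(overall)) {
    p <- p + ggplot2::geom_hline(yintercept = overall[[metric]][1],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a breakpoint-accuracy curve
#'
#' Sensitivity as a function of the bi-directional slop added to the
#' predicted breakpoints.
#'
#' @param object a `clipsv_bpcurve` tibble from
#'   [breakpoint_accuracy_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.clipsv_bpcurve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$slop, y = .data$sensitivity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "breakpoint slop (bp)", y = "sensitivity") +
    ggplot2::theme_bw()
}
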