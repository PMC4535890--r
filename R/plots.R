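# ggplot2 views of the pipeline's result types.

#' @export
tidy.het_intensity_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("bin_lower", "bin_upper", "n_calls", "n_het",
                                 "het_fraction", "frac_calls_below")])
}

#' Plot the het-vs-intensity curve
#'
#' Per-bin heterozygous fraction against relative signal intensity, with
#' an optional reliability-threshold line and the chosen het level.
#'
#' @param object A [het_intensity_curve()].
#' @param threshold Optional intensity threshold to mark.
#' @param het_level Het level to mark, default 0.01.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.het_intensity_curve <- function(object, threshold = NULL,
                                         het_level = 0.01, ...) {
  df <- tidy(object)
  df <- df[df$n_calls > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lower + .data$bin_upper) / 2, y = .data$het_fraction)) +
    ggplot2::geom_col(width = attr(object, "bin_width") %||% 0.1,
                      fill = "grey35") +
    ggplot2::geom_hline(yintercept = het_level, linetype = "dotted",
                        colour = "red") +
    ggplot2::labs(x = "relative signal intensity (log2-ratio scale)",
                  y = "heterozygous fraction of calls") +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, colour = "blue")
  }
  p
}

#' @export
plot.het_intensity_curve <- function(x, ...) print(autoplot(x, ...))

#' @export
tidy.segment_coverage_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("bin_lower", "bin_upper", "bp_covered",
                                 "cumulative_bp")])
}

#' Plot the segment-coverage distribution
#'
#' Total segment length per mean-intensity bin (log scale), with optional
#' loss/gain threshold lines; the bimodal shape below zero is what the
#' loss threshold is derived from.
#'
#' @param object A [coverage_profile()].
#' @param loss_threshold,gain_threshold Optional boundaries to mark.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.segment_coverage_profile <- function(object, loss_threshold = NULL,
                                              gain_threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lower + .data$bin_upper) / 2, y = .data$bp_covered)) +
    ggplot2::geom_col(width = attr(object, "bin_width") %||% 0.1,
                      fill = "grey35") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "segment mean relative signal intensity",
                  y = "bp covered") +
    ggplot2::theme_minimal()
  for (v in c(loss_threshold, gain_threshold)) {
    if (!is.null(v) && is.finite(v)) {
      p <- p + ggplot2::geom_vline(xintercept = v, colour = "red",
                                   linetype = "dashed")
    }
  }
  p
}

#' @export
plot.segment_coverage_profile <- function(x, ...) print(autoplot(x, ...))

#' Plot cross-platform segment size agreement
#'
#' Log-log scatter of overlapped CNV-segment lengths, platform A against
#' platform B.
#'
#' @param object A [intersect_platforms()] report.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$len_A, y = .data$len_B,
                               colour = .data$opposite_state)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "platform A segment length (bp)",
                  y = "platform B segment length (bp)",
                  colour = "opposite state") +
    ggplot2::theme_minimal()
}

#' @export
plot.concordance_report <- function(x, ...) print(autoplot(x, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a
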