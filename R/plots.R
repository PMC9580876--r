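# ggplot2 views of the comparison results.

#' @describeIn concordance_table Mosaic-style tile plot of the paired 2x2
#'   call table.
#' @param object,x A `concordance_table`.
#' @param ... Unused.
#' @export
autoplot.concordance_table <- function(object, ...) {
  df <- tibble(
    st = factor(c("positive", "positive", "negative", "negative"),
                levels = c("positive", "negative")),
    mt = factor(c("positive", "negative", "positive", "negative"),
                levels = c("negative", "positive")),
    count = c(object$n_both_pos, object$n_st_only, object$n_mt_only,
              object$n_both_neg)
  )
  ggplot(df, aes(x = .data$st, y = .data$mt, fill = .data$count)) +
    geom_tile(colour = "grey30") +
    geom_text(aes(label = .data$count), colour = "white", size = 5) +
    scale_fill_gradient(low = "grey60", high = "grey10", guide = "none") +
    labs(x = "ST call", y = "MT call",
         title = sprintf("Call concordance (N = %d)", object$total)) +
    theme_minimal()
}

#' @describeIn pearson_loglog Scatter of the paired log10 levels with the
#'   fitted line.
#' @param object,x A `loglog_fit`.
#' @param ... Unused.
#' @export
autoplot.loglog_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$log10_st, y = .data$log10_mt)) +
    geom_point(alpha = 0.6) +
    labs(x = "log10 ST level (GE/mL)", y = "log10 MT level (GE/mL)",
         title = sprintf("ctDNA level correlation (n = %d, r = %.3f)",
                         object$n, object$r)) +
    theme_minimal()
  if (!object$degenerate) {
    p <- p + geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue")
  }
  p
}

#' Detection rates with Wilson intervals, by timing and method
#'
#' @param x An `mrd_comparison` from [compare_cohort()].
#' @return A ggplot object.
#' @export
plot_detection_rates <- function(x) {
  stopifnot(inherits(x, "mrd_comparison"))
  df <- x$detection |> filter(.data$n > 0)
  ggplot(df, aes(x = .data$timing, y = .data$rate, fill = .data$method)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                  position = position_dodge(width = 0.8), width = 0.2) +
    scale_y_continuous(limits = c(0, 1), labels = function(v) 100 * v) +
    labs(x = NULL, y = "ctDNA detection rate (%)", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
}

#' @describeIn plot_detection_rates Default plot for a comparison object.
#' @param object An `mrd_comparison`.
#' @param ... Unused.
#' @export
autoplot.mrd_comparison <- function(object, ...) {
  plot_detection_rates(object)
}
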