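#' MA plot of one array against the median reference
#'
#' Diagnostic for intensity-dependent bias: M (array minus reference) against
#' A (their mean) with a lowess trend line. On well-normalized data the trend
#' hugs M = 0.
#'
#' @param expr Log2-scale expression tibble.
#' @param array Array id (column name) to plot; defaults to the first array.
#' @param span Lowess span for the trend line.
#' @return A ggplot object.
#' @export
plot_ma <- function(expr, array = NULL, span = 0.3) {
  expr_assert(expr)
  array <- array %||% expr_arrays(expr)[1]
  if (!array %in% expr_arrays(expr)) {
    abort(sprintf("Array '%s' not found.", array))
  }
  m <- expr_matrix(expr)
  ref <- apply(m, 1, median)
  df <- tibble::tibble(
    A = (m[, array] + ref) / 2,
    M = m[, array] - ref
  )
  df$trend <- ma_lowess_fit(df$A, df$M, span, 3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "#b2182b") +
    ggplot2::labs(
      title = sprintf("MA plot: %s vs median reference", array),
      x = "A = mean log2 intensity", y = "M = log2 ratio"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param object A [differential_table()] result.
#' @param alpha Significance level highlighted.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mirna_de <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$status <- dplyr::case_when(
    df$q_value <= alpha ~ "q ≤ alpha",
    df$p_value <= alpha ~ "p ≤ alpha",
    TRUE ~ "not significant"
  )
  finite_p <- df$p_value[df$p_value > 0]
  cap <- if (length(finite_p) > 0) -log10(min(finite_p)) + 1 else 1
  df$neglog_p <- ifelse(df$p_value > 0, -log10(df$p_value), cap)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_log2_diff, y = .data$neglog_p, colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(
      "q ≤ alpha" = "#b2182b", "p ≤ alpha" = "#ef8a62",
      "not significant" = "grey60"
    )) +
    ggplot2::labs(
      x = "mean log2(scar) - log2(normal)", y = "-log10 p",
      colour = NULL, title = "Paired differential expression"
    ) +
    ggplot2::theme_minimal()
}

#' Screening-score profile of a DC-SIS result
#'
#' Squared distance correlation by rank, with the retained model (top d)
#' highlighted.
#'
#' @param object A [dcsis_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dcsis_screen <- function(object, ...) {
  df <- tidy(object)
  d <- attr(object, "d")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$omega, colour = .data$selected
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = d + 0.5, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c("TRUE" = "#2166ac", "FALSE" = "grey60")) +
    ggplot2::labs(
      x = "rank", y = expression(omega ~ "(squared distance correlation)"),
      colour = "selected",
      title = sprintf("DC-SIS screening (d = %d of %d)", d, nrow(df))
    ) +
    ggplot2::theme_minimal()
}
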