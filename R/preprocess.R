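#' Subtract scanner background from raw intensities
#'
#' Subtracts a global or per-array background estimate and clamps the result
#' at a small positive floor so the subsequent log2 transform stays finite.
#'
#' @param expr Raw expression tibble (`mirna_id` + one column per array),
#'   non-negative intensities.
#' @param background Single non-negative number, or a vector named by array
#'   id giving a per-array background.
#' @param floor Lower clamp applied after subtraction (raw scale).
#'
#' @return A new expression tibble; the input is not modified.
#' @export
#' @examples
#' expr <- tibble::tibble(mirna_id = "m1", A1 = 100, A2 = 10)
#' subtract_background(expr, background = 20)
subtract_background <- function(expr, background = 0, floor = 1) {
  expr_assert(expr)
  check_number(floor, "floor", min = 0)
  arrays <- expr_arrays(expr)
  if (length(background) == 1 && is.null(names(background))) {
    background <- setNames(rep(as.numeric(background), length(arrays)), arrays)
  }
  if (!all(arrays %in% names(background))) {
    abort(sprintf(
      "`background` must be a single number or named per array; missing: %s.",
      toString(setdiff(arrays, names(background)))
    ))
  }
  if (any(!is.finite(background)) || any(background < 0)) {
    abort("`background` must be finite and >= 0.")
  }
  m <- expr_matrix(expr)
  m <- sweep(m, 2, background[arrays], "-")
  m[m < floor] <- floor
  expr_tibble(m, expr_ids(expr))
}

#' Log2-transform an intensity matrix
#'
#' @param expr Expression tibble with strictly positive values.
#' @return The same tibble on the log2 scale.
#' @export
log2_transform <- function(expr) {
  expr_assert(expr)
  m <- expr_matrix(expr)
  if (any(!is.finite(m)) || any(m <= 0)) {
    bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-positive intensity at miRNA '%s', array '%s'; subtract background with a positive floor first.",
      expr_ids(expr)[bad[1]], expr_arrays(expr)[bad[2]]
    ))
  }
  expr_tibble(log2(m), expr_ids(expr))
}

# Robust lowess fit of M on A evaluated at the original A values.
# stats::lowess sorts and deduplicates x, so interpolate back.
ma_lowess_fit <- function(A, M, span, iterations) {
  fit <- lowess(A, M, f = span, iter = iterations)
  approx(fit$x, fit$y, xout = A, rule = 2, ties = "ordered")$y
}

#' MA-lowess normalization against a median reference array
#'
#' Removes per-array intensity-dependent bias. For each array `x`, with
#' reference `r` = per-miRNA median across all arrays, the MA coordinates
#' `A = (x + r) / 2`, `M = x - r` are formed; a robust locally weighted
#' regression of M on A is fitted and subtracted, so systematic trends of an
#' array against the consensus vanish while per-miRNA biology is preserved.
#'
#' @param expr Log2-scale expression tibble with at least 10 miRNAs and 2
#'   arrays.
#' @param span Lowess span: fraction of points in each local window.
#' @param iterations Robustness (bisquare reweighting) iterations.
#'
#' @return The normalized tibble, with a `provenance` attribute recording the
#'   parameters and reference construction.
#' @export
lowess_normalize <- function(expr, span = 0.3, iterations = 3) {
  expr_assert(expr)
  check_number(span, "span", min = 1e-6, max = 1)
  check_number(iterations, "iterations", min = 0, integerish = TRUE)
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("lowess normalization needs at least 2 arrays.")
  if (nrow(m) < 10) abort("lowess normalization needs at least 10 miRNAs.")
  ref <- apply(m, 1, median)
  out <- m
  for (j in seq_len(ncol(m))) {
    A <- (m[, j] + ref) / 2
    M <- m[, j] - ref
    out[, j] <- m[, j] - ma_lowess_fit(A, M, span, iterations)
  }
  res <- expr_tibble(out, expr_ids(expr))
  attr(res, "provenance") <- list(
    step = "lowess_normalize", reference = "per-miRNA median pseudo-array",
    span = span, iterations = iterations
  )
  res
}

#' Filter undetected miRNAs
#'
#' Keeps rows whose log2 signal exceeds `min_signal` in at least
#' `ceiling(min_fraction * n_arrays)` arrays; rows that fail are removed
#' (never NA-filled) and the removal count is reported via a message.
#'
#' @param expr Log2-scale expression tibble.
#' @param min_signal Detection threshold on the log2 scale. The default,
#'   `log2(2)`, is twice the background floor of [subtract_background()].
#' @param min_fraction Minimum fraction of arrays in which a miRNA must be
#'   detected.
#'
#' @return The filtered tibble.
#' @export
detection_filter <- function(expr, min_signal = log2(2), min_fraction = 0.5) {
  expr_assert(expr)
  check_number(min_signal, "min_signal")
  check_number(min_fraction, "min_fraction", min = 0, max = 1)
  m <- expr_matrix(expr)
  need <- ceiling(min_fraction * ncol(m))
  keep <- rowSums(m > min_signal) >= need
  if (any(!keep)) {
    inform(sprintf(
      "detection_filter: removed %d of %d miRNAs (min_signal = %.3g in >= %d arrays).",
      sum(!keep), nrow(m), min_signal, need
    ))
  }
  expr[keep, , drop = FALSE]
}

#' Full preprocessing: background subtraction, log2, lowess, detection filter
#'
#' Convenience composition of the individual steps, in the order a scanner
#' export is prepared for analysis.
#'
#' @inheritParams subtract_background
#' @inheritParams lowess_normalize
#' @inheritParams detection_filter
#' @return A normalized, filtered log2 expression tibble with a `provenance`
#'   attribute describing every step applied.
#' @export
preprocess_expression <- function(expr, background = 0, floor = 1,
                                  span = 0.3, iterations = 3,
                                  min_signal = log2(2 * floor),
                                  min_fraction = 0.5) {
  out <- expr |>
    subtract_background(background = background, floor = floor) |>
    log2_transform() |>
    lowess_normalize(span = span, iterations = iterations) |>
    detection_filter(min_signal = min_signal, min_fraction = min_fraction)
  attr(out, "provenance") <- list(
    background = background, floor = floor, span = span,
    iterations = iterations, reference = "per-miRNA median pseudo-array",
    min_signal = min_signal, min_fraction = min_fraction,
    n_removed = nrow(expr) - nrow(out)
  )
  out
}
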