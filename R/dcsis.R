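#' Squared distance covariance (V-statistic)
#'
#' The biased V-statistic estimator: with pairwise distance matrices
#' `a_kl = |x_k - x_l|` and `b_kl = |y_k - y_l|`, double-center each
#' (`A_kl = a_kl - rowmean_k - colmean_l + grandmean`, analogously `B`) and
#' average the elementwise product, `dCov^2 = mean(A * B)`. Always
#' non-negative in exact arithmetic; tiny negative rounding residues are
#' clamped to zero.
#'
#' @param x,y Numeric vectors of equal length `m >= 2`.
#' @return A single non-negative number.
#' @export
#' @examples
#' distance_covariance_sq(c(0, 1), c(0, 1)) # 0.25
distance_covariance_sq <- function(x, y) {
  m <- length(x)
  if (length(y) != m) abort("`x` and `y` must have equal length.")
  if (m < 2) abort("Distance covariance needs at least 2 observations.")
  A <- dcenter(abs(outer(x, x, "-")))
  B <- dcenter(abs(outer(y, y, "-")))
  max(sum(A * B) / m^2, 0)
}

# Double-center a symmetric distance matrix.
dcenter <- function(D) {
  rm <- rowMeans(D)
  D - rm - rep(rm, each = nrow(D)) + mean(D)
}

#' Squared distance correlation
#'
#' `dCor^2(x, y) = dCov^2(x, y) / sqrt(dCov^2(x, x) * dCov^2(y, y))`, a
#' dependence measure in \[0, 1\] that vanishes iff `x` and `y` are
#' independent (in the population). Defined as 0 when either input is
#' constant.
#'
#' @inheritParams distance_covariance_sq
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' distance_correlation_sq(1:10, 2 * (1:10) + 3) # 1
distance_correlation_sq <- function(x, y) {
  vx <- distance_covariance_sq(x, x)
  vy <- distance_covariance_sq(y, y)
  if (vx == 0 || vy == 0) return(0)
  min(distance_covariance_sq(x, y) / sqrt(vx * vy), 1)
}

#' Screening model size d = multiplier * floor(n / log(n))
#'
#' The number of top-ranked predictors retained by sure independence
#' screening. The natural logarithm is the screening-literature convention;
#' the base is exposed because it changes d materially at small n.
#'
#' @param n Sample size (number of arrays entering the screen), `n >= 2`.
#' @param multiplier Positive integer scaling of the floor term.
#' @param log_base Base of the logarithm.
#' @return A positive integer, at least 1.
#' @export
#' @examples
#' model_size(18) # 36
#' model_size(9) # 24
model_size <- function(n, multiplier = 6, log_base = exp(1)) {
  check_number(n, "n", min = 2, integerish = TRUE)
  check_number(multiplier, "multiplier", min = 1, integerish = TRUE)
  check_number(log_base, "log_base", min = 1 + 1e-9)
  max(as.integer(multiplier * floor(n / log(n, base = log_base))), 1L)
}

#' Distance-correlation sure independence screening (DC-SIS)
#'
#' Ranks every miRNA by the squared distance correlation between its
#' expression vector across arrays and the binary tissue response
#' (1 = scar, 0 = normal), and selects the top `d = model_size(n_arrays)`.
#' The method is model-free: no linear (or any) model links expression to
#' the response, so it complements the paired t-test as a third selection
#' criterion. Pairing is ignored — the screen treats arrays as the sample.
#'
#' @param expr Normalized log2 expression tibble.
#' @param samples Sample sheet tibble covering the matrix columns.
#' @param multiplier,log_base Passed to [model_size()].
#'
#' @return A tibble of class `"dcsis_screen"` with columns `mirna_id`,
#'   `omega` (squared distance correlation), `rank` (1 = largest omega, ties
#'   broken by id lexicographically), `selected`; attributes `n_used`, `d`,
#'   `multiplier`, `log_base`.
#' @export
dcsis_screen <- function(expr, samples, multiplier = 6, log_base = exp(1)) {
  expr_assert(expr)
  sheet_assert(samples, expr_arrays(expr))
  m <- expr_matrix(expr)
  y <- as.numeric(samples$condition[match(colnames(m), samples$array_id)] == "scar")
  n <- length(y)
  d <- model_size(n, multiplier = multiplier, log_base = log_base)

  # The response's centered distance matrix is shared by every miRNA.
  B <- dcenter(abs(outer(y, y, "-")))
  vy <- sum(B * B) / n^2
  omega <- apply(m, 1, function(x) {
    A <- dcenter(abs(outer(x, x, "-")))
    vx <- sum(A * A) / n^2
    if (vx == 0 || vy == 0) return(0)
    min(max(sum(A * B) / n^2, 0) / sqrt(vx * vy), 1)
  })

  if (all(omega == 0)) {
    warn("dcsis_screen: all screening scores are zero; selection falls back to id order.")
  }
  ord <- order(-omega, expr_ids(expr))
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  out <- tibble::tibble(
    mirna_id = expr_ids(expr),
    omega = omega,
    rank = rank,
    selected = rank <= min(d, length(rank))
  ) |>
    dplyr::arrange(.data$rank)
  attr(out, "n_used") <- n
  attr(out, "d") <- d
  attr(out, "multiplier") <- multiplier
  attr(out, "log_base") <- log_base
  class(out) <- c("dcsis_screen", class(out))
  out
}

#' @exportS3Method generics::tidy
#' @rdname dcsis_screen
#' @param x A `"dcsis_screen"` result.
#' @param ... Unused.
tidy.dcsis_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dcsis_screen")
  out
}

#' @exportS3Method generics::glance
#' @rdname dcsis_screen
glance.dcsis_screen <- function(x, ...) {
  tibble::tibble(
    n_mirnas = nrow(x),
    n_used = attr(x, "n_used"),
    d = attr(x, "d"),
    multiplier = attr(x, "multiplier"),
    log_base = attr(x, "log_base"),
    n_selected = sum(x$selected)
  )
}
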