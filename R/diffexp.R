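#' Paired t-test for one miRNA
#'
#' The traditional paired Student t-test on per-patient differences
#' `d = scar - normal`: `t = mean(d) / (sd(d) / sqrt(n))` with the
#' `n - 1`-denominator sample SD and a two-sided p-value on `n - 1` degrees
#' of freedom. Degenerate zero-variance rows are kept total: all-zero
#' differences give `t = 0, p = 1`; constant nonzero differences give
#' `t = +/-Inf, p = 0` (and are flagged downstream).
#'
#' @param scar,normal Numeric vectors of log2 expression, aligned by patient.
#' @return A one-row tibble with `t_stat`, `df`, `p_value`.
#' @export
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))
paired_t_test <- function(scar, normal) {
  if (length(scar) != length(normal)) {
    abort("`scar` and `normal` must have equal length (aligned by patient).")
  }
  n <- length(scar)
  if (n < 2) abort("Paired t-test needs at least 2 pairs.")
  d <- scar - normal
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  }
  tibble::tibble(t_stat = t_stat, df = n - 1L, p_value = p)
}

#' Adjust p-values for multiple testing (FDR)
#'
#' Benjamini–Hochberg step-up adjusted p-values (the default), or a simple
#' Storey-style q-value that rescales BH by the estimated null proportion
#' `pi0 = min(1, mean(p > 0.5) / 0.5)`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"storey"`.
#' @return Adjusted values in input order; never smaller than `p`.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
fdr_adjust <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values.")
  }
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    q <- pmax(pmin(pi0 * q, 1), p)
  }
  q
}

#' Per-miRNA paired differential expression table
#'
#' Applies the paired t-test to every miRNA using the pairing defined by the
#' sample sheet, adjusts all p-values jointly for the false discovery rate,
#' and attaches fold change and direction. This implements selection
#' criteria 1 (p <= alpha) and 2 (q <= alpha) of the three-criteria screen.
#'
#' @param expr Normalized log2 expression tibble (`mirna_id` + array columns).
#' @param samples Sample sheet tibble (`array_id`, `patient_id`, `condition`)
#'   defining one complete scar/normal pair per patient.
#' @param fdr_method Passed to [fdr_adjust()].
#'
#' @return A tibble of class `"mirna_de"`, sorted by p ascending (ties by
#'   miRNA id), with columns `mirna_id`, `mean_log2_diff`, `fold_change`
#'   (`2^mean_log2_diff`), `direction` (`elevated`/`lowered`/`unchanged`),
#'   `t_stat`, `df`, `p_value`, `q_value`, and attribute `n_pairs`. Rows with
#'   zero-variance differences are retained with degenerate p-values and
#'   counted in a message.
#' @export
differential_table <- function(expr, samples, fdr_method = c("bh", "storey")) {
  fdr_method <- match.arg(fdr_method)
  expr_assert(expr)
  sheet_assert(samples, expr_arrays(expr))
  m <- expr_matrix(expr)

  sc <- samples[samples$condition == "scar", ]
  no <- samples[samples$condition == "normal", ]
  no <- no[match(sc$patient_id, no$patient_id), ]
  d <- m[, sc$array_id, drop = FALSE] - m[, no$array_id, drop = FALSE]

  n <- ncol(d)
  if (n < 2) abort("Need at least 2 patient pairs.")
  mean_d <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mean_d)^2) / (n - 1))
  t_stat <- ifelse(sd_d == 0,
    ifelse(mean_d == 0, 0, sign(mean_d) * Inf),
    mean_d / (sd_d / sqrt(n))
  )
  p <- ifelse(sd_d == 0,
    ifelse(mean_d == 0, 1, 0),
    2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  )
  n_degenerate <- sum(sd_d == 0)
  if (n_degenerate > 0) {
    inform(sprintf(
      "differential_table: %d zero-variance miRNA(s) retained with degenerate p-values.",
      n_degenerate
    ))
  }

  mean_d <- unname(mean_d)
  t_stat <- unname(t_stat)
  p <- unname(p)
  out <- tibble::tibble(
    mirna_id = expr_ids(expr),
    mean_log2_diff = mean_d,
    fold_change = 2^mean_d,
    direction = dplyr::case_when(
      mean_d > 0 ~ "elevated",
      mean_d < 0 ~ "lowered",
      TRUE ~ "unchanged"
    ),
    t_stat = t_stat,
    df = n - 1L,
    p_value = p,
    q_value = fdr_adjust(p, method = fdr_method)
  ) |>
    dplyr::arrange(.data$p_value, .data$mirna_id)
  attr(out, "n_pairs") <- n
  class(out) <- c("mirna_de", class(out))
  out
}

#' @exportS3Method generics::tidy
#' @rdname differential_table
#' @param x A `"mirna_de"` table.
#' @param ... Unused.
tidy.mirna_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirna_de")
  out
}

#' @exportS3Method generics::glance
#' @rdname differential_table
#' @param alpha Significance level used by [glance()] to count selections.
glance.mirna_de <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_mirnas = nrow(x),
    n_pairs = attr(x, "n_pairs"),
    n_p_significant = sum(x$p_value <= alpha),
    n_q_significant = sum(x$q_value <= alpha),
    n_elevated = sum(x$direction == "elevated"),
    n_lowered = sum(x$direction == "lowered")
  )
}
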