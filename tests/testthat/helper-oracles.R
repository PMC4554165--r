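# Independent oracles, deliberately naive and sharing no helpers with the
# package implementation.

# Squared distance covariance by explicit double loops over the
# double-centering definition.
oracle_dcov_sq <- function(x, y) {
  m <- length(x)
  a <- matrix(0, m, m)
  b <- matrix(0, m, m)
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      a[k, l] <- abs(x[k] - x[l])
      b[k, l] <- abs(y[k] - y[l])
    }
  }
  A <- matrix(0, m, m)
  B <- matrix(0, m, m)
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      A[k, l] <- a[k, l] - mean(a[k, ]) - mean(a[, l]) + mean(a)
      B[k, l] <- b[k, l] - mean(b[k, ]) - mean(b[, l]) + mean(b)
    }
  }
  total <- 0
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      total <- total + A[k, l] * B[k, l]
    }
  }
  total / m^2
}

# Upper-tail overlap probability P(X >= k) by enumerating every possible
# draw of n items from a universe of N containing K marked items.
oracle_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Small hand-buildable expression table + matching sample sheet.
make_expr <- function(values, ids = NULL, arrays = NULL) {
  values <- as.matrix(values)
  ids <- ids %||% sprintf("miR-%04d", seq_len(nrow(values)))
  arrays <- arrays %||% sprintf("A%02d", seq_len(ncol(values)))
  colnames(values) <- arrays
  dplyr::bind_cols(
    tibble::tibble(mirna_id = ids),
    tibble::as_tibble(as.data.frame(values, optional = TRUE))
  )
}

make_sheet <- function(n_patients) {
  tibble::tibble(
    array_id = sprintf("A%02d", seq_len(2 * n_patients)),
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)), each = 2),
    condition = rep(c("scar", "normal"), times = n_patients)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
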