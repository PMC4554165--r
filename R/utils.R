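# Internal helpers shared across modules. An expression table is a tibble
# whose first column is `mirna_id` and whose remaining columns are arrays;
# a sample sheet is a tibble with columns array_id, patient_id, condition.

expr_assert <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) {
    abort(sprintf("`%s` must be a data frame with a `mirna_id` column.", arg))
  }
  if (!identical(names(expr)[1], "mirna_id")) {
    abort(sprintf("`%s` must have `mirna_id` as its first column.", arg))
  }
  if (ncol(expr) < 2) {
    abort(sprintf("`%s` has no array columns.", arg))
  }
  if (anyDuplicated(expr$mirna_id) > 0) {
    abort(sprintf("`%s` has duplicated miRNA identifiers.", arg))
  }
  if (anyDuplicated(names(expr)) > 0) {
    abort(sprintf("`%s` has duplicated array identifiers.", arg))
  }
  invisible(expr)
}

expr_ids <- function(expr) expr$mirna_id

expr_arrays <- function(expr) names(expr)[-1]

# Numeric matrix view (rows = miRNAs, columns = arrays), id order preserved.
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$mirna_id
  m
}

# Rebuild an expression tibble from a matrix, preserving column names.
expr_tibble <- function(values, mirna_id) {
  out <- tibble::as_tibble(as.data.frame(values, optional = TRUE))
  dplyr::bind_cols(tibble::tibble(mirna_id = mirna_id), out)
}

sheet_assert <- function(samples, arrays = NULL) {
  need <- c("array_id", "patient_id", "condition")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    abort("`samples` must have columns array_id, patient_id, condition.")
  }
  bad <- setdiff(unique(samples$condition), c("scar", "normal"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition value(s): %s.", toString(bad)))
  }
  if (anyDuplicated(samples$array_id) > 0) {
    abort("`samples` has duplicated array identifiers.")
  }
  counts <- table(samples$patient_id, samples$condition)
  ok <- nrow(counts) > 0 && all(counts == 1) && ncol(counts) == 2
  if (!ok) {
    off <- rownames(counts)[rowSums(counts != 1) > 0]
    abort(sprintf(
      "Incomplete pairing: each patient needs exactly one scar and one normal array (offending patients: %s).",
      toString(off %||% "none listed")
    ))
  }
  if (!is.null(arrays)) {
    missing <- setdiff(arrays, samples$array_id)
    extra <- setdiff(samples$array_id, arrays)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(sprintf(
        "Sample sheet does not match matrix columns (missing: %s; extra: %s).",
        toString(missing), toString(extra)
      ))
    }
  }
  invisible(samples)
}

# round() halves-to-even; printed summary tables round half away from zero.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x <= max
  if (ok && integerish) ok <- abs(x - round(x)) < 1e-8
  if (!ok) {
    abort(sprintf(
      "`%s` must be a %s in [%s, %s]; got %s.",
      name, if (integerish) "whole number" else "number",
      format(min), format(max), toString(x)
    ))
  }
  invisible(x)
}
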