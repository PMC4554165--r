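#' Write a simulated (or real) paired miRNA dataset to disk
#'
#' Emits the expression matrix as tab-separated text (first column
#' `mirna_id`, header = array ids), the sample sheet as CSV, and — when
#' ground truth is available — the planted effects as JSON
#' (`{"de": [{"id": ..., "log2_effect": ...}], "seed": ...}`). All files
#' round-trip losslessly through [read_expression_matrix()],
#' [read_sample_sheet()] and [read_ground_truth()].
#'
#' @param dataset A `"mirna_sim"` object from [simulate_mirna_dataset()], or
#'   a list with elements `expression`, `samples` and optionally `truth` and
#'   `config`.
#' @param dir Output directory (created if absent).
#'
#' @return Invisibly, a named character vector of the files written.
#' @export
write_mirna_dataset <- function(dataset, dir) {
  expr_assert(dataset$expression, "dataset$expression")
  sheet_assert(dataset$samples, expr_arrays(dataset$expression))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.csv")
  )
  readr::write_tsv(dataset$expression, paths[["expression"]])
  readr::write_csv(dataset$samples, paths[["samples"]])
  if (!is.null(dataset$truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    truth <- list(
      de = lapply(seq_len(nrow(dataset$truth)), function(i) {
        list(
          id = dataset$truth$mirna_id[i],
          log2_effect = dataset$truth$log2_effect[i]
        )
      }),
      seed = if (!is.null(dataset$config)) dataset$config$seed else NA_integer_
    )
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects the dialect written by [write_mirna_dataset()]: a header line
#' `mirna_id<TAB><array ids>` followed by one row per miRNA.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `mirna_id` first and one numeric column per array.
#' @export
read_expression_matrix <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "mirna_id"
  expr$mirna_id <- as.character(expr$mirna_id)
  expr_assert(expr)
  expr
}

#' Read a sample sheet mapping arrays to patients and conditions
#'
#' @param path Path to a CSV with columns `array_id`, `patient_id`,
#'   `condition` (values `scar` / `normal`).
#' @return A validated tibble (one complete pair per patient).
#' @export
read_sample_sheet <- function(path) {
  samples <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  sheet_assert(samples)
  samples
}

#' Read planted ground truth written by [write_mirna_dataset()]
#'
#' @param path Path to the truth JSON file.
#' @return A tibble with columns `mirna_id` and `log2_effect`.
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble::tibble(
    mirna_id = purrr::map_chr(truth$de, "id"),
    log2_effect = purrr::map_dbl(truth$de, "log2_effect")
  )
}
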