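#' Configuration for an end-to-end pipeline run
#'
#' Validates every stage's parameters up front (fail-fast), so a run never
#' dies halfway through on a bad setting. Either a simulation configuration
#' or paths to a user-supplied expression matrix and sample sheet must be
#' given.
#'
#' @param simulation A [sim_config()], or `NULL` when analysing user data.
#' @param expression_path,samples_path Paths to a TSV expression matrix and a
#'   CSV sample sheet (used when `simulation` is `NULL`).
#' @param background,floor,span,iterations,min_signal,min_fraction
#'   Preprocessing parameters; see [preprocess_expression()]. By default the
#'   background subtracted equals the simulation's `background_level`.
#' @param alpha Significance level for criteria 1 and 2.
#' @param fdr_method `"bh"` or `"storey"`.
#' @param multiplier,log_base DC-SIS model-size parameters; see
#'   [model_size()].
#' @param gmt_path,query_path Optional paths to a GMT collection and a
#'   newline-separated query gene list; when both are given the enrichment
#'   stage runs.
#' @param enrich_top Number of top sets reported by the enrichment stage.
#' @param seed Overrides the simulation seed when not `NULL`.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            expression_path = NULL,
                            samples_path = NULL,
                            background = NULL,
                            floor = 1,
                            span = 0.3,
                            iterations = 3,
                            min_signal = log2(2 * floor),
                            min_fraction = 0.5,
                            alpha = 0.05,
                            fdr_method = "bh",
                            multiplier = 6,
                            log_base = exp(1),
                            gmt_path = NULL,
                            query_path = NULL,
                            enrich_top = 10,
                            seed = NULL) {
  if (is.null(simulation) && (is.null(expression_path) || is.null(samples_path))) {
    abort("Provide either `simulation` or both `expression_path` and `samples_path`.")
  }
  if (!is.null(simulation)) {
    if (!inherits(simulation, "sim_config")) {
      abort("`simulation` must be created with sim_config().")
    }
    if (!is.null(seed)) {
      args <- unclass(simulation)
      args$seed <- seed
      simulation <- do.call(sim_config, args)
    }
    if (is.null(background)) background <- simulation$background_level
  }
  background <- background %||% 0
  check_number(floor, "floor", min = 0)
  check_number(span, "span", min = 1e-6, max = 1)
  check_number(iterations, "iterations", min = 0, integerish = TRUE)
  check_number(min_signal, "min_signal")
  check_number(min_fraction, "min_fraction", min = 0, max = 1)
  check_number(alpha, "alpha", min = 0, max = 1)
  fdr_method <- match.arg(fdr_method, c("bh", "storey"))
  check_number(multiplier, "multiplier", min = 1, integerish = TRUE)
  check_number(log_base, "log_base", min = 1 + 1e-9)
  check_number(enrich_top, "enrich_top", min = 1, integerish = TRUE)
  if (xor(is.null(gmt_path), is.null(query_path))) {
    abort("Enrichment needs both `gmt_path` and `query_path` (or neither).")
  }
  structure(
    list(
      simulation = simulation,
      expression_path = expression_path, samples_path = samples_path,
      background = background, floor = floor, span = span,
      iterations = iterations, min_signal = min_signal,
      min_fraction = min_fraction, alpha = alpha, fdr_method = fdr_method,
      multiplier = multiplier, log_base = log_base,
      gmt_path = gmt_path, query_path = query_path, enrich_top = enrich_top
    ),
    class = "pipeline_config"
  )
}

#' Run the full scar/normal miRNA analysis pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> differential expression ->
#' DC-SIS screening -> criteria report (-> enrichment when gene sets are
#' supplied), writes every stage's table under `out_dir`, and records a
#' manifest with parameters, row counts and MD5 hashes of all outputs.
#' Re-running with the same configuration reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`). Side effects: `normalized.tsv`, `diffexp.tsv`,
#'   `screening.tsv`, `summary.tsv`, `listing.tsv`, `intersections.json`
#'   and, if enrichment ran, `enrichment.tsv`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with pipeline_config().")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  counts <- list()

  if (!is.null(config$simulation)) {
    sim <- simulate_mirna_dataset(config$simulation)
    expr <- sim$expression
    samples <- sim$samples
    write_mirna_dataset(sim, out_dir)
    stages <- c(stages, "simulate")
  } else {
    expr <- read_expression_matrix(config$expression_path)
    samples <- read_sample_sheet(config$samples_path)
    stages <- c(stages, "ingest")
  }
  counts$input_mirnas <- nrow(expr)
  counts$arrays <- length(expr_arrays(expr))

  norm <- preprocess_expression(
    expr,
    background = config$background, floor = config$floor,
    span = config$span, iterations = config$iterations,
    min_signal = config$min_signal, min_fraction = config$min_fraction
  )
  counts$mirnas_after_filter <- nrow(norm)
  readr::write_tsv(norm, file.path(out_dir, "normalized.tsv"))
  stages <- c(stages, "preprocess")

  de <- differential_table(norm, samples, fdr_method = config$fdr_method)
  counts$p_significant <- sum(de$p_value <= config$alpha)
  counts$q_significant <- sum(de$q_value <= config$alpha)
  readr::write_tsv(tidy(de), file.path(out_dir, "diffexp.tsv"))
  stages <- c(stages, "diffexp")

  screen <- dcsis_screen(
    norm, samples,
    multiplier = config$multiplier, log_base = config$log_base
  )
  counts$dcsis_selected <- sum(screen$selected)
  readr::write_tsv(tidy(screen), file.path(out_dir, "screening.tsv"))
  stages <- c(stages, "dcsis")

  summary_tbl <- criteria_summary(de, screen, alpha = config$alpha)
  sets <- criteria_sets(de, screen, alpha = config$alpha)
  inter <- intersect_criteria(sets)
  listing <- ranked_listing(de, screen)
  readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))
  readr::write_tsv(listing, file.path(out_dir, "listing.tsv"))
  jsonlite::write_json(
    list(
      sizes = summary_sizes_list(inter$sizes),
      members = inter$members,
      fdr_in_t_test = inter$fdr_in_t_test,
      fdr_in_dcsis = inter$fdr_in_dcsis
    ),
    file.path(out_dir, "intersections.json"),
    auto_unbox = TRUE, digits = NA
  )
  stages <- c(stages, "report")

  if (!is.null(config$gmt_path)) {
    collection <- read_gmt(config$gmt_path)
    query <- readr::read_lines(config$query_path, progress = FALSE)
    query <- query[nzchar(trimws(query))]
    enr <- hypergeom_enrich(query, collection, top = config$enrich_top)
    counts$enriched_sets <- nrow(enr)
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    stages <- c(stages, "enrich")
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "mirscar",
    version = as.character(utils::packageVersion("mirscar")),
    stages = stages,
    seed = if (!is.null(config$simulation)) config$simulation$seed else NULL,
    parameters = config_to_list(config),
    counts = counts,
    outputs = as.list(setNames(
      unname(tools::md5sum(sort(outputs))), basename(sort(outputs))
    ))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}

summary_sizes_list <- function(sizes) {
  as.list(setNames(sizes$size, sizes$set))
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out[!vapply(out, is.null, logical(1))]
}
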