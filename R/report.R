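#' Direction counts and percentages for a selected miRNA set
#'
#' The Table-1-style summary: how many of the selected miRNAs are elevated
#' versus lowered in scar tissue, with percentages of the selection size
#' rounded half-up to one decimal. miRNAs with an exactly zero mean paired
#' difference (possible on synthetic data) go to a separate `n_unchanged`
#' bucket and are excluded from the elevated/lowered split.
#'
#' @param selected_ids Character vector of selected miRNA ids.
#' @param de A [differential_table()] result covering those ids.
#'
#' @return A one-row tibble: `n_selected`, `n_elevated`, `n_lowered`,
#'   `n_unchanged`, `pct_elevated`, `pct_lowered` (0 with a message when the
#'   selection is empty).
#' @export
#' @examples
#' de <- tibble::tibble(
#'   mirna_id = c("a", "b", "c"),
#'   direction = c("elevated", "lowered", "lowered")
#' )
#' summarize_criterion(c("a", "b", "c"), de)
summarize_criterion <- function(selected_ids, de) {
  unknown <- setdiff(selected_ids, de$mirna_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Selected id(s) absent from the differential table: %s.",
      toString(head(unknown, 5))
    ))
  }
  sel <- de[de$mirna_id %in% selected_ids, ]
  n <- nrow(sel)
  n_up <- sum(sel$direction == "elevated")
  n_down <- sum(sel$direction == "lowered")
  n_unch <- sum(sel$direction == "unchanged")
  if (n == 0) {
    inform("summarize_criterion: empty selection; percentages reported as 0.")
    pct_up <- pct_down <- 0
  } else {
    pct_up <- round_half_up(100 * n_up / n, 1)
    pct_down <- round_half_up(100 * n_down / n, 1)
  }
  tibble::tibble(
    n_selected = n, n_elevated = n_up, n_lowered = n_down,
    n_unchanged = n_unch, pct_elevated = pct_up, pct_lowered = pct_down
  )
}

#' Summary of all three selection criteria
#'
#' One row per criterion — t-test (p <= alpha), FDR (q <= alpha) and DC-SIS
#' (top-d screening) — each summarized by [summarize_criterion()].
#'
#' @param de A [differential_table()] result.
#' @param screen A [dcsis_screen()] result over the same miRNAs.
#' @param alpha Significance level for criteria 1 and 2.
#' @return A tibble with a `criterion` column bound to the per-criterion
#'   summaries.
#' @export
criteria_summary <- function(de, screen, alpha = 0.05) {
  sets <- criteria_sets(de, screen, alpha)
  purrr::imap(sets, \(ids, nm) {
    dplyr::bind_cols(tibble::tibble(criterion = nm), summarize_criterion(ids, de))
  }) |>
    purrr::list_rbind()
}

criteria_sets <- function(de, screen, alpha = 0.05) {
  list(
    t_test = de$mirna_id[de$p_value <= alpha],
    fdr = de$mirna_id[de$q_value <= alpha],
    dcsis = screen$mirna_id[screen$selected]
  )
}

#' Intersections of the three criteria's selected sets
#'
#' Reports the size and membership of every pairwise and the triple
#' intersection. The FDR set is asserted to be nested in the t-test set
#' (guaranteed because BH adjustment never decreases a p-value); whether the
#' FDR set is contained in the DC-SIS selection is an empirical finding and
#' is reported, not assumed.
#'
#' @param sets Named list of character vectors with elements `t_test`, `fdr`,
#'   `dcsis` (as produced internally by [criteria_summary()]'s selection
#'   rule, or any three id sets).
#' @return A list with `sizes` (tibble of each set and intersection size),
#'   `members` (list of intersection id vectors), `fdr_in_t_test` and
#'   `fdr_in_dcsis` logicals.
#' @export
intersect_criteria <- function(sets) {
  stopifnot(all(c("t_test", "fdr", "dcsis") %in% names(sets)))
  pairs <- list(
    t_test_fdr = intersect(sets$t_test, sets$fdr),
    t_test_dcsis = intersect(sets$t_test, sets$dcsis),
    fdr_dcsis = intersect(sets$fdr, sets$dcsis)
  )
  triple <- intersect(pairs$t_test_fdr, sets$dcsis)
  fdr_in_t <- all(sets$fdr %in% sets$t_test)
  if (!fdr_in_t) {
    abort("Invariant violated: an FDR-significant miRNA is not t-test-significant.")
  }
  list(
    sizes = tibble::tibble(
      set = c(names(sets), names(pairs), "triple"),
      size = unname(c(lengths(sets), lengths(pairs), length(triple)))
    ),
    members = c(pairs, list(triple = triple)),
    fdr_in_t_test = fdr_in_t,
    fdr_in_dcsis = all(sets$fdr %in% sets$dcsis)
  )
}

#' Table-2-style listing of the screened miRNAs
#'
#' Joins the DC-SIS-selected miRNAs with their differential-expression
#' statistics, sorted by screening score descending.
#'
#' @param de A [differential_table()] result.
#' @param screen A [dcsis_screen()] result on the same id space.
#' @return A tibble with columns `mirna_id`, `direction`, `fold_change`,
#'   `mean_log2_diff`, `p_value`, `q_value`, `omega`, `rank`.
#' @export
ranked_listing <- function(de, screen) {
  sel <- screen[screen$selected, c("mirna_id", "omega", "rank")]
  missing <- setdiff(sel$mirna_id, de$mirna_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Screened id(s) absent from the differential table: %s.",
      toString(head(missing, 5))
    ))
  }
  dplyr::inner_join(
    sel,
    de[, c(
      "mirna_id", "direction", "fold_change", "mean_log2_diff",
      "p_value", "q_value"
    )],
    by = "mirna_id"
  ) |>
    dplyr::select(
      "mirna_id", "direction", "fold_change", "mean_log2_diff",
      "p_value", "q_value", "omega", "rank"
    ) |>
    dplyr::arrange(dplyr::desc(.data$omega), .data$mirna_id)
}
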