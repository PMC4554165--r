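#' Read a GMT gene-set collection
#'
#' Parses the standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate members within a set are
#' collapsed; the universe defaults to the union of all members.
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector overriding the annotated
#'   universe.
#'
#' @return A tibble of class `"gene_set_collection"` with columns
#'   `set_name`, `description`, `genes` (list-column) and `size`, plus a
#'   `universe` attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("GMT file '%s' contains no gene sets.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf(
      "Malformed GMT line %d: expected name, description and at least one member.",
      which(n_fields < 3)[1]
    ))
  }
  sets <- tibble::tibble(
    set_name = purrr::map_chr(fields, 1),
    description = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, \(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(sets$set_name) > 0) {
    abort(sprintf(
      "Duplicate set name(s) in GMT: %s.",
      toString(unique(sets$set_name[duplicated(sets$set_name)]))
    ))
  }
  sets$size <- lengths(sets$genes)
  attr(sets, "universe") <- universe %||% sort(unique(unlist(sets$genes)))
  class(sets) <- c("gene_set_collection", class(sets))
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the overlap seen: with `N` = universe size, `K` = set size within
#' the universe, `n` = query size within the universe and `k` = overlap,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (the tail includes the
#' observed `k`). P-values are FDR-adjusted across all sets with the same
#' Benjamini–Hochberg routine used for differential expression.
#'
#' @param query Character vector of gene identifiers (e.g. predicted miRNA
#'   targets). Genes outside the universe are dropped with a message, never
#'   silently.
#' @param collection A [read_gmt()] collection.
#' @param universe Optional character vector overriding the collection's
#'   universe.
#' @param top If given, keep only the `top` most significant sets (the
#'   study-style "top 10" view).
#'
#' @return A tibble with columns `set_name`, `description`, `k`, `K`, `n`,
#'   `N`, `ratio` (`k/n`), `p_value`, `q_value`, sorted by p ascending with
#'   ties broken by set name.
#' @export
hypergeom_enrich <- function(query, collection, universe = NULL, top = NULL) {
  if (!inherits(collection, "gene_set_collection")) {
    abort("`collection` must come from read_gmt().")
  }
  universe <- universe %||% attr(collection, "universe")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    inform(sprintf(
      "hypergeom_enrich: %d of %d query genes are outside the universe and were dropped.",
      length(dropped), length(query)
    ))
  }
  query <- intersect(query, universe)
  if (length(query) == 0) abort("No query gene lies in the universe.")
  N <- length(universe)
  n <- length(query)

  out <- collection |>
    tidy_collection() |>
    dplyr::mutate(
      genes = purrr::map(.data$genes, intersect, universe),
      K = lengths(.data$genes),
      k = purrr::map_int(.data$genes, \(g) length(intersect(g, query))),
      n = n,
      N = N,
      ratio = .data$k / n,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    ) |>
    dplyr::select(
      "set_name", "description", "k", "K", "n", "N", "ratio", "p_value"
    ) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value)) |>
    dplyr::arrange(.data$p_value, .data$set_name)
  if (!is.null(top)) out <- head(out, top)
  out
}

tidy_collection <- function(collection) {
  out <- collection
  class(out) <- setdiff(class(out), "gene_set_collection")
  out
}
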