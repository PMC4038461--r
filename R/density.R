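# Density of significant enrichment: per top-level disease tree, the fraction
# of unique disease terms whose (position-averaged) pooled p-value falls below
# a cutoff. Densities are z-scored within each query set for display, so the
# heatmap compares categories relative to that query set's own spread.

#' Position-averaged p-values per unique disease term
#'
#' A disease term may occupy several positions within the same top-level tree;
#' when the instances have different p-values they are averaged
#' (arithmetically), giving one p-value per (tree, term).
#'
#' @param result An `enrich_result` (pooled-mode p-values are used).
#' @return A tibble with columns `category` (top-level tree number),
#'   `term_id`, `p` (averaged pooled p), `n_positions`.
#' @examples
#' ex <- pooling_example()
#' res <- enrich(attach_links(ex$forest, ex$links), ex$query,
#'               n_perm = 100, seed = 1)
#' term_pvalues(res)
#' @export
term_pvalues <- function(result) {
  stopifnot(inherits(result, "enrich_result"))
  as_tibble(unclass_result(result)) |>
    mutate(category = tn_root(.data$tree_number)) |>
    group_by(.data$category, .data$term_id) |>
    summarise(p = mean(.data$p_pooled), n_positions = n(), .groups = "drop")
}

#' Density of significant enrichment per query set and category
#'
#' For each query set and each top-level tree, the fraction of that tree's
#' unique disease terms whose position-averaged pooled p-value lies strictly
#' below `alpha`. Raw densities are then z-scored across categories within
#' each query set (population standard deviation; a constant row maps to
#' zeros), which is the form used for heatmap display.
#'
#' @param results A single `enrich_result`, a named list of them (names become
#'   query-set labels), or a tibble carrying a `query_set` column alongside
#'   `tree_number`, `term_id`, `p_pooled`.
#' @param alpha Significance cutoff in (0, 1); default 0.005.
#' @return A `density_matrix`: a long tibble with columns `query_set`,
#'   `category`, `n_terms`, `density`, `z`, and the cutoff in the `alpha`
#'   attribute. Categories with no terms are absent (reported as missing).
#' @examples
#' ex <- pooling_example()
#' res <- enrich(attach_links(ex$forest, ex$links), ex$query,
#'               n_perm = 100, seed = 1)
#' density_matrix(res, alpha = 0.05)
#' @export
density_matrix <- function(results, alpha = 0.005) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    abort("alpha must be a single number in (0, 1)")
  }
  long <- collect_results(results)
  out <- long |>
    mutate(category = tn_root(.data$tree_number)) |>
    group_by(.data$query_set, .data$category, .data$term_id) |>
    summarise(p = mean(.data$p_pooled), .groups = "drop") |>
    group_by(.data$query_set, .data$category) |>
    summarise(n_terms = n(),
              density = mean(.data$p < alpha), .groups = "drop") |>
    group_by(.data$query_set) |>
    mutate(z = zscore(.data$density)) |>
    ungroup() |>
    arrange(.data$query_set, .data$category)
  structure(out, class = c("density_matrix", class(out)), alpha = alpha)
}

collect_results <- function(results) {
  if (inherits(results, "enrich_result")) {
    results <- stats::setNames(list(results),
                               attr(results, "query_name") %||% "query")
  }
  if (is.data.frame(results)) {
    need <- c("query_set", "tree_number", "term_id", "p_pooled")
    if (!all(need %in% names(results))) {
      abort("Result tibble needs columns query_set, tree_number, term_id, p_pooled")
    }
    return(as_tibble(results)[need])
  }
  if (!is.list(results) || is.null(names(results)) || any(names(results) == "")) {
    abort("Provide an enrich_result, a NAMED list of them, or a result tibble")
  }
  purrr::imap_dfr(results, function(r, nm) {
    stopifnot(inherits(r, "enrich_result"))
    tibble(query_set = nm, tree_number = r$tree_number,
           term_id = r$term_id, p_pooled = r$p_pooled)
  })
}

zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))  # population (n-divisor) convention
  if (s == 0) rep(0, length(x)) else (x - m) / s
}

#' Row-wise z-scoring of a density matrix
#'
#' Centers and scales each row by its population (divide-by-n) standard
#' deviation; constant rows become all zeros.
#'
#' @param m Numeric matrix (rows = query sets, columns = categories).
#' @return Matrix of the same shape with zero-mean rows.
#' @examples
#' zscore_rows(rbind(c(0, 1), c(3, 3)))
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1L) abort("Need at least one column")
  t(apply(m, 1L, zscore))
}

#' @rdname density_matrix
#' @param x,object A `density_matrix`.
#' @param value Which value to spread: raw `"density"` or `"z"`.
#' @param ... Unused.
#' @return `density_wide()`: a tibble with one row per query set and one
#'   column per category (sorted), for the chosen value.
#' @export
density_wide <- function(x, value = c("density", "z")) {
  value <- match.arg(value)
  as_tibble(unclass_result(x)) |>
    select("query_set", "category", dplyr::all_of(value)) |>
    arrange(.data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = dplyr::all_of(value))
}

#' @rdname density_matrix
#' @method tidy density_matrix
#' @export
tidy.density_matrix <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname density_matrix
#' @method autoplot density_matrix
#' @export
autoplot.density_matrix <- function(object, value = c("z", "density"), ...) {
  value <- match.arg(value)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$query_set,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::labs(x = "disease category", y = "query gene set", fill = value,
                  title = sprintf("Density of enrichment (alpha = %g)",
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
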