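# Permutation enrichment of a query gene set over all forest nodes. One stream
# of random query-sized gene draws from the universe scores BOTH the pooled and
# the direct gene sets at every node, so p-values are directly comparable
# between the two modes and between related nodes: the draw is a permutation of
# gene labels, leaving the gene-disease structure (and hence the correlation
# between overlapping nodes) intact.

#' Observed overlap between a query set and a node's genes
#'
#' @param index A `node_gene_index` from [attach_links()].
#' @param node A single tree number.
#' @param genes Character vector of query gene symbols.
#' @param mode `"pooled"` or `"direct"`.
#' @return Integer overlap size.
#' @export
observed_overlap <- function(index, node, genes,
                             mode = c("pooled", "direct")) {
  mode <- match.arg(mode)
  sum(node_genes(index, node, mode) %in% toupper(trimws(genes)))
}

#' Upper tail of the hypergeometric overlap distribution
#'
#' The probability of seeing an overlap of at least `k` genes between a random
#' query of size `q`, drawn from a universe of `N` genes of which `K` are
#' linked to the node, under independent uniform sampling. This is the
#' closed-form companion to the permutation test; computed via
#' [stats::phyper()] (log-space internally, so large `N` is safe).
#'
#' @param k Observed overlap(s); vectorized.
#' @param K Number of genes at the node.
#' @param q Query-set size.
#' @param N Universe size.
#' @return `P(X >= k)`; 1 for `k <= 0`, 0 for `k > min(K, q)`.
#' @examples
#' hypergeom_tail(2, K = 3, q = 2, N = 6)  # 3/15 = 0.2
#' @export
hypergeom_tail <- function(k, K, q, N) {
  if (any(K < 0) || any(q < 0) || any(K > N) || any(q > N)) {
    abort("Need 0 <= K <= N and 0 <= q <= N")
  }
  phyper(k - 1, m = K, n = N - K, k = q, lower.tail = FALSE)
}

# node x universe sparse indicator matrix from a named list of gene sets
gene_set_matrix <- function(sets, universe) {
  j <- match(unlist(sets, use.names = FALSE), universe)
  i <- rep(seq_along(sets), lengths(sets))
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep],
                       dims = c(length(sets), length(universe)), x = 1)
}

#' Permutation enrichment of a query gene set at every node
#'
#' Scores the observed overlap between the query set and each node's direct
#' and pooled gene sets, and estimates, per node and mode, the probability of
#' an overlap at least as large (`tail = "ge"`, default) or strictly larger
#' (`tail = "gt"`) under random queries of the same effective size drawn
#' uniformly from the gene universe. The same draws score every node in both
#' modes. Query genes absent from the universe are excluded before sizing the
#' draws. The empirical p-value is `exceedances / n_perm`; a node with zero
#' exceedances is reported as `p = 0` and should be read as `p < 1/n_perm`
#' (writers print it that way).
#'
#' With `method = "exhaustive"` every query-sized subset of the universe is
#' enumerated instead of sampled — exact, but only feasible for toy universes
#' (the number of subsets is capped at 500,000).
#'
#' @param index A `node_gene_index` from [attach_links()].
#' @param genes Character vector of query gene symbols.
#' @param name Query-set name carried into the result.
#' @param n_perm Number of random query draws (default 10,000).
#' @param seed Integer seed; `NULL` continues the caller's RNG stream.
#' @param tail `"ge"` counts draws with overlap `>=` observed; `"gt"` counts
#'   strict exceedance.
#' @param method `"permutation"` (Monte Carlo) or `"exhaustive"` (enumerate
#'   all subsets).
#' @param universe Optional explicit gene universe (default: the index's own).
#'   Useful to hold the universe fixed across reduced link tables.
#' @return An `enrich_result`: a tibble with one row per node — `tree_number`,
#'   `term_id`, `name`, `depth`, `k_direct`, `k_pooled`, `p_direct`,
#'   `p_pooled` — with the run configuration in attributes (`n_perm`, `seed`,
#'   `tail`, `method`, `query_name`, `query_size`, `effective_size`,
#'   `universe_size`).
#' @examples
#' ex <- pooling_example()
#' idx <- attach_links(ex$forest, ex$links)
#' enrich(idx, ex$query, name = "lung development", n_perm = 200, seed = 1)
#' @export
enrich <- function(index, genes, name = "query", n_perm = 10000,
                   seed = NULL, tail = c("ge", "gt"),
                   method = c("permutation", "exhaustive"),
                   universe = NULL) {
  stopifnot(is_node_gene_index(index))
  tail <- match.arg(tail)
  method <- match.arg(method)
  if (method == "permutation" && n_perm < 1) abort("n_perm must be >= 1")

  genes <- unique(toupper(trimws(genes)))
  genes <- genes[genes != ""]
  if (!length(genes)) abort("Empty query gene set")
  universe <- universe %||% index$universe
  N <- length(universe)
  eff <- intersect(genes, universe)
  q <- length(eff)
  if (q == 0L) abort("query disjoint from universe")

  nd <- index$forest$nodes
  Gd <- gene_set_matrix(index$direct[nd$tree_number], universe)
  Gp <- gene_set_matrix(index$pooled[nd$tree_number], universe)
  e <- as.numeric(universe %in% eff)
  k_direct <- as.integer(round(as.vector(Gd %*% e)))
  k_pooled <- as.integer(round(as.vector(Gp %*% e)))
  obs_d <- if (tail == "ge") k_direct else k_direct + 1L
  obs_p <- if (tail == "ge") k_pooled else k_pooled + 1L

  if (method == "exhaustive") {
    if (choose(N, q) > 5e5) {
      abort("exhaustive mode: too many subsets; use method = \"permutation\"")
    }
    draws <- combn(N, q)
    n_total <- ncol(draws)
    cnt <- count_exceedances(draws, Gd, Gp, obs_d, obs_p)
  } else {
    if (!is.null(seed)) set.seed(seed)
    n_total <- as.integer(n_perm)
    cnt <- list(direct = integer(length(obs_d)),
                pooled = integer(length(obs_p)))
    # chunked so the n_perm x n_nodes count matrices stay small
    left <- n_total
    while (left > 0L) {
      b <- min(left, 2000L)
      draws <- vapply(seq_len(b), function(i) sample.int(N, q), integer(q))
      draws <- matrix(draws, nrow = q)  # q = 1 returns a vector otherwise
      inc <- count_exceedances(draws, Gd, Gp, obs_d, obs_p)
      cnt$direct <- cnt$direct + inc$direct
      cnt$pooled <- cnt$pooled + inc$pooled
      left <- left - b
    }
  }

  out <- tibble(tree_number = nd$tree_number,
                term_id = nd$term_id,
                name = nd$name,
                depth = nd$depth,
                k_direct = k_direct,
                k_pooled = k_pooled,
                p_direct = cnt$direct / n_total,
                p_pooled = cnt$pooled / n_total)
  structure(out,
            class = c("enrich_result", class(out)),
            n_perm = n_total, seed = seed, tail = tail, method = method,
            query_name = name, query_size = length(genes),
            effective_size = q, universe_size = N)
}

# draws: q x n matrix of universe indices; returns per-node exceedance counts
count_exceedances <- function(draws, Gd, Gp, obs_d, obs_p) {
  n <- ncol(draws)
  q <- nrow(draws)
  S <- Matrix::sparseMatrix(i = rep(seq_len(n), each = q),
                            j = as.vector(draws),
                            dims = c(n, ncol(Gd)), x = 1)
  cd <- as.matrix(Matrix::tcrossprod(S, Gd))  # n x nodes overlap counts
  cp <- as.matrix(Matrix::tcrossprod(S, Gp))
  list(direct = colSums(cd >= rep(obs_d, each = n)),
       pooled = colSums(cp >= rep(obs_p, each = n)))
}

#' @export
print.enrich_result <- function(x, ...) {
  cat(sprintf(
    "<enrich_result> query %s (%d genes, %d in universe of %d), %s, n = %d, tail = %s\n",
    sQuote(attr(x, "query_name")), attr(x, "query_size"),
    attr(x, "effective_size"), attr(x, "universe_size"),
    attr(x, "method"), attr(x, "n_perm"), attr(x, "tail")))
  NextMethod()
}

#' @rdname enrich
#' @param x An `enrich_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-node tibble without the result class;
#'   `glance()`: a one-row tibble of run configuration plus the number of
#'   nodes with pooled p below 0.005.
#' @method tidy enrich_result
#' @export
tidy.enrich_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname enrich
#' @method glance enrich_result
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(query = attr(x, "query_name"),
         query_size = attr(x, "query_size"),
         effective_size = attr(x, "effective_size"),
         universe_size = attr(x, "universe_size"),
         n_nodes = nrow(x),
         n_perm = attr(x, "n_perm"),
         tail = attr(x, "tail"),
         method = attr(x, "method"),
         n_sig_pooled = sum(x$p_pooled < 0.005),
         min_p_pooled = min(x$p_pooled))
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("enrich_result", "validation_report",
                                  "density_matrix"))
  x
}

#' @rdname enrich
#' @param object An `enrich_result`.
#' @return `autoplot()`: a ggplot comparing pooled and direct significance per
#'   node (p-values floored at `1/n_perm` for display).
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, ...) {
  floor_p <- 1 / attr(object, "n_perm")
  df <- tidy(object) |>
    mutate(p_direct = pmax(.data$p_direct, floor_p),
           p_pooled = pmax(.data$p_pooled, floor_p))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_direct),
                                   y = -log10(.data$p_pooled))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "-log10 p (direct)", y = "-log10 p (pooled)",
                  title = sprintf("Pooled vs direct enrichment: %s",
                                  attr(object, "query_name"))) +
    ggplot2::theme_minimal()
}
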