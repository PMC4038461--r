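# Gene-disease link tables and the per-node gene index. A link table is a
# tibble unique on (gene, term); attaching it to a forest yields, per node, the
# directly linked genes and the pooled union over the node's subtree.

#' Build a link table from a data frame
#'
#' Normalizes gene symbols (uppercased, whitespace-stripped), drops rows with
#' an empty gene field (with a warning), and collapses duplicate
#' `(gene, term)` pairs, concatenating their source tags.
#'
#' @param x Data frame with columns `gene` and `term` (a term identifier or a
#'   tree number) and optionally `source`.
#' @return A `link_table`: a tibble with columns `gene`, `term`, `source`,
#'   unique on `(gene, term)`. The number of skipped rows is recorded in the
#'   `n_skipped` attribute.
#' @examples
#' as_link_table(data.frame(gene = c("Vegfa", "VEGFA"), term = "Dementia"))
#' @export
as_link_table <- function(x) {
  x <- as_tibble(x)
  if (!all(c("gene", "term") %in% names(x))) {
    abort("A link table needs `gene` and `term` columns")
  }
  if (!"source" %in% names(x)) x$source <- NA_character_
  x <- x |>
    mutate(gene = toupper(trimws(as.character(.data$gene))),
           term = trimws(as.character(.data$term)),
           source = as.character(.data$source))
  skipped <- is.na(x$gene) | x$gene == "" | is.na(x$term) | x$term == ""
  if (any(skipped)) {
    warn(sprintf("Skipped %d link row(s) with empty gene or term field",
                 sum(skipped)))
  }
  out <- x[!skipped, ] |>
    group_by(.data$gene, .data$term) |>
    summarise(source = paste(sort(unique(unlist(
      strsplit(.data$source[!is.na(.data$source)], ";", fixed = TRUE)
    ))), collapse = ";"), .groups = "drop") |>
    mutate(source = ifelse(.data$source == "", NA_character_, .data$source)) |>
    arrange(.data$gene, .data$term)
  structure(out, class = c("link_table", class(out)),
            n_skipped = sum(skipped))
}

#' Read gene-disease links from TSV
#'
#' Expects headerless tab-separated rows `gene <TAB> term [<TAB> source]`;
#' lines starting with `#` are ignored. The term reference may be a term
#' identifier or a tree number — resolution happens in [attach_links()].
#'
#' @param path Path to a TSV file.
#' @param default_source Source tag used for rows without a third column.
#' @return A `link_table` (see [as_link_table()]).
#' @export
read_links <- function(path, default_source = NA_character_) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(as_link_table(tibble(gene = character(), term = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)  # third column is optional
  if (any(lengths(parts) < 2L)) {
    abort(sprintf("%s: link rows need >= 2 columns", path))
  }
  df <- tibble(gene = vapply(parts, `[[`, character(1), 1L),
               term = vapply(parts, `[[`, character(1), 2L),
               source = vapply(parts, function(p) {
                 if (length(p) >= 3L && nzchar(p[[3L]])) p[[3L]]
                 else default_source
               }, character(1)))
  as_link_table(df)
}

#' Merge link tables, removing duplicate associations
#'
#' Takes the union on `(gene, term)`; one copy of each association found in
#' several tables is kept and the source tags are concatenated. This is how
#' link collections from independent databases (e.g. a literature-curated
#' compendium and a curated Mendelian catalogue) are combined into one
#' deduplicated set.
#'
#' @param ... Link tables (or data frames coercible via [as_link_table()]),
#'   or a single list of them.
#' @return A `link_table` with `sum(sizes) - duplicates` rows.
#' @examples
#' a <- as_link_table(data.frame(gene = c("A", "B"), term = "t1"))
#' b <- as_link_table(data.frame(gene = c("B", "C"), term = "t1"))
#' nrow(merge_links(a, b))  # 3: (B, t1) deduplicated
#' @export
merge_links <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  if (!length(tabs)) abort("Need at least one link table")
  as_link_table(bind_rows(lapply(tabs, as_tibble)))
}

#' Read query gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> gene ...`.
#' Gene symbols are uppercased.
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per (set, gene): columns `set`,
#'   `description`, `gene`.
#' @seealso [gmt_sets()] to turn the long tibble into a named list.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  }
  purrr::map_dfr(parts, function(p) {
    genes <- unique(toupper(trimws(p[-(1:2)])))
    tibble(set = p[[1L]], description = p[[2L]], gene = genes[genes != ""])
  })
}

#' @rdname read_gmt
#' @param gmt A tibble as returned by [read_gmt()].
#' @return `gmt_sets()`: a named list of gene-symbol vectors.
#' @export
gmt_sets <- function(gmt) {
  split(gmt$gene, gmt$set)
}

#' Attach a link table to a forest: direct and pooled gene sets per node
#'
#' Resolves each link's term reference (a term identifier, or a tree number
#' standing for the term at that position) and adds the gene to the direct set
#' of *every* position of that term. Pooled sets are then computed bottom-up:
#' the pooled set of a node is its direct set unioned with the pooled sets of
#' its children, i.e. all genes linked anywhere in the subtree. Links whose
#' term cannot be found in the forest are dropped and counted, not fatal.
#'
#' @param forest A `disease_forest`.
#' @param links A `link_table` (or coercible data frame).
#' @return A `node_gene_index`: list with named-list elements `direct` and
#'   `pooled` (tree number -> character vector of genes), `universe` (all
#'   genes in any direct set), `dropped_count`, and the `forest`.
#' @examples
#' ex <- pooling_example()
#' idx <- attach_links(ex$forest, ex$links)
#' lengths(idx$direct)
#' length(idx$pooled[[forest_roots(ex$forest)]])  # 7 distinct genes
#' @export
attach_links <- function(forest, links) {
  stopifnot(is_disease_forest(forest))
  links <- as_link_table(links)
  nd <- forest$nodes

  # resolve term refs: term_id match wins, else a tree-number match stands for
  # the term at that position
  ref <- unique(links$term)
  ref_term <- ifelse(ref %in% nd$term_id, ref,
                     nd$term_id[match(ref, nd$tree_number)])
  term_of <- ref_term[match(links$term, ref)]
  dropped <- sum(is.na(term_of))

  kept <- tibble(gene = as.character(links$gene[!is.na(term_of)]),
                 term_id = as.character(term_of[!is.na(term_of)])) |>
    distinct()
  # fan out to every position of the term
  pos <- nd |> select("tree_number", "term_id")
  direct_tbl <- kept |>
    left_join(pos, by = "term_id", relationship = "many-to-many")

  direct <- lapply(stats::setNames(nm = nd$tree_number), function(x) character())
  if (nrow(direct_tbl)) {
    got <- split(direct_tbl$gene, direct_tbl$tree_number)
    got <- lapply(got, function(g) sort(unique(g)))
    direct[names(got)] <- got
  }

  # post-order union: deepest nodes first, children feed parents
  pooled <- direct
  ord <- order(nd$depth, decreasing = TRUE)
  kids <- split(nd$tree_number, factor(nd$parent, levels = nd$tree_number))
  for (i in ord) {
    tn <- nd$tree_number[i]
    ch <- kids[[tn]]
    if (length(ch)) {
      pooled[[tn]] <- sort(unique(c(direct[[tn]], unlist(pooled[ch],
                                                         use.names = FALSE))))
    }
  }

  structure(list(forest = forest,
                 direct = direct,
                 pooled = pooled,
                 universe = sort(unique(unlist(direct, use.names = FALSE))),
                 dropped_count = dropped,
                 n_links = nrow(kept)),
            class = "node_gene_index")
}

#' @export
print.node_gene_index <- function(x, ...) {
  cat(sprintf(
    "<node_gene_index> %d node(s), %d attached link(s), %d gene universe, %d dropped link(s)\n",
    length(x$direct), x$n_links, length(x$universe), x$dropped_count))
  invisible(x)
}

is_node_gene_index <- function(x) inherits(x, "node_gene_index")

#' Genes at a node
#'
#' @param index A `node_gene_index`.
#' @param node A single tree number.
#' @param mode `"pooled"` (genes anywhere in the subtree) or `"direct"`.
#' @return Character vector of gene symbols.
#' @export
node_genes <- function(index, node, mode = c("pooled", "direct")) {
  stopifnot(is_node_gene_index(index))
  mode <- match.arg(mode)
  sets <- index[[mode]]
  if (!node %in% names(sets)) {
    abort(sprintf("Tree number %s not present in index", sQuote(node)))
  }
  sets[[node]]
}
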