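# The disease forest: a multi-rooted tree of disease terms, one node per tree
# position. A term (identified by its preferred name) may occupy several
# positions; node identity is the position, not the term, and every position is
# scored independently downstream.

#' Parse a disease forest from "name;tree_number" records
#'
#' Reads the MeSH-trees-style text format: one `"Preferred Name;TreeNumber"`
#' record per line, UTF-8, lines starting with `#` ignored. One node is created
#' per distinct tree number. A term listed at several tree numbers becomes one
#' term with several positions. Tree numbers whose parent positions are absent
#' from the input get synthesized placeholder ancestors (flagged in the node
#' table and reported), so the forest is always structurally complete.
#'
#' @param lines Character vector of records (one per element).
#' @param quiet Suppress the message reporting synthesized placeholder nodes.
#' @return A `disease_forest` object: a list with element `nodes`, a tibble
#'   with one row per tree position (columns `tree_number`, `term_id`, `name`,
#'   `parent`, `depth`, `placeholder`), sorted by tree number.
#' @seealso [read_forest()] to parse from a file, [subtree_nodes()],
#'   [term_positions()], [forest_lines()] for serialization.
#' @examples
#' f <- parse_forest(c("Dementia;C10.228.140.380", "Alzheimer Disease;C10.228.140.380.100"))
#' f
#' @export
parse_forest <- function(lines, quiet = FALSE) {
  lines <- as.character(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- lines[keep]
  parts <- strsplit(recs, ";", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(sprintf(
      "Malformed forest record at line %d: %s (expected exactly one ';')",
      idx[bad[1L]], sQuote(recs[bad[1L]])))
  }
  name <- trimws(vapply(parts, `[[`, character(1), 1L))
  tn <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (length(tn)) {
    bad <- which(!tn_is_valid(tn) | name == "")
    if (length(bad)) {
      abort(sprintf("Malformed forest record at line %d: %s",
                    idx[bad[1L]], sQuote(recs[bad[1L]])))
    }
  }

  named <- tibble(tree_number = tn, name = name) |> distinct()
  dup <- named |> dplyr::count(.data$tree_number) |> filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("Tree number %s listed with conflicting names",
                  sQuote(dup$tree_number[1L])))
  }

  # synthesize missing ancestors as flagged placeholders
  all_tn <- as.character(unlist(lapply(named$tree_number, tn_ancestors)))
  missing <- setdiff(unique(all_tn), named$tree_number)
  if (length(missing) && !quiet) {
    message(sprintf("Synthesized %d placeholder ancestor node(s)",
                    length(missing)))
  }
  nodes <- bind_rows(
    named |> mutate(placeholder = FALSE),
    tibble(tree_number = missing,
           name = paste0("<unnamed ", missing, ">"),
           placeholder = TRUE)
  ) |>
    mutate(term_id = ifelse(.data$placeholder,
                            paste0("placeholder:", .data$tree_number),
                            .data$name),
           parent = tn_parent(.data$tree_number),
           depth = tn_depth(.data$tree_number)) |>
    select("tree_number", "term_id", "name", "parent", "depth",
           "placeholder") |>
    arrange(.data$tree_number)

  new_disease_forest(nodes)
}

new_disease_forest <- function(nodes) {
  structure(list(nodes = nodes), class = "disease_forest")
}

#' Read a disease forest from a file
#'
#' @param path Path to a UTF-8 text file, one `"name;tree_number"` per line.
#' @inheritParams parse_forest
#' @return A `disease_forest`.
#' @export
read_forest <- function(path, quiet = FALSE) {
  parse_forest(readr::read_lines(path), quiet = quiet)
}

#' Serialize a forest back to "name;tree_number" lines
#'
#' Placeholder nodes are omitted: they carry no information beyond their tree
#' number and are re-synthesized identically on re-parsing, so
#' `parse_forest(forest_lines(f))` reproduces `f` exactly.
#'
#' @param forest A `disease_forest`.
#' @return Character vector of records.
#' @export
forest_lines <- function(forest) {
  stopifnot(is_disease_forest(forest))
  nd <- forest$nodes |> filter(!.data$placeholder)
  paste0(nd$name, ";", nd$tree_number)
}

#' Write a forest as JSON
#'
#' One record per node: `tree_number`, `term_id`, `name`, `parent` (null for
#' roots) and the `placeholder` flag.
#'
#' @param forest A `disease_forest`.
#' @param path Output path.
#' @export
write_forest_json <- function(forest, path) {
  stopifnot(is_disease_forest(forest))
  jsonlite::write_json(forest$nodes, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.disease_forest <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<disease_forest> %d node(s), %d root(s), %d distinct term(s)\n",
              nrow(nd), sum(is.na(nd$parent)), length(unique(nd$term_id))))
  if (nrow(nd)) {
    cat("Roots:", paste(head(nd$tree_number[is.na(nd$parent)], 8L),
                        collapse = ", "))
    if (sum(is.na(nd$parent)) > 8L) cat(", ...")
    cat("\n")
  }
  invisible(x)
}

#' @method as_tibble disease_forest
#' @export
as_tibble.disease_forest <- function(x, ...) x$nodes

is_disease_forest <- function(x) inherits(x, "disease_forest")

#' Roots of a forest
#'
#' @param forest A `disease_forest`.
#' @return Character vector of top-level tree numbers, sorted.
#' @export
forest_roots <- function(forest) {
  stopifnot(is_disease_forest(forest))
  forest$nodes$tree_number[is.na(forest$nodes$parent)]
}

#' Positions in the subtree rooted at a node
#'
#' Returns the tree numbers of the node itself and every descendant position.
#'
#' @param forest A `disease_forest`.
#' @param node A single tree number present in the forest.
#' @return Character vector of tree numbers (the node first, then descendants
#'   in lexicographic order).
#' @export
subtree_nodes <- function(forest, node) {
  stopifnot(is_disease_forest(forest), length(node) == 1L)
  tn <- forest$nodes$tree_number
  if (!node %in% tn) {
    abort(sprintf("Tree number %s not present in forest", sQuote(node)))
  }
  tn[tn_in_subtree(tn, node)]
}

#' Tree positions of a disease term
#'
#' A disease term may occupy several positions in the forest (type 1 diabetes,
#' for instance, sits under nutritional/metabolic, endocrine and immune-system
#' categories in MeSH). Unknown terms yield an empty vector, not an error.
#'
#' @param forest A `disease_forest`.
#' @param term_id A single term identifier (the preferred name for parsed
#'   input).
#' @return Character vector of tree numbers carrying the term.
#' @export
term_positions <- function(forest, term_id) {
  stopifnot(is_disease_forest(forest), length(term_id) == 1L)
  forest$nodes$tree_number[forest$nodes$term_id == term_id]
}
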