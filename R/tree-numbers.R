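# Tree-number arithmetic. A tree number is a dotted address like
# "C10.228.140.380"; the first segment names the top-level tree.

#' Tree-number helpers
#'
#' A tree number addresses one position in a disease forest as a dot-separated
#' path of alphanumeric segments (e.g. `"C10.228.140.380"`). The first segment
#' identifies the top-level tree; removing the last segment gives the parent
#' position.
#'
#' @param x Character vector of tree numbers.
#' @return `tn_parent()` returns the parent tree number, or `NA` for top-level
#'   numbers. `tn_root()` returns the first segment. `tn_depth()` returns the
#'   number of segments below the top level (a root has depth 0).
#'   `tn_ancestors()` returns, for a single tree number, all prefixes from the
#'   root down to the number itself. `tn_is_valid()` returns a logical vector.
#' @examples
#' tn_parent("C10.228.140.380")
#' tn_root("C10.228.140.380")
#' tn_ancestors("C10.228.140")
#' @name tree_number
NULL

#' @rdname tree_number
#' @export
tn_is_valid <- function(x) {
  grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", x)
}

#' @rdname tree_number
#' @export
tn_parent <- function(x) {
  out <- sub("\\.[^.]*$", "", x)
  out[!grepl(".", x, fixed = TRUE)] <- NA_character_
  out
}

#' @rdname tree_number
#' @export
tn_root <- function(x) sub("\\..*$", "", x)

#' @rdname tree_number
#' @export
tn_depth <- function(x) {
  lengths(gregexpr(".", x, fixed = TRUE)) - !grepl(".", x, fixed = TRUE)
}

#' @rdname tree_number
#' @export
tn_ancestors <- function(x) {
  stopifnot(length(x) == 1L)
  segs <- strsplit(x, ".", fixed = TRUE)[[1L]]
  vapply(seq_along(segs), function(i) paste(segs[seq_len(i)], collapse = "."),
         character(1))
}

# TRUE where `x` lies in the subtree rooted at `root` (inclusive).
tn_in_subtree <- function(x, root) {
  x == root | startsWith(x, paste0(root, "."))
}
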