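# Shared fixtures, all generated in code.

# a small two-tree forest with one term at several positions
tiny_forest <- function() {
  parse_forest(c(
    "Alpha;A01",
    "Alpha one;A01.100",
    "Alpha two;A01.200",
    "Shared disease;A01.100.500",
    "Beta;B01",
    "Shared disease;B01.300",
    "Beta leaf;B01.300.100",
    "Shared disease;B01.300.100.200"
  ), quiet = TRUE)
}

tiny_links <- function() {
  as_link_table(data.frame(
    gene = c("G1", "G2", "G3", "G2", "G4", "G5"),
    term = c("Alpha", "Alpha one", "Shared disease", "Shared disease",
             "Beta leaf", "Alpha two"),
    source = "test"))
}

# random forest generator used by property-style tests
random_forest <- function(n_nodes = 50, n_trees = 3, seed = 1) {
  withr::with_seed(seed, {
    tns <- sprintf("R%02d", seq_len(n_trees))
    pool <- tns
    while (length(tns) < n_nodes) {
      parent <- sample(pool, 1)
      child <- paste0(parent, ".", sprintf("%03d", sample.int(999, 1)))
      if (!child %in% tns) {
        tns <- c(tns, child)
        pool <- c(pool, child)
      }
    }
    parse_forest(paste0("Term ", tns, ";", tns), quiet = TRUE)
  })
}

# random link table over a forest (term refs are term_ids)
random_links <- function(forest, n_genes = 30, n_links = 80, seed = 1) {
  withr::with_seed(seed, {
    nd <- tibble::as_tibble(forest)
    as_link_table(data.frame(
      gene = sprintf("G%03d", sample.int(n_genes, n_links, replace = TRUE)),
      term = sample(nd$term_id, n_links, replace = TRUE),
      source = "rand"))
  })
}

# brute-force oracle: all genes attached anywhere in the subtree of `node`
brute_subtree_genes <- function(forest, links, node) {
  nd <- tibble::as_tibble(forest)
  sub <- subtree_nodes(forest, node)
  terms <- nd$term_id[nd$tree_number %in% sub]
  sort(unique(links$gene[links$term %in% terms]))
}

# breadth-first reachability oracle for subtree_nodes
bfs_subtree <- function(forest, node) {
  nd <- tibble::as_tibble(forest)
  out <- character()
  frontier <- node
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- nd$tree_number[!is.na(nd$parent) & nd$parent %in% frontier]
  }
  sort(out)
}
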