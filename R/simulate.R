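# Synthetic study generator. Emulates the features the method depends on: a
# multi-rooted forest of complete trees; a dense background of gene-disease
# associations so that nodes across the whole forest carry genes (query genes
# included, since in real collections a developmental gene links to many
# diseases); and "annotation-precision jitter" — every association has a true
# disease node but is *recorded* at a position up to jitter levels below it,
# so the direct sets at the true node miss genes that the pooled sets recover,
# which is exactly the situation pooling exists for. Planted query sets add
# concentrated true signal at chosen target nodes, recorded with the same
# kind of jitter.

#' Configuration for a synthetic study
#'
#' Defaults describe the package's reference synthetic study, sized so that a
#' withheld-link experiment removes only a few percent of the eligible links
#' (as in a large curated collection) while staying desk-scale: three disease
#' trees of depth 5 with branching 3 (1092 nodes); a 500-gene pool; a uniform
#' background (nominal rate 0.005 links per gene-node pair) whose true disease
#' concepts sit at depths 0 to `depth - 2` and whose recorded annotations
#' scatter up to 1 level below the true concept; and two planted query sets
#' of 100 genes, each truly linked to two depth-1 target nodes in different
#' trees (150 links per target, recorded up to 3 levels below the target, so
#' no single window node carries more than a few of them: the planted signal
#' is individually weak and only aggregates to significance when pooled).
#' The deepest levels of each tree are fine subtypes that receive annotation
#' only by spillover, as in real curated collections where links attach to
#' recognizable disease concepts, not to maximally specific leaves. Several
#' [planted_set()] entries may share a name: they then plant links for one
#' and the same query set at several targets, which mimics a real process
#' gene set linked to more than one disease class.
#'
#' @param n_trees Number of top-level trees.
#' @param depth Levels below each root (a root has depth 0); `depth >= 1`.
#' @param branching Children per internal node; `>= 1`.
#' @param n_genes Size of the gene pool.
#' @param background_rate Baseline probability mass per (gene, node) pair; the
#'   nominal background link count is `background_rate * n_genes * n_nodes`,
#'   drawn with replacement and deduplicated (realized size may be smaller).
#' @param background_jitter Levels below its true node at which a background
#'   association may be recorded (0 = recorded exactly at the true node).
#' @param truth_depth_max Deepest level at which background true concepts
#'   live; defaults to `depth - 2` so the deepest two levels carry only
#'   spillover annotation.
#' @param planted List of planted query-set descriptions from [planted_set()].
#' @param seed Seed used by the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trees = 3, depth = 5, branching = 3,
                       n_genes = 500, background_rate = 0.005,
                       background_jitter = 1,
                       truth_depth_max = NULL,
                       planted = list(
                         planted_set("devA", target = "T01.001",
                                     n_links = 150, jitter_depth = 3,
                                     query_size = 100),
                         planted_set("devA", target = "T02.002",
                                     n_links = 150, jitter_depth = 3,
                                     query_size = 100),
                         planted_set("devB", target = "T02.001",
                                     n_links = 150, jitter_depth = 3,
                                     query_size = 100),
                         planted_set("devB", target = "T03.002",
                                     n_links = 150, jitter_depth = 3,
                                     query_size = 100)),
                       seed = 1L) {
  stopifnot(n_trees >= 1, depth >= 1, branching >= 1, n_genes >= 1,
            background_rate >= 0, background_rate <= 1,
            background_jitter >= 0)
  if (is.null(truth_depth_max)) truth_depth_max <- max(0L, depth - 2L)
  stopifnot(truth_depth_max >= 0, truth_depth_max <= depth)
  structure(list(n_trees = n_trees, depth = depth, branching = branching,
                 n_genes = n_genes, background_rate = background_rate,
                 background_jitter = background_jitter,
                 truth_depth_max = truth_depth_max,
                 planted = planted, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param name Query-set name.
#' @param target Tree number of the true disease node for this set.
#' @param n_links Planted links to draw (gene from the query set, node from
#'   the jitter window, both uniform with replacement; deduplicated later).
#' @param jitter_depth Levels below `target` over which planted links scatter;
#'   0 places every planted link exactly at the target.
#' @param query_size Genes in the query set.
#' @export
planted_set <- function(name, target, n_links, jitter_depth = 0,
                        query_size = 25) {
  stopifnot(jitter_depth >= 0, n_links >= 0, query_size >= 1)
  list(name = name, target = target, n_links = n_links,
       jitter_depth = jitter_depth, query_size = query_size)
}

#' Generate a complete synthetic disease forest
#'
#' Builds `n_trees` complete trees of the configured depth and branching, with
#' one unique synthetic term per position (roots `T01`, `T02`, ...; children
#' append zero-padded segments). The structure is fully determined by the
#' shape parameters.
#'
#' @param config A `sim_config`.
#' @return A `disease_forest` with
#'   `n_trees * sum(branching^(0:depth))` nodes.
#' @export
simulate_forest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tns <- character()
  for (t in seq_len(config$n_trees)) {
    level <- sprintf("T%02d", t)
    tns <- c(tns, level)
    for (d in seq_len(config$depth)) {
      level <- as.vector(outer(level, sprintf("%03d", seq_len(config$branching)),
                               paste, sep = "."))
      tns <- c(tns, level)
    }
  }
  parse_forest(paste0("Synthetic disease ", tns, ";", tns), quiet = TRUE)
}

#' Generate synthetic gene-disease links and planted query sets
#'
#' Background associations pair uniform random genes with uniform random true
#' nodes; each is *recorded* at a node drawn uniformly from the true node's
#' subtree restricted to at most `background_jitter` levels below it (the
#' annotation-precision jitter of real curation, clipped at the leaves). Each
#' planted query set draws its links' genes from the query set and records
#' them uniformly within `jitter_depth` levels below the target node (a
#' warning is issued if the target's subtree is shallower than `jitter_depth`
#' and the window is clipped); `jitter_depth = 0` places every planted link
#' exactly at the target. All links are deduplicated on (gene, term).
#' Deterministic given `config$seed`.
#'
#' @param forest The forest from [simulate_forest()].
#' @param config A `sim_config`.
#' @return A list: `links` (a `link_table`), `query_sets` (named list of gene
#'   vectors).
#' @examples
#' cfg <- sim_config(n_trees = 1, depth = 2, branching = 2, n_genes = 50,
#'                   planted = list(planted_set("q", "T01.001", 20,
#'                                              jitter_depth = 1)))
#' sim <- simulate_links(simulate_forest(cfg), cfg)
#' nrow(sim$links)
#' @export
simulate_links <- function(forest, config) {
  stopifnot(is_disease_forest(forest), inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  nd <- forest$nodes
  n_nodes <- nrow(nd)

  # per-node recording windows: descendants within j levels (self included)
  jitter_window <- function(tn, j) {
    win <- subtree_nodes(forest, tn)
    win[tn_depth(win) - tn_depth(tn) <= j]
  }
  record_at <- function(true_tn, j) {
    if (j == 0) return(true_tn)
    wins <- lapply(unique(true_tn), jitter_window, j = j)
    names(wins) <- unique(true_tn)
    vapply(true_tn, function(tn) {
      w <- wins[[tn]]
      w[sample.int(length(w), 1L)]
    }, character(1), USE.NAMES = FALSE)
  }

  n_bg <- round(config$background_rate * config$n_genes * n_nodes)
  concept_nodes <- nd$tree_number[nd$depth <= config$truth_depth_max]
  true_bg <- concept_nodes[sample.int(length(concept_nodes), n_bg,
                                      replace = TRUE)]
  rec_bg <- record_at(true_bg, config$background_jitter)
  rows <- tibble(gene = genes[sample.int(config$n_genes, n_bg, replace = TRUE)],
                 term = nd$term_id[match(rec_bg, nd$tree_number)],
                 source = "background")

  query_sets <- list()
  for (p in config$planted) {
    if (!p$target %in% nd$tree_number) {
      abort(sprintf("Planted target %s not in forest", sQuote(p$target)))
    }
    # entries sharing a name plant links for one query set at several targets
    if (is.null(query_sets[[p$name]])) {
      query_sets[[p$name]] <- sample(genes, p$query_size)
    }
    qs <- query_sets[[p$name]]
    win <- subtree_nodes(forest, p$target)
    d0 <- tn_depth(p$target)
    avail <- max(tn_depth(win)) - d0
    if (avail < p$jitter_depth) {
      warn(sprintf("Target %s subtree is only %d level(s) deep; jitter clipped",
                   p$target, avail))
    }
    win <- win[tn_depth(win) - d0 <= p$jitter_depth]
    if (p$n_links > 0) {
      rows <- bind_rows(rows, tibble(
        gene = qs[sample.int(length(qs), p$n_links, replace = TRUE)],
        term = nd$term_id[match(win[sample.int(length(win), p$n_links,
                                               replace = TRUE)],
                                nd$tree_number)],
        source = paste0("planted:", p$name)))
    }
  }
  list(links = as_link_table(rows), query_sets = query_sets)
}

#' Worked pooling example
#'
#' The three-node fixture used throughout the documentation: a parent disease
#' ("Neural tube defects") with two child terms ("Meningomyelocele", "Spinal
#' dysraphism"), and a lung-development-style query set of seven genes. Four
#' query genes are linked directly to the parent, two to the first child and
#' three to the second, with exactly two genes each linked under two nodes —
#' so the direct counts are 4/2/3, while pooling the subtree at the parent
#' collects 7 distinct query genes, enough to expose enrichment that none of
#' the three nodes shows on its own. Gene names are synthetic
#' (`LUNG01`..`LUNG07`); the tree numbers are illustrative MeSH-style
#' addresses.
#'
#' @param n_background Extra background genes linked to an unrelated sibling
#'   term, enlarging the universe (0 keeps the bare three-node example).
#' @return A list: `forest` (a `disease_forest`), `links` (a `link_table`),
#'   `query` (character vector of the 7 query genes).
#' @examples
#' ex <- pooling_example()
#' idx <- attach_links(ex$forest, ex$links)
#' vapply(idx$direct[c("C16.131.666", "C16.131.666.411", "C16.131.666.800")],
#'        length, integer(1))  # 4 2 3
#' observed_overlap(idx, "C16.131.666", ex$query, mode = "pooled")  # 7
#' @export
pooling_example <- function(n_background = 0) {
  lines <- c("Neural tube defects;C16.131.666",
             "Meningomyelocele;C16.131.666.411",
             "Spinal dysraphism;C16.131.666.800")
  query <- sprintf("LUNG%02d", 1:7)
  links <- tibble(
    gene = c("LUNG01", "LUNG02", "LUNG03", "LUNG04",   # 4 direct at parent
             "LUNG01", "LUNG05",                        # 2 at first child
             "LUNG02", "LUNG06", "LUNG07"),             # 3 at second child
    term = c(rep("Neural tube defects", 4),
             rep("Meningomyelocele", 2),
             rep("Spinal dysraphism", 3)),
    source = "example")
  if (n_background > 0) {
    lines <- c(lines, "Other malformations;C16.131.900")
    links <- bind_rows(links, tibble(
      gene = sprintf("BG%03d", seq_len(n_background)),
      term = "Other malformations", source = "example"))
  }
  list(forest = parse_forest(lines, quiet = TRUE),
       links = as_link_table(links),
       query = query)
}
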