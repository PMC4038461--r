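test_that("simulate_forest builds complete trees of the stated shape", {
  cfg <- sim_config(n_trees = 1, depth = 1, branching = 3,
                    planted = list(), n_genes = 10)
  f <- simulate_forest(cfg)
  expect_equal(nrow(tibble::as_tibble(f)), 4L)  # root + 3 leaves

  for (shape in list(c(2, 2, 2), c(1, 3, 2), c(3, 2, 3))) {
    cfg <- sim_config(n_trees = shape[1], depth = shape[2],
                      branching = shape[3], planted = list(), n_genes = 10)
    f <- simulate_forest(cfg)
    expected <- shape[1] * sum(shape[3]^(0:shape[2]))
    expect_equal(nrow(tibble::as_tibble(f)), expected)
  }
  # term names are unique
  nd <- tibble::as_tibble(simulate_forest(sim_config()))
  expect_equal(anyDuplicated(nd$term_id), 0L)
})

test_that("simulated links are deterministic under seed and differ across seeds", {
  cfg1 <- sim_config(seed = 5)
  f <- simulate_forest(cfg1)
  s1 <- suppressWarnings(simulate_links(f, cfg1))
  s2 <- suppressWarnings(simulate_links(f, cfg1))
  expect_identical(tibble::as_tibble(s1$links), tibble::as_tibble(s2$links))
  expect_identical(s1$query_sets, s2$query_sets)
  cfg3 <- sim_config(seed = 6)
  s3 <- suppressWarnings(simulate_links(f, cfg3))
  expect_false(identical(tibble::as_tibble(s1$links),
                         tibble::as_tibble(s3$links)))
})

test_that("jitter zero plants every link exactly at the target", {
  cfg <- sim_config(n_trees = 1, depth = 2, branching = 2, n_genes = 30,
                    background_rate = 0,
                    planted = list(planted_set("q", "T01.001", 25,
                                               jitter_depth = 0,
                                               query_size = 10)),
                    seed = 3)
  f <- simulate_forest(cfg)
  sim <- simulate_links(f, cfg)
  nd <- tibble::as_tibble(f)
  target_term <- nd$term_id[nd$tree_number == "T01.001"]
  expect_true(all(sim$links$term == target_term))
  expect_true(all(sim$links$gene %in% sim$query_sets$q))
})

test_that("zero planted links yield pure background; zero rates yield nothing", {
  cfg <- sim_config(n_trees = 1, depth = 2, branching = 2, n_genes = 30,
                    background_rate = 0.05,
                    planted = list(planted_set("q", "T01.001", 0,
                                               query_size = 5)),
                    seed = 4)
  f <- simulate_forest(cfg)
  sim <- simulate_links(f, cfg)
  expect_true(all(sim$links$source == "background"))
  expect_length(sim$query_sets$q, 5L)

  cfg0 <- sim_config(n_trees = 1, depth = 1, branching = 2, n_genes = 10,
                     background_rate = 0, planted = list(), seed = 4)
  sim0 <- simulate_links(simulate_forest(cfg0), cfg0)
  expect_equal(nrow(sim0$links), 0L)
})

test_that("jitter deeper than the target subtree warns and clips", {
  cfg <- sim_config(n_trees = 1, depth = 2, branching = 2, n_genes = 20,
                    background_rate = 0,
                    planted = list(planted_set("q", "T01.001.001", 10,
                                               jitter_depth = 3,
                                               query_size = 5)),
                    seed = 7)
  f <- simulate_forest(cfg)
  expect_warning(sim <- simulate_links(f, cfg), "clipped")
  nd <- tibble::as_tibble(f)
  leaf_term <- nd$term_id[nd$tree_number == "T01.001.001"]
  expect_true(all(sim$links$term == leaf_term))
})

test_that("with jitter the target's direct overlap falls below its pooled overlap", {
  cfg <- sim_config(n_trees = 1, depth = 3, branching = 3, n_genes = 100,
                    background_rate = 0,
                    planted = list(planted_set("q", "T01.001", 60,
                                               jitter_depth = 2,
                                               query_size = 20)),
                    seed = 8)
  f <- simulate_forest(cfg)
  sim <- simulate_links(f, cfg)
  idx <- attach_links(f, sim$links)
  q <- sim$query_sets$q
  expect_lt(observed_overlap(idx, "T01.001", q, "direct"),
            observed_overlap(idx, "T01.001", q, "pooled"))
})

test_that("planted enrichment is detectable at the target node", {
  hits <- 0L
  for (s in 1:8) {
    cfg <- sim_config(n_trees = 2, depth = 3, branching = 3, n_genes = 150,
                      background_rate = 0.005,
                      planted = list(planted_set("q", "T01.001", 80,
                                                 jitter_depth = 2,
                                                 query_size = 25)),
                      seed = s)
    f <- simulate_forest(cfg)
    sim <- simulate_links(f, cfg)
    idx <- attach_links(f, sim$links)
    res <- enrich(idx, sim$query_sets$q, n_perm = 2000, seed = 100 + s)
    if (res$p_pooled[res$tree_number == "T01.001"] < 0.005) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("entries sharing a name plant one query set at several targets", {
  cfg <- sim_config(n_trees = 2, depth = 2, branching = 2, n_genes = 50,
                    background_rate = 0,
                    planted = list(
                      planted_set("q", "T01.001", 15, query_size = 8),
                      planted_set("q", "T02.001", 15, query_size = 8)),
                    seed = 9)
  f <- simulate_forest(cfg)
  sim <- simulate_links(f, cfg)
  expect_length(sim$query_sets, 1L)
  expect_true(all(sim$links$gene %in% sim$query_sets$q))
  nd <- tibble::as_tibble(f)
  cats <- unique(tn_root(nd$tree_number[match(sim$links$term, nd$term_id)]))
  expect_setequal(cats, c("T01", "T02"))
})

test_that("the worked pooling example has the canonical 4/2/3 -> 7 structure", {
  ex <- pooling_example()
  idx <- attach_links(ex$forest, ex$links)
  counts <- lengths(idx$direct[c("C16.131.666", "C16.131.666.411",
                                 "C16.131.666.800")])
  expect_equal(unname(counts), c(4L, 2L, 3L))
  expect_equal(length(idx$pooled[["C16.131.666"]]), 7L)
  # children are leaves: pooled equals direct there
  expect_equal(idx$pooled[["C16.131.666.411"]], idx$direct[["C16.131.666.411"]])
  expect_equal(idx$pooled[["C16.131.666.800"]], idx$direct[["C16.131.666.800"]])
  # exactly two genes are linked under two nodes each
  tab <- table(tibble::as_tibble(ex$links)$gene)
  expect_equal(sum(tab == 2), 2L)
})
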