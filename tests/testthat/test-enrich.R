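# The permutation test and its closed-form companion. The independent oracle
# for the permutation path is exhaustive enumeration of all query-sized
# subsets; for a single node with K of N universe genes marked, the
# enumeration p must equal the hypergeometric upper tail.

test_that("observed overlaps count query genes at a node", {
  ex <- pooling_example()
  idx <- attach_links(ex$forest, ex$links)
  root <- "C16.131.666"
  expect_equal(observed_overlap(idx, root, ex$query, mode = "pooled"), 7L)
  expect_equal(observed_overlap(idx, root, ex$query, mode = "direct"), 4L)
  # disjoint query
  expect_equal(observed_overlap(idx, root, c("ZZZ1", "ZZZ2")), 0L)
  # query superset of node genes
  expect_equal(observed_overlap(idx, root, c(ex$query, "EXTRA")), 7L)
  expect_error(observed_overlap(idx, "Z99", ex$query), "not present")
})

test_that("hypergeometric tail matches exact enumeration and edge cases", {
  # k=2, K=3, q=2, N=6: of the 15 draws of 2 from 6, C(3,2)=3 hit both marked
  expect_equal(hypergeom_tail(2, K = 3, q = 2, N = 6), 0.2)
  expect_equal(hypergeom_tail(0, K = 3, q = 2, N = 6), 1.0)
  expect_equal(hypergeom_tail(3, K = 3, q = 2, N = 6), 0.0)  # k > min(K, q)
  expect_error(hypergeom_tail(1, K = 7, q = 2, N = 6), "K <= N")
  # large-N stability
  expect_gt(hypergeom_tail(20, K = 100, q = 200, N = 12000), 0)
})

test_that("permutation p-values are deterministic and respect granularity", {
  ex <- pooling_example(n_background = 10)
  idx <- attach_links(ex$forest, ex$links)
  r1 <- enrich(idx, ex$query, n_perm = 300, seed = 42)
  r2 <- enrich(idx, ex$query, n_perm = 300, seed = 42)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- enrich(idx, ex$query, n_perm = 300, seed = 43)
  expect_false(identical(tidy(r1), tidy(r3)))
  # n_perm = 1: p is 0 or 1 everywhere
  r4 <- enrich(idx, ex$query, n_perm = 1, seed = 1)
  expect_true(all(r4$p_direct %in% c(0, 1)))
  expect_true(all(r4$p_pooled %in% c(0, 1)))
})

test_that("query equal to the universe gives p = 1 at every node", {
  f <- tiny_forest()
  idx <- attach_links(f, tiny_links())
  res <- enrich(idx, idx$universe, n_perm = 50, seed = 1)
  expect_true(all(res$p_direct == 1))
  expect_true(all(res$p_pooled == 1))
})

test_that("zero observed overlap gives p = 1 under tail = ge", {
  f <- tiny_forest()
  idx <- attach_links(f, tiny_links())
  # query inside universe but absent from tree A01's nodes
  res <- enrich(idx, "G4", n_perm = 100, seed = 5, tail = "ge")
  zero <- res$k_pooled == 0
  expect_true(any(zero))
  expect_true(all(res$p_pooled[zero] == 1))
  # strict tail: p < 1 possible at zero overlap (chance of any overlap)
  res_gt <- enrich(idx, "G4", n_perm = 100, seed = 5, tail = "gt")
  expect_true(all(res_gt$p_pooled <= res$p_pooled + 1e-12))
})

test_that("k_pooled >= k_direct and p-values lie in [0, 1]", {
  for (seed in 1:3) {
    f <- random_forest(n_nodes = 40, seed = seed)
    links <- random_links(f, seed = seed)
    idx <- attach_links(f, links)
    query <- withr::with_seed(seed, sample(idx$universe, 5))
    res <- enrich(idx, query, n_perm = 200, seed = seed)
    expect_true(all(res$k_pooled >= res$k_direct))
    expect_true(all(res$p_direct >= 0 & res$p_direct <= 1))
    expect_true(all(res$p_pooled >= 0 & res$p_pooled <= 1))
  }
})

test_that("query genes outside the universe are excluded before drawing", {
  f <- tiny_forest()
  idx <- attach_links(f, tiny_links())
  res <- enrich(idx, c("G1", "G2", "NOT_LINKED"), n_perm = 50, seed = 1)
  expect_equal(attr(res, "query_size"), 3L)
  expect_equal(attr(res, "effective_size"), 2L)
  expect_error(enrich(idx, c("X1", "X2"), n_perm = 10),
               "disjoint from universe")
})

test_that("exhaustive mode equals the hypergeometric tail exactly", {
  # node-independent placement: each node's genes drawn independently, then
  # every node's marginal enumeration p must be the closed-form tail
  for (seed in 1:4) {
    withr::with_seed(seed, {
      N <- sample(6:12, 1)
      universe <- sprintf("U%02d", seq_len(N))
      f <- random_forest(n_nodes = 8, seed = seed)
      nd <- tibble::as_tibble(f)
      links <- as_link_table(data.frame(
        gene = sample(universe, 30, replace = TRUE),
        term = sample(nd$term_id, 30, replace = TRUE)))
      idx <- attach_links(f, links)
      q <- sample(2:4, 1)
      query <- sample(idx$universe, min(q, length(idx$universe)))
    })
    res <- enrich(idx, query, method = "exhaustive")
    N_eff <- attr(res, "universe_size")
    q_eff <- attr(res, "effective_size")
    for (i in seq_len(nrow(res))) {
      K_d <- length(idx$direct[[res$tree_number[i]]])
      K_p <- length(idx$pooled[[res$tree_number[i]]])
      expect_equal(res$p_direct[i],
                   hypergeom_tail(res$k_direct[i], K_d, q_eff, N_eff),
                   tolerance = 1e-12)
      expect_equal(res$p_pooled[i],
                   hypergeom_tail(res$k_pooled[i], K_p, q_eff, N_eff),
                   tolerance = 1e-12)
    }
  }
})

test_that("permutation p agrees with the hypergeometric within Monte Carlo error", {
  # a handful of configurations here; the acceptance suite runs the full 20
  withr::with_seed(7, {
    n_ok <- 0L; n_tot <- 0L
    for (i in 1:6) {
      N <- sample(40:120, 1)
      universe <- sprintf("U%03d", seq_len(N))
      f <- parse_forest(c("Root;X01", "Kid;X01.100"), quiet = TRUE)
      K <- sample(5:20, 1)
      links <- as_link_table(data.frame(
        gene = c(sample(universe, K), universe),
        term = c(rep("Kid", K), rep("Root", N))))
      idx <- attach_links(f, links)
      q <- sample(5:15, 1)
      query <- sample(universe, q)
      res <- enrich(idx, query, n_perm = 10000, seed = i)
      row <- res[res$tree_number == "X01.100", ]
      p_hyper <- hypergeom_tail(row$k_direct, K, q, N)
      band <- 4 * sqrt(p_hyper * (1 - p_hyper) / 10000)
      n_tot <- n_tot + 1L
      if (abs(row$p_direct - p_hyper) <= band + 1e-12) n_ok <- n_ok + 1L
    }
    expect_gte(n_ok, n_tot - 1L)
  })
})

test_that("nodes sharing all genes receive identical p-values", {
  # the shared permutation stream preserves dependence between related nodes
  f <- parse_forest(c("A;D01", "B;D01.100", "C;D02"), quiet = TRUE)
  links <- as_link_table(data.frame(
    gene = rep(c("G1", "G2", "G3", "G4"), 2),
    term = rep(c("B", "C"), each = 4)))
  idx <- attach_links(f, links)
  res <- enrich(idx, c("G1", "G2"), n_perm = 500, seed = 9)
  b <- res[res$tree_number == "D01.100", ]
  c_ <- res[res$tree_number == "D02", ]
  expect_identical(b$p_direct, c_$p_direct)
  expect_identical(b$p_pooled, c_$p_pooled)
})

test_that("null rejection rate matches the test's attainable level", {
  # fixed node, independent random queries: testing at alpha must reject at
  # the attainable level of the discrete null (within binomial noise)
  N <- 60; K <- 20; q <- 10; alpha <- 0.05
  universe <- sprintf("U%02d", seq_len(N))
  marked <- withr::with_seed(11, sample(universe, K))
  # a second tree carries the rest so the universe is all N genes
  f2 <- parse_forest(c("Solo;Y01", "Rest;Y02"), quiet = TRUE)
  links2 <- as_link_table(data.frame(
    gene = c(marked, universe),
    term = c(rep("Solo", K), rep("Rest", N))))
  idx <- attach_links(f2, links2)
  # attainable level: smallest hypergeometric tail above alpha boundary
  k_crit <- min(which(hypergeom_tail(0:K, K, q, N) < alpha)) - 1L
  alpha_star <- hypergeom_tail(k_crit, K, q, N)
  R <- 400L
  withr::with_seed(12, {
    rej <- vapply(seq_len(R), function(i) {
      query <- sample(universe, q)
      res <- enrich(idx, query, n_perm = 400)
      res$p_direct[res$tree_number == "Y01"] < alpha
    }, logical(1))
  })
  se <- sqrt(alpha_star * (1 - alpha_star) / R)
  expect_lt(abs(mean(rej) - alpha_star), 2.58 * se + 0.01)
})

test_that("tidy, glance and autoplot work on enrichment results", {
  ex <- pooling_example(n_background = 5)
  idx <- attach_links(ex$forest, ex$links)
  res <- enrich(idx, ex$query, name = "lung development", n_perm = 100,
                seed = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "enrich_result"))
  g <- glance(res)
  expect_equal(g$query, "lung development")
  expect_equal(g$n_perm, 100)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
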