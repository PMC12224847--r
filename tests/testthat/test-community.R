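# modularity, the native Louvain optimizer, and the brute-force oracle

test_that("modularity matches hand-derived values on the bridge graph", {
  g <- bridge_graph()
  expect_equal(modularity_q(g, rep(1, 6)), 0, tolerance = 1e-12)
  expect_equal(modularity_q(g, c(1, 1, 1, 2, 2, 2)), 5 / 14,
               tolerance = 1e-12)
  expect_equal(modularity_q(g, 1:6), -34 / 196, tolerance = 1e-12)
  expect_error(modularity_q(make_graph(data.frame(i = integer(0),
                                                  j = integer(0),
                                                  weight = numeric(0)),
                                       n = 3), c(1, 1, 1)),
               "edgeless")
})

test_that("modularity is invariant to label permutation and agrees with igraph", {
  set.seed(31)
  for (r in 1:20) {
    g <- random_gnp_graph(10, 0.35, seed = 100 + r)
    lab <- sample(1:3, 10, replace = TRUE)
    perm <- sample(3)
    expect_equal(modularity_q(g, lab), modularity_q(g, perm[lab]),
                 tolerance = 1e-12)
    ig <- igraph::graph_from_edgelist(as.matrix(g$edges[, 1:2]),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, 10 - igraph::vcount(ig))
    expect_equal(modularity_q(g, lab), igraph::modularity(ig, lab),
                 tolerance = 1e-12)
  }
})

test_that("louvain recovers planted disconnected and bridge structure", {
  g <- two_cliques_graph(4, 4)
  for (seed in 0:4) {
    p <- louvain(g, seed = seed)
    expect_equal(p$n_communities, 2)
    expect_equal(unname(p$membership), rep(1:2, each = 4))
  }
  p <- louvain(bridge_graph(), seed = 1)
  expect_equal(p$n_communities, 2)
  expect_equal(p$modularity, 5 / 14, tolerance = 1e-12)
})

test_that("louvain's reported Q equals from-scratch recomputation and is
           monotone over levels", {
  for (r in 1:10) {
    g <- random_gnp_graph(40, 0.15, seed = 50 + r)
    p <- louvain(g, seed = r)
    expect_equal(modularity_q(g, p$membership), p$modularity,
                 tolerance = 1e-12)
    expect_true(all(diff(p$level_modularity) >= -1e-12))
    # dominates the singleton baseline
    expect_gte(p$modularity, modularity_q(g, seq_len(g$n_nodes)))
    # relabeling nodes leaves the Q of any fixed partition unchanged
    perm <- sample(g$n_nodes)
    g2 <- make_graph(data.frame(i = pmin(perm[g$edges$i], perm[g$edges$j]),
                                j = pmax(perm[g$edges$i], perm[g$edges$j]),
                                weight = 1), n = g$n_nodes)
    lab <- p$membership
    lab2 <- integer(g$n_nodes); lab2[perm] <- lab
    expect_equal(modularity_q(g2, lab2), p$modularity, tolerance = 1e-12)
  }
})

test_that("brute-force oracle: 2-node graph and bridge graph", {
  g2 <- make_graph(data.frame(i = 1, j = 2, weight = 1))
  bf <- brute_force_best_partition(g2)
  expect_equal(bf$n_communities, 1)
  expect_equal(bf$modularity, 0, tolerance = 1e-12)
  bf <- brute_force_best_partition(bridge_graph())
  expect_equal(unname(bf$membership), c(1, 1, 1, 2, 2, 2))
  expect_equal(bf$modularity, 5 / 14, tolerance = 1e-12)
  expect_error(brute_force_best_partition(random_gnp_graph(11, 0.3, 1)),
               "10 nodes")
})

test_that("oracle Q dominates louvain Q; equality on clean block structure", {
  worse <- 0
  for (r in 1:30) {
    g <- random_gnp_graph(sample(4:8, 1), runif(1, 0.25, 0.7), seed = 200 + r)
    lv <- louvain(g, seed = r)
    bf <- brute_force_best_partition(g)
    expect_lte(lv$modularity, bf$modularity + 1e-12)
    if (lv$modularity < bf$modularity - 1e-9) worse <- worse + 1
  }
  # clean two-clique instances: the heuristic attains the global optimum
  for (sizes in list(c(3, 3), c(4, 4), c(4, 3))) {
    g <- two_cliques_graph(sizes[1], sizes[2])
    expect_equal(louvain(g, seed = 0)$modularity,
                 brute_force_best_partition(g)$modularity,
                 tolerance = 1e-12)
  }
})

test_that("oracle fast path agrees with modularity_q at several gammas", {
  for (r in 1:5) {
    g <- random_gnp_graph(6, 0.5, seed = 300 + r)
    for (gam in c(0.5, 1, 1.5)) {
      bf <- brute_force_best_partition(g, gamma = gam)
      expect_equal(modularity_q(g, bf$membership, gamma = gam),
                   bf$modularity, tolerance = 1e-12)
    }
  }
})

test_that("higher resolution tends to smaller largest communities", {
  # documented as a tendency, not a theorem: checked on planted graphs
  sizes <- sapply(c(0.6, 1.4), function(gam) {
    mx <- 0
    for (s in 1:5) {
      g <- planted_partition_graph(rep(20, 4), 0.5, 0.05, seed = s)
      mx <- mx + max(table(louvain(g, gamma = gam, seed = s)$membership))
    }
    mx
  })
  expect_lte(sizes[2], sizes[1])
})

test_that("planted-partition recovery: ARI >= 0.9 across seeds", {
  aris <- sapply(1:10, function(s) {
    g <- planted_partition_graph(rep(30, 4), 0.4, 0.02, seed = s)
    adjusted_rand_index(louvain(g, seed = s)$membership,
                        attr(g, "planted"))
  })
  expect_true(all(aris >= 0.9))
})

test_that("adjusted_rand_index behaves at the reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(77)
  a <- sample(1:4, 2000, TRUE); b <- sample(1:4, 2000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})

test_that("partition export writes TSV and a JSON trace", {
  p <- louvain(bridge_graph(), seed = 0)
  path <- file.path(tempdir(), "part.tsv")
  write_partition(p, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 6)
  rep <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(rep$modularity, 5 / 14, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})
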