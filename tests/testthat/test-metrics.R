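test_that("closed-form metric values hold", {
  # mean jump length
  expect_identical(mean_jump_length(diag(5)), 0)
  expect_identical(mean_jump_length(matrix(c(0, 1, 1, 0), 2, 2)), 1)
  expect_equal(mean_jump_length(matrix(1 / 20, 20, 20)), 6.65)
  # Laplacian Estrada index
  expect_equal(laplacian_estrada_index(matrix(0, 7, 7)), 7)
  expect_equal(laplacian_estrada_index(matrix(c(0, 1, 1, 0), 2, 2)),
               1 + exp(2))
  # clustering
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(clustering_coefficient(K3), 1)
  cyc <- matrix(0, 4, 4); cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  expect_equal(clustering_coefficient(cyc + t(cyc)), 0) # triangle-free
  # betweenness
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(betweenness_centrality(K5), 0)
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(betweenness_centrality(p3), 1 / 3) # middle node carries all
  # modularity of two disconnected triangles
  tt <- matrix(0, 6, 6)
  tt[1, 2] <- tt[2, 3] <- tt[3, 1] <- tt[4, 5] <- tt[5, 6] <- tt[6, 4] <- 1
  tt <- tt + t(tt)
  dm <- detect_modules(tt)
  expect_equal(dm$modularity, 0.5)
  expect_identical(length(unique(dm$membership)), 2L)
  # whole graph as one module scores 0; singleton modules score <= 0
  expect_equal(modularity_score(tt, rep(1, 6)), 0)
  expect_lte(modularity_score(tt, 1:6), 0)
})

test_that("each metric matches its brute-force oracle on random graphs", {
  set.seed(31)
  n_cc <- n_bc <- 0
  for (rep in 1:110) {
    Q <- sample(3:7, 1)
    W <- random_markov(Q, density = 0.45)$W
    expect_equal(clustering_coefficient(W), cc_oracle(W), tolerance = 1e-10)
    expect_equal(mean_jump_length(W), mjl_oracle(W), tolerance = 1e-12)
    expect_equal(laplacian_estrada_index(W), lee_oracle(W),
                 tolerance = 1e-8)
    memb <- sample(1:3, Q, replace = TRUE)
    if (sum(W + t(W)) - sum(diag(W)) * 2 > 0)
      expect_equal(modularity_score(W, memb), mo_oracle(W, memb),
                   tolerance = 1e-12)
    expect_equal(betweenness_centrality(W), bc_oracle(W), tolerance = 1e-10)
  }
})

test_that("detected partitions are self-consistent and maximize locally", {
  set.seed(32)
  for (rep in 1:20) {
    W <- random_markov(sample(4:8, 1))$W
    if (sum(sym_between <- (W + t(W))) == 0) next
    dm <- detect_modules(W)
    expect_equal(dm$modularity, modularity_score(W, dm$membership),
                 tolerance = 1e-12)
    expect_true(dm$modularity >= -0.5 && dm$modularity <= 1)
  }
  # no arcs: single-module partition with modularity 0 by convention
  dm0 <- detect_modules(matrix(0, 4, 4))
  expect_identical(dm0$membership, rep(1L, 4))
  expect_identical(dm0$modularity, 0)
  expect_error(modularity_score(matrix(0, 4, 4), rep(1, 4)), "no edges")
  # detected score cross-checked against an independent implementation
  set.seed(33)
  W <- random_markov(6)$W
  Wp <- (W + t(W)) / 2; diag(Wp) <- 0
  g <- igraph::graph_from_adjacency_matrix(Wp, mode = "undirected",
                                           weighted = TRUE)
  memb <- sample(1:2, 6, replace = TRUE)
  expect_equal(modularity_score(W, memb),
               igraph::modularity(g, memb, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("random-walk estimate matches the trace formula", {
  expect_equal(mean_jump_length_walk(diag(3), S = 500, seed = 1)$delta, 0)
  swap <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(mean_jump_length_walk(swap, S = 500, seed = 2)$delta, 1)
  # doubly-stochastic: uniform stationary law makes walk and trace agree
  set.seed(41)
  P <- Reduce(`+`, lapply(1:4, function(i) {
    p <- sample(1:6); m <- matrix(0, 6, 6); m[cbind(1:6, p)] <- 1; m
  })) / 4
  w <- mean_jump_length_walk(P, S = 2e5, seed = 7)
  expect_lt(abs(w$delta - mean_jump_length(P)), 3 * w$se)
  expect_error(mean_jump_length_walk(matrix(0, 3, 3), S = 10),
               "unsupported")
  # dead-end rows restart without biasing reachable-state jumps
  dead <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_true(is.finite(mean_jump_length_walk(dead, S = 1e3, seed = 3)$delta))
})

test_that("metrics are permutation-invariant except the jump length", {
  set.seed(51)
  W <- random_markov(6, density = 0.7)$W
  perm <- c(3, 6, 1, 5, 2, 4)
  Wp <- W[perm, perm][order(perm), order(perm)] # sanity: identity
  expect_identical(Wp, W)
  Wperm <- matrix(0, 6, 6)
  Wperm[perm, perm] <- W
  expect_equal(clustering_coefficient(Wperm), clustering_coefficient(W))
  expect_equal(betweenness_centrality(Wperm), betweenness_centrality(W))
  expect_equal(laplacian_estrada_index(Wperm), laplacian_estrada_index(W))
  memb <- sample(1:2, 6, replace = TRUE)
  membp <- integer(6); membp[perm] <- memb
  expect_equal(modularity_score(Wperm, membp), modularity_score(W, memb))
  # the jump length uses node indices and must change under relabeling
  expect_false(isTRUE(all.equal(mean_jump_length(Wperm),
                                mean_jump_length(W))))
})

test_that("metrics stay finite and bounded on pipeline matrices", {
  set.seed(61)
  x <- rnorm(300)
  for (k in c(1, 5, 12)) {
    W <- to_markov(quantile_graph(x, k))
    for (m in qg_metrics()) {
      v <- qg_metric(W, m)
      expect_true(is.finite(v), info = m)
    }
    expect_gte(qg_metric(W, "CC"), 0); expect_lte(qg_metric(W, "CC"), 1)
    expect_gte(qg_metric(W, "MJL"), 0)
    expect_lte(qg_metric(W, "MJL"), W$Q - 1)
    expect_gte(qg_metric(W, "BC"), 0); expect_lte(qg_metric(W, "BC"), 1)
    expect_gte(qg_metric(W, "LEE"), W$Q * exp(0) * 0) # finite, positive
  }
  # matrices with unsupported rows are tolerated by every metric
  holey <- to_markov(matrix(c(0, 0, 0, 2, 0, 1, 1, 1, 0), 3, 3,
                            byrow = TRUE))
  for (m in qg_metrics()) expect_true(is.finite(qg_metric(holey, m)))
})
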