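test_that("cube-root rule gives the published quantile counts", {
  expect_identical(default_num_quantiles(1024), 20L)
  expect_identical(default_num_quantiles(8), 4L)
  expect_identical(default_num_quantiles(1000), 20L)
  expect_identical(default_num_quantiles(2), 3L) # 2 * 2^(1/3) rounds to 3
  expect_error(default_num_quantiles(1), "T must")
})

test_that("partition boundaries reproduce the worked-example quantiles", {
  # 20 sorted samples with ties placed so the interpolated quantiles land
  # exactly on the published interval boundaries
  anchors <- c(-7.783, -3.050, 0.829, 4.657, 7.070, 9.090)
  s <- numeric(20)
  s[1] <- anchors[1]
  s[c(4, 5)] <- anchors[2]
  s[c(8, 9)] <- anchors[3]
  s[c(12, 13)] <- anchors[4]
  s[c(16, 17)] <- anchors[5]
  s[20] <- anchors[6]
  fill <- function(i, j) s[i:j] <<- seq(s[i - 1], s[j + 1],
                                        length.out = j - i + 3)[2:(j - i + 2)]
  fill(2, 3); fill(6, 7); fill(10, 11); fill(14, 15); fill(18, 19)
  p <- fit_partition(sample(s), Q = 5)
  expect_equal(p$boundaries, anchors, tolerance = 1e-12)
})

test_that("quantile intervals share the samples evenly", {
  p <- fit_partition(1:20, Q = 5)
  expect_true(all(table(quantile_indices(1:20, p)) == 4))
  set.seed(11)
  u <- runif(1000)
  occ <- table(quantile_indices(u, fit_partition(u, Q = 10)))
  expect_true(all(occ == 100))
  # floor/ceiling occupancy property for distinct values, uneven T/Q
  for (rep in 1:20) {
    T <- sample(20:90, 1); Q <- sample(2:9, 1)
    x <- sample(rnorm(500), T)
    occ <- tabulate(quantile_indices(x, fit_partition(x, Q)), nbins = Q)
    expect_true(all(occ >= floor(T / Q) & occ <= ceiling(T / Q)),
                info = sprintf("T=%d Q=%d occ=%s", T, Q,
                               paste(occ, collapse = ",")))
  }
})

test_that("degenerate and invalid partitions are rejected", {
  expect_error(fit_partition(rep(3.5, 10), Q = 2), "degenerate")
  expect_error(fit_partition(1:5, Q = 6), "may not exceed")
  expect_error(fit_partition(1:5, Q = 1), "at least 2")
})

test_that("index assignment follows left-closed intervals, last closed", {
  p <- structure(list(Q = 2L, boundaries = c(1, 2.5, 4)),
                 class = "qg_partition")
  expect_identical(quantile_indices(c(1, 2, 3, 4), p), c(1L, 1L, 2L, 2L))
  # boundary value goes to the upper interval; the maximum stays in Q
  p3 <- structure(list(Q = 3L, boundaries = c(0, 1, 2, 3)),
                  class = "qg_partition")
  expect_identical(quantile_indices(c(0, 1, 2, 3), p3), c(1L, 2L, 3L, 3L))
  # monotone distinct series with Q = T puts one sample per bin
  x <- sort(rnorm(12))
  expect_identical(quantile_indices(x, fit_partition(x, Q = 12)), 1:12)
})

test_that("index assignment agrees with per-sample interval search", {
  set.seed(4)
  for (rep in 1:10) {
    x <- rnorm(80)
    p <- fit_partition(x, Q = 7)
    got <- quantile_indices(x, p)
    b <- p$boundaries
    want <- vapply(x, function(v) {
      for (i in 1:7)
        if (v >= b[i] && (v < b[i + 1] || (i == 7 && v <= b[8]))) return(i)
      NA_integer_
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("reusing a reference partition clamps outliers with a warning", {
  p <- fit_partition(1:10, Q = 2)
  expect_warning(idx <- quantile_indices(c(0, 5, 99), p), "clamped")
  expect_identical(idx, c(1L, 1L, 2L))
})

test_that("graph counts are exact transition tallies summing to T - k", {
  g <- build_quantile_graph(c(1, 2, 1, 2, 1), k = 1, Q = 2)
  expect_identical(g$counts, matrix(c(0L, 2L, 2L, 0L), 2, 2))
  expect_identical(sum(g$counts), 4L)
  set.seed(9)
  for (rep in 1:15) {
    T <- sample(10:60, 1); Q <- sample(2:6, 1); k <- sample(1:(T - 1), 1)
    idx <- sample(1:Q, T, replace = TRUE)
    g <- build_quantile_graph(idx, k, Q = Q)
    # naive double-loop tally
    want <- matrix(0L, Q, Q)
    for (t in 1:(T - k))
      want[idx[t], idx[t + k]] <- want[idx[t], idx[t + k]] + 1L
    expect_identical(g$counts, want)
    expect_identical(sum(g$counts), as.integer(T - k))
  }
  expect_error(build_quantile_graph(c(1, 2, 1), k = 3, Q = 2), "1 <= k < T")
})

test_that("row normalization yields a Markov matrix, zero rows flagged", {
  m <- to_markov(matrix(c(2, 0, 2, 4), 2, 2))
  expect_equal(m$W, matrix(c(0.5, 0, 0.5, 1), 2, 2))
  expect_identical(m$row_support, c(TRUE, TRUE))
  z <- to_markov(matrix(c(0, 0, 3, 1), 2, 2, byrow = TRUE))
  expect_identical(unname(z$row_support), c(FALSE, TRUE))
  expect_true(all(z$W[1, ] == 0))
  set.seed(2)
  for (rep in 1:10) {
    g <- random_graph(sample(3:8, 1))
    m <- to_markov(g)
    expect_equal(unname(rowSums(m$W)[m$row_support]),
                 rep(1, sum(m$row_support)), tolerance = 1e-12)
    expect_true(all(m$W >= 0 & m$W <= 1))
  }
})

test_that("worked-example k=1 row normalizes to the printed weights", {
  W <- to_markov(arcs_to_counts(qg_demo_arcs$k1, Q = 5))$W
  expect_equal(W[1, ], c(0.25, 0, 0.25, 0, 0.5))
})

test_that("median aggregation matches a per-entry brute-force median", {
  g <- random_graph(5)
  one <- median_transition_matrix(list(g))
  expect_equal(one$W, to_markov(g)$W)
  # idempotence on duplicated graphs
  expect_equal(median_transition_matrix(list(g, g))$W, to_markov(g)$W)
  set.seed(6)
  graphs <- replicate(24, random_graph(5), simplify = FALSE)
  got <- median_transition_matrix(graphs)
  want <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    want[i, j] <- median(vapply(graphs, function(g) g$counts[i, j],
                                numeric(1)))
  rs <- rowSums(want)
  want <- want / ifelse(rs > 0, rs, 1)
  expect_equal(got$W, want)
  g2 <- build_quantile_graph(sample(1:5, 30, replace = TRUE), k = 2, Q = 5)
  expect_error(median_transition_matrix(list(g, g2)), "same Q and lag")
})

test_that("quantile relabeling permutes the count matrix rows and columns", {
  set.seed(13)
  idx <- sample(1:5, 50, replace = TRUE)
  perm <- sample(1:5)
  g <- build_quantile_graph(idx, 3, Q = 5)
  gp <- build_quantile_graph(perm[idx], 3, Q = 5)
  expect_identical(gp$counts[perm, perm], g$counts)
})

test_that("graph construction is deterministic", {
  x <- rnorm(100)
  expect_identical(quantile_graph(x, 4)$counts, quantile_graph(x, 4)$counts)
})
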