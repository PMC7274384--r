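# Independent brute-force oracles for the five metrics, and small fixture
# generators.  Oracles follow the definitions literally (loops, path
# enumeration, matrix exponentials) and share no code with the package
# implementations they check.

# Weighted clustering coefficient: literal triple loop.
cc_oracle <- function(W) {
  Q <- nrow(W)
  W <- W; diag(W) <- 0
  A <- (W > 0) * 1
  cc <- numeric(Q)
  for (i in 1:Q) {
    nbrs <- which(A[i, ] > 0 | A[, i] > 0)
    d_i <- length(nbrs)
    s_i <- sum(W[i, ])
    if (d_i <= 1 || s_i == 0) next
    acc <- 0
    for (j in 1:Q) for (d in 1:Q) {
      if (A[i, j] == 1 && A[j, d] == 1 && A[i, d] == 1)
        acc <- acc + (W[i, j] + W[i, d]) / 2
    }
    cc[i] <- acc / (s_i * (d_i - 1))
  }
  mean(cc)
}

# Mean jump length: literal double sum.
mjl_oracle <- function(W) {
  Q <- nrow(W)
  acc <- 0
  for (i in 1:Q) for (j in 1:Q) acc <- acc + abs(i - j) * W[i, j]
  acc / Q
}

# Betweenness: enumerate every simple directed path between each ordered
# pair, keep those of minimal length, count pass-throughs.
bc_oracle <- function(W) {
  Q <- nrow(W)
  A <- (W > 0); diag(A) <- FALSE
  all_paths <- function(from, to) {
    res <- list()
    walk <- function(path) {
      cur <- path[length(path)]
      if (cur == to) { res[[length(res) + 1L]] <<- path; return(invisible()) }
      for (nxt in which(A[cur, ])) if (!nxt %in% path) walk(c(path, nxt))
    }
    walk(from)
    res
  }
  bc <- numeric(Q)
  for (i in 1:Q) for (j in 1:Q) {
    if (i == j) next
    paths <- all_paths(i, j)
    if (length(paths) == 0L) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    for (u in setdiff(1:Q, c(i, j))) {
      thru <- sum(vapply(sp, function(p) u %in% p, logical(1)))
      bc[u] <- bc[u] + thru / length(sp)
    }
  }
  mean(bc / ((Q - 1) * (Q - 2)))
}

# Modularity: literal evaluation on the symmetrized graph.
mo_oracle <- function(W, membership) {
  Q <- nrow(W)
  Wp <- (W + t(W)) / 2; diag(Wp) <- 0
  E <- sum(Wp) / 2
  M <- 0
  for (mod in unique(membership)) {
    v <- which(membership == mod)
    e_i <- 0; d_i <- 0
    for (a in v) {
      for (b in v) e_i <- e_i + Wp[a, b]
      d_i <- d_i + sum(Wp[a, ])
    }
    e_i <- e_i / 2
    M <- M + e_i / E - (d_i / (2 * E))^2
  }
  M
}

# Laplacian Estrada index via the trace of the matrix exponential.
lee_oracle <- function(W) {
  Wp <- (W + t(W)) / 2; diag(Wp) <- 0
  L <- diag(rowSums(Wp), nrow(Wp)) - Wp
  sum(diag(as.matrix(Matrix::expm(L))))
}

# Mann-Whitney AUC by exhaustive pair counting (ties count 1/2).
auc_oracle <- function(x, y) {
  wins <- 0
  for (a in x) for (b in y) wins <- wins + (a > b) + 0.5 * (a == b)
  auc <- wins / (length(x) * length(y))
  max(auc, 1 - auc)
}

# Random transition matrix from random integer counts (occasionally with
# all-zero rows, which metrics must tolerate).
random_markov <- function(Q, density = 0.5) {
  counts <- matrix(rpois(Q * Q, 2) * (runif(Q * Q) < density), Q, Q)
  to_markov(counts)
}

random_graph <- function(Q, T = 60) {
  build_quantile_graph(sample(1:Q, T, replace = TRUE), k = 1, Q = Q)
}

# Small two-group cohort with the default class contrast, one channel.
two_class_cohort <- function(n = 24, seed = 1, channels = "F7", T = 1024) {
  spec <- cohort_spec(groups = c("A", "C"), subjects_per_group = n,
                      channels = channels, T = T,
                      band_power = list(
                        A = c(delta = 1.0, theta = 0.8, alpha = 1.6, beta = 0.6),
                        C = c(delta = 2.6, theta = 2.0, alpha = 0.7, beta = 0.45)),
                      rhythm_power = c(A = 0.4, C = 0.15))
  generate_cohort(spec, seed = seed)
}

# Two well-separated Gaussian blobs as a five-feature table.
blob_table <- function(n = 24, gap = 8, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 5), n), matrix(rnorm(n * 5, gap), n))
  df <- as.data.frame(X)
  names(df) <- qg_metrics()
  df$label <- factor(rep(c("healthy", "AD"), each = n),
                     levels = c("healthy", "AD"))
  df
}

# Cache expensive cohorts across test files within one run.
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}
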