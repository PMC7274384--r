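## The five topological metrics used to characterize quantile graphs.  All
## five consume the Markov transition weights W_k (entries in [0, 1]); the
## spectral and community metrics first symmetrize the weights and drop
## self-loops so the underlying operators are those of a simple weighted
## undirected graph.

# Arithmetic-mean symmetrization with self-loops removed.
sym_weights <- function(W) {
  W <- weight_matrix(W)
  Wp <- (W + t(W)) / 2
  diag(Wp) <- 0
  Wp
}

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering for directed graphs:
#' \deqn{CC_i = \frac{1}{s_i (d_i - 1)} \sum_{j,d}
#'   \frac{w_{ij} + w_{id}}{2} a_{ij} a_{jd} a_{id}}
#' where \eqn{a_{ij} = 1} iff \eqn{w_{ij} > 0}, \eqn{d_i} is the number of
#' distinct neighbors over the union of in- and out-arcs, and \eqn{s_i} is
#' the out-strength.  Self-loops are excluded.  Nodes with \eqn{d_i \le 1}
#' or \eqn{s_i = 0} contribute 0.  Returns the average over all nodes.
#'
#' @param W A `qg_markov`, `qg_graph` or weight matrix.
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(W) {
  W <- weight_matrix(W)
  Q <- nrow(W)
  if (Q < 2L) stop("need at least 2 nodes")
  diag(W) <- 0
  A <- (W > 0) * 1
  und <- pmax(A, t(A))
  d <- rowSums(und)           # distinct neighbors, in/out union
  s <- rowSums(W)             # out-strength, self-loops excluded
  cc <- numeric(Q)
  for (i in seq_len(Q)) {
    if (d[i] <= 1 || s[i] == 0) next
    ai <- A[i, ]
    wa <- W[i, ] * ai
    cc[i] <- 0.5 * (sum(wa * (A %*% ai)) + sum(ai * (A %*% wa))) /
      (s[i] * (d[i] - 1))
  }
  mean(cc)
}

#' Mean jump length (trace formula)
#'
#' \eqn{\Delta = \frac{1}{Q} \mathrm{tr}(P W^T)} with
#' \eqn{p_{ij} = |i - j|}; equivalently
#' \eqn{\frac{1}{Q} \sum_{ij} |i-j| w_{ij}}.  Small for persistent
#' (strongly autocorrelated) signals; approaches \eqn{(Q^2-1)/(3Q)} for
#' independent noise.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in \[0, Q-1\].
#' @export
mean_jump_length <- function(W) {
  W <- weight_matrix(W)
  Q <- nrow(W)
  P <- abs(outer(seq_len(Q), seq_len(Q), "-"))
  sum(P * W) / Q
}

#' Mean jump length by explicit random walk
#'
#' Monte-Carlo evaluation of the mean jump length: an S-step random walk
#' follows the transition weights, and \eqn{|i - j|} is averaged over the
#' jumps.  The start node, and any restart after reaching a node with no
#' outgoing transitions, are drawn uniformly over supported rows; restart
#' jumps are not counted.  For doubly-stochastic matrices (uniform
#' stationary distribution) this converges to [mean_jump_length()].
#'
#' @inheritParams clustering_coefficient
#' @param S Number of jumps (default 10000).
#' @param seed Optional integer seed; when given the walk is reproducible
#'   and the caller's RNG state is untouched.
#' @return List with `delta` (the estimate) and `se` (standard error of the
#'   jump lengths).
#' @export
mean_jump_length_walk <- function(W, S = 10000, seed = NULL) {
  W <- weight_matrix(W)
  Q <- nrow(W)
  rs <- rowSums(W)
  sup <- which(rs > 0)
  if (length(sup) == 0L) stop("all rows unsupported: no walk is possible")
  if (S < 1) stop("S must be at least 1")
  run <- function() {
    cum <- t(apply(W / ifelse(rs > 0, rs, 1), 1, cumsum))
    state <- if (length(sup) == 1L) sup else sample(sup, 1L)
    jumps <- numeric(S)
    u <- runif(S)
    restarts <- runif(S) # pre-drawn uniforms for dead-end restarts
    for (s in seq_len(S)) {
      if (rs[state] == 0) {
        state <- sup[1L + floor(restarts[s] * length(sup))]
      }
      j <- findInterval(u[s], cum[state, ]) + 1L
      if (j > Q) j <- Q
      jumps[s] <- abs(state - j)
      state <- j
    }
    jumps
  }
  jumps <- if (is.null(seed)) run() else with_seed(seed, run())
  list(delta = mean(jumps), se = sd(jumps) / sqrt(S))
}

#' Average betweenness centrality
#'
#' Betweenness of node u is the sum over ordered pairs (i, j) of distinct
#' other nodes of the fraction of shortest i-to-j paths passing through u.
#' Paths are counted on the directed graph of arcs with positive weight,
#' unweighted (hop count), self-loops ignored.  Each node's value is
#' normalized by (Q-1)(Q-2) and the node average is returned.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in \[0, 1\].
#' @export
betweenness_centrality <- function(W) {
  W <- weight_matrix(W)
  Q <- nrow(W)
  if (Q < 3L) stop("betweenness needs at least 3 nodes")
  A <- (W > 0) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  b <- igraph::betweenness(g, directed = TRUE, weights = NA)
  mean(b / ((Q - 1) * (Q - 2)))
}

#' Modularity of a node partition
#'
#' \deqn{M(P) = \sum_{i=1}^{m} \left[ \frac{e_i}{E} -
#'   \left(\frac{d_i}{2E}\right)^2 \right]}
#' evaluated on the symmetrized weighted graph (self-loops dropped):
#' \eqn{e_i} is the total intra-module weight, \eqn{d_i} the sum of module
#' node strengths, \eqn{E} the total weight.
#'
#' @inheritParams clustering_coefficient
#' @param membership Integer vector assigning each node to a module.
#' @return Scalar in \[-0.5, 1\].
#' @export
modularity_score <- function(W, membership) {
  Wp <- sym_weights(W)
  Q <- nrow(Wp)
  if (length(membership) != Q) stop("membership must cover all nodes")
  E <- sum(Wp) / 2
  if (E == 0) stop("undefined metric: the graph has no edges (E = 0)")
  M <- 0
  for (mod in unique(membership)) {
    v <- membership == mod
    e_i <- sum(Wp[v, v, drop = FALSE]) / 2
    d_i <- sum(Wp[v, , drop = FALSE])
    M <- M + e_i / E - (d_i / (2 * E))^2
  }
  M
}

#' Detect modules by greedy modularity maximization
#'
#' Deterministic greedy agglomeration on the symmetrized weighted graph.
#' Returns the partition together with its modularity score recomputed with
#' [modularity_score()].  A graph with no arcs yields the single-module
#' partition with modularity 0 by convention.
#'
#' @inheritParams clustering_coefficient
#' @return List with `membership` (integer per node) and `modularity`.
#' @export
detect_modules <- function(W) {
  Wp <- sym_weights(W)
  Q <- nrow(Wp)
  if (sum(Wp) == 0)
    return(list(membership = rep(1L, Q), modularity = 0))
  g <- igraph::graph_from_adjacency_matrix(Wp, mode = "undirected",
                                           weighted = TRUE)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- as.integer(igraph::membership(cl))
  list(membership = memb, modularity = modularity_score(Wp, memb))
}

#' Laplacian Estrada index
#'
#' The weights are symmetrized and self-loops dropped, giving a simple
#' weighted undirected graph; with D the diagonal matrix of strengths and A
#' the weight matrix, the Laplacian is L = D - A and
#' \deqn{LEE = \sum_i e^{\mu_i}} over the (real) eigenvalues of L.  An
#' edgeless graph on n nodes gives LEE = n.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar, at least the number of nodes with zero strength.
#' @export
laplacian_estrada_index <- function(W) {
  Wp <- sym_weights(W)
  L <- diag(rowSums(Wp), nrow(Wp)) - Wp
  mu <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (!all(is.finite(mu))) stop("non-finite Laplacian eigenvalue")
  sum(exp(mu))
}

#' Evaluate one of the five metrics by name
#'
#' @inheritParams clustering_coefficient
#' @param metric One of `"CC"`, `"MJL"`, `"BC"`, `"MO"`, `"LEE"`.
#' @return Scalar metric value.
#' @export
qg_metric <- function(W, metric = c("CC", "MJL", "BC", "MO", "LEE")) {
  metric <- match.arg(metric)
  switch(metric,
         CC  = clustering_coefficient(W),
         MJL = mean_jump_length(W),
         BC  = betweenness_centrality(W),
         MO  = detect_modules(W)$modularity,
         LEE = laplacian_estrada_index(W))
}

#' Names of the five quantile-graph metrics
#' @return Character vector `c("CC", "MJL", "BC", "MO", "LEE")`.
#' @export
qg_metrics <- function() c("CC", "MJL", "BC", "MO", "LEE")
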