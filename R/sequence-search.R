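#' Worked-example arc lists (T = 20, Q = 5, lags 1, 2 and 5)
#'
#' Published worked illustration of the quantile-graph construction: the
#' weighted arc lists obtained from one 20-sample series partitioned into 5
#' quantiles, at lags 1, 2 and 5.  Each element is a data frame with
#' columns `src`, `dst`, `weight` (1-based node ids).  The weights sum to
#' 19, 18 and 15 respectively, i.e. T - k for T = 20.  The raw series was
#' not published; [find_generating_sequence()] recovers a quantile-index
#' sequence consistent with all three lists.
#'
#' @format Named list of three data frames (`k1`, `k2`, `k5`).
#' @export
qg_demo_arcs <- local({
  arcs <- function(m) {
    m <- matrix(m, ncol = 3, byrow = TRUE)
    data.frame(src = m[, 1], dst = m[, 2], weight = m[, 3])
  }
  list(
    k1 = arcs(c(1,1,1, 1,3,1, 1,5,2, 2,1,1, 2,2,1, 2,4,2, 3,3,2, 3,4,1,
                4,1,1, 4,2,1, 4,3,1, 4,4,1, 5,1,1, 5,2,1, 5,5,2)),
    k2 = arcs(c(1,3,1, 1,5,2, 2,1,1, 2,4,2, 2,5,1, 3,2,1, 3,3,1, 3,4,1,
                4,1,1, 4,3,2, 4,4,1, 5,1,1, 5,2,2, 5,5,1)),
    k5 = arcs(c(1,4,1, 1,5,1, 2,3,2, 2,5,1, 3,1,2, 3,4,1, 4,2,1, 4,3,1,
                4,4,1, 5,2,2, 5,3,1, 5,4,1))
  )
})

#' Count matrix from an arc list
#'
#' @param arcs Data frame with columns `src`, `dst`, `weight`.
#' @param Q Number of nodes (default: largest node id seen).
#' @return Q x Q numeric count matrix.
#' @export
arcs_to_counts <- function(arcs, Q = max(arcs$src, arcs$dst)) {
  m <- matrix(0, Q, Q)
  m[cbind(arcs$src, arcs$dst)] <- arcs$weight
  m
}

#' Search for an index sequence generating given lag-k arc lists
#'
#' Depth-first search over Eulerian paths of the lag-1 transition multigraph,
#' pruned so that the partial sequence never exceeds the transition counts
#' required at the other lags.  Returns a quantile-index sequence whose
#' lag-k graphs (built with [build_quantile_graph()]) reproduce every
#' supplied arc list exactly, or `NULL` if no such sequence exists.
#'
#' The lag-1 list must be present: it fixes the sequence length at
#' (total weight) + 1 and drives the Eulerian walk.
#'
#' @param arc_lists Named list of arc data frames; names are the lags as
#'   strings prefixed with "k" (e.g. `list(k1 = ..., k2 = ..., k5 = ...)`),
#'   or bare integers as names.
#' @param Q Number of nodes (default deduced from the lists).
#' @return Integer vector (a valid quantile-index sequence) or `NULL`.
#' @examples
#' s <- find_generating_sequence(qg_demo_arcs)
#' length(s) # 20
#' @export
find_generating_sequence <- function(arc_lists, Q = NULL) {
  lags <- as.integer(sub("^k", "", names(arc_lists)))
  if (any(is.na(lags))) stop("arc list names must encode lags, e.g. 'k1'")
  if (!1L %in% lags) stop("a lag-1 arc list is required")
  if (is.null(Q))
    Q <- max(vapply(arc_lists, function(a) max(a$src, a$dst), numeric(1)))
  counts <- lapply(arc_lists, arcs_to_counts, Q = Q)
  names(counts) <- as.character(lags)
  c1 <- counts[["1"]]
  T <- sum(c1) + 1L
  for (l in lags)
    if (sum(counts[[as.character(l)]]) != T - l)
      return(NULL) # inconsistent totals: no sequence can exist
  other <- lags[lags != 1L]

  # Eulerian path start: node with out-degree exceeding in-degree, if any.
  surplus <- rowSums(c1) - colSums(c1)
  if (any(abs(surplus) > 1) || sum(surplus[surplus > 0]) > 1) return(NULL)
  starts <- if (any(surplus == 1)) which(surplus == 1) else which(rowSums(c1) > 0)

  rem1 <- c1
  used <- lapply(other, function(l) matrix(0L, Q, Q))
  names(used) <- as.character(other)
  path <- integer(T)

  dfs <- function(pos) {
    if (pos == T) return(TRUE)
    cur <- path[pos]
    for (nxt in which(rem1[cur, ] > 0)) {
      ok <- TRUE
      touched <- integer(0)
      for (l in other) {
        if (pos + 1L > l) {
          a <- path[pos + 1L - l]
          lk <- as.character(l)
          if (used[[lk]][a, nxt] + 1L > counts[[lk]][a, nxt]) { ok <- FALSE; break }
          used[[lk]][a, nxt] <<- used[[lk]][a, nxt] + 1L
          touched <- c(touched, l)
        }
      }
      if (ok) {
        rem1[cur, nxt] <<- rem1[cur, nxt] - 1L
        path[pos + 1L] <<- nxt
        if (dfs(pos + 1L)) return(TRUE)
        rem1[cur, nxt] <<- rem1[cur, nxt] + 1L
      }
      for (l in touched) {
        lk <- as.character(l)
        used[[lk]][path[pos + 1L - l], nxt] <<- used[[lk]][path[pos + 1L - l], nxt] - 1L
      }
    }
    FALSE
  }

  for (s in starts) {
    path[1] <- s
    if (dfs(1L)) return(path)
  }
  NULL
}
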