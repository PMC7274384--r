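#' Time-series segment
#'
#' Light container for one channel's samples from one subject.  Most
#' functions in the package also accept a bare numeric vector; the container
#' exists to carry the sampling rate and the group / channel / subject
#' labels through the pipeline.
#'
#' @param values Numeric vector of samples (signal units, e.g. microvolts).
#' @param sampling_rate Sampling frequency in Hz (default 128).
#' @param channel Channel label, e.g. `"F7"` (10-20 system).
#' @param group Group label, e.g. one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param subject Subject identifier.
#' @return An object of class `qg_segment`.
#' @export
qg_segment <- function(values, sampling_rate = 128, channel = NA_character_,
                       group = NA_character_, subject = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a segment needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("segment values must all be finite")
  structure(list(values = values, sampling_rate = sampling_rate,
                 channel = channel, group = group, subject = subject),
            class = "qg_segment")
}

#' @export
print.qg_segment <- function(x, ...) {
  cat(sprintf("<qg_segment> T=%d, fs=%g Hz, channel=%s, group=%s, subject=%s\n",
              length(x$values), x$sampling_rate, x$channel, x$group, x$subject))
  invisible(x)
}

seg_values <- function(x) {
  if (inherits(x, "qg_segment")) x$values else as.numeric(x)
}

#' Default number of quantiles for a series of length T
#'
#' The number of quantile nodes follows the cube-root rule
#' \eqn{Q \approx 2 T^{1/3}}, rounded half-up to the nearest integer, with a
#' floor of 2.  For the 1024-sample segments of the reference study design
#' this gives Q = 20.
#'
#' @param T Series length (integer, at least 2).
#' @return Integer number of quantiles.
#' @examples
#' default_num_quantiles(1024) # 20
#' @export
default_num_quantiles <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 2)
    stop("T must be a single integer >= 2")
  max(2L, as.integer(floor(2 * T^(1 / 3) + 0.5)))
}

#' Fit a quantile partition to a series
#'
#' Boundaries are the empirical quantiles of the sample at probabilities
#' i/Q, i = 0..Q, computed with linear interpolation between order
#' statistics (R's type-7 convention), so that with distinct values each
#' interval holds between floor(T/Q) and ceiling(T/Q) samples.  The outer
#' boundaries are the sample minimum and maximum.  Intervals are half-open
#' on the right, with the last interval closed.
#'
#' @param x Numeric vector or [qg_segment()].
#' @param Q Number of quantiles; defaults to [default_num_quantiles()] of
#'   the series length.
#' @return An object of class `qg_partition` with fields `Q` and
#'   `boundaries` (Q+1 nondecreasing reals).
#' @export
fit_partition <- function(x, Q = NULL) {
  v <- seg_values(x)
  T <- length(v)
  if (is.null(Q)) Q <- default_num_quantiles(T)
  Q <- as.integer(Q)
  if (Q < 2L) stop("Q must be at least 2")
  if (Q > T) stop(sprintf("Q (%d) may not exceed the series length (%d)", Q, T))
  if (!all(is.finite(v))) stop("series values must all be finite")
  b <- quantile(v, probs = (0:Q) / Q, type = 7, names = FALSE)
  if (b[1] == b[Q + 1L])
    stop("degenerate partition: the series is constant (min equals max), ",
         "no quantile intervals can be formed")
  structure(list(Q = Q, boundaries = b), class = "qg_partition")
}

#' @export
print.qg_partition <- function(x, ...) {
  cat(sprintf("<qg_partition> Q=%d\nboundaries: %s\n", x$Q,
              paste(signif(x$boundaries, 5), collapse = ", ")))
  invisible(x)
}

#' Map samples to quantile indices
#'
#' Each sample is assigned the index i of the interval
#' \eqn{[b_{i-1}, b_i)} containing it (last interval closed).  When a
#' reference partition fitted on another segment is reused, values outside
#' its range are clamped to the end bins with a warning.
#'
#' @param x Numeric vector or [qg_segment()].
#' @param partition A `qg_partition`.
#' @return Integer vector of indices in 1..Q, same length as the series.
#' @export
quantile_indices <- function(x, partition) {
  stopifnot(inherits(partition, "qg_partition"))
  v <- seg_values(x)
  b <- partition$boundaries
  Q <- partition$Q
  idx <- findInterval(v, b, rightmost.closed = TRUE)
  out <- idx < 1L | idx > Q
  if (any(out)) {
    warning(sprintf(
      "%d value(s) outside the partition range [%g, %g]; clamped to end bins",
      sum(out), b[1], b[Q + 1L]))
    idx[idx < 1L] <- 1L
    idx[idx > Q] <- Q
  }
  as.integer(idx)
}

#' Build a lag-k quantile graph
#'
#' Counts transitions between quantile indices k steps apart: entry (i, j)
#' of the count matrix is the number of times index i at time t is followed
#' by index j at time t + k.  The total count is exactly T - k.
#'
#' @param indices Integer vector of quantile indices (from
#'   [quantile_indices()]).
#' @param k Lag, a positive integer strictly smaller than the series length.
#' @param Q Number of nodes; defaults to `max(indices)`.
#' @return An object of class `qg_graph` with fields `counts` (Q x Q integer
#'   matrix, rows = source quantile at time t, columns = destination at
#'   t + k), `Q`, `k` and `T`.
#' @export
build_quantile_graph <- function(indices, k, Q = max(indices)) {
  indices <- as.integer(indices)
  T <- length(indices)
  k <- as.integer(k)
  if (k < 1L || k >= T)
    stop(sprintf("lag k must satisfy 1 <= k < T (got k=%d, T=%d)", k, T))
  Q <- as.integer(Q)
  if (any(indices < 1L | indices > Q))
    stop("indices must lie in 1..Q")
  src <- indices[seq_len(T - k)]
  dst <- indices[seq.int(k + 1L, T)]
  counts <- matrix(tabulate((dst - 1L) * Q + src, nbins = Q * Q), Q, Q)
  structure(list(counts = counts, Q = Q, k = k, T = T), class = "qg_graph")
}

#' @export
print.qg_graph <- function(x, ...) {
  cat(sprintf("<qg_graph> Q=%d nodes, lag k=%d, total weight %d (T=%d)\n",
              x$Q, x$k, sum(x$counts), x$T))
  invisible(x)
}

#' Quantile graph straight from a segment
#'
#' Convenience wrapper: fits the partition, maps indices and builds the
#' lag-k graph in one call.
#'
#' @inheritParams build_quantile_graph
#' @inheritParams fit_partition
#' @export
quantile_graph <- function(x, k, Q = NULL) {
  p <- fit_partition(x, Q)
  build_quantile_graph(quantile_indices(x, p), k, Q = p$Q)
}

count_matrix <- function(g) {
  if (inherits(g, "qg_graph")) g$counts
  else if (is.matrix(g)) g
  else stop("expected a qg_graph or a count matrix")
}

#' Row-normalize a quantile graph into a Markov transition matrix
#'
#' Each row with a positive sum is divided by that sum; all-zero rows are
#' preserved as zero and flagged as unsupported (no transitions were ever
#' observed leaving that quantile).  No mass is fabricated for unsupported
#' rows; downstream metrics tolerate them.
#'
#' @param g A `qg_graph` or a nonnegative count matrix.
#' @return An object of class `qg_markov`: fields `W` (row-stochastic on
#'   supported rows), `Q`, `k`, `row_support` (logical per row).
#' @export
to_markov <- function(g) {
  counts <- count_matrix(g)
  k <- if (inherits(g, "qg_graph")) g$k else NA_integer_
  rs <- rowSums(counts)
  support <- rs > 0
  W <- counts / ifelse(support, rs, 1)
  structure(list(W = W, Q = nrow(counts), k = k, row_support = support),
            class = "qg_markov")
}

#' @export
print.qg_markov <- function(x, ...) {
  cat(sprintf("<qg_markov> Q=%d, k=%s, %d/%d supported rows\n", x$Q,
              ifelse(is.na(x$k), "?", x$k), sum(x$row_support), x$Q))
  invisible(x)
}

#' Median-aggregated transition matrix over a group of graphs
#'
#' The element-wise median of the count matrices is taken first, and the
#' median matrix is then row-normalized as in [to_markov()].  All graphs
#' must share the same Q and lag k.
#'
#' @param graphs List of `qg_graph` objects (at least one).
#' @return A `qg_markov`.
#' @export
median_transition_matrix <- function(graphs) {
  if (length(graphs) < 1L) stop("need at least one graph")
  Qs <- vapply(graphs, function(g) g$Q, integer(1))
  ks <- vapply(graphs, function(g) g$k, integer(1))
  if (length(unique(Qs)) != 1L || length(unique(ks)) != 1L)
    stop("all graphs must share the same Q and lag k")
  Q <- Qs[1]
  arr <- vapply(graphs, function(g) as.numeric(g$counts), numeric(Q * Q))
  med <- if (length(graphs) == 1L) arr[, 1] else apply(arr, 1, median)
  m <- to_markov(matrix(med, Q, Q))
  m$k <- ks[1]
  m
}

weight_matrix <- function(W) {
  if (inherits(W, "qg_markov")) W$W
  else if (inherits(W, "qg_graph")) to_markov(W)$W
  else if (is.matrix(W)) W
  else stop("expected a qg_markov, qg_graph or weight matrix")
}
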