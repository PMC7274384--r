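## Group-discrimination pipeline: metric-versus-lag curves on
## median-aggregated transition matrices, maximum-separation lag selection,
## per-segment features, Mann-Whitney ROC and two-level ANOVA, and the
## per-channel average-AUC sweep.

# Per-segment quantile-index sequences for one channel (partition refitted
# per segment), plus the count matrices for all lags 1..k_cap.
channel_counts <- function(cohort, channel, k_cap, Q = NULL) {
  sub <- channel_segments(cohort, channel)
  T <- length(sub$values[[1]])
  if (is.null(Q)) Q <- default_num_quantiles(T)
  if (k_cap >= T) stop("k_cap must be smaller than the segment length")
  idx <- lapply(sub$values, function(v)
    quantile_indices(v, fit_partition(v, Q)))
  graphs <- lapply(idx, function(ix)
    lapply(seq_len(k_cap), function(k) build_quantile_graph(ix, k, Q = Q)))
  list(sub = sub, graphs = graphs, Q = Q, T = T,
       n_graphs = as.integer(length(idx) * k_cap))
}

# Metric curves for several metrics at once, sharing the graph builds and
# median aggregation.  Returns long data frame (metric, group, k, value).
curves_engine <- function(cc, metrics, k_cap) {
  groups <- unique(cc$sub$meta$group)
  out <- vector("list", 0)
  for (g in groups) {
    rows <- which(cc$sub$meta$group == g)
    for (k in seq_len(k_cap)) {
      Wmed <- median_transition_matrix(lapply(cc$graphs[rows],
                                              function(gl) gl[[k]]))
      for (m in metrics)
        out[[length(out) + 1L]] <- data.frame(
          metric = m, group = g, k = k, value = qg_metric(Wmed, m),
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Metric-versus-lag curves per group
#'
#' For each group and each lag k in 1..k_cap: the element-wise median of
#' the group's count matrices is taken, row-normalized into the transition
#' matrix of medians, and the metric evaluated on it.  One curve per group.
#'
#' @param cohort A [qg_cohort()].
#' @param channel Channel to analyse.
#' @param metric One of [qg_metrics()], or a vector of them.
#' @param k_cap Largest lag (default 25).
#' @param Q Number of quantiles (default from the cube-root rule).
#' @return Data frame (metric, group, k, value) with attributes `n_graphs`
#'   (number of quantile graphs built, = segments x k_cap) and `Q`.
#' @export
metric_curves <- function(cohort, channel, metric = "MJL", k_cap = 25,
                          Q = NULL) {
  cc <- channel_counts(cohort, channel, k_cap, Q)
  df <- curves_engine(cc, metric, k_cap)
  attr(df, "n_graphs") <- cc$n_graphs
  attr(df, "Q") <- cc$Q
  df
}

curves_matrix <- function(df, groups) {
  ks <- sort(unique(df$k))
  m <- t(vapply(groups, function(g)
    df$value[df$group == g][order(df$k[df$group == g])],
    numeric(length(ks))))
  rownames(m) <- groups
  m
}

#' Select the lag of maximum curve separation
#'
#' Separation at lag k is the worst-case gap between the two clusters:
#' the minimum over all (healthy, patient) curve pairs of the absolute
#' difference at k.  k_max is the smallest lag attaining the maximum.
#'
#' @param healthy,patient Numeric matrix (curves in rows) or vector (one
#'   curve) per side, on a common lag grid.
#' @return List with `k_max`, `separation` (vector over k) and `value`
#'   (the maximal separation).
#' @export
select_kmax <- function(healthy, patient) {
  H <- if (is.matrix(healthy)) healthy else matrix(healthy, nrow = 1)
  U <- if (is.matrix(patient)) patient else matrix(patient, nrow = 1)
  if (ncol(H) != ncol(U)) stop("curves must share the lag grid")
  if (anyNA(H) || anyNA(U)) stop("curves contain NA/NaN")
  sep <- vapply(seq_len(ncol(H)), function(k)
    min(abs(outer(H[, k], U[, k], "-"))), numeric(1))
  list(k_max = which.max(sep), separation = sep, value = max(sep))
}

#' Per-segment metric values at one lag
#'
#' The metric evaluated on each segment's own transition matrix at lag k
#' (no median aggregation): one value per subject, for box plots, ANOVA,
#' ROC and classification.
#'
#' @inheritParams metric_curves
#' @param k Lag at which to evaluate.
#' @return Data frame (group, subject, value).
#' @export
per_segment_metrics <- function(cohort, channel, metric = "MJL", k,
                                Q = NULL) {
  sub <- channel_segments(cohort, channel)
  T <- length(sub$values[[1]])
  if (is.null(Q)) Q <- default_num_quantiles(T)
  vals <- vapply(sub$values, function(v) {
    W <- to_markov(quantile_graph(v, k, Q = Q))
    qg_metric(W, metric)
  }, numeric(1))
  data.frame(group = sub$meta$group, subject = sub$meta$subject,
             value = vals, stringsAsFactors = FALSE)
}

#' Mann-Whitney area under the ROC curve
#'
#' Rank-based (Mann-Whitney U) AUC between two samples, oriented as
#' max(AUC, 1 - AUC) so the value is direction-free: it measures how
#' separable the two groups are regardless of which one has the larger
#' metric.
#'
#' @param x,y Numeric vectors, one per group (at least 2 values each).
#' @return Scalar in \[0.5, 1\].
#' @export
roc_auc <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 values per group")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  max(auc, 1 - auc)
}

#' Two-level ANOVA comparing healthy and patient samples
#'
#' One-way ANOVA with two levels, equivalent to the pooled-variance t test:
#' returns the F statistic, the p value and the 95% confidence interval of
#' mean(healthy) - mean(patient).
#'
#' @param healthy,patient Numeric vectors (at least 2 values each).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `F`, `p` and `ci` (length-2 vector).
#' @export
group_anova <- function(healthy, patient, conf_level = 0.95) {
  if (length(healthy) < 2L || length(patient) < 2L)
    stop("need at least 2 values per group")
  if (sd(healthy) == 0 && sd(patient) == 0) {
    d <- mean(healthy) - mean(patient)
    if (d == 0) return(list(F = 0, p = 1, ci = c(0, 0)))
    return(list(F = Inf, p = 0, ci = c(d, d)))
  }
  tt <- t.test(healthy, patient, var.equal = TRUE, conf.level = conf_level)
  list(F = unname(tt$statistic)^2, p = tt$p.value,
       ci = unname(tt$conf.int))
}

#' Per-channel average ROC area
#'
#' For every channel: build the metric curves, choose k_max from the
#' healthy-versus-patient cluster separation, evaluate the metric per
#' segment at k_max, compute the ROC area for each healthy/patient group
#' pair, and average them.  The default pairs are (A,C), (B,D), (A,D),
#' (B,C) -- every healthy-versus-AD combination; within-condition pairs are
#' excluded.
#'
#' @inheritParams metric_curves
#' @param metric A single metric name.
#' @param healthy,patient Group labels forming the two clusters.
#' @param pairs List of length-2 character vectors (healthy, patient).
#' @return Data frame with one row per channel: `channel`, `k_max`, one
#'   `auc_<pair>` column per pair, and `auc_mean` (the average ROC area
#'   over available pairs).  Attribute `n_graphs` counts every quantile
#'   graph built across channels.
#' @export
channel_auc_map <- function(cohort, metric = "MJL", k_cap = 25,
                            healthy = c("A", "B"), patient = c("C", "D"),
                            pairs = list(c("A", "C"), c("B", "D"),
                                         c("A", "D"), c("B", "C")),
                            Q = NULL) {
  channels <- unique(cohort$meta$channel)
  if (length(channels) < 2L) stop("cohort must have at least 2 channels")
  total_graphs <- 0L
  rows <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    cc <- channel_counts(cohort, ch, k_cap, Q)
    total_graphs <- total_graphs + cc$n_graphs
    df <- curves_engine(cc, metric, k_cap)
    present <- unique(df$group)
    H <- curves_matrix(df, intersect(healthy, present))
    U <- curves_matrix(df, intersect(patient, present))
    if (nrow(H) == 0L || nrow(U) == 0L)
      stop("need at least one healthy and one patient group")
    km <- select_kmax(H, U)$k_max
    seg <- per_segment_metrics(cohort, ch, metric, km, Q = cc$Q)
    aucs <- stats::setNames(rep(NA_real_, length(pairs)),
                            paste0("auc_", vapply(pairs, paste, "",
                                                  collapse = "")))
    for (pi in seq_along(pairs)) {
      pr <- pairs[[pi]]
      if (all(pr %in% present)) {
        aucs[pi] <- roc_auc(seg$value[seg$group == pr[1]],
                            seg$value[seg$group == pr[2]])
      } else {
        warning(sprintf("channel %s: pair (%s) skipped, group missing",
                        ch, paste(pr, collapse = ",")))
      }
    }
    rows[[ci]] <- data.frame(channel = ch, k_max = km, t(aucs),
                             auc_mean = mean(aucs, na.rm = TRUE),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_graphs") <- total_graphs
  out
}
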