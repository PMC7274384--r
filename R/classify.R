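#' Assemble the per-subject feature table
#'
#' One row per subject on the given channel; one column per metric,
#' evaluated on the subject's own transition matrix at that metric's
#' selected lag.  The label is `"healthy"` for subjects in the healthy
#' groups and `"AD"` otherwise.
#'
#' @param cohort A [qg_cohort()].
#' @param channel Channel to use.
#' @param k_max Named numeric vector giving the lag per metric, e.g.
#'   `c(CC = 9, MJL = 10, BC = 6, MO = 6, LEE = 8)`.
#' @param healthy Group labels considered healthy (default A and B).
#' @param Q Number of quantiles (default from the cube-root rule).
#' @return Data frame with columns `subject`, `group`, `label` and one
#'   column per metric.
#' @export
build_feature_table <- function(cohort, channel,
                                k_max = c(CC = 9, MJL = 10, BC = 6,
                                          MO = 6, LEE = 8),
                                healthy = c("A", "B"), Q = NULL) {
  if (is.null(names(k_max)) || !all(names(k_max) %in% qg_metrics()))
    stop("k_max must be named by metric (CC, MJL, BC, MO, LEE)")
  base <- NULL
  for (m in names(k_max)) {
    seg <- per_segment_metrics(cohort, channel, m, k_max[[m]], Q = Q)
    if (is.null(base)) {
      base <- seg[, c("group", "subject")]
    }
    base[[m]] <- seg$value
  }
  base$label <- factor(ifelse(base$group %in% healthy, "healthy", "AD"),
                       levels = c("healthy", "AD"))
  base[, c("subject", "group", "label", names(k_max))]
}

# Stratified fold assignment: class proportions per fold differ by at most
# one subject.
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Cross-validated two-class classification
#'
#' Stratified k-fold cross-validation of a max-margin linear classifier
#' (support vector machine, linear kernel by default) on the metric
#' features.  Features are z-scored with means and scales fitted on each
#' training fold only.  Accuracy, sensitivity and specificity are computed
#' from the confusion matrix pooled over held-out folds; AUC from the
#' pooled decision values.  The positive class is `"AD"` (the second
#' factor level).
#'
#' @param features Feature table from [build_feature_table()], or any data
#'   frame with a two-level factor column `label` and numeric feature
#'   columns.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost SVM cost parameter (default 1).
#' @return List with `ACC`, `SEN`, `SPE`, `AUC`, the pooled `confusion`
#'   matrix and a per-fold data frame `fold_results`.
#' @export
crossval_classify <- function(features, folds = 10, seed = 1,
                              kernel = "linear", cost = 1) {
  y <- features$label
  if (is.null(y)) stop("features must contain a 'label' column")
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L)
    stop("classification needs exactly 2 classes in 'label'")
  if (any(table(y) < 2L)) stop("need at least 2 subjects per class")
  pos <- if ("AD" %in% levels(y)) "AD" else levels(y)[2]
  neg <- setdiff(levels(y), pos)
  num <- vapply(features, is.numeric, logical(1))
  X <- as.matrix(features[, num, drop = FALSE])
  if (ncol(X) == 0L) stop("no numeric feature columns")
  if (anyNA(X)) stop("feature table has missing cells")

  fold_id <- with_seed(seed, stratified_folds(y, folds))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  dec <- numeric(length(y))
  fold_rows <- list()
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    ctr <- colMeans(X[!te, , drop = FALSE])
    scl <- apply(X[!te, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    Ztr <- scale(X[!te, , drop = FALSE], center = ctr, scale = scl)
    Zte <- scale(X[te, , drop = FALSE], center = ctr, scale = scl)
    fit <- e1071::svm(x = Ztr, y = y[!te], kernel = kernel, cost = cost,
                      scale = FALSE)
    p <- stats::predict(fit, Zte, decision.values = TRUE)
    pred[te] <- p
    d <- drop(attr(p, "decision.values"))
    # orient decision values so larger means more AD-like
    if (!startsWith(colnames(attr(p, "decision.values"))[1], pos)) d <- -d
    dec[te] <- d
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      fold = f, n_test = sum(te), acc = mean(p == y[te]))
  }
  confusion <- table(truth = y, predicted = pred)
  TP <- confusion[pos, pos]; TN <- confusion[neg, neg]
  FP <- confusion[neg, pos]; FN <- confusion[pos, neg]
  list(ACC = (TP + TN) / length(y),
       SEN = TP / (TP + FN),
       SPE = TN / (TN + FP),
       AUC = roc_auc(dec[y == pos], dec[y == neg]),
       confusion = confusion,
       fold_results = do.call(rbind, fold_rows))
}
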