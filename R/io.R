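#' Write a cohort to a long-format TSV
#'
#' Canonical interchange layout: columns `subject`, `group`, `channel`,
#' `t` (1-based sample index) and `value`, tab-separated with a header.
#'
#' @param cohort A [qg_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  n <- lengths(cohort$values)
  df <- data.frame(
    subject = rep(cohort$meta$subject, n),
    group = rep(cohort$meta$group, n),
    channel = rep(cohort$meta$channel, n),
    t = unlist(lapply(n, seq_len), use.names = FALSE),
    value = unlist(cohort$values, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_long_tsv <- function(path, sampling_rate) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
  need <- c("subject", "group", "channel", "t", "value")
  if (!all(need %in% names(raw)))
    stop(sprintf("'%s': expected columns %s", path,
                 paste(need, collapse = ", ")))
  tn <- suppressWarnings(as.numeric(raw$t))
  vn <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.finite(tn) | !is.finite(vn))
  if (length(bad) > 0L)
    stop(sprintf("'%s': malformed numeric fields at line(s) %s", path,
                 paste(utils::head(bad + 1L, 10), collapse = ", ")))
  key <- paste(raw$group, raw$subject, raw$channel, sep = "\r")
  ord <- order(match(key, unique(key)), tn)
  raw <- raw[ord, ]; vn <- vn[ord]; key <- key[ord]
  idx <- split(seq_along(key), factor(key, levels = unique(key)))
  values <- lapply(idx, function(i) vn[i])
  first <- vapply(idx, `[`, integer(1), 1L)
  meta <- data.frame(group = raw$group[first], subject = raw$subject[first],
                     channel = raw$channel[first], stringsAsFactors = FALSE)
  qg_cohort(unname(values), meta, sampling_rate)
}

#' Read a cohort from disk
#'
#' Accepts either a long-format TSV (columns `subject`, `group`, `channel`,
#' `t`, `value`, as written by [write_cohort()]) or a directory of
#' one-column plain-text files, one segment per file, named
#' `<group>_<subject>_<channel>.<ext>`.
#'
#' @param path File or directory.
#' @param sampling_rate Sampling rate to record (Hz, default 128).
#' @return A [qg_cohort()].
#' @export
read_cohort <- function(path, sampling_rate = 128) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(txt|csv|tsv)$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop(sprintf("empty cohort: no segment files found in '%s'", path))
    values <- list(); meta <- list()
    for (f in files) {
      v <- suppressWarnings(as.numeric(readLines(f)))
      bad <- which(!is.finite(v))
      if (length(bad) > 0L)
        stop(sprintf("'%s': malformed numeric value at line(s) %s", f,
                     paste(utils::head(bad, 10), collapse = ", ")))
      parts <- strsplit(sub("\\.[^.]+$", "", basename(f)), "_")[[1]]
      if (length(parts) != 3L)
        stop(sprintf(
          "'%s': file name must follow <group>_<subject>_<channel>.<ext>",
          basename(f)))
      values[[length(values) + 1L]] <- v
      meta[[length(meta) + 1L]] <- data.frame(
        group = parts[1], subject = parts[2], channel = parts[3],
        stringsAsFactors = FALSE)
    }
    return(qg_cohort(values, do.call(rbind, meta), sampling_rate))
  }
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  parse_long_tsv(path, sampling_rate)
}

#' Export a quantile graph as a weighted edge list
#'
#' Tab-separated columns `src`, `dst`, `weight` with 1-based node ids;
#' only arcs with positive weight are written.
#'
#' @param g A `qg_graph` or count/weight matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(g, path) {
  m <- if (inherits(g, "qg_markov")) g$W else count_matrix(g)
  nz <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(src = nz[, 1], dst = nz[, 2], weight = m[nz])
  df <- df[order(df$src, df$dst), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a quantile graph as GraphML
#'
#' @inheritParams export_edgelist
#' @export
export_graphml <- function(g, path) {
  m <- if (inherits(g, "qg_markov")) g$W else count_matrix(g)
  ig <- igraph::graph_from_adjacency_matrix(m, mode = "directed",
                                            weighted = TRUE, diag = TRUE)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Run the full quantile-graph discrimination pipeline
#'
#' Orchestrates build -> metrics -> discrimination (and optionally
#' classification and band analysis) over a cohort, returning a report and
#' optionally writing tidy CSV/JSON outputs.
#'
#' @param cohort A [qg_cohort()], or a path accepted by [read_cohort()].
#' @param channels Channels to analyse (default: all in the cohort).
#' @param metrics Metrics to compute (default all five).
#' @param k_cap Largest lag (default 25).
#' @param healthy,patient Group labels forming the two clusters.
#' @param pairs Healthy/patient group pairs for ROC (see
#'   [channel_auc_map()]).
#' @param classify Run 10-fold SVM cross-validation on the first channel's
#'   feature table (default TRUE).
#' @param bands Run the per-band analysis (default FALSE).
#' @param band_channel,band_groups Arguments for [band_qg_analysis()].
#' @param seed Seed for the cross-validation fold assignment.
#' @param outdir Optional output directory for CSV/JSON reports.
#' @return List with elements `curves`, `separation`, `anova`,
#'   `classification` (or NULL), `bands` (or NULL), `n_graphs` (total
#'   quantile graphs built), `Q` and `config_hash`.
#' @export
run_full_pipeline <- function(cohort, channels = NULL,
                              metrics = qg_metrics(), k_cap = 25,
                              healthy = c("A", "B"), patient = c("C", "D"),
                              pairs = list(c("A", "C"), c("B", "D"),
                                           c("A", "D"), c("B", "C")),
                              classify = TRUE, bands = FALSE,
                              band_channel = "P3",
                              band_groups = c("B", "D"),
                              seed = 1, outdir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.null(channels)) channels <- unique(cohort$meta$channel)
  config <- list(channels = channels, metrics = metrics, k_cap = k_cap,
                 healthy = healthy, patient = patient, pairs = pairs,
                 classify = classify, bands = bands,
                 band_channel = band_channel, band_groups = band_groups,
                 seed = seed, version = as.character(utils::packageVersion("qgnet")))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  hash <- fnv1a_hash(cfg_json)

  n_graphs <- 0L
  curve_rows <- list(); sep_rows <- list(); anova_rows <- list()
  kmax_first <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  Q_used <- NA_integer_
  for (ch in channels) {
    cc <- channel_counts(cohort, ch, k_cap)
    Q_used <- cc$Q
    n_graphs <- n_graphs + cc$n_graphs
    df <- curves_engine(cc, metrics, k_cap)
    df$channel <- ch
    curve_rows[[ch]] <- df
    present <- unique(df$group)
    for (m in metrics) {
      dm <- df[df$metric == m, ]
      H <- curves_matrix(dm, intersect(healthy, present))
      U <- curves_matrix(dm, intersect(patient, present))
      km <- select_kmax(H, U)$k_max
      if (ch == channels[1]) kmax_first[m] <- km
      seg <- per_segment_metrics(cohort, ch, m, km, Q = cc$Q)
      hv <- seg$value[seg$group %in% healthy]
      uv <- seg$value[seg$group %in% patient]
      an <- group_anova(hv, uv)
      anova_rows[[paste(ch, m)]] <- data.frame(
        channel = ch, metric = m, k_max = km, F = an$F, p = an$p,
        ci_lo = an$ci[1], ci_hi = an$ci[2], stringsAsFactors = FALSE)
      for (pr in pairs) {
        if (!all(pr %in% present)) next
        sep_rows[[paste(ch, m, paste(pr, collapse = ""))]] <- data.frame(
          channel = ch, metric = m, k_max = km,
          pair = paste(pr, collapse = ""),
          auc = roc_auc(seg$value[seg$group == pr[1]],
                        seg$value[seg$group == pr[2]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  separation <- do.call(rbind, sep_rows)
  agg <- stats::aggregate(auc ~ channel + metric, separation, mean)
  names(agg)[names(agg) == "auc"] <- "auc_mean"
  separation <- merge(separation, agg, by = c("channel", "metric"),
                      sort = FALSE)

  classification <- NULL
  if (classify) {
    ft <- build_feature_table(cohort, channels[1], k_max = kmax_first,
                              healthy = healthy)
    classification <- crossval_classify(ft, folds = 10, seed = seed)
  }
  band_res <- NULL
  if (bands) {
    band_res <- band_qg_analysis(cohort, channel = band_channel,
                                 groups = band_groups, k_cap = k_cap)
    n_graphs <- n_graphs + band_res$n_graphs
  }

  report <- list(curves = do.call(rbind, curve_rows),
                 separation = separation,
                 anova = do.call(rbind, anova_rows),
                 classification = classification,
                 bands = band_res,
                 n_graphs = n_graphs, Q = Q_used, config_hash = hash)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) { df$config_hash <- hash; df }
    write.csv(stamp(report$curves), file.path(outdir, "curves.csv"),
              row.names = FALSE)
    write.csv(stamp(report$separation), file.path(outdir, "separation.csv"),
              row.names = FALSE)
    write.csv(stamp(report$anova), file.path(outdir, "anova.csv"),
              row.names = FALSE)
    if (bands)
      write.csv(stamp(band_res$comparison),
                file.path(outdir, "bands.csv"), row.names = FALSE)
    summary <- list(config = config, config_hash = hash,
                    n_graphs = n_graphs, Q = Q_used)
    if (classify)
      summary$classification <- classification[c("ACC", "SEN", "SPE", "AUC")]
    jsonlite::write_json(summary, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
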