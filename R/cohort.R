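#' Cohort of time-series segments
#'
#' Container holding one segment per (group, subject, channel) triple.
#'
#' @param values List of numeric vectors, one per segment.
#' @param meta Data frame with one row per segment and columns `group`,
#'   `subject`, `channel`.
#' @param sampling_rate Common sampling rate in Hz.
#' @return Object of class `qg_cohort`.
#' @export
qg_cohort <- function(values, meta, sampling_rate = 128) {
  stopifnot(is.list(values), is.data.frame(meta),
            nrow(meta) == length(values),
            all(c("group", "subject", "channel") %in% names(meta)))
  meta$group <- as.character(meta$group)
  meta$subject <- as.character(meta$subject)
  meta$channel <- as.character(meta$channel)
  structure(list(values = values, meta = meta,
                 sampling_rate = sampling_rate),
            class = "qg_cohort")
}

#' @export
print.qg_cohort <- function(x, ...) {
  Ts <- unique(lengths(x$values))
  cat(sprintf(
    "<qg_cohort> %d segments | groups: %s | %d channel(s) | T: %s | fs=%g Hz\n",
    length(x$values), paste(sort(unique(x$meta$group)), collapse = ","),
    length(unique(x$meta$channel)), paste(Ts, collapse = ","),
    x$sampling_rate))
  invisible(x)
}

#' Subset a cohort by group and/or channel
#'
#' @param cohort A `qg_cohort`.
#' @param groups,channels,subjects Optional character vectors to keep.
#' @return A `qg_cohort`.
#' @export
cohort_subset <- function(cohort, groups = NULL, channels = NULL,
                          subjects = NULL) {
  keep <- rep(TRUE, nrow(cohort$meta))
  if (!is.null(groups)) keep <- keep & cohort$meta$group %in% groups
  if (!is.null(channels)) keep <- keep & cohort$meta$channel %in% channels
  if (!is.null(subjects)) keep <- keep & cohort$meta$subject %in% subjects
  qg_cohort(cohort$values[keep], cohort$meta[keep, , drop = FALSE],
            cohort$sampling_rate)
}

#' Number of segments in a cohort
#' @param cohort A `qg_cohort`.
#' @export
n_segments <- function(cohort) length(cohort$values)

# Segments for one channel, erroring if lengths differ.
channel_segments <- function(cohort, channel) {
  sub <- cohort_subset(cohort, channels = channel)
  if (n_segments(sub) == 0L)
    stop(sprintf("no segments for channel '%s'", channel))
  Ts <- lengths(sub$values)
  if (length(unique(Ts)) != 1L) {
    bad <- sub$meta[Ts != Ts[1], , drop = FALSE]
    stop(sprintf(
      "segments differ in length on channel '%s' (offenders: %s)", channel,
      paste(paste(bad$group, bad$subject, sep = "/"), collapse = ", ")))
  }
  sub
}
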