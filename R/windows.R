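#' Cohort mean trajectory of a graph metric across windows
#'
#' Mean and SD across subjects of one metric at each cumulative window,
#' ordered by window end. Windows with no data are reported with `NA`
#' rather than dropped.
#'
#' @param metrics long data.frame (subject_id, window_end_min, metric,
#'   threshold, value).
#' @param metric_name `"AD"` or `"Eglob"`.
#' @param threshold required for Eglob, ignored for AD.
#' @param windows windows to report (default: those present).
#' @return data.frame: window_end_min, mean, sd, n.
#' @export
metric_trajectory <- function(metrics, metric_name, threshold = NULL,
                              windows = NULL) {
  sub <- select_metric(metrics, metric_name, threshold)
  if (is.null(windows)) windows <- sort(unique(sub$window_end_min))
  if (length(unique(sub$subject_id)) < 2)
    stop("metric_trajectory needs at least 2 subjects")
  rows <- lapply(windows, function(w) {
    v <- sub$value[sub$window_end_min == w]
    data.frame(window_end_min = w,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

select_metric <- function(metrics, metric_name, threshold = NULL) {
  sel <- metrics$metric == metric_name
  if (metric_name == "Eglob") {
    if (is.null(threshold)) stop("threshold required for Eglob")
    sel <- sel & !is.na(metrics$threshold) &
      abs(metrics$threshold - threshold) < 1e-9
  } else {
    sel <- sel & is.na(metrics$threshold)
  }
  metrics[sel, , drop = FALSE]
}

#' Window-vs-full-window consistency of a graph metric
#'
#' For every window w, the partial correlation across subjects (controlling
#' for age and sex) between the metric at w and the metric at the full
#' (longest) window, with two-sided p-values. The full window against
#' itself is exactly 1 — a pipeline sanity invariant. Subjects missing
#' either value are dropped listwise per window and the per-window n is
#' reported.
#'
#' @param metrics long metric data.frame.
#' @param behavior data.frame with subject_id and the covariates.
#' @param metric_name,threshold which metric column to track.
#' @param full_window reference window (default: the longest present).
#' @param covariates covariate column names in `behavior`.
#' @return data.frame: window_end_min, metric, threshold, mean, sd,
#'   r_vs_full, p, n.
#' @export
window_consistency <- function(metrics, behavior, metric_name,
                               threshold = NULL, full_window = NULL,
                               covariates = c("age", "sex")) {
  sub <- select_metric(metrics, metric_name, threshold)
  wins <- sort(unique(sub$window_end_min))
  if (is.null(full_window)) full_window <- max(wins)
  ref <- sub[sub$window_end_min == full_window, c("subject_id", "value")]
  if (!nrow(ref)) stop("no data at the full window")
  rows <- lapply(wins, function(w) {
    cur <- sub[sub$window_end_min == w, c("subject_id", "value")]
    ids <- intersect(cur$subject_id, ref$subject_id)
    ids <- intersect(ids, behavior$subject_id)
    x <- cur$value[match(ids, cur$subject_id)]
    y <- ref$value[match(ids, ref$subject_id)]
    bi <- match(ids, behavior$subject_id)
    if (length(ids) <= length(covariates) + 2)
      stop(sprintf("insufficient sample at window %g (n = %d)", w, length(ids)))
    pc <- tryCatch(
      partial_correlation(x, y, behavior[bi, covariates, drop = FALSE]),
      error = function(e) {
        if (grepl("undefined correlation", conditionMessage(e)))
          return(list(r = NA_real_, p = NA_real_, n = length(ids)))
        stop(e)
      })
    # the reference window against itself is a self-correlation: exactly 1
    if (identical(x, y)) pc$r <- 1
    data.frame(window_end_min = w, metric = metric_name,
               threshold = if (is.null(threshold)) NA_real_ else threshold,
               mean = mean(x), sd = stats::sd(x),
               r_vs_full = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
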