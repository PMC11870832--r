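#' Canonical cumulative analysis windows (minutes)
#'
#' All windows are anchored at t = 0; the recording is analyzed over
#' `[0, k]` minutes for k in {1, 2, 3, 5, 8, 10, 12, 15, 20, 25, 30}.
#'
#' @return numeric vector of window end points in minutes.
#' @export
canonical_windows <- function() c(1, 2, 3, 5, 8, 10, 12, 15, 20, 25, 30)

#' Cumulative window specification
#' @param end_min window end in minutes (> 0); start is always 0.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(end_min) {
  stopifnot(is.numeric(end_min), length(end_min) == 1L, end_min > 0)
  structure(list(start = 0, end = end_min), class = "window_spec")
}

#' Windowed functional-connectivity matrix from HbO
#'
#' Pearson correlation of all channel pairs of the oxyhemoglobin series
#' over the cumulative window `[0, end)` minutes. The diagonal is 1 by
#' construction and is excluded (not treated as data) by all downstream
#' graph statistics.
#'
#' @param hb an `hb_series`.
#' @param window a [window_spec()] or a numeric window end in minutes.
#' @param subject_id carried into the result for bookkeeping.
#' @return An `fc_matrix`: list with `r` (symmetric correlation matrix),
#'   `z` (`NULL` until [fisher_z()]), `window`, `subject_id`.
#' @export
compute_fc <- function(hb, window, subject_id = "") {
  stopifnot(inherits(hb, "hb_series"))
  if (is.numeric(window)) window <- window_spec(window)
  fs <- hb$sampling_rate
  n_t <- ncol(hb$hbo)
  i2 <- floor(window$end * 60 * fs)
  if (i2 > n_t)
    stop(sprintf("window [0, %g min] exceeds scan duration (%.2f min)",
                 window$end, n_t / fs / 60))
  if (i2 < 30)
    stop("window too short: fewer than 30 samples")
  x <- t(hb$hbo[, seq_len(i2), drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance channel(s) in window: ",
         paste(which(sds == 0), collapse = ", "))
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, z = NULL, window = window, subject_id = subject_id),
            class = "fc_matrix")
}

#' Fisher r-to-z transform of an FC matrix
#'
#' Applies `atanh` to the off-diagonal correlations, clipping values with
#' |r| >= 1 to 1 - 1e-7 in magnitude (with a warning) so the transform is
#' finite. The diagonal is set to `NA`: self-connections carry no
#' information and are excluded from every downstream statistic.
#'
#' @param fc an `fc_matrix` from [compute_fc()].
#' @return The same `fc_matrix` with the `z` slot filled.
#' @export
fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  r <- fc$r
  off <- row(r) != col(r)
  clip <- off & abs(r) >= 1 - 1e-7
  if (any(clip)) {
    warning(sprintf("%d off-diagonal correlation(s) clipped to |r| = 1 - 1e-7 before atanh",
                    sum(clip)))
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  fc$z <- z
  fc
}

#' Compute FC matrices for a set of cumulative windows
#'
#' @param hb an `hb_series`.
#' @param windows numeric window ends in minutes (default: all 11 canonical
#'   windows that fit inside the scan).
#' @param subject_id bookkeeping label.
#' @return Named list of Fisher-transformed `fc_matrix` objects, one per
#'   window, names are the window ends.
#' @export
fc_by_windows <- function(hb, windows = canonical_windows(), subject_id = "") {
  out <- lapply(windows, function(w)
    fisher_z(compute_fc(hb, w, subject_id = subject_id)))
  names(out) <- as.character(windows)
  out
}
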