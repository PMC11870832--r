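#' Repair saturation dropouts by spline interpolation
#'
#' Missing (`NA`) samples in each channel-wavelength trace are filled by a
#' natural cubic spline through the surrounding valid samples; gaps touching
#' the start or end of the recording are extended with the nearest valid
#' value. Non-missing samples are left untouched. A channel-wavelength trace
#' that is entirely missing cannot be repaired and is reported via the
#' `"unrepairable"` attribute (and excluded later by [channel_quality()]).
#'
#' @param scan a [raw_scan()].
#' @return A `raw_scan` with no missing samples outside unrepairable
#'   channels; attribute `unrepairable` lists fully-missing channel indices.
#' @export
repair_nans <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  intensity <- scan$intensity
  d <- dim(intensity)
  unrepairable <- integer(0)
  for (ch in seq_len(d[1])) for (w in seq_len(d[2])) {
    x <- intensity[ch, w, ]
    nas <- is.na(x)
    if (!any(nas)) next
    if (all(nas)) {
      unrepairable <- union(unrepairable, ch)
      next
    }
    t_valid <- which(!nas)
    t_miss <- which(nas)
    interior <- t_miss[t_miss > t_valid[1] & t_miss < t_valid[length(t_valid)]]
    if (length(interior)) {
      fill <- stats::spline(t_valid, x[t_valid], xout = interior,
                            method = "natural")$y
      # spline overshoot next to steep transients must not take detected
      # light intensity to or below zero
      floor_val <- 0.5 * min(x[t_valid][x[t_valid] > 0], Inf)
      x[interior] <- pmax(fill, floor_val)
    }
    lead <- t_miss[t_miss < t_valid[1]]
    if (length(lead)) x[lead] <- x[t_valid[1]]
    trail <- t_miss[t_miss > t_valid[length(t_valid)]]
    if (length(trail)) x[trail] <- x[t_valid[length(t_valid)]]
    intensity[ch, w, ] <- x
  }
  out <- raw_scan(scan$subject_id, intensity, scan$sampling_rate, scan$probe)
  attr(out, "unrepairable") <- unrepairable
  out
}

#' Convert intensity to optical-density change
#'
#' Delta-OD(t) = -log(I(t) / mean(I)) per channel-wavelength trace, the
#' linear domain of the Beer-Lambert relation.
#'
#' @param scan a repaired [raw_scan()] with strictly positive intensity.
#' @return An `od_series`: list with `od` array
#'   `[channel x wavelength x sample]` and `sampling_rate`.
#' @export
intensity_to_od <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  d <- dim(scan$intensity)
  od <- array(0, dim = d)
  for (ch in seq_len(d[1])) for (w in seq_len(d[2])) {
    x <- scan$intensity[ch, w, ]
    bad <- which(!(x > 0))
    if (length(bad))
      stop(sprintf("non-positive intensity at channel %d wavelength %d sample %d (repair NaNs first)",
                   ch, w, bad[1]))
    od[ch, w, ] <- -log(x / mean(x))
  }
  structure(list(od = od, sampling_rate = scan$sampling_rate,
                 probe = scan$probe),
            class = "od_series")
}

#' Raw-intensity channel quality report
#'
#' Computes the coefficient of variation CV = 100 * SD/mean per
#' channel-wavelength on the raw (pre-filter) intensity, ignoring missing
#' samples. A channel is excluded when any wavelength exceeds the CV
#' threshold, has a non-positive mean, or is entirely missing — mirroring
#' cohort-level exclusion of subjects with noisy or missing channels.
#'
#' @param scan a [raw_scan()] (may contain `NA`).
#' @param cv_threshold exclusion threshold in percent (default 15).
#' @return list with `cv` matrix `[channel x wavelength]` (percent),
#'   `excluded_channels`, `exclusion_reasons`, `nan_segment_count`, and
#'   `nan_fraction`.
#' @export
channel_quality <- function(scan, cv_threshold = 15) {
  stopifnot(inherits(scan, "raw_scan"))
  d <- dim(scan$intensity)
  cv <- matrix(NA_real_, d[1], d[2],
               dimnames = list(channel_labels(scan$probe),
                               paste0("wl", scan$probe$wavelengths)))
  excluded <- integer(0)
  reasons <- character(0)
  nan_segments <- 0L
  for (ch in seq_len(d[1])) {
    reason <- NULL
    for (w in seq_len(d[2])) {
      x <- scan$intensity[ch, w, ]
      nas <- is.na(x)
      nan_segments <- nan_segments + sum(diff(c(FALSE, nas)) == 1L)
      if (all(nas)) { reason <- "all samples missing"; next }
      m <- mean(x, na.rm = TRUE)
      if (!(m > 0)) { reason <- "non-positive mean intensity"; next }
      cv[ch, w] <- 100 * stats::sd(x, na.rm = TRUE) / m
      if (cv[ch, w] > cv_threshold)
        reason <- sprintf("CV %.1f%% > %g%%", cv[ch, w], cv_threshold)
    }
    if (!is.null(reason)) {
      excluded <- c(excluded, ch)
      reasons <- c(reasons, reason)
    }
  }
  list(cv = cv,
       excluded_channels = excluded,
       exclusion_reasons = stats::setNames(reasons, as.character(excluded)),
       nan_segment_count = nan_segments,
       nan_fraction = mean(is.na(scan$intensity)))
}

# Zero-phase band-pass on one vector: cascaded Butterworth high-pass
# (order 3) and low-pass (order 5), each run forward-backward, with
# reflection padding long enough for the 0.01 Hz edge. The steeper
# low-pass section is needed to reject Mayer waves at ~0.1 Hz, just
# above the 0.08 Hz band edge.
bandpass_vector <- function(x, fs, low = 0.01, high = 0.08, order = 3L,
                            lp_order = 5L) {
  if (high >= fs / 2)
    stop(sprintf("config error: band edge %g Hz requires sampling rate > %g Hz",
                 high, 2 * high))
  if (low <= 0 || low >= high) stop("config error: need 0 < low < high")
  n <- length(x)
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(lp_order, high / (fs / 2), type = "low")
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / low)))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(lp, signal::filtfilt(hp, xp))
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter a series
#'
#' Applies the 0.01-0.08 Hz zero-phase band-pass (cascaded forward-backward
#' Butterworth, order 3 each section) that isolates slow hemodynamics from
#' drift, cardiac (~1 Hz), respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz)
#' components. Works on an `hb_series`, an `od_series`, or a plain matrix
#' `[channel x sample]` (then `sampling_rate` is required).
#'
#' @param x series to filter.
#' @param low,high band edges in Hz.
#' @param sampling_rate required for plain matrices.
#' @return Object of the same class, filtered per channel.
#' @export
bandpass <- function(x, low = 0.01, high = 0.08, sampling_rate = NULL) {
  if (inherits(x, "hb_series")) {
    fs <- x$sampling_rate
    hbo <- t(apply(x$hbo, 1, bandpass_vector, fs = fs, low = low, high = high))
    hbr <- t(apply(x$hbr, 1, bandpass_vector, fs = fs, low = low, high = high))
    return(hb_series(hbo, hbr, fs))
  }
  if (inherits(x, "od_series")) {
    fs <- x$sampling_rate
    out <- x
    for (w in seq_len(dim(x$od)[2]))
      out$od[, w, ] <- t(apply(x$od[, w, , drop = FALSE][, 1, ], 1,
                               bandpass_vector, fs = fs, low = low, high = high))
    return(out)
  }
  if (is.matrix(x)) {
    if (is.null(sampling_rate)) stop("sampling_rate required for matrices")
    return(t(apply(x, 1, bandpass_vector, fs = sampling_rate,
                   low = low, high = high)))
  }
  stop("unsupported input to bandpass()")
}
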