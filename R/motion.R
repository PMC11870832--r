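#' Motion-detection parameters
#'
#' The four thresholds of the sliding-window motion-artifact detector:
#' `tMotion` (window length, s), `tMask` (dilation of each detection, s),
#' `STDEVthresh` (multiplier of the channel's first-difference SD), and
#' `AMPthresh` (absolute signal-change threshold, optical-density units).
#' Defaults are the standard Homer-style settings 0.5 s / 5 s / 15 / 0.5.
#'
#' @param tMotion,tMask seconds, > 0.
#' @param STDEVthresh,AMPthresh dimensionless / OD units, > 0.
#' @return list of class `motion_params`.
#' @export
motion_params <- function(tMotion = 0.5, tMask = 5,
                          STDEVthresh = 15, AMPthresh = 0.5) {
  vals <- c(tMotion = tMotion, tMask = tMask,
            STDEVthresh = STDEVthresh, AMPthresh = AMPthresh)
  if (any(vals <= 0)) stop("all motion parameters must be strictly positive")
  structure(as.list(vals), class = "motion_params")
}

# Detector on one vector: flag sample t when the max-min excursion within
# any tMotion window containing t exceeds STDEVthresh * sd(diff) or
# AMPthresh; dilate by tMask seconds.
detect_motion_vector <- function(x, fs, params = motion_params()) {
  n <- length(x)
  win <- max(2L, as.integer(round(params$tMotion * fs)))
  if (n < win) return(rep(FALSE, n))
  sd_diff <- stats::sd(diff(x))
  thr <- if (is.finite(sd_diff) && sd_diff > 0)
    min(params$STDEVthresh * sd_diff, params$AMPthresh)
  else params$AMPthresh
  # sliding max-min over windows of `win` samples
  emb <- stats::embed(x, win)          # rows: windows ending at win..n
  excursion <- do.call(pmax, as.data.frame(emb)) -
    do.call(pmin, as.data.frame(emb))
  hit_win <- which(excursion > thr)    # window ends at index hit + win - 1
  flag <- rep(FALSE, n)
  for (h in hit_win) flag[h:(h + win - 1L)] <- TRUE
  if (!any(flag)) return(flag)
  # dilate +/- tMask seconds
  k <- as.integer(round(params$tMask * fs))
  idx <- which(flag)
  lo <- pmax(1L, idx - k); hi <- pmin(n, idx + k)
  out <- rep(FALSE, n)
  for (i in seq_along(idx)) out[lo[i]:hi[i]] <- TRUE
  out
}

#' Detect motion artifacts on optical-density traces
#'
#' Per channel, a sample is flagged when the signal excursion within any
#' sliding window of length `tMotion` exceeds `STDEVthresh` times the SD of
#' the channel's first differences, or exceeds `AMPthresh` in amplitude;
#' flagged samples are dilated by `tMask` seconds on both sides. A constant
#' channel (zero difference SD) is judged by the amplitude criterion alone.
#' Artifacts are optode-level events: a sample flagged at either wavelength
#' masks the channel at both.
#'
#' @param od an `od_series` from [intensity_to_od()], or a plain matrix
#'   `[channel x sample]` with `sampling_rate` given.
#' @param params a [motion_params()].
#' @param sampling_rate required for plain matrices.
#' @return logical matrix `[channel x sample]`; `TRUE` = artifact.
#' @export
detect_motion <- function(od, params = motion_params(), sampling_rate = NULL) {
  if (inherits(od, "od_series")) {
    fs <- od$sampling_rate
    d <- dim(od$od)
    mask <- matrix(FALSE, d[1], d[3])
    for (ch in seq_len(d[1])) for (w in seq_len(d[2]))
      mask[ch, ] <- mask[ch, ] | detect_motion_vector(od$od[ch, w, ], fs, params)
    return(mask)
  }
  if (is.matrix(od)) {
    if (is.null(sampling_rate)) stop("sampling_rate required for matrices")
    return(t(apply(od, 1, detect_motion_vector, fs = sampling_rate,
                   params = params)))
  }
  stop("unsupported input to detect_motion()")
}

# Segment stage on one vector: inside masked segments the artifact is
# reconstructed in the temporal-derivative domain as the cumulative sum of
# outlier first-differences (robust sigma from the unmasked samples) and
# subtracted. Baseline shifts are removed exactly (their jump is a single
# outlier difference), spike bodies almost entirely, and continuity across
# segment boundaries holds by construction; in-band slow signal inside the
# dilated mask has small differences and is untouched. Residual spike
# wings are left to the wavelet stage.
remove_segment_artifacts <- function(x, mask, fs, k_sigma = 6) {
  if (!any(mask)) return(x)
  n <- length(x)
  d <- c(0, diff(x))
  ref <- d[!mask]
  if (length(ref) < 10) ref <- d
  sigma <- stats::mad(ref)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(ref)
  if (!is.finite(sigma) || sigma == 0) return(x)
  outlier <- which(mask & abs(d) > k_sigma * sigma)
  if (!length(outlier)) return(x)
  med <- stats::median(ref)
  artifact_d <- numeric(n)
  # group outlier differences into events (gap <= 1 s); a spike's rising
  # and falling flanks cancel, so its artifact must integrate to zero or a
  # residual level error would persist for the rest of the recording.
  gap <- as.integer(round(fs))
  ev_start <- c(TRUE, diff(outlier) > gap)
  ev_id <- cumsum(ev_start)
  for (ev in unique(ev_id)) {
    idx <- outlier[ev_id == ev]
    a <- d[idx] - med
    net <- sum(a)
    if (abs(net) < 0.3 * sum(abs(a)))
      a <- a - net / length(a)   # spike-like: force return to baseline
    artifact_d[idx] <- a
  }
  x - cumsum(artifact_d)
}

#' Hybrid segment + wavelet motion correction
#'
#' Two-stage correction of detected artifacts: (1) within each masked
#' segment the artifact is estimated from outlier temporal derivatives
#' and its cumulative trajectory subtracted — baseline shifts are removed
#' exactly and continuity at segment boundaries holds by construction,
#' while slow in-band signal inside the mask is preserved;
#' (2) the whole series is wavelet-decomposed (periodized Daubechies-5,
#' `levels` scales) and detail coefficients beyond `iqr_factor` times the
#' interquartile range from the quartiles are zeroed before
#' reconstruction (suppresses residual spikes). With an empty mask and no
#' outlying coefficients the series is returned unchanged up to
#' reconstruction error (< 1e-10).
#'
#' @param od an `od_series`, or a plain matrix/vector with `sampling_rate`.
#' @param mask logical `[channel x sample]` matrix from [detect_motion()]
#'   (or a vector for vector input).
#' @param levels,iqr_factor wavelet depth and outlier rule
#'   (`iqr_factor = Inf` disables the wavelet stage).
#' @param sampling_rate required for plain input.
#' @return Corrected object of the same shape; channels whose mask covers
#'   more than half the recording are listed in attribute `low_quality`.
#' @export
correct_motion <- function(od, mask, levels = 4L, iqr_factor = 1.5,
                           sampling_rate = NULL) {
  fix_one <- function(x, m, fs) {
    y <- remove_segment_artifacts(x, m, fs)
    wavelet_despike(y, levels = levels, iqr_factor = iqr_factor)
  }
  if (inherits(od, "od_series")) {
    fs <- od$sampling_rate
    d <- dim(od$od)
    out <- od
    low_quality <- integer(0)
    for (ch in seq_len(d[1])) {
      if (mean(mask[ch, ]) > 0.5) low_quality <- c(low_quality, ch)
      for (w in seq_len(d[2]))
        out$od[ch, w, ] <- fix_one(od$od[ch, w, ], mask[ch, ], fs)
    }
    attr(out, "low_quality") <- low_quality
    return(out)
  }
  if (is.numeric(od) && is.null(dim(od))) {
    if (is.null(sampling_rate)) stop("sampling_rate required for vectors")
    return(fix_one(od, as.logical(mask), sampling_rate))
  }
  if (is.matrix(od)) {
    if (is.null(sampling_rate)) stop("sampling_rate required for matrices")
    out <- od
    for (ch in seq_len(nrow(od)))
      out[ch, ] <- fix_one(od[ch, ], mask[ch, ], sampling_rate)
    return(out)
  }
  stop("unsupported input to correct_motion()")
}
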