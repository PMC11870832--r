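#' Run the full preprocessing chain on one scan
#'
#' Fixed, logged stage order (default `"od_filter"`):
#' saturation-NaN repair on intensity, intensity to optical density,
#' motion detection and hybrid spline+wavelet correction on OD, zero-phase
#' band-pass on OD, then the modified Beer-Lambert inversion to HbO/HbR/HbT.
#' The alternative order `"hb_filter"` applies the Beer-Lambert inversion
#' before the band-pass; the two commute up to filter edge effects because
#' both stages are linear, which the test suite checks.
#'
#' @param scan a [raw_scan()].
#' @param params a [motion_params()].
#' @param band numeric pair, band-pass edges in Hz.
#' @param dpf,distance,extinction Beer-Lambert constants, see [od_to_hb()].
#' @param cv_threshold channel-exclusion CV threshold in percent.
#' @param wavelet_levels,iqr_factor motion-correction wavelet settings.
#' @param order `"od_filter"` (band-pass on OD, then MBLL) or
#'   `"hb_filter"` (MBLL, then band-pass on Hb).
#' @return list with `hb` (an `hb_series`), `quality` (see
#'   [channel_quality()], augmented with `motion_fraction` and
#'   `low_quality_channels`), and `log` (character vector of stage records).
#' @export
preprocess_scan <- function(scan,
                            params = motion_params(),
                            band = c(0.01, 0.08),
                            dpf = c(6, 6), distance = 3,
                            extinction = extinction_coefficients(),
                            cv_threshold = 15,
                            wavelet_levels = 4L, iqr_factor = 1.5,
                            order = c("od_filter", "hb_filter")) {
  order <- match.arg(order)
  log <- sprintf("preprocess subject=%s order=%s tMotion=%g tMask=%g STDEVthresh=%g AMPthresh=%g band=[%g,%g] dpf=[%s] distance=%g cv_threshold=%g wavelet_levels=%d iqr_factor=%g",
                 scan$subject_id, order, params$tMotion, params$tMask,
                 params$STDEVthresh, params$AMPthresh, band[1], band[2],
                 paste(dpf, collapse = ","), distance, cv_threshold,
                 wavelet_levels, iqr_factor)
  quality <- channel_quality(scan, cv_threshold = cv_threshold)
  repaired <- repair_nans(scan)
  quality$excluded_channels <- union(quality$excluded_channels,
                                     attr(repaired, "unrepairable"))
  log <- c(log, sprintf("repair_nans: %d saturation segments, %.3f%% samples missing",
                        quality$nan_segment_count, 100 * quality$nan_fraction))
  od <- intensity_to_od(repaired)
  mask <- detect_motion(od, params)
  quality$motion_fraction <- mean(mask)
  log <- c(log, sprintf("detect_motion: %.3f%% samples flagged",
                        100 * quality$motion_fraction))
  od <- correct_motion(od, mask, levels = wavelet_levels,
                       iqr_factor = iqr_factor)
  quality$low_quality_channels <- attr(od, "low_quality")
  if (order == "od_filter") {
    od <- bandpass(od, low = band[1], high = band[2])
    hb <- od_to_hb(od, dpf = dpf, distance = distance, extinction = extinction)
  } else {
    hb <- od_to_hb(od, dpf = dpf, distance = distance, extinction = extinction)
    hb <- bandpass(hb, low = band[1], high = band[2])
  }
  log <- c(log, "bandpass + MBLL complete")
  list(hb = hb, quality = quality, log = log)
}
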