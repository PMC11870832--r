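#' Construct a raw dual-wavelength intensity scan
#'
#' The container for one subject's continuous-wave recording: an
#' `[channel x wavelength x sample]` array of detected light intensity in
#' arbitrary units, plus the probe layout and sampling rate. Saturation
#' dropouts are carried as `NA` samples, never as sentinel numbers.
#'
#' @param subject_id character scalar.
#' @param intensity numeric array `[channel x wavelength x sample]`;
#'   non-negative where not `NA`.
#' @param sampling_rate sampling frequency in Hz, > 0.
#' @param probe a [probe_layout()]; defaults to the 18-channel DLPFC montage.
#' @return An object of class `raw_scan`.
#' @export
raw_scan <- function(subject_id, intensity, sampling_rate,
                     probe = default_probe_layout()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3-d array [channel x wavelength x sample]")
  if (dim(intensity)[1] != n_channels(probe))
    stop(sprintf("montage mismatch: intensity has %d channels, probe has %d",
                 dim(intensity)[1], n_channels(probe)))
  if (dim(intensity)[2] != length(probe$wavelengths))
    stop("intensity wavelength dimension does not match probe wavelengths")
  if (!(is.numeric(sampling_rate) && length(sampling_rate) == 1L &&
        sampling_rate > 0))
    stop("sampling_rate must be a positive scalar (Hz)")
  bad <- intensity[!is.na(intensity)] < 0
  if (any(bad)) stop("intensity must be non-negative where not missing")
  structure(
    list(subject_id = subject_id,
         intensity = intensity,
         sampling_rate = as.numeric(sampling_rate),
         probe = probe),
    class = "raw_scan"
  )
}

#' @export
print.raw_scan <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("raw_scan '%s': %d channels x %d wavelengths x %d samples @ %g Hz (%.1f min), %d missing samples\n",
              x$subject_id, d[1], d[2], d[3], x$sampling_rate,
              d[3] / x$sampling_rate / 60, sum(is.na(x$intensity))))
  invisible(x)
}

#' Scan duration in seconds
#' @param scan a `raw_scan`.
#' @return duration in seconds.
#' @export
scan_duration <- function(scan) dim(scan$intensity)[3] / scan$sampling_rate

n_samples <- function(scan) dim(scan$intensity)[3]

#' Read a behavior table
#'
#' Reads a CSV with required columns `subject_id`, `age`, `sex`, `rapm`
#' (Raven's Advanced Progressive Matrices set II score, 0-36). Sex labels
#' are normalized to `"female"` / `"male"` (accepting `f`/`m`, any case).
#' Rows violating the score range (0-36) or the adult-age inclusion rule
#' (age >= 18) are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return data.frame with one validated row per subject.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop("behavior table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "sex", "rapm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("behavior table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  sex <- tolower(trimws(as.character(df$sex)))
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  bad_sex <- which(!sex %in% c("female", "male"))
  bad_rapm <- which(!(df$rapm >= 0 & df$rapm <= 36 & df$rapm == round(df$rapm)))
  bad_age <- which(!(df$age >= 18))
  bad <- sort(unique(c(bad_sex, bad_rapm, bad_age)))
  if (length(bad))
    stop(sprintf("behavior table validation error at row(s) %s (rapm must be an integer in 0-36, age >= 18, sex female/male)",
                 paste(bad, collapse = ", ")))
  data.frame(subject_id = as.character(df$subject_id),
             age = as.numeric(df$age),
             sex = sex,
             rapm = as.integer(df$rapm),
             stringsAsFactors = FALSE)
}

#' Write a behavior table
#' @param behavior data.frame with columns subject_id, age, sex, rapm.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior[, c("subject_id", "age", "sex", "rapm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
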