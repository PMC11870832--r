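#' Write a scan to the package's plain-text interchange format
#'
#' One file per scan: a commented header (subject id, sampling rate,
#' wavelengths, channel table) followed by a CSV matrix with one column per
#' channel-wavelength pair, one row per sample. Values are written with 17
#' significant digits so that a write/read round trip reproduces the
#' intensity payload bit for bit; missing samples are written as `NA`.
#'
#' @param scan a [raw_scan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "raw_scan"))
  nc <- n_channels(scan$probe)
  wl <- scan$probe$wavelengths
  ch <- scan$probe$channels
  header <- c(
    "# fnirsgraph scan v1",
    paste0("# subject_id: ", scan$subject_id),
    paste0("# sampling_rate: ", sprintf("%.17g", scan$sampling_rate)),
    paste0("# wavelengths: ", paste(wl, collapse = ",")),
    paste0("# n_channels: ", nc),
    paste0("# channels: ",
           paste(sprintf("%d:%d:%s", ch$source, ch$detector, ch$hemisphere),
                 collapse = ";"))
  )
  cols <- character(nc * length(wl))
  mat <- matrix(NA_real_, nrow = dim(scan$intensity)[3], ncol = nc * length(wl))
  k <- 0L
  for (c_i in seq_len(nc)) for (w_i in seq_along(wl)) {
    k <- k + 1L
    cols[k] <- sprintf("ch%02d_wl%d", c_i, wl[w_i])
    mat[, k] <- scan$intensity[c_i, w_i, ]
  }
  txt <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  txt[is.na(mat)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = ","), con)
  writeLines(do.call(paste, c(asplit(txt, 2), sep = ",")), con)
  invisible(path)
}

#' Read a scan from the plain-text interchange format
#'
#' Validates the header against the expected 18-channel montage and
#' preserves missing samples as `NA`.
#'
#' @param path file written by [write_scan()].
#' @param expected_channels montage size to validate against (default 18).
#' @return A [raw_scan()].
#' @export
read_scan <- function(path, expected_channels = 18L) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  head_lines <- readLines(path, n = 6L)
  if (length(head_lines) < 6L || head_lines[1] != "# fnirsgraph scan v1")
    stop("format error: missing 'fnirsgraph scan v1' signature line")
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), head_lines, value = TRUE)
    if (!length(ln)) stop("format error: missing header field '", key, "'")
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  subject_id <- get_field("subject_id")
  fs <- as.numeric(get_field("sampling_rate"))
  if (!is.finite(fs) || fs <= 0)
    stop("format error: field 'sampling_rate' is not a positive number")
  wl <- as.numeric(strsplit(get_field("wavelengths"), ",")[[1]])
  nc <- as.integer(get_field("n_channels"))
  if (nc != expected_channels)
    stop(sprintf("montage mismatch: file declares %d channels, expected %d",
                 nc, expected_channels))
  ch_spec <- strsplit(strsplit(get_field("channels"), ";")[[1]], ":")
  if (length(ch_spec) != nc)
    stop("format error: field 'channels' length disagrees with n_channels")
  channels <- data.frame(
    source = as.integer(vapply(ch_spec, `[`, "", 1L)),
    detector = as.integer(vapply(ch_spec, `[`, "", 2L)),
    hemisphere = vapply(ch_spec, `[`, "", 3L),
    stringsAsFactors = FALSE)
  probe <- probe_layout(channels, wavelengths = wl,
                        n_sources = max(channels$source),
                        n_detectors = max(channels$detector))
  dt <- data.table::fread(path, skip = 6L, header = TRUE, sep = ",",
                          na.strings = "NA", data.table = FALSE)
  n_t <- nrow(dt)
  intensity <- array(NA_real_, dim = c(nc, length(wl), n_t))
  for (c_i in seq_len(nc)) for (w_i in seq_along(wl)) {
    col <- sprintf("ch%02d_wl%d", c_i, wl[w_i])
    if (is.null(dt[[col]]))
      stop("format error: missing data column '", col, "'")
    intensity[c_i, w_i, ] <- dt[[col]]
  }
  raw_scan(subject_id, intensity, fs, probe)
}
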