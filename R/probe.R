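#' Probe layout for the DLPFC montage
#'
#' Describes a continuous-wave fNIRS probe: source and detector counts, the
#' ordered list of source-detector channels with hemisphere labels, and the
#' two measurement wavelengths. The default layout is the 8-source,
#' 8-detector, 18-channel bilateral dorsolateral-prefrontal montage at
#' 760 and 850 nm.
#'
#' @param channels data.frame with columns `source`, `detector`,
#'   `hemisphere` (one of `"L"`, `"R"`), one row per channel, in channel
#'   order.
#' @param n_sources,n_detectors number of optodes of each kind.
#' @param wavelengths strictly increasing numeric pair of wavelengths in nm.
#' @return An object of class `probe_layout`.
#' @export
probe_layout <- function(channels,
                         n_sources = 8L,
                         n_detectors = 8L,
                         wavelengths = c(760, 850)) {
  stopifnot(is.data.frame(channels),
            all(c("source", "detector", "hemisphere") %in% names(channels)))
  if (length(wavelengths) != 2L || diff(wavelengths) <= 0)
    stop("wavelengths must be a strictly increasing pair (nm)")
  if (!all(channels$source >= 1L & channels$source <= n_sources))
    stop("channel references a source index outside 1..n_sources")
  if (!all(channels$detector >= 1L & channels$detector <= n_detectors))
    stop("channel references a detector index outside 1..n_detectors")
  if (!all(channels$hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'")
  structure(
    list(n_sources = as.integer(n_sources),
         n_detectors = as.integer(n_detectors),
         channels = channels,
         wavelengths = as.numeric(wavelengths)),
    class = "probe_layout"
  )
}

#' Default 18-channel bilateral DLPFC montage
#'
#' Sources 1-4 and detectors 1-4 cover the left hemisphere, sources 5-8 and
#' detectors 5-8 the right, giving nine channels per side.
#'
#' @return A `probe_layout` with exactly 18 channels.
#' @export
default_probe_layout <- function() {
  left <- data.frame(
    source   = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L),
    detector = c(1L, 2L, 1L, 2L, 3L, 2L, 3L, 3L, 4L),
    hemisphere = "L")
  right <- data.frame(
    source   = c(5L, 5L, 6L, 6L, 6L, 7L, 7L, 8L, 8L),
    detector = c(5L, 6L, 5L, 6L, 7L, 6L, 7L, 7L, 8L),
    hemisphere = "R")
  probe_layout(rbind(left, right))
}

#' Number of channels in a probe layout
#' @param probe a `probe_layout`.
#' @return integer channel count.
#' @export
n_channels <- function(probe) nrow(probe$channels)

#' Channel labels ("ch01".."ch18")
#' @param probe a `probe_layout`.
#' @return character vector of channel names.
#' @export
channel_labels <- function(probe) sprintf("ch%02d", seq_len(n_channels(probe)))

validate_probe <- function(probe, expected_channels = 18L) {
  if (!inherits(probe, "probe_layout")) stop("not a probe_layout")
  if (n_channels(probe) != expected_channels)
    stop(sprintf("montage mismatch: expected %d channels, found %d",
                 expected_channels, n_channels(probe)))
  invisible(probe)
}
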