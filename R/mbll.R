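#' Hemoglobin extinction coefficients at the measurement wavelengths
#'
#' Molar extinction coefficients (cm^-1 M^-1) of oxy- and deoxyhemoglobin
#' at 760 and 850 nm, from the compiled hemoglobin absorption spectra in
#' standard use for continuous-wave NIRS. Shipped as a fixed, versioned
#' table rather than delegated to a library default so that concentration
#' scaling is reproducible.
#'
#' @param wavelengths which wavelengths (nm) to return; only 760 and 850
#'   are tabulated.
#' @return matrix `[wavelength x chromophore]` with columns `hbo`, `hbr`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(`760` = c(hbo = 1486.5865, hbr = 3843.707),
               `850` = c(hbo = 2526.391,  hbr = 1798.643))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("extinction coefficients tabulated only for 760 and 850 nm")
  tab[key, , drop = FALSE]
}

# Per-wavelength design matrix of the modified Beer-Lambert law:
# dOD_lambda = distance * dpf_lambda * sum_c eps_{lambda,c} * dC_c * 1e-6
# with concentrations in micromolar. Returns the 2x2 matrix A such that
# dOD = A %*% c(hbo, hbr).
mbll_matrix <- function(dpf = c(6, 6), distance = 3,
                        extinction = extinction_coefficients()) {
  if (length(dpf) == 1L) dpf <- rep(dpf, nrow(extinction))
  A <- diag(dpf * distance, nrow(extinction)) %*% extinction * 1e-6
  dimnames(A) <- dimnames(extinction)
  if (abs(det(A)) < .Machine$double.eps * 100)
    stop("config error: extinction matrix is singular for these wavelengths")
  A
}

#' Forward modified Beer-Lambert model
#'
#' Maps chromophore concentration changes to optical-density changes at
#' each wavelength. Used by the synthetic generator so that the analysis
#' pipeline's inverse ([od_to_hb()]) is round-trip testable.
#'
#' @param hbo,hbr numeric matrices `[channel x sample]`, micromolar.
#' @param dpf differential pathlength factor per wavelength (dimensionless).
#' @param distance source-detector separation in cm.
#' @param extinction see [extinction_coefficients()].
#' @return array `[channel x wavelength x sample]` of delta-OD.
#' @export
hb_to_od <- function(hbo, hbr, dpf = c(6, 6), distance = 3,
                     extinction = extinction_coefficients()) {
  A <- mbll_matrix(dpf, distance, extinction)
  nch <- nrow(hbo); nt <- ncol(hbo)
  od <- array(0, dim = c(nch, nrow(A), nt))
  for (w in seq_len(nrow(A)))
    od[, w, ] <- A[w, "hbo"] * hbo + A[w, "hbr"] * hbr
  od
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and sample, the 2x2 linear system relating
#' optical-density changes at the two wavelengths to oxy- and
#' deoxyhemoglobin concentration changes. Total hemoglobin is their sum.
#'
#' @param od an `od_series` from [intensity_to_od()] (or a raw
#'   `[channel x wavelength x sample]` array with attribute-free use via
#'   `sampling_rate`).
#' @param dpf,distance,extinction see [hb_to_od()].
#' @param sampling_rate required if `od` is a bare array.
#' @return An `hb_series`: list with `hbo`, `hbr`, `hbt` matrices
#'   `[channel x sample]` in micromolar and `sampling_rate`.
#' @export
od_to_hb <- function(od, dpf = c(6, 6), distance = 3,
                     extinction = extinction_coefficients(),
                     sampling_rate = NULL) {
  if (inherits(od, "od_series")) {
    arr <- od$od
    fs <- od$sampling_rate
  } else {
    arr <- od
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for bare OD arrays")
  }
  A <- mbll_matrix(dpf, distance, extinction)
  Ainv <- solve(A)
  nch <- dim(arr)[1]; nt <- dim(arr)[3]
  hbo <- matrix(0, nch, nt); hbr <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    sol <- Ainv %*% arr[ch, , ]
    hbo[ch, ] <- sol[1, ]
    hbr[ch, ] <- sol[2, ]
  }
  hb_series(hbo, hbr, fs)
}

#' Construct an hb_series container
#' @param hbo,hbr matrices `[channel x sample]`, micromolar.
#' @param sampling_rate Hz.
#' @return An object of class `hb_series` with `hbt = hbo + hbr`.
#' @export
hb_series <- function(hbo, hbr, sampling_rate) {
  stopifnot(identical(dim(hbo), dim(hbr)))
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 sampling_rate = sampling_rate),
            class = "hb_series")
}
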