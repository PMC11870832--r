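#' Specification of a synthetic fNIRS cohort
#'
#' All knobs of the synthetic-data generator. Defaults mirror the study
#' conditions the pipeline is designed for: ~30-min recordings, a cohort
#' whose latent connectivity density correlates negatively (rho = -0.33)
#' with a 0-36 behavior score of mean 25.24 and SD 4.00, young-adult ages,
#' and physiological contamination (cardiac ~1.1 Hz, respiratory ~0.3 Hz,
#' Mayer ~0.1 Hz) riding on a band-limited correlated neural component.
#'
#' @param n_subjects cohort size (>= 4).
#' @param duration scan length in seconds.
#' @param sampling_rate Hz.
#' @param target_brain_behavior_rho planted correlation between latent
#'   connectivity density and behavior score, |rho| < 1.
#' @param behavior_mean,behavior_sd score distribution before rounding and
#'   clipping to 0-36.
#' @param artifact_rate motion events per minute (>= 0).
#' @param saturation_rate expected saturation-NaN segments per scan (>= 0).
#' @param saturation_mean_s mean NaN-segment length in seconds.
#' @param seed integer master seed; every output bit is a function of it.
#' @param density_range range of the per-subject latent density u (the
#'   subject's mean inter-channel correlation level).
#' @param fc_pair_sd SD of the per-pair correlation spread around the
#'   subject's density (heterogeneous pairwise coupling; keeps binarized
#'   graphs informative across thresholds).
#' @param neural_sd SD of the neural HbO component, micromolar.
#' @param hbr_ratio neural HbR amplitude relative to HbO (negative:
#'   activation raises HbO and lowers HbR).
#' @param physio_hbr_ratio HbR fraction of the physiological oscillations
#'   (positive: pulsatile blood volume raises both chromophores together).
#' @param cardiac_amp,resp_amp,mayer_amp physiological amplitudes as
#'   multiples of `neural_sd`.
#' @param cardiac_freq,resp_freq,mayer_freq component frequencies in Hz.
#' @param drift_od maximal linear optical-density drift over the scan.
#' @param noise_od white measurement-noise SD in OD units.
#' @param dpf,distance Beer-Lambert constants used for the forward
#'   wavelength mapping (same defaults as the preprocessing inverse).
#' @param unstable_gain_subjects indices of subjects given one
#'   unstable-gain channel (CV above the exclusion threshold), for
#'   channel-quality tests.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        duration = 1800,
                        sampling_rate = 10,
                        target_brain_behavior_rho = -0.33,
                        behavior_mean = 25.24,
                        behavior_sd = 4.00,
                        artifact_rate = 0.5,
                        saturation_rate = 1,
                        saturation_mean_s = 2,
                        seed = 1L,
                        density_range = c(0.5, 0.9),
                        fc_pair_sd = 0.15,
                        neural_sd = 0.3,
                        hbr_ratio = -0.4,
                        physio_hbr_ratio = 0.3,
                        cardiac_amp = 3, resp_amp = 1.5, mayer_amp = 1,
                        cardiac_freq = 1.1, resp_freq = 0.3, mayer_freq = 0.1,
                        drift_od = 0.02,
                        noise_od = 0.005,
                        dpf = c(6, 6), distance = 3,
                        unstable_gain_subjects = integer(0)) {
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (abs(target_brain_behavior_rho) >= 1) stop("|rho| must be < 1")
  if (artifact_rate < 0 || saturation_rate < 0) stop("rates must be >= 0")
  if (target_brain_behavior_rho != 0 && behavior_sd == 0)
    stop("config error: nonzero rho unattainable with behavior_sd = 0")
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

# Named RNG contract: everything downstream of a cohort_spec seed is
# bit-reproducible under these generators.
set_generator_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Draw the cohort ground truth (latent densities, covariances, behavior)
#'
#' Per subject: a latent density level u (uniform on `density_range`),
#' an 18x18 channel correlation matrix whose pairwise couplings scatter
#' around u with SD `fc_pair_sd` (projected to the nearest positive
#' semi-definite correlation matrix), and a behavior score drawn so that
#' corr(density, score) ~= `target_brain_behavior_rho` across the cohort
#' before integer rounding, where density is the realized mean
#' off-diagonal correlation — exactly the quantity average degree
#' estimates. Ages and sexes echo a young-adult cohort
#' (age ~ N(20.05, 2.01^2) clipped at 18; P(female) = 88/152).
#'
#' @param spec a [cohort_spec()].
#' @return list with `density` (vector), `covariance`
#'   (`[18 x 18 x n]` array), and `behavior` (data.frame
#'   subject_id/age/sex/rapm).
#' @export
draw_ground_truth <- function(spec) {
  set_generator_seed(spec$seed)
  n <- spec$n_subjects
  nch <- 18L
  u <- stats::runif(n, spec$density_range[1], spec$density_range[2])
  covs <- array(0, dim = c(nch, nch, n))
  density <- numeric(n)
  for (i in seq_len(n)) {
    w <- matrix(0, nch, nch)
    up <- upper.tri(w)
    w[up] <- pmin(0.97, pmax(-0.5,
                             u[i] + stats::rnorm(sum(up), 0, spec$fc_pair_sd)))
    w <- w + t(w)
    diag(w) <- 1
    # project to the nearest PSD correlation matrix (eigenvalue clipping)
    e <- eigen(w, symmetric = TRUE)
    s <- e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors)
    s <- stats::cov2cor(s)
    covs[, , i] <- s
    density[i] <- mean(s[row(s) != col(s)])
  }
  rho <- spec$target_brain_behavior_rho
  z_u <- as.numeric(scale(density))
  score_z <- rho * z_u + sqrt(1 - rho^2) * stats::rnorm(n)
  rapm <- pmin(36L, pmax(0L, as.integer(round(
    spec$behavior_mean + spec$behavior_sd * score_z))))
  age <- pmax(18, round(stats::rnorm(n, 20.05, 2.01)))
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(88, 64) / 152)
  behavior <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         age = age, sex = sex, rapm = rapm,
                         stringsAsFactors = FALSE)
  list(density = density, covariance = covs, behavior = behavior)
}

# Band-limited correlated component: iid Gaussian [nch x nt] colored by
# chol(Sigma), band-passed per channel, rescaled to per-channel sd.
band_limited_component <- function(sigma, n_t, fs, target_sd,
                                   band = c(0.01, 0.08)) {
  nch <- nrow(sigma)
  z <- matrix(stats::rnorm(nch * n_t), nch, n_t)
  x <- t(chol(sigma)) %*% z
  for (ch in seq_len(nch)) {
    v <- bandpass_vector(x[ch, ], fs, band[1], band[2])
    x[ch, ] <- v / stats::sd(v) * target_sd
  }
  x
}

# Build one subject's scan. Returns the raw_scan plus the clean neural HbO
# (the planted correlated component) for recovery tests.
generate_subject_scan <- function(subject_id, sigma, spec, subject_seed,
                                  unstable_gain = FALSE) {
  set_generator_seed(subject_seed)
  fs <- spec$sampling_rate
  n_t <- as.integer(round(spec$duration * fs))
  nch <- nrow(sigma)
  tt <- (seq_len(n_t) - 1) / fs
  hbo <- band_limited_component(sigma, n_t, fs, spec$neural_sd)
  clean_hbo <- hbo
  hbr <- spec$hbr_ratio * hbo +
    band_limited_component(diag(nch), n_t, fs, 0.2 * spec$neural_sd)
  # physiological oscillations with per-channel phase jitter and slight
  # amplitude variation; all outside the 0.01-0.08 Hz analysis band
  physio <- rbind(cardiac = c(spec$cardiac_freq, spec$cardiac_amp),
                  resp = c(spec$resp_freq, spec$resp_amp),
                  mayer = c(spec$mayer_freq, spec$mayer_amp))
  for (p in seq_len(nrow(physio))) {
    f <- physio[p, 1]
    amp <- physio[p, 2] * spec$neural_sd
    phase0 <- stats::runif(1, 0, 2 * pi)
    for (ch in seq_len(nch)) {
      a <- amp * stats::runif(1, 0.8, 1.2)
      wave <- a * sin(2 * pi * f * tt + phase0 + stats::rnorm(1, 0, 0.5))
      hbo[ch, ] <- hbo[ch, ] + wave
      hbr[ch, ] <- hbr[ch, ] + spec$physio_hbr_ratio * wave
    }
  }
  od <- hb_to_od(hbo, hbr, dpf = spec$dpf, distance = spec$distance)
  ramp <- seq(0, 1, length.out = n_t)
  for (ch in seq_len(nch)) for (w in 1:2) {
    od[ch, w, ] <- od[ch, w, ] +
      stats::runif(1, -1, 1) * spec$drift_od * ramp +
      stats::rnorm(n_t, 0, spec$noise_od)
  }
  i0 <- matrix(1000 * stats::runif(nch * 2, 0.8, 1.2), nch, 2)
  intensity <- array(0, dim = c(nch, 2, n_t))
  for (ch in seq_len(nch)) for (w in 1:2)
    intensity[ch, w, ] <- i0[ch, w] * exp(-od[ch, w, ])
  if (unstable_gain) {
    # one channel with slowly wandering detector gain -> CV above threshold
    gain <- 1 + 0.3 * sin(2 * pi * 0.004 * tt)
    for (w in 1:2) intensity[1, w, ] <- intensity[1, w, ] * gain
  }
  scan <- raw_scan(subject_id, intensity, fs)
  if (spec$saturation_rate > 0)
    scan <- inject_saturation(scan, spec$saturation_rate,
                              spec$saturation_mean_s)
  list(scan = scan, clean_hbo = clean_hbo)
}

# Saturation dropouts: Poisson number of NA segments, exponential lengths,
# random channel, both wavelengths. Uses the current RNG stream.
inject_saturation <- function(scan, rate, mean_s) {
  n_seg <- stats::rpois(1, rate)
  if (n_seg == 0) return(scan)
  fs <- scan$sampling_rate
  n_t <- dim(scan$intensity)[3]
  for (k in seq_len(n_seg)) {
    len <- max(3L, as.integer(round(stats::rexp(1, 1 / mean_s) * fs)))
    start <- sample.int(max(1L, n_t - len), 1)
    ch <- sample.int(dim(scan$intensity)[1], 1)
    scan$intensity[ch, , start:(start + len - 1L)] <- NA_real_
  }
  scan
}

#' Inject motion artifacts into a scan
#'
#' Adds head-motion-like transients at a Poisson rate: sharp spikes
#' (duration < 1 s, default amplitude 20x the channel's optical-density
#' SD) and persistent baseline shifts modeling optode displacement — an
#' abrupt change of source-detector coupling, i.e. a multiplicative
#' intensity step, default 0.6 OD (~45% intensity). Events are
#' optode-level: every channel is perturbed, with per-channel amplitude
#' jitter and random sign. Artifacts are applied multiplicatively to
#' intensity (`I * exp(-a)`), which is exactly additive in the
#' optical-density domain where detection operates. The exact sample mask
#' of injected events is returned for detector-sensitivity tests (for
#' baseline shifts the transition samples are marked).
#'
#' @param scan a [raw_scan()] without missing samples.
#' @param rate events per minute (>= 0).
#' @param seed integer seed.
#' @param spike_amp_sd spike amplitude in channel-OD-SD units.
#' @param shift_amp_od baseline-shift amplitude in absolute OD units
#'   (coupling change is a property of the optode, not of signal scale).
#' @param p_spike probability an event is a spike (vs a baseline shift).
#' @return list with `scan` (perturbed), `mask` (logical
#'   `[channel x sample]` of all injected event samples), `spike_mask`
#'   (spike samples only; baseline shifts at a few SD can legitimately
#'   elude detection), and `n_events`.
#' @export
inject_motion <- function(scan, rate, seed = 1L,
                          spike_amp_sd = 20, shift_amp_od = 0.6,
                          p_spike = 0.7) {
  stopifnot(rate >= 0)
  set_generator_seed(seed)
  d <- dim(scan$intensity)
  mask <- matrix(FALSE, d[1], d[3])
  spike_mask <- matrix(FALSE, d[1], d[3])
  if (rate == 0)
    return(list(scan = scan, mask = mask, spike_mask = spike_mask,
                n_events = 0L))
  fs <- scan$sampling_rate
  n_t <- d[3]
  dur_min <- n_t / fs / 60
  n_events <- stats::rpois(1, rate * dur_min)
  od_sd <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[1])) for (w in seq_len(d[2])) {
    x <- scan$intensity[ch, w, ]
    od_sd[ch, w] <- stats::sd(-log(x / mean(x, na.rm = TRUE)), na.rm = TRUE)
  }
  art <- array(0, dim = d)
  for (e in seq_len(n_events)) {
    is_spike <- stats::runif(1) < p_spike
    if (is_spike) {
      len <- max(2L, as.integer(round(stats::runif(1, 0.2, 0.8) * fs)))
      start <- sample.int(n_t - len, 1)
      shape <- exp(-((seq_len(len) - (len + 1) / 2)^2) / (len / 4)^2)
      idx <- start:(start + len - 1L)
    } else {
      start <- sample.int(n_t - 1L, 1)
      shape <- rep(1, n_t - start + 1L)
      idx <- start:n_t
    }
    for (ch in seq_len(d[1])) {
      sgn <- sample(c(-1, 1), 1)
      jit <- stats::runif(1, 0.8, 1.2)
      for (w in seq_len(d[2])) {
        amp <- if (is_spike) spike_amp_sd * od_sd[ch, w] * jit * sgn
               else shift_amp_od * jit * sgn
        art[ch, w, idx] <- art[ch, w, idx] + amp * shape
      }
    }
    ev_idx <- if (is_spike) idx else start:min(n_t, start + 1L)
    mask[, ev_idx] <- TRUE
    if (is_spike) spike_mask[, idx] <- TRUE
  }
  intensity <- scan$intensity * exp(-art)
  list(scan = raw_scan(scan$subject_id, intensity, fs, scan$probe),
       mask = mask, spike_mask = spike_mask, n_events = n_events)
}

#' Generate a synthetic cohort of scans, behavior, and ground truth
#'
#' Draws the cohort ground truth with [draw_ground_truth()], then builds
#' each subject's dual-wavelength intensity recording: the planted
#' band-limited correlated neural component, physiological oscillations,
#' forward Beer-Lambert wavelength mapping (same constants as the
#' analysis inverse), linear drift and white measurement noise in the
#' optical-density domain, then motion events and saturation dropouts at
#' the configured rates. Randomness flows from the single master seed
#' through named per-subject substreams, so fixing the seed fixes every
#' output bit.
#'
#' @param spec a [cohort_spec()].
#' @param keep_clean keep each subject's clean neural HbO matrix in the
#'   ground truth (memory-heavy; meant for tests).
#' @return list with `scans` (list of [raw_scan()]), `behavior`
#'   (data.frame), and `truth` (density, covariance, motion masks, and
#'   optionally `clean_hbo`).
#' @export
generate_cohort <- function(spec, keep_clean = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- draw_ground_truth(spec)
  set_generator_seed(spec$seed + 1L)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  scans <- vector("list", spec$n_subjects)
  masks <- vector("list", spec$n_subjects)
  clean <- if (keep_clean) vector("list", spec$n_subjects) else NULL
  for (i in seq_len(spec$n_subjects)) {
    gs <- generate_subject_scan(truth$behavior$subject_id[i],
                                truth$covariance[, , i], spec,
                                subject_seeds[i],
                                unstable_gain = i %in% spec$unstable_gain_subjects)
    scan <- gs$scan
    if (spec$artifact_rate > 0) {
      im <- inject_motion(scan, spec$artifact_rate,
                          seed = subject_seeds[i] %% 1000003L + 7L)
      scan <- im$scan
      masks[[i]] <- im$mask
    } else {
      masks[[i]] <- matrix(FALSE, dim(scan$intensity)[1],
                           dim(scan$intensity)[3])
    }
    scans[[i]] <- scan
    if (keep_clean) clean[[i]] <- gs$clean_hbo
  }
  truth$motion_masks <- masks
  if (keep_clean) truth$clean_hbo <- clean
  list(scans = scans, behavior = truth$behavior,
       truth = truth[c("density", "covariance", "motion_masks",
                       if (keep_clean) "clean_hbo")])
}
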