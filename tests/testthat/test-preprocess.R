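scan_from_matrix <- function(x, fs = 10) {
  # embed a single test trace into channel 1 of an otherwise flat scan
  n_t <- length(x)
  intensity <- array(1000, dim = c(18, 2, n_t))
  intensity[1, 1, ] <- x
  raw_scan("T", intensity, fs)
}

test_that("NaN repair reproduces smooth signals and leaves valid samples alone", {
  fs <- 10
  # linear ramp with interior samples deleted: cubic spline is exact
  ramp <- seq(100, 200, length.out = 100)
  x <- ramp; x[40:42] <- NA
  sc <- repair_nans(scan_from_matrix(x, fs))
  expect_equal(sc$intensity[1, 1, ], ramp, tolerance = 1e-10)
  # 0.05 Hz sinusoid, 1-s gap: repair error < 1% of amplitude
  tt <- (0:1199) / fs
  amp <- 50
  sine <- 1000 + amp * sin(2 * pi * 0.05 * tt)
  x2 <- sine; x2[600:609] <- NA
  sc2 <- repair_nans(scan_from_matrix(x2, fs))
  expect_lt(max(abs(sc2$intensity[1, 1, 600:609] - sine[600:609])), 0.01 * amp)
  # non-missing samples bitwise untouched
  expect_identical(sc2$intensity[1, 1, -(600:609)], sine[-(600:609)])
  # no NaNs -> identical scan
  clean <- scan_from_matrix(sine, fs)
  expect_identical(repair_nans(clean)$intensity, clean$intensity)
  # edge gap: nearest-value extension
  x3 <- sine; x3[1:5] <- NA
  expect_equal(repair_nans(scan_from_matrix(x3, fs))$intensity[1, 1, 1:5],
               rep(sine[6], 5))
})

test_that("fully missing channels are flagged, not repaired", {
  x <- rep(NA_real_, 50)
  sc <- scan_from_matrix(seq(900, 1100, length.out = 50))
  sc$intensity[4, , ] <- NA_real_
  out <- repair_nans(sc)
  expect_identical(attr(out, "unrepairable"), 4L)
  q <- channel_quality(sc)
  expect_true(4L %in% q$excluded_channels)
})

test_that("optical density conversion satisfies the log identities", {
  n_t <- 100
  const <- scan_from_matrix(rep(500, n_t))
  od <- intensity_to_od(const)
  expect_equal(max(abs(od$od)), 0)
  # I = mean * exp(-x) -> OD = x
  x <- seq(-0.2, 0.2, length.out = n_t)
  x <- x + log(mean(exp(-x)))  # shift so mean(exp(-x)) = 1, i.e. mean(I) = I0
  sc <- scan_from_matrix(exp(-x))
  expect_equal(intensity_to_od(sc)$od[1, 1, ], x, tolerance = 1e-12)
  bad <- scan_from_matrix(c(rep(10, 50), 0, rep(10, 49)))
  expect_error(intensity_to_od(bad), "channel 1 wavelength 1 sample 51")
})

test_that("Beer-Lambert forward and inverse are an exact round trip", {
  # known constant concentrations
  hbo <- matrix(1.0, 2, 50)
  hbr <- matrix(-0.5, 2, 50)
  od <- hb_to_od(hbo, hbr)
  hb <- od_to_hb(od, sampling_rate = 10)
  expect_equal(hb$hbo, hbo, tolerance = 1e-12)
  expect_equal(hb$hbr, hbr, tolerance = 1e-12)
  expect_equal(hb$hbt, hbo + hbr, tolerance = 1e-12)
  # zero OD -> zero concentrations
  z <- od_to_hb(array(0, c(3, 2, 10)), sampling_rate = 10)
  expect_equal(max(abs(z$hbo)), 0)
  # random time-varying concentrations, non-default constants
  set.seed(4)
  hbo2 <- matrix(rnorm(18 * 200), 18)
  hbr2 <- matrix(rnorm(18 * 200), 18)
  od2 <- hb_to_od(hbo2, hbr2, dpf = c(5.5, 6.5), distance = 2.8)
  hb2 <- od_to_hb(od2, dpf = c(5.5, 6.5), distance = 2.8, sampling_rate = 10)
  expect_equal(hb2$hbo, hbo2, tolerance = 1e-10)
  expect_equal(hb2$hbr, hbr2, tolerance = 1e-10)
})

test_that("band-pass meets its stopband and passband measurements", {
  fs <- 10
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)
  rms <- function(v) sqrt(mean(v^2))
  cardiac <- sin(2 * pi * 1.1 * tt)
  expect_lt(rms(fnirsgraph:::bandpass_vector(cardiac, fs)) / rms(cardiac), 0.01)
  resp <- sin(2 * pi * 0.3 * tt)
  expect_lt(rms(fnirsgraph:::bandpass_vector(resp, fs)) / rms(resp), 0.1)   # >= 20 dB
  mid <- sin(2 * pi * 0.04 * tt)
  expect_gt(rms(fnirsgraph:::bandpass_vector(mid, fs)) / rms(mid), 0.89)
  # < 1 dB ripple inside [0.02, 0.06] Hz
  for (f in c(0.02, 0.04, 0.06)) {
    s <- sin(2 * pi * f * tt)
    expect_gt(rms(fnirsgraph:::bandpass_vector(s, fs)) / rms(s), 10^(-1 / 20))
  }
  expect_equal(fnirsgraph:::bandpass_vector(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass(matrix(0, 1, 100), sampling_rate = 0.1), "config error")
})

test_that("motion detection flags steps with the documented mask extent", {
  fs <- 10
  p <- motion_params()
  x <- rep(0, 1200)
  x[601:1200] <- 10 * p$AMPthresh     # step at sample 601
  mask <- fnirsgraph:::detect_motion_vector(x, fs, p)
  k <- round(p$tMask * fs)
  win <- round(p$tMotion * fs)
  # everything within tMask of the transition must be flagged
  expect_true(all(mask[(601 - k):(600 + k)]))
  # far from the step (beyond tMask + tMotion) nothing is flagged
  expect_false(any(mask[1:(600 - k - win - 1)]))
  expect_false(any(mask[(601 + k + win):1200]))
  # constant signal -> empty mask
  expect_false(any(fnirsgraph:::detect_motion_vector(rep(5, 500), fs, p)))
})

test_that("motion detection reaches 95% sensitivity on injected artifacts", {
  spec <- cohort_spec(n_subjects = 4, duration = 300, sampling_rate = 10,
                      artifact_rate = 0, saturation_rate = 0, seed = 21)
  coh <- generate_cohort(spec)
  inj <- inject_motion(coh$scans[[1]], rate = 2, seed = 77)
  expect_gt(inj$n_events, 0)
  od <- intensity_to_od(inj$scan)
  mask <- detect_motion(od)
  sens <- sum(mask & inj$spike_mask) / sum(inj$spike_mask)
  expect_gte(sens, 0.95)
})

test_that("injected event counts follow the configured Poisson rate", {
  spec <- cohort_spec(n_subjects = 4, duration = 1800, sampling_rate = 4,
                      artifact_rate = 0, saturation_rate = 0, seed = 13)
  coh <- generate_cohort(spec)
  inj <- inject_motion(coh$scans[[1]], rate = 2, seed = 5)
  # rate 2/min over 30 min: mean 60; Poisson 99% interval
  expect_gte(inj$n_events, qpois(0.005, 60))
  expect_lte(inj$n_events, qpois(0.995, 60))
  # rate 0: unchanged scan, empty mask
  inj0 <- inject_motion(coh$scans[[2]], rate = 0, seed = 5)
  expect_identical(inj0$scan$intensity, coh$scans[[2]]$intensity)
  expect_false(any(inj0$mask))
})

test_that("motion correction is a near-identity without artifacts and removes steps", {
  fs <- 10
  set.seed(6)
  x <- rnorm(1024)
  # no mask, thresholding disabled: perfect reconstruction
  y <- correct_motion(x, rep(FALSE, 1024), iqr_factor = Inf,
                      sampling_rate = fs)
  expect_lt(max(abs(y - x)), 1e-10)
  # step artifact of amplitude A on a flat noisy signal
  A <- 5
  noise_sd <- 0.02
  x2 <- rnorm(2400, sd = noise_sd)
  x2[1201:2400] <- x2[1201:2400] + A
  mask <- fnirsgraph:::detect_motion_vector(x2, fs, motion_params())
  expect_true(any(mask))
  y2 <- correct_motion(x2, mask, sampling_rate = fs)
  residual_step <- abs(mean(y2[1301:2400]) - mean(y2[1:1100]))
  expect_lt(residual_step, 0.05 * A)
})

test_that("correcting a spike train restores the clean channel variability", {
  spec <- cohort_spec(n_subjects = 4, duration = 300, sampling_rate = 10,
                      artifact_rate = 0, saturation_rate = 0, seed = 31)
  coh <- generate_cohort(spec, keep_clean = TRUE)
  clean_scan <- coh$scans[[1]]
  inj <- inject_motion(clean_scan, rate = 3, seed = 8, p_spike = 1)
  od_clean <- intensity_to_od(clean_scan)
  od_dirty <- intensity_to_od(inj$scan)
  mask <- detect_motion(od_dirty)
  od_fixed <- correct_motion(od_dirty, mask)
  for (ch in c(1, 9, 18)) {
    sd_clean <- sd(od_clean$od[ch, 1, ])
    sd_fixed <- sd(od_fixed$od[ch, 1, ])
    expect_lt(abs(sd_fixed - sd_clean) / sd_clean, 0.2)
  }
})

test_that("channel quality computes CV and excludes noisy channels", {
  n_t <- 1000
  intensity <- array(1000, dim = c(18, 2, n_t))
  set.seed(3)
  intensity[2, 1, ] <- rnorm(n_t, 1000, 200)   # CV ~ 20% -> excluded
  intensity[5, 1, ] <- rnorm(n_t, 1000, 50)    # CV ~ 5% -> retained
  sc <- raw_scan("T", pmax(intensity, 1), 10)
  q <- channel_quality(sc)
  expect_true(2L %in% q$excluded_channels)
  expect_false(5L %in% q$excluded_channels)
  expect_equal(unname(q$cv[1, 1]), 0)
  expect_lt(abs(q$cv[2, 1] - 20), 2)
})

test_that("a planted unstable-gain subject is the one flagged by quality control", {
  spec <- cohort_spec(n_subjects = 5, duration = 300, sampling_rate = 5,
                      artifact_rate = 0, saturation_rate = 0, seed = 17,
                      unstable_gain_subjects = 3L)
  coh <- generate_cohort(spec)
  flagged <- which(vapply(coh$scans, function(s)
    length(channel_quality(s)$excluded_channels) > 0, TRUE))
  expect_identical(flagged, 3L)
})

test_that("preprocessing is deterministic and preserves the hbt identity", {
  spec <- cohort_spec(n_subjects = 4, duration = 120, sampling_rate = 10,
                      artifact_rate = 1, saturation_rate = 1, seed = 41)
  coh <- generate_cohort(spec)
  pp1 <- preprocess_scan(coh$scans[[1]])
  pp2 <- preprocess_scan(coh$scans[[1]])
  expect_identical(pp1$hb$hbo, pp2$hb$hbo)
  expect_lt(max(abs(pp1$hb$hbt - (pp1$hb$hbo + pp1$hb$hbr))), 1e-9)
})

test_that("filter-before-MBLL and MBLL-before-filter orders agree on linear stages", {
  spec <- cohort_spec(n_subjects = 4, duration = 300, sampling_rate = 10,
                      artifact_rate = 0, saturation_rate = 0, seed = 19)
  coh <- generate_cohort(spec)
  a <- preprocess_scan(coh$scans[[1]], order = "od_filter")
  b <- preprocess_scan(coh$scans[[1]], order = "hb_filter")
  expect_equal(a$hb$hbo, b$hb$hbo, tolerance = 1e-8)
})

test_that("preprocessing barely perturbs channel-pair correlations of clean slow signals", {
  # full 30-min study-length scan: pair-correlation estimates are then
  # precise enough to isolate preprocessing distortion from sampling noise
  spec <- cohort_spec(n_subjects = 4, duration = 1800, sampling_rate = 10,
                      artifact_rate = 0, saturation_rate = 0, seed = 23,
                      cardiac_amp = 0, resp_amp = 0, mayer_amp = 0)
  coh <- generate_cohort(spec, keep_clean = TRUE)
  pp <- preprocess_scan(coh$scans[[1]])
  # reference: the clean component restricted to the analysis band — the
  # signal the pipeline is supposed to pass through unchanged; its
  # out-of-band spectral skirts are not preservation targets
  clean_band <- t(apply(coh$truth$clean_hbo[[1]], 1,
                        fnirsgraph:::bandpass_vector, fs = 10))
  r_clean <- cor(t(clean_band))
  r_proc <- cor(t(pp$hb$hbo))
  off <- row(r_clean) != col(r_clean)
  expect_lt(max(abs(r_proc[off] - r_clean[off])), 0.02)
})
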