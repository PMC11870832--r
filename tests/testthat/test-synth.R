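test_that("fixed seeds reproduce every output bit", {
  spec <- cohort_spec(n_subjects = 4, duration = 60, sampling_rate = 5,
                      artifact_rate = 2, saturation_rate = 1, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$truth$density, b$truth$density)
  for (i in 1:4)
    expect_identical(a$scans[[i]]$intensity, b$scans[[i]]$intensity)
  spec2 <- cohort_spec(n_subjects = 4, duration = 60, sampling_rate = 5,
                       artifact_rate = 2, saturation_rate = 1, seed = 6)
  c_ <- generate_cohort(spec2)
  expect_false(identical(a$scans[[1]]$intensity, c_$scans[[1]]$intensity))
})

test_that("cohort spec invariants are enforced", {
  expect_error(cohort_spec(n_subjects = 3), "n_subjects")
  expect_error(cohort_spec(n_subjects = 10, target_brain_behavior_rho = 1),
               "rho")
  expect_error(cohort_spec(n_subjects = 10, artifact_rate = -1), "rates")
  expect_error(cohort_spec(n_subjects = 10, behavior_sd = 0,
                           target_brain_behavior_rho = -0.3), "config error")
  # rho = 0 with zero SD is fine
  expect_s3_class(cohort_spec(n_subjects = 10, behavior_sd = 0,
                              target_brain_behavior_rho = 0), "cohort_spec")
})

test_that("planted covariances are PSD with density equal to the off-diagonal mean", {
  spec <- cohort_spec(n_subjects = 8, seed = 2)
  truth <- draw_ground_truth(spec)
  for (i in 1:8) {
    s <- truth$covariance[, , i]
    expect_equal(s, t(s), tolerance = 1e-12)
    expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(unname(diag(s)), rep(1, 18), tolerance = 1e-12)
    off <- row(s) != col(s)
    expect_equal(mean(s[off]), truth$density[i], tolerance = 1e-12)
  }
})

test_that("a null cohort shows no density-score coupling beyond sampling noise", {
  spec <- cohort_spec(n_subjects = 4, duration = 30, sampling_rate = 5,
                      target_brain_behavior_rho = 0,
                      artifact_rate = 0, saturation_rate = 0, seed = 9)
  coh <- generate_cohort(spec)
  r <- cor(coh$truth$density, coh$behavior$rapm)
  expect_lt(abs(r), 0.9)  # n = 4: only a wide interval is meaningful
})

test_that("the planted density-score correlation is recovered at n = 116", {
  spec <- cohort_spec(n_subjects = 116, target_brain_behavior_rho = -0.33,
                      seed = 12)
  truth <- draw_ground_truth(spec)
  r <- cor(truth$density, truth$behavior$rapm)
  expect_lt(abs(r - (-0.33)), 0.18)  # 2 * SE at n = 116
})

test_that("saturation injection produces missing segments near the configured length", {
  spec <- cohort_spec(n_subjects = 6, duration = 120, sampling_rate = 10,
                      artifact_rate = 0, saturation_rate = 3,
                      saturation_mean_s = 2, seed = 14)
  coh <- generate_cohort(spec)
  nas <- vapply(coh$scans, function(s) sum(is.na(s$intensity)), 0)
  expect_gt(sum(nas), 0)
  seg_lengths <- unlist(lapply(coh$scans, function(s) {
    unlist(lapply(seq_len(18), function(ch) {
      r <- rle(is.na(s$intensity[ch, 1, ]))
      r$lengths[r$values]
    }))
  }))
  expect_gt(length(seg_lengths), 0)
  # exponential with mean 2 s at 10 Hz (floor 3 samples): mean within wide CI
  expect_lt(abs(mean(seg_lengths) / 10 - 2), 1.5)
})

test_that("FC of the generated neural component converges to the planted correlation", {
  spec <- cohort_spec(n_subjects = 4, duration = 1800, sampling_rate = 5,
                      artifact_rate = 0, saturation_rate = 0,
                      cardiac_amp = 0, resp_amp = 0, mayer_amp = 0, seed = 25)
  coh <- generate_cohort(spec, keep_clean = TRUE)
  for (i in 1:2) {
    r <- cor(t(coh$truth$clean_hbo[[i]]))
    planted <- coh$truth$covariance[, , i]
    off <- row(r) != col(r)
    expect_lt(mean(abs(r[off] - planted[off])), 0.1)
  }
})

test_that("higher planted density yields higher average degree through the full pipeline", {
  run_one <- function(lo, hi, seed) {
    spec <- cohort_spec(n_subjects = 4, duration = 300, sampling_rate = 5,
                        artifact_rate = 0, saturation_rate = 0,
                        density_range = c(lo, hi), seed = seed)
    coh <- generate_cohort(spec)
    mean(vapply(coh$scans, function(s) {
      pp <- preprocess_scan(s)
      average_degree(fisher_z(compute_fc(pp$hb, window_spec(5))))
    }, 0.0))
  }
  expect_gt(run_one(0.75, 0.85, 33), run_one(0.25, 0.35, 33))
})

test_that("the fast cohort simulator is deterministic and matches the design shape", {
  sim <- simulate_metric_cohort(n_subjects = 12, rho = -0.33, seed = 3)
  sim2 <- simulate_metric_cohort(n_subjects = 12, rho = -0.33, seed = 3)
  expect_identical(sim$metrics, sim2$metrics)
  expect_identical(nrow(sim$metrics), 12L * 11L * 6L)
  expect_identical(nrow(sim$behavior), 12L)
  # AD tracks planted density ordering across subjects
  ad30 <- sim$metrics$value[sim$metrics$metric == "AD" &
                              sim$metrics$window_end_min == 30]
  expect_gt(cor(ad30, sim$truth$density, method = "spearman"), 0.8)
})
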