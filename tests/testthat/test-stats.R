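test_that("partial correlation reduces to plain correlation under orthogonal covariates", {
  set.seed(1)
  n <- 200
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  # covariate orthogonal to both by construction (residualized)
  c0 <- rnorm(n)
  c_orth <- residuals(lm(c0 ~ x + y))
  pc <- partial_correlation(x, y, c_orth)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)
  # y = x exactly: r = 1 whatever the covariates
  pc2 <- partial_correlation(x, x, cbind(rnorm(n), rnorm(n)))
  expect_equal(pc2$r, 1, tolerance = 1e-12)
})

test_that("partial correlation matches hand-residualized and precision-matrix oracles", {
  # 6-point dataset, one covariate; oracle = explicit two-regression route
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  y <- c(2.1, 2.9, 4.2, 3.8, 5.1, 6.3)
  cv <- c(0.5, 1.5, 1.0, 2.5, 2.0, 3.0)
  rx <- residuals(lm(x ~ cv))
  ry <- residuals(lm(y ~ cv))
  oracle_r <- cor(rx, ry)
  pc <- partial_correlation(x, y, cv)
  expect_equal(pc$r, oracle_r, tolerance = 1e-10)
  expect_identical(pc$df, 3L)  # n - k - 2 = 6 - 1 - 2
  expect_equal(pc$p, 2 * pt(-abs(oracle_r * sqrt(3 / (1 - oracle_r^2))), 3),
               tolerance = 1e-12)
  # precision-matrix formulation on a larger random problem
  set.seed(7)
  n <- 120
  covs <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  x2 <- rnorm(n) + 0.3 * covs[, 1]
  y2 <- 0.4 * x2 + rnorm(n) - 0.2 * covs[, 2]
  expect_equal(partial_correlation(x2, y2, covs)$r,
               precision_partial_cor(x2, y2, covs), tolerance = 1e-10)
})

test_that("partial correlation is invariant to affine recoding of covariates", {
  set.seed(3)
  n <- 80
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- rnorm(n, 20, 2)
  x <- rnorm(n) + (sex == "male") * 0.5
  y <- rnorm(n) + 0.2 * age
  a <- partial_correlation(x, y, data.frame(age, sex))
  recoded <- data.frame(age = 3 * age - 10,
                        sex = ifelse(sex == "male", -5, 7))
  b <- partial_correlation(x, y, recoded)
  expect_equal(a$r, b$r, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("degenerate stats inputs are refused with explicit errors", {
  x <- rnorm(10)
  expect_error(partial_correlation(x, rnorm(10), cbind(1:10, 2 * (1:10))),
               "rank-deficient")
  expect_error(partial_correlation(x[1:3], rnorm(3), rnorm(3)),
               "insufficient sample")
  expect_error(partial_correlation(x, rep(2, 10), rnorm(10)),
               "undefined correlation")
})

test_that("the association table covers the full 66-cell design", {
  sim <- simulate_metric_cohort(n_subjects = 30, rho = -0.33, seed = 21)
  tab <- brain_behavior_table(sim$metrics, sim$behavior)
  expect_identical(nrow(tab), 66L)
  expect_identical(sum(tab$metric == "AD"), 11L)
  expect_identical(sum(tab$metric == "Eglob"), 55L)
  expect_true(all(tab$n == 30))
  # AD and mid/high-threshold Eglob cells are informative; saturated cells
  # (efficiency pinned at 1) are reported as NA, never silently dropped
  expect_true(all(!is.na(tab$partial_r[tab$metric == "AD"])))
  ok <- !is.na(tab$partial_r)
  expect_true(all(abs(tab$partial_r[ok]) <= 1))
  expect_true(all(tab$p_value[ok] > 0 & tab$p_value[ok] <= 1))
  expect_identical(attr(tab, "sex_coding"), "female=0, male=1")
})

test_that("unmatched subjects are excluded with a warning; tiny cohorts refused", {
  sim <- simulate_metric_cohort(n_subjects = 12, rho = 0, windows = 30,
                                seed = 5)
  metrics <- sim$metrics
  metrics$subject_id[metrics$subject_id == "S001"] <- "GHOST"
  expect_warning(tab <- brain_behavior_table(metrics, sim$behavior), "GHOST")
  expect_true(all(tab$n == 11))
  sim_small <- simulate_metric_cohort(n_subjects = 8, rho = 0, windows = 30,
                                      seed = 6)
  expect_error(brain_behavior_table(sim_small$metrics, sim_small$behavior),
               "refusing")
})

test_that("planted brain-behavior coupling is recovered without material bias", {
  # moderate replicate count: bias check on the AD cell at 30 min
  rs <- vapply(1:40, function(s) {
    sim <- simulate_metric_cohort(n_subjects = 116, rho = -0.33,
                                  windows = 30, seed = 1000 + s)
    tab <- brain_behavior_table(sim$metrics, sim$behavior)
    tab$partial_r[tab$metric == "AD"]
  }, 0.0)
  expect_lt(abs(mean(rs) - (-0.33)), 0.05)
})
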