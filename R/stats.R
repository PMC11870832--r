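#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on an intercept plus the covariate columns. The two-sided
#' p-value comes from `t = r * sqrt((n - k - 2) / (1 - r^2))` on
#' `n - k - 2` degrees of freedom, with k the number of covariates.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix or data.frame (n rows); character or
#'   factor columns are converted to numeric codes (invariance to affine
#'   recoding is a tested property).
#' @return list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates) {
  cov_m <- covariate_matrix(covariates)
  n <- length(x)
  if (length(y) != n || nrow(cov_m) != n)
    stop("x, y and covariates must have the same number of observations")
  k <- ncol(cov_m)
  if (n <= k + 2) stop("insufficient sample: need n > number of covariates + 2")
  X <- cbind(1, cov_m)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient covariate matrix")
  rx <- stats::residuals(stats::lm.fit(X, x))
  ry <- stats::residuals(stats::lm.fit(X, y))
  tol_x <- 1e-10 * max(stats::sd(x), 1)
  tol_y <- 1e-10 * max(stats::sd(y), 1)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y)
    stop("undefined correlation: constant residuals after covariate adjustment")
  r <- stats::cor(rx, ry)
  df <- as.integer(n - k - 2)
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, n = n, df = df)
}

# Coerce covariates to a numeric matrix; sex-style character/factor
# columns become 0/1 codes (first level alphabetically = 0; "female" = 0
# under the default labels).
covariate_matrix <- function(covariates) {
  if (is.null(dim(covariates))) covariates <- data.frame(cov = covariates)
  covariates <- as.data.frame(covariates)
  m <- vapply(covariates, function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    as.numeric(factor(col)) - 1
  }, numeric(nrow(covariates)))
  if (is.null(dim(m))) m <- matrix(m, ncol = ncol(covariates))
  m
}

#' Brain-behavior association table
#'
#' Partial correlations (controlling for age and sex; sex coded female = 0,
#' male = 1) between the behavior score and every graph-metric cell:
#' average degree per window, and global efficiency per window and
#' binarization threshold. For the full 11-window, 5-threshold design this
#' is 11 + 55 = 66 rows. No multiple-testing correction is applied; all
#' raw two-sided p-values are reported.
#'
#' @param metrics long data.frame from [metrics_for_subject()] /
#'   [simulate_metric_cohort()] (columns subject_id, window_end_min,
#'   metric, threshold, value).
#' @param behavior data.frame with subject_id, age, sex, rapm.
#' @param covariates covariate column names in `behavior`.
#' @param min_n refuse to test with fewer matched subjects than this.
#' @return data.frame: metric, threshold, window_end_min, partial_r,
#'   p_value, n, covariates.
#' @export
brain_behavior_table <- function(metrics, behavior,
                                 covariates = c("age", "sex"),
                                 min_n = 10L) {
  unmatched <- setdiff(unique(metrics$subject_id), behavior$subject_id)
  if (length(unmatched)) {
    warning("excluding subject(s) without behavior rows: ",
            paste(unmatched, collapse = ", "))
    metrics <- metrics[!metrics$subject_id %in% unmatched, ]
  }
  cells <- unique(metrics[, c("metric", "threshold", "window_end_min")])
  cells <- cells[order(cells$metric, cells$threshold, cells$window_end_min), ]
  rows <- lapply(seq_len(nrow(cells)), function(j) {
    cell <- cells[j, ]
    sel <- metrics$metric == cell$metric &
      metrics$window_end_min == cell$window_end_min &
      (if (is.na(cell$threshold)) is.na(metrics$threshold)
       else !is.na(metrics$threshold) & metrics$threshold == cell$threshold)
    sub <- metrics[sel, c("subject_id", "value")]
    idx <- match(sub$subject_id, behavior$subject_id)
    ok <- !is.na(idx)
    sub <- sub[ok, ]; idx <- idx[ok]
    if (nrow(sub) < min_n)
      stop(sprintf("refusing to test %s window %g: only %d matched subjects (< %d)",
                   cell$metric, cell$window_end_min, nrow(sub), min_n))
    # a metric that is constant across the cohort (e.g. global efficiency
    # saturated at 1 below the lowest informative threshold) has no defined
    # correlation; report the cell as NA instead of aborting the table
    pc <- tryCatch(
      partial_correlation(sub$value, behavior$rapm[idx],
                          behavior[idx, covariates, drop = FALSE]),
      error = function(e) {
        if (grepl("undefined correlation", conditionMessage(e)))
          return(list(r = NA_real_, p = NA_real_, n = nrow(sub)))
        stop(e)
      })
    data.frame(metric = cell$metric, threshold = cell$threshold,
               window_end_min = cell$window_end_min,
               partial_r = pc$r, p_value = pc$p, n = pc$n,
               covariates = paste(covariates, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "sex_coding") <- "female=0, male=1"
  out
}
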