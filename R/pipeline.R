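#' Assemble a validated end-to-end run configuration
#'
#' Collects every tunable of the pipeline in one object: input/output
#' paths (or an inline synthetic [cohort_spec()]), preprocessing
#' parameters, graph parameters, the cumulative-window list, covariates,
#' and the master seed. Window and threshold lists must be subsets of the
#' canonical design (11 windows, thresholds 0.1-0.5). Every parameter is
#' echoed verbatim into the run log and manifest.
#'
#' @param output_dir directory for the CSV artifacts.
#' @param input_dir directory of scan files plus `behavior.csv`; `NULL`
#'   when `synth` is given.
#' @param synth optional [cohort_spec()] to generate the cohort in-run.
#' @param windows cumulative window ends (minutes), subset of
#'   [canonical_windows()].
#' @param thresholds binarization thresholds, subset of 0.1-0.5.
#' @param motion a [motion_params()].
#' @param band band-pass edges in Hz.
#' @param dpf,distance,cv_threshold,wavelet_levels,iqr_factor,order
#'   see [preprocess_scan()].
#' @param ad_on,bin_on matrix choice for average degree / binarization.
#' @param covariates covariate columns for the partial correlations.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       input_dir = NULL,
                       synth = NULL,
                       windows = canonical_windows(),
                       thresholds = seq(0.1, 0.5, by = 0.1),
                       motion = motion_params(),
                       band = c(0.01, 0.08),
                       dpf = c(6, 6), distance = 3,
                       cv_threshold = 15,
                       wavelet_levels = 4L, iqr_factor = 1.5,
                       order = "od_filter",
                       ad_on = "z", bin_on = "r",
                       covariates = c("age", "sex"),
                       seed = 1L) {
  if (!all(windows %in% canonical_windows()))
    stop("windows must be a subset of the 11 canonical windows")
  near <- function(x, set) vapply(x, function(v) any(abs(v - set) < 1e-9), TRUE)
  if (!all(near(thresholds, seq(0.1, 0.5, by = 0.1))))
    stop("thresholds must be a subset of {0.1, 0.2, 0.3, 0.4, 0.5}")
  if (is.null(input_dir) && is.null(synth))
    stop("either input_dir or a synthetic cohort_spec is required")
  cfg <- list(output_dir = output_dir, input_dir = input_dir, synth = synth,
              windows = windows, thresholds = thresholds, motion = motion,
              band = band, dpf = dpf, distance = distance,
              cv_threshold = cv_threshold, wavelet_levels = wavelet_levels,
              iqr_factor = iqr_factor, order = order, ad_on = ad_on,
              bin_on = bin_on, covariates = covariates, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

# Plain-list view of the config for the JSON manifest.
config_echo <- function(cfg) {
  flat <- unclass(cfg)
  if (!is.null(flat$synth)) flat$synth <- unclass(flat$synth)
  flat$motion <- unclass(flat$motion)
  flat
}

#' Run the full pipeline end to end
#'
#' Stages: optional synthetic-cohort generation, per-subject
#' preprocessing, windowed FC, graph metrics, cohort trajectories,
#' window-vs-full consistency, and the brain-behavior association table.
#' Writes CSV artifacts plus `manifest.json` listing every file with its
#' MD5 checksum and the full configuration echo; reruns under the same
#' config and seed are bit-identical. A stage failure aborts with the
#' stage and subject named, leaving partial outputs beside a `FAILED`
#' marker file.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return Invisibly, a list with the in-memory results (`metrics`,
#'   `associations`, `trajectories`, `consistency`, `quality`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "load"
  fail <- function(e, subject = NA) {
    writeLines(sprintf("stage=%s subject=%s error=%s", stage, subject,
                       conditionMessage(e)),
               file.path(config$output_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s' (subject %s): %s",
                 stage, subject, conditionMessage(e)), call. = FALSE)
  }
  if (!is.null(config$synth)) {
    stage <- "synth"
    say("generating synthetic cohort (n = %d)", config$synth$n_subjects)
    cohort <- tryCatch(generate_cohort(config$synth), error = fail)
    scans <- cohort$scans
    behavior <- cohort$behavior
    write_behavior(behavior, file.path(config$output_dir, "behavior.csv"))
    utils::write.csv(
      data.frame(subject_id = behavior$subject_id,
                 density = cohort$truth$density),
      file.path(config$output_dir, "ground_truth.csv"), row.names = FALSE)
  } else {
    stage <- "load"
    behavior <- read_behavior(file.path(config$input_dir, "behavior.csv"))
    paths <- file.path(config$input_dir,
                       paste0(behavior$subject_id, ".scan.csv"))
    scans <- lapply(paths, function(p) tryCatch(read_scan(p), error = fail))
  }
  all_metrics <- vector("list", length(scans))
  quality <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    sid <- scans[[i]]$subject_id
    stage <- "preprocess"
    say("preprocess %s", sid)
    pp <- tryCatch(
      preprocess_scan(scans[[i]], params = config$motion, band = config$band,
                      dpf = config$dpf, distance = config$distance,
                      cv_threshold = config$cv_threshold,
                      wavelet_levels = config$wavelet_levels,
                      iqr_factor = config$iqr_factor, order = config$order),
      error = function(e) fail(e, sid))
    quality[[i]] <- data.frame(
      subject_id = sid,
      excluded_channels = paste(pp$quality$excluded_channels, collapse = ";"),
      nan_segments = pp$quality$nan_segment_count,
      motion_fraction = pp$quality$motion_fraction,
      stringsAsFactors = FALSE)
    stage <- "fc"
    fcs <- tryCatch(
      fc_by_windows(pp$hb, windows = config$windows, subject_id = sid),
      error = function(e) fail(e, sid))
    stage <- "graph"
    all_metrics[[i]] <- tryCatch(
      metrics_for_subject(fcs, thresholds = config$thresholds,
                          ad_on = config$ad_on, bin_on = config$bin_on),
      error = function(e) fail(e, sid))
  }
  metrics <- do.call(rbind, c(all_metrics, list(make.row.names = FALSE)))
  quality <- do.call(rbind, c(quality, list(make.row.names = FALSE)))

  stage <- "stability"
  traj <- list(metric_trajectory(metrics, "AD"))
  cons <- list(window_consistency(metrics, behavior, "AD",
                                  covariates = config$covariates))
  for (tau in config$thresholds) {
    traj <- c(traj, list(cbind(metric_trajectory(metrics, "Eglob", tau),
                               threshold = tau)))
    cons <- c(cons, list(window_consistency(metrics, behavior, "Eglob", tau,
                                            covariates = config$covariates)))
  }
  traj[[1]] <- cbind(traj[[1]], threshold = NA_real_)
  trajectories <- do.call(rbind, c(traj, list(make.row.names = FALSE)))
  consistency <- do.call(rbind, c(cons, list(make.row.names = FALSE)))

  stage <- "associate"
  associations <- tryCatch(
    brain_behavior_table(metrics, behavior, covariates = config$covariates),
    error = fail)

  stage <- "report"
  outputs <- list(metrics = metrics, quality = quality,
                  trajectories = trajectories, consistency = consistency,
                  associations = associations)
  files <- character(0)
  for (nm in names(outputs)) {
    f <- file.path(config$output_dir, paste0(nm, ".csv"))
    utils::write.csv(outputs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(config$synth))
    files <- c(files, file.path(config$output_dir, "behavior.csv"),
               file.path(config$output_dir, "ground_truth.csv"))
  manifest <- list(
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(md5 = unname(tools::md5sum(f)))),
    config = config_echo(config))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unlink(file.path(config$output_dir, "FAILED"))
  invisible(c(outputs, list(manifest_path = manifest_path)))
}
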