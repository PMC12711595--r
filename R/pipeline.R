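#' Mean playback sound pressure level (midpoint of a calibrated range)
#'
#' Playback amplitudes fluctuate within an exemplar (propeller
#' acceleration, engine rhythm, speech dynamics); the reported mean
#' playback SPL is the midpoint of the measured calibration range, rounded
#' to the nearest whole decibel (half up).
#'
#' @param range_low_db,range_high_db Lower/upper SPL of the measured range
#'   (dB), vectorized; `low <= high`.
#' @return Midpoint SPL in whole dB.
#' @export
#' @examples
#' spl_midpoint(68, 78)  # 73
spl_midpoint <- function(range_low_db, range_high_db) {
  if (any(range_low_db > range_high_db)) {
    stop("range_low_db must not exceed range_high_db")
  }
  floor((range_low_db + range_high_db) / 2 + 0.5)
}

#' The calibrated playback SPL table
#'
#' Reads the packaged playback sound-pressure-level calibration ranges per
#' stimulus type and adds the midpoint column via [spl_midpoint()].
#'
#' @return Data.frame with `stimulus`, `spl_low_db`, `spl_high_db`,
#'   `spl_mid_db`.
#' @export
playback_spl_table <- function() {
  tab <- utils::read.csv(system.file("extdata", "playback_spl.csv",
                                     package = "vigilr", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  tab$spl_mid_db <- spl_midpoint(tab$spl_low_db, tab$spl_high_db)
  tab
}

#' Descriptive duration summaries per site x stimulus cell
#'
#' @param features Per-trial features with `duration_s`.
#' @param trials Trial metadata with `site` and `stimulus`.
#' @return Data.frame with one row per observed site x stimulus cell:
#'   `site`, `stimulus`, `n`, `mean_s`, `sd_s` (sample SD, n - 1; 0 with a
#'   warning for singleton cells), sorted by site then stimulus.
#' @export
summarize_durations <- function(features, trials) {
  idx <- match(trials$trial_id, features$trial_id)
  stopifnot(!anyNA(idx))
  dur <- features$duration_s[idx]
  cells <- split(dur, list(site = trials$site, stimulus = trials$stimulus),
                 drop = TRUE)
  singletons <- sum(lengths(cells) == 1)
  if (singletons > 0) {
    warning(singletons, " singleton cell(s): SD reported as 0")
  }
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    v <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(site = parts[1], stimulus = parts[2], n = length(v),
               mean_s = mean(v),
               sd_s = if (length(v) > 1) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  out[order(out$site, out$stimulus), , drop = FALSE]
}

#' Run configuration for the full pipeline
#'
#' @param events_path,trials_path Input CSVs (event log, trial metadata);
#'   `events_path` may be `NULL` when `features_path` supplies pre-scored
#'   features.
#' @param features_path Optional pre-computed feature CSV (used instead of
#'   scoring events).
#' @param out_dir Output directory (created if missing).
#' @param response `"reaction_intensity"` or `"duration_s"`.
#' @param seed Integer seed recorded in every output and used for the
#'   sampler.
#' @param weights A [weight_params()].
#' @param match A [match_config()].
#' @param model A [model_spec()] (its seed is overridden by `seed`).
#' @param window_s Analysis window (s).
#' @return An object of class `run_config`.
#' @export
run_config <- function(events_path = NULL, trials_path, out_dir,
                       features_path = NULL,
                       response = "reaction_intensity", seed = 1,
                       weights = weight_params(), match = match_config(),
                       model = model_spec(), window_s = 180) {
  if (is.null(events_path) && is.null(features_path)) {
    stop("either events_path or features_path is required")
  }
  for (p in c(events_path, trials_path, features_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(events_path = events_path, trials_path = trials_path,
                 features_path = features_path, out_dir = out_dir,
                 response = response, seed = as.integer(seed),
                 weights = weights, match = match, model = model,
                 window_s = window_s),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `events_path`, `trials_path`, `features_path`,
#' `out_dir`, `response`, `seed`, `window_s`, nested `weights`
#' (`center_s`, `steepness`), `match` (`date_weight`, `within_individual`,
#' `replacement`), and `model` (`chains`, `iter`, `warmup`).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  wp <- do.call(weight_params, y$weights %||% list())
  mc <- do.call(match_config, y$match %||% list())
  ms <- do.call(model_spec, y$model %||% list())
  run_config(events_path = y$events_path, trials_path = y$trials_path,
             features_path = y$features_path, out_dir = y$out_dir,
             response = y$response %||% "reaction_intensity",
             seed = y$seed %||% 1, weights = wp, match = mc, model = ms,
             window_s = y$window_s %||% 180)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full playback-vigilance analysis
#'
#' Orchestrates every stage: ingest and filter trials, score behavioral
#' features (or load pre-scored features), build the design, fit the raw
#' Bayesian interaction model, compute the contrast table and
#' partial-dependence predictions, match anthropogenic trials to
#' same-individual dove controls, fit the matched difference-score model,
#' and write all tabular outputs plus a manifest (input hashes, seed,
#' package version) to the output directory. All non-MCMC outputs are pure
#' functions of the inputs; MCMC outputs are reproducible given the seed.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with `features`, `summary` (posterior
#'   summaries), `contrasts`, `partial_dependence`, `pairs`, `unmatched`,
#'   `matched_effects`, `duration_summary`, `excluded`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  trials <- read_trials(config$trials_path)
  flt <- apply_trial_filters(trials)
  trials <- flt$included

  if (!is.null(config$features_path)) {
    features <- utils::read.csv(config$features_path,
                                stringsAsFactors = FALSE)
  } else {
    events <- read_events(config$events_path)
    features <- score_trials(events, trial_ids = trials$trial_id,
                             params = config$weights,
                             window_s = config$window_s)
  }

  design <- build_design(trials, features, response = config$response)
  spec <- config$model
  spec$seed <- config$seed
  fit <- fit_lmm(design, spec = spec)
  ctab <- contrast_table(fit)
  pd <- partial_dependence(fit)

  matching <- match_controls(trials, config$match)
  pairs <- difference_scores(matching$pairs, features)
  matched <- fit_matched_model(pairs, trials, spec = spec)
  dursum <- summarize_durations(features, trials)

  outputs <- list(features = features, excluded = flt$excluded,
                  summary = fit$summary, contrasts = ctab,
                  partial_dependence = pd, pairs = pairs,
                  unmatched = matching$unmatched,
                  matched_effects = matched$effects,
                  duration_summary = dursum)
  paths <- character(0)
  for (nm in names(outputs)) {
    p <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(outputs[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  inputs <- c(config$events_path, config$trials_path, config$features_path)
  manifest <- list(
    seed = config$seed,
    response = config$response,
    package_version = as.character(utils::packageVersion("vigilr")),
    inputs = as.list(stats::setNames(as.character(tools::md5sum(inputs)),
                                     basename(inputs))),
    outputs = as.list(stats::setNames(as.character(tools::md5sum(paths)),
                                      names(paths))),
    n_trials = nrow(trials), n_excluded = nrow(flt$excluded),
    n_pairs = nrow(pairs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- manifest
  outputs$fit <- fit
  outputs$matched_fit <- matched$fit
  invisible(outputs)
}
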