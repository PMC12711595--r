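#' Configuration of the synthetic playback study
#'
#' Describes the simulated study design and its ground truth. Defaults
#' emulate the field design: three sites along a human-exposure gradient
#' with 19/10/4 focal individuals (low/moderate/high exposure), four
#' stimulus types (dove control plus drone, vehicle, talking) with 8
#' exemplars each, repeated sessions per individual in which a dove control
#' and one anthropogenic stimulus are both presented (guaranteeing
#' same-individual controls for matching), 1--3 co-observed individuals
#' sharing each playback event, speaker distances uniform on the 30--100 m
#' inclusion window, wind uniform on 0--25 km/h (the trial cutoff), and
#' group sizes of 1--15. The ground-truth anthropogenic effects follow the
#' habituation gradient: strong at the low-exposure site (drone +4.3,
#' vehicle +5.3, talking +1.9), moderate (~+1) at the moderate-exposure
#' site, and near zero (~+0.3) at the high-exposure site.
#'
#' @param individuals_per_site Named counts for
#'   low/moderate/high_exposure sites.
#' @param sessions_per_individual Sessions per focal animal; each session
#'   yields one dove and one anthropogenic trial. Default 7 (~460 trials).
#' @param exemplars_per_stimulus Exemplars rotated per stimulus type.
#' @param intercept Expected dove-control response at the low-exposure
#'   site for an adult female at covariate means.
#' @param site_effects Additive site shifts of the control response.
#' @param sound_effects 3 x 3 matrix (site x sound) of ground-truth
#'   anthropogenic effects relative to dove within each site.
#' @param beta_group,beta_wind,beta_dist,beta_dist2,beta_date Ground-truth
#'   coefficients on the standardized covariates.
#' @param sd_giraffe,sd_event,sd_exemplar,sd_resid Variance-component SDs.
#' @param window_s Analysis window (s) used for event-stream generation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(individuals_per_site = c(low_exposure = 19,
                                                moderate_exposure = 10,
                                                high_exposure = 4),
                       sessions_per_individual = 7,
                       exemplars_per_stimulus = 8,
                       intercept = 3,
                       site_effects = c(low_exposure = 0,
                                        moderate_exposure = -0.2,
                                        high_exposure = -0.4),
                       sound_effects = default_sound_effects(),
                       beta_group = -0.17, beta_wind = 0.05,
                       beta_dist = -0.8, beta_dist2 = 0.15, beta_date = 0,
                       sd_giraffe = 0.5, sd_event = 0.4, sd_exemplar = 0.3,
                       sd_resid = 1.5, window_s = 180) {
  stopifnot(all(individuals_per_site >= 1), sessions_per_individual >= 1,
            all(c(sd_giraffe, sd_event, sd_exemplar, sd_resid) >= 0))
  structure(list(individuals_per_site = individuals_per_site,
                 sessions_per_individual = sessions_per_individual,
                 exemplars_per_stimulus = exemplars_per_stimulus,
                 intercept = intercept, site_effects = site_effects,
                 sound_effects = sound_effects,
                 beta_group = beta_group, beta_wind = beta_wind,
                 beta_dist = beta_dist, beta_dist2 = beta_dist2,
                 beta_date = beta_date,
                 sd_giraffe = sd_giraffe, sd_event = sd_event,
                 sd_exemplar = sd_exemplar, sd_resid = sd_resid,
                 window_s = window_s),
            class = "sim_config")
}

#' Default ground-truth sound x site effect pattern
#'
#' @return 3 x 3 matrix, rows = sites, columns = anthropogenic sounds.
#' @export
default_sound_effects <- function() {
  matrix(c(4.3, 5.3, 1.9,
           1.1, 0.9, 1.3,
           0.4, 0.2, 0.3),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("low_exposure", "moderate_exposure",
                           "high_exposure"),
                         c("drone", "vehicle", "talking")))
}

#' A null configuration with no sound effects
#'
#' @param ... Passed to [sim_config()].
#' @return A `sim_config` whose sound x site effects are all zero.
#' @export
null_sim_config <- function(...) {
  cfg <- sim_config(...)
  cfg$sound_effects[] <- 0
  cfg
}

#' Simulate a trial table with known ground truth
#'
#' Generates trial metadata and response features from the crossed
#' random-effects model the analysis assumes: the response is the fixed
#' linear predictor (site, sound x site, standardized covariates) plus
#' giraffe, playback-event and exemplar intercepts plus Gaussian residual
#' noise, clamped to the \[0, 12\] score range. Individuals within a site
#' are grouped 1--3 per playback event so co-observed animals share event
#' effects; each session presents a dove control and one anthropogenic
#' stimulus to the same group on the same date, in randomized order.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return List with `trials` (metadata table accepted by the ingest
#'   module), `features` (per-trial `reaction_intensity`, `duration_s`,
#'   `latency_first_s`, `category`), and `truth` (the generating
#'   parameters, per-trial latent means, realized random effects, and the
#'   clamped-response fraction).
#' @export
simulate_trials <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  sites <- names(config$individuals_per_site)
  anthro <- colnames(config$sound_effects)
  stimuli <- c("dove", anthro)
  ex_ids <- lapply(stats::setNames(stimuli, stimuli), function(s)
    sprintf("%s_ex%02d", s, seq_len(config$exemplars_per_stimulus)))

  giraffes <- do.call(rbind, lapply(sites, function(st) {
    n <- config$individuals_per_site[[st]]
    data.frame(giraffe_id = sprintf("%s_G%02d", toupper(substr(st, 1, 3)),
                                    seq_len(n)),
               site = st,
               sex = sample(c("female", "male"), n, replace = TRUE),
               age_class = sample(c("adult", "subadult"), n, replace = TRUE,
                                  prob = c(0.75, 0.25)),
               stringsAsFactors = FALSE)
  }))

  rows <- list()
  event_counter <- 0
  for (st in sites) {
    ids <- giraffes$giraffe_id[giraffes$site == st]
    for (sess in seq_len(config$sessions_per_individual)) {
      pool <- sample(ids)
      while (length(pool) > 0) {
        gsize <- min(sample(1:3, 1), length(pool))
        grp <- pool[seq_len(gsize)]
        pool <- setdiff(pool, grp)
        day <- sample(0:335, 1)
        test_stim <- sample(anthro, 1)
        order_first <- sample(c("dove", test_stim))
        wind <- stats::runif(1, 0, 25)
        group_size <- sample(1:15, 1)
        for (stim in order_first) {
          event_counter <- event_counter + 1
          ev_id <- sprintf("V%04d", event_counter)
          exemplar <- sample(ex_ids[[stim]], 1)
          for (g in grp) {
            rows[[length(rows) + 1]] <- data.frame(
              giraffe_id = g, playback_event_id = ev_id,
              exemplar_id = exemplar, stimulus = stim, site = st,
              date = as.Date("2023-07-01") + day,
              speaker_distance_m = stats::runif(1, 30, 100),
              wind_speed_kmh = wind, group_size = group_size,
              order_in_session = if (stim == order_first[1]) "first" else "second",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  trials$trial_id <- sprintf("T%04d", seq_len(nrow(trials)))
  trials$sex <- giraffes$sex[match(trials$giraffe_id, giraffes$giraffe_id)]
  trials$age_class <- giraffes$age_class[match(trials$giraffe_id,
                                               giraffes$giraffe_id)]
  trials$disturbance_look_s <- 0
  trials$moved_from_disturbance <- FALSE
  trials <- trials[, c("trial_id", "giraffe_id", "playback_event_id",
                       "exemplar_id", "stimulus", "site", "date",
                       "speaker_distance_m", "wind_speed_kmh", "group_size",
                       "sex", "age_class", "order_in_session",
                       "disturbance_look_s", "moved_from_disturbance")]

  # ground-truth linear predictor on the pooled standardized covariates
  gz <- suppressWarnings(zscore(trials$group_size))
  wz <- suppressWarnings(zscore(trials$wind_speed_kmh))
  dz <- suppressWarnings(zscore(trials$speaker_distance_m))
  datez <- suppressWarnings(zscore(as.numeric(trials$date -
                                                min(trials$date))))
  eff <- rep(0, nrow(trials))
  is_anthro <- trials$stimulus != "dove"
  eff[is_anthro] <- config$sound_effects[cbind(trials$site[is_anthro],
                                               trials$stimulus[is_anthro])]
  lp <- config$intercept + config$site_effects[trials$site] + eff +
    config$beta_group * gz + config$beta_wind * wz +
    config$beta_dist * dz + config$beta_dist2 * dz^2 +
    config$beta_date * datez

  u_g <- stats::rnorm(nrow(giraffes), 0, config$sd_giraffe)
  names(u_g) <- giraffes$giraffe_id
  events_all <- unique(trials$playback_event_id)
  u_e <- stats::rnorm(length(events_all), 0, config$sd_event)
  names(u_e) <- events_all
  ex_all <- unlist(ex_ids, use.names = FALSE)
  u_x <- stats::rnorm(length(ex_all), 0, config$sd_exemplar)
  names(u_x) <- ex_all

  latent <- lp + u_g[trials$giraffe_id] + u_e[trials$playback_event_id] +
    u_x[trials$exemplar_id] +
    stats::rnorm(nrow(trials), 0, config$sd_resid)
  y <- pmin(pmax(latent, 0), 12)
  clamp_frac <- mean(latent < 0 | latent > 12)

  # descriptive companions to the intensity (rough monotone relations)
  duration <- round(pmax(0, y * 4 + stats::rnorm(nrow(trials), 0, 6)))
  duration <- pmin(duration, config$window_s)
  latency <- ifelse(y >= 0.5, stats::runif(nrow(trials), 0, 3), NA)
  features <- data.frame(trial_id = trials$trial_id,
                         latency_first_s = floor(latency),
                         duration_s = duration,
                         reaction_intensity = y,
                         category = categorize(y),
                         stringsAsFactors = FALSE)
  truth <- list(config = config, seed = seed,
                linear_predictor = stats::setNames(as.numeric(lp),
                                                   trials$trial_id),
                u_giraffe = u_g, u_event = u_e, u_exemplar = u_x,
                clamp_fraction = clamp_frac)
  list(trials = trials, features = features, truth = truth)
}

#' Simulate a behavior event stream realizing a latent reaction intensity
#'
#' Constructs 1--3 distinct ethogram behaviors (plus a maintenance
#' behavior) whose intensities and latencies are chosen so that the
#' scoring pipeline (one-zero sampling, first-three-distinct extraction,
#' logistic time-weighting) recovers the latent intensity to within about
#' half a score point: the score-carrying behavior has intensity
#' `floor(latent + 0.5)` and an onset in the full-weight region
#' (< 3 s), and any additional behaviors have strictly lower intensity so
#' they cannot overtake the maximum.
#'
#' @param latent_intensity Real in \[0, 12\].
#' @param trial_id Trial id stamped on the events.
#' @param config A [sim_config()] (for the window length).
#' @param ethogram Intensity map used to pick representative codes.
#' @return Data.frame of events (`trial_id`, `behavior_code`, `onset_s`,
#'   `offset_s`).
#' @export
simulate_event_stream <- function(latent_intensity, trial_id = "T1",
                                  config = sim_config(),
                                  ethogram = default_ethogram()) {
  stopifnot(latent_intensity >= 0, latent_intensity <= 12)
  code_for <- function(i) names(ethogram)[match(i, ethogram)]
  win <- config$window_s
  feed <- data.frame(trial_id = trial_id,
                     behavior_code = code_for(0),
                     onset_s = 0, offset_s = win,
                     stringsAsFactors = FALSE)
  if (latent_intensity < 0.5) return(feed)
  main_i <- min(max(floor(latent_intensity + 0.5), 1), 12)
  onset <- stats::runif(1, 0, 2.9)
  main <- data.frame(trial_id = trial_id,
                     behavior_code = code_for(main_i),
                     onset_s = onset,
                     offset_s = onset + stats::runif(1, 2, 20),
                     stringsAsFactors = FALSE)
  extras <- NULL
  n_extra <- sample(0:2, 1)
  if (n_extra > 0 && main_i > 1) {
    lower <- sample(seq_len(main_i - 1), min(n_extra, main_i - 1))
    extras <- do.call(rbind, lapply(lower, function(i) {
      on <- main$offset_s + stats::runif(1, 0, 30)
      data.frame(trial_id = trial_id, behavior_code = code_for(i),
                 onset_s = on, offset_s = on + stats::runif(1, 1, 10),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(feed, main, extras)
}

#' Simulate event streams for a whole feature table
#'
#' @param features Feature table from [simulate_trials()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data.frame of events for all trials, ingestible by
#'   [one_zero_sample()] / [score_trials()].
#' @export
simulate_event_streams <- function(features, config = sim_config(),
                                   seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(features)), function(r) {
    simulate_event_stream(features$reaction_intensity[r],
                          trial_id = features$trial_id[r], config = config)
  }))
}

#' Write simulated tables in the ingest CSV formats
#'
#' Writes the event log (`trial_id`, `behavior`, `onset_s`, `offset_s`) and
#' trial metadata in exactly the layouts [read_events()] and
#' [read_trials()] read, so fixture compatibility is a round trip.
#'
#' @param events Event data.frame (`behavior_code` column is renamed to
#'   `behavior` on disk).
#' @param trials Trial metadata.
#' @param events_path,trials_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_study_csv <- function(events, trials, events_path, trials_path) {
  ev <- data.frame(trial_id = events$trial_id,
                   behavior = events$behavior_code,
                   onset_s = events$onset_s, offset_s = events$offset_s)
  utils::write.csv(ev, events_path, row.names = FALSE)
  utils::write.csv(trials, trials_path, row.names = FALSE)
  invisible(c(events_path, trials_path))
}
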