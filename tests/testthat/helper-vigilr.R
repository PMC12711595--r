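# shared fixtures, built in code

make_events <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(trial_id = r[[1]], behavior_code = r[[2]],
               onset_s = as.numeric(r[[3]]), offset_s = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

make_trial <- function(trial_id = "T1", giraffe_id = "G1",
                       playback_event_id = "V1", exemplar_id = "dove_ex01",
                       stimulus = "dove", site = "low_exposure",
                       date = as.Date("2023-08-01"),
                       speaker_distance_m = 60, wind_speed_kmh = 5,
                       group_size = 3, sex = "female", age_class = "adult",
                       order_in_session = "first", disturbance_look_s = 0,
                       moved_from_disturbance = FALSE) {
  data.frame(trial_id = trial_id, giraffe_id = giraffe_id,
             playback_event_id = playback_event_id,
             exemplar_id = exemplar_id, stimulus = stimulus, site = site,
             date = date, speaker_distance_m = speaker_distance_m,
             wind_speed_kmh = wind_speed_kmh, group_size = group_size,
             sex = sex, age_class = age_class,
             order_in_session = order_in_session,
             disturbance_look_s = disturbance_look_s,
             moved_from_disturbance = moved_from_disturbance,
             stringsAsFactors = FALSE)
}

# a small but fully-crossed simulated study, and one fit of it, cached
# across test files (helpers are sourced once per run)
.toy_cache <- new.env()

toy_config <- function() {
  sim_config(individuals_per_site = c(low_exposure = 6,
                                      moderate_exposure = 5,
                                      high_exposure = 4),
             sessions_per_individual = 4)
}

toy_sim <- function() {
  if (is.null(.toy_cache$sim)) {
    .toy_cache$sim <- simulate_trials(toy_config(), seed = 42)
  }
  .toy_cache$sim
}

toy_fit <- function() {
  if (is.null(.toy_cache$fit)) {
    sim <- toy_sim()
    design <- build_design(sim$trials, sim$features)
    .toy_cache$fit <- fit_lmm(design,
                              spec = model_spec(chains = 2, iter = 800,
                                                warmup = 400, seed = 42,
                                                rhat_max = 1.05))
  }
  .toy_cache$fit
}

# independent brute-force oracle for the one-zero sampling convention
brute_one_zero <- function(onset, offset, window_s = 180) {
  vapply(seq_len(window_s) - 1, function(i) {
    as.integer(min(offset, i + 1) - max(onset, i) > 0)
  }, 0L)
}

# simulated matching instances and the exhaustive matching oracle,
# shared between the unit and acceptance suites
sim_match_set <- function(n_giraffes = 10, tests_per = 3, doves_per = 6,
                          seed = 1) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (g in seq_len(n_giraffes)) {
    for (i in seq_len(tests_per + doves_per)) {
      k <- k + 1
      rows[[k]] <- make_trial(
        sprintf("T%04d", k), giraffe_id = sprintf("G%02d", g),
        stimulus = if (i <= tests_per) sample(c("drone", "vehicle",
                                                "talking"), 1) else "dove",
        exemplar_id = "x",
        date = as.Date("2023-07-01") + sample(0:300, 1),
        speaker_distance_m = runif(1, 30, 100),
        wind_speed_kmh = runif(1, 0, 25),
        group_size = sample(1:15, 1),
        sex = sample(c("female", "male"), 1),
        age_class = sample(c("adult", "subadult"), 1))
    }
  }
  do.call(rbind, rows)
}

# exhaustive oracle reproducing the documented metric and tie-breaks
brute_match <- function(trials, config) {
  Zm <- vigilr:::match_covariates(trials, config)
  S_inv <- solve(cov(Zm) + diag(1e-8, ncol(Zm)))
  w <- rep(1, length(config$covariates))
  w[config$covariates == "date_z"] <- config$date_weight
  day <- as.numeric(trials$date - min(trials$date))
  out <- list()
  for (i in order(trials$trial_id)) {
    if (trials$stimulus[i] == "dove") next
    cand <- which(trials$stimulus == "dove" &
                    trials$giraffe_id == trials$giraffe_id[i])
    if (length(cand) == 0) next
    dv <- vapply(cand, function(j) {
      delta <- (Zm[i, ] - Zm[j, ]) * w
      sqrt(drop(t(delta) %*% S_inv %*% delta))
    }, 0)
    best <- cand[order(dv, abs(day[cand] - day[i]), trials$trial_id[cand])][1]
    out[[length(out) + 1]] <- data.frame(
      test_trial_id = trials$trial_id[i],
      control_trial_id = trials$trial_id[best], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

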