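test_that("the generator is deterministic and respects its marginals", {
  cfg <- toy_config()
  s1 <- simulate_trials(cfg, seed = 12)
  s2 <- simulate_trials(cfg, seed = 12)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$features, s2$features)
  s3 <- simulate_trials(cfg, seed = 13)
  expect_false(identical(s1$features$reaction_intensity,
                         s3$features$reaction_intensity))

  tr <- s1$trials
  expect_true(all(tr$speaker_distance_m >= 30 & tr$speaker_distance_m <= 100))
  expect_true(all(tr$wind_speed_kmh >= 0 & tr$wind_speed_kmh <= 25))
  expect_true(all(tr$group_size %in% 1:15))
  expect_true(all(startsWith(tr$exemplar_id, tr$stimulus)))
  expect_equal(sort(unique(tr$site)),
               sort(names(cfg$individuals_per_site)))
  expect_equal(length(unique(tr$giraffe_id)),
               sum(cfg$individuals_per_site))
  # every individual gets a dove and an anthropogenic trial per session
  per_g <- table(tr$giraffe_id, tr$stimulus == "dove")
  expect_true(all(per_g[, "TRUE"] == cfg$sessions_per_individual))
  # co-observed groups share playback events (1-3 animals per video)
  per_event <- table(tr$playback_event_id)
  expect_true(all(per_event >= 1 & per_event <= 3))
  expect_gt(max(per_event), 1)
  expect_true(all(s1$features$reaction_intensity >= 0 &
                    s1$features$reaction_intensity <= 12))
})

test_that("with all variance components zero the response is the linear predictor", {
  cfg <- toy_config()
  cfg$sd_giraffe <- cfg$sd_event <- cfg$sd_exemplar <- cfg$sd_resid <- 0
  sim <- simulate_trials(cfg, seed = 3)
  lp <- sim$truth$linear_predictor[sim$trials$trial_id]
  expect_equal(sim$features$reaction_intensity,
               unname(pmin(pmax(lp, 0), 12)))
  expect_equal(sim$truth$clamp_fraction, mean(lp < 0 | lp > 12))
})

test_that("generator cell means recover the configured effects (CLT check)", {
  cfg <- sim_config(sessions_per_individual = 15)
  sim <- simulate_trials(cfg, seed = 1)
  expect_gte(nrow(sim$trials), 900)
  expect_lt(sim$truth$clamp_fraction, 0.05)
  y <- sim$features$reaction_intensity
  tr <- sim$trials
  dr <- y[tr$site == "low_exposure" & tr$stimulus == "drone"]
  dv <- y[tr$site == "low_exposure" & tr$stimulus == "dove"]
  diff <- mean(dr) - mean(dv)
  sem <- sqrt(var(dr) / length(dr) + var(dv) / length(dv))
  expect_lt(abs(diff - cfg$sound_effects["low_exposure", "drone"]), 3 * sem)
})

test_that("ground truth round-trips through JSON serialization", {
  sim <- simulate_trials(toy_config(), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(linear_predictor = as.list(sim$truth$linear_predictor),
                            u_giraffe = as.list(sim$truth$u_giraffe),
                            clamp_fraction = sim$truth$clamp_fraction),
                       path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$linear_predictor), sim$truth$linear_predictor,
               tolerance = 1e-12)
  expect_equal(unlist(back$u_giraffe), sim$truth$u_giraffe,
               tolerance = 1e-12)
  expect_equal(back$clamp_fraction, sim$truth$clamp_fraction)
})

test_that("event streams realize the latent intensity through the pipeline", {
  set.seed(44)
  ev0 <- simulate_event_stream(0.2, trial_id = "Z")
  expect_true(all(score_behavior(ev0$behavior_code) == 0))

  ev12 <- simulate_event_stream(12, trial_id = "R")
  run <- ev12[ev12$behavior_code == "run away", ]
  expect_equal(nrow(run), 1)
  expect_lte(run$onset_s, 2.9)

  lat <- runif(150, 0, 12)
  rec <- vapply(lat, function(l) {
    ev <- simulate_event_stream(l, trial_id = "T")
    score_trials(ev)$reaction_intensity
  }, 0)
  expect_gte(mean(abs(rec - lat) <= 0.5), 0.95)
})

test_that("written fixtures are read back by the ingest module unchanged", {
  cfg <- toy_config()
  sim <- simulate_trials(cfg, seed = 6)
  sub <- sim$features[1:25, ]
  events <- simulate_event_streams(sub, cfg, seed = 7)
  ep <- withr::local_tempfile(fileext = ".csv")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(events, sim$trials[1:25, ], ep, tp)

  ev_back <- read_events(ep)
  expect_setequal(ev_back$trial_id, events$trial_id)
  ord <- order(events$trial_id, events$onset_s)
  expect_equal(ev_back$onset_s, events$onset_s[ord])
  expect_equal(ev_back$behavior_code, events$behavior_code[ord])

  tr_back <- read_trials(tp)
  expect_equal(tr_back$trial_id, sim$trials$trial_id[1:25])
  expect_s3_class(tr_back$date, "Date")
  expect_equal(tr_back$speaker_distance_m,
               sim$trials$speaker_distance_m[1:25])

  # and the scored features agree with the generator's latent intensities
  ft <- score_trials(ev_back)
  idx <- match(ft$trial_id, sub$trial_id)
  expect_gte(mean(abs(ft$reaction_intensity -
                        sub$reaction_intensity[idx]) <= 0.5), 0.9)
})
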