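test_that("mahalanobis distance matches hand computations", {
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), diag(2)), 0)
  # identity covariance reduces to Euclidean distance
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3)
    expect_equal(mahalanobis_distance(x, y, diag(3)),
                 sqrt(sum((x - y)^2)))
  }
  # explicit quadratic form: diff (1,1), Sigma = diag(2, 0.5)
  d <- mahalanobis_distance(c(1, 1), c(0, 0),
                            solve(matrix(c(2, 0, 0, 0.5), 2)))
  expect_equal(d, sqrt(2.5), tolerance = 1e-9)
  expect_equal(round(d, 4), 1.5811)

  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(mahalanobis_distance(c(1, 1), c(0, 0), bad),
               "positive-definite")
})

test_that("matching equals exhaustive brute-force minimization", {
  trials <- sim_match_set(seed = 21)
  cfg <- match_config()
  res <- match_controls(trials, cfg)
  oracle <- brute_match(trials, cfg)
  expect_equal(res$pairs[, c("test_trial_id", "control_trial_id")], oracle)
  expect_true(all(res$pairs$distance >= 0))
  # within-individual constraint holds for every pair
  gid <- function(id) trials$giraffe_id[match(id, trials$trial_id)]
  expect_equal(gid(res$pairs$test_trial_id), gid(res$pairs$control_trial_id))
})

test_that("ties break by date proximity then lexicographic trial id", {
  base <- as.Date("2023-07-01")
  trials <- rbind(
    make_trial("T_test", stimulus = "drone", exemplar_id = "d1",
               date = base + 10),
    # both controls identical in every matching covariate except date
    make_trial("C_far", date = base + 30),
    make_trial("C_near", date = base + 15),
    # a second giraffe widens the covariate SDs so scores differ
    make_trial("Other", giraffe_id = "G9", speaker_distance_m = 90,
               wind_speed_kmh = 20, group_size = 9, date = base + 200))
  # date excluded from the metric: the two controls are exactly
  # equidistant, so the date-proximity tie-break decides
  cfg_nodate <- match_config(covariates = c("wind_z", "dist_z",
                                            "group_size_z"))
  res <- match_controls(trials, cfg_nodate)
  expect_equal(res$pairs$control_trial_id, "C_near")

  trials2 <- trials
  trials2$date[trials2$trial_id == "C_far"] <- base + 5  # same |gap| = 5
  res2 <- match_controls(trials2, cfg_nodate)
  expect_equal(res2$pairs$control_trial_id, "C_far")  # lexicographic
})

test_that("a singleton candidate is selected regardless of distance", {
  trials <- rbind(
    make_trial("T1", stimulus = "vehicle", exemplar_id = "v1",
               speaker_distance_m = 30, wind_speed_kmh = 0, group_size = 1,
               date = as.Date("2023-07-01")),
    make_trial("T2", speaker_distance_m = 100, wind_speed_kmh = 25,
               group_size = 15, date = as.Date("2024-05-01")),
    make_trial("T3", giraffe_id = "G2", date = as.Date("2023-09-01")))
  res <- match_controls(trials, match_config())
  expect_equal(res$pairs$control_trial_id, "T2")
})

test_that("unmatched tests are reported and excluded", {
  trials <- rbind(
    make_trial("T1", stimulus = "drone", exemplar_id = "d1"),
    make_trial("T2", giraffe_id = "G2"))
  res <- match_controls(trials, match_config())
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$unmatched$trial_id, "T1")
  expect_equal(res$unmatched$reason, "no_same_individual_control")
})

test_that("extreme date weight degenerates to nearest-date matching", {
  trials <- sim_match_set(seed = 33)
  res <- match_controls(trials, match_config(date_weight = 1e9))
  day <- as.numeric(trials$date - min(trials$date))
  for (r in seq_len(nrow(res$pairs))) {
    i <- match(res$pairs$test_trial_id[r], trials$trial_id)
    cand <- which(trials$stimulus == "dove" &
                    trials$giraffe_id == trials$giraffe_id[i])
    gaps <- abs(day[cand] - day[i])
    j <- match(res$pairs$control_trial_id[r], trials$trial_id)
    expect_equal(abs(day[j] - day[i]), min(gaps))
  }
})

test_that("matching without replacement uses each control at most once", {
  trials <- sim_match_set(n_giraffes = 5, tests_per = 4, doves_per = 4,
                          seed = 5)
  res <- match_controls(trials, match_config(replacement = FALSE))
  expect_false(any(duplicated(res$pairs$control_trial_id)))
})

test_that("without within-individual matching, sex-age must match exactly", {
  trials <- rbind(
    make_trial("T1", stimulus = "drone", exemplar_id = "d1",
               sex = "male", age_class = "adult"),
    make_trial("C1", giraffe_id = "G2", sex = "female", age_class = "adult"),
    make_trial("C2", giraffe_id = "G3", sex = "male", age_class = "adult",
               speaker_distance_m = 90, date = as.Date("2024-01-01")))
  res <- match_controls(trials, match_config(within_individual = FALSE))
  expect_equal(res$pairs$control_trial_id, "C2")
})

test_that("difference scores follow the test-minus-control convention", {
  pairs <- data.frame(test_trial_id = c("A", "B", "C"),
                      control_trial_id = c("X", "Y", "Z"),
                      distance = 0, stringsAsFactors = FALSE)
  features <- data.frame(trial_id = c("A", "B", "C", "X", "Y", "Z"),
                         reaction_intensity = c(6, 5.99, 0, 6, 0, 4))
  ds <- difference_scores(pairs, features)
  expect_equal(ds$diff_score, c(0, 5.99, -4))
  expect_true(all(abs(ds$diff_score) <= 12))
  expect_error(difference_scores(pairs, features[-4, ]), "A/X")
})

test_that("the matched model reports near-zero effects for null data", {
  trials <- sim_match_set(n_giraffes = 12, tests_per = 4, doves_per = 4,
                          seed = 9)
  res <- match_controls(trials, match_config())
  pairs <- res$pairs
  pairs$diff_score <- 0
  mm <- fit_matched_model(pairs, trials,
                          spec = model_spec(chains = 2, iter = 500,
                                            warmup = 250, seed = 3,
                                            rhat_max = 1.2))
  expect_true(all(abs(mm$effects$beta) < 0.1))
  expect_true(all(!mm$effects$supported))
  expect_true(all(mm$effects$n_pairs >= 1))
})
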