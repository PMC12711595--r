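test_that("ethogram scores and categories partition as documented", {
  eth <- default_ethogram()
  expect_equal(score_behavior("one ear moves", eth), 1L)
  expect_equal(score_behavior("stops chewing/ruminating and looks", eth), 6L)
  expect_equal(score_behavior("run away", eth), 12L)
  expect_error(score_behavior("moonwalk", eth), "moonwalk")

  expect_equal(as.character(categorize(c(0, 7, 12))), c("A", "B", "C"))
  expect_error(categorize(13), "0, 12")

  # the 13 scores fall 6/4/3 into A/B/C
  cats <- categorize(score_behavior(names(eth), eth))
  expect_equal(as.integer(table(cats)), c(6L, 4L, 3L))
})

test_that("logistic weight has the stated center, bounds and symmetry", {
  expect_identical(logistic_weight(12), 0.5)
  expect_gt(logistic_weight(3), 0.999)
  expect_lt(logistic_weight(20), 0.001)
  # full weight within ~9 s, minimal after ~15 s
  expect_gte(logistic_weight(9), 0.95)
  expect_lte(logistic_weight(15), 0.05 + 1e-9)

  grid <- seq(0, 60, by = 0.25)
  expect_true(all(diff(logistic_weight(grid)) < 0))

  for (d in c(0.5, 2, 7, 11)) {
    expect_equal(logistic_weight(12 - d) + logistic_weight(12 + d), 1)
  }
  expect_error(logistic_weight(-1))
})

test_that("latency to first response ignores intensity-0 behaviors", {
  m0 <- one_zero_sample(make_events(list("T1", "continues feeding/ruminating",
                                         0, 180)))
  expect_true(is.na(latency_first_response(m0)))

  m1 <- one_zero_sample(make_events(list("T1", "both ears move", 7.2, 9)))
  expect_equal(latency_first_response(m1), 7)

  m2 <- one_zero_sample(make_events(
    list("T1", "continues feeding/ruminating", 5, 8),
    list("T1", "walks toward trees to continue browsing", 9.4, 12)))
  expect_equal(latency_first_response(m2), 9)
})

test_that("first three distinct reacting behaviors are extracted in order", {
  ev <- make_events(list("T1", "one ear moves", 2, 3),
                    list("T1", "one ear moves", 5, 6),
                    list("T1", "both ears move", 6, 7),
                    list("T1", "turns body posture", 8, 9),
                    list("T1", "run away", 9, 10))
  f3 <- first_three_behaviors(ev)
  expect_equal(f3$behavior_code,
               c("one ear moves", "both ears move", "turns body posture"))
  expect_equal(f3$latency_s, c(2, 6, 8))

  none <- first_three_behaviors(
    make_events(list("T1", "continues feeding/ruminating", 0, 100)))
  expect_equal(nrow(none), 0)

  one <- first_three_behaviors(make_events(list("T1", "both ears move", 4, 6)))
  expect_equal(nrow(one), 1)
  expect_equal(one$latency_s, 4)
})

test_that("time-weighted score takes the max and annuls late responses", {
  expect_equal(time_weighted_score(data.frame(intensity = integer(0),
                                              latency_s = numeric(0))), 0)

  f3 <- data.frame(intensity = c(6, 9, 2), latency_s = c(3, 20, 1))
  s <- time_weighted_score(f3)
  expect_equal(s, 6 * logistic_weight(3))
  expect_equal(s, 5.999, tolerance = 1e-3)
  expect_lt(9 * logistic_weight(20), 0.01)  # the 20-s behavior is annulled

  expect_equal(time_weighted_score(data.frame(intensity = 12, latency_s = 0)),
               12 * logistic_weight(0))

  # permutation invariance and the intensity bound
  set.seed(5)
  for (i in 1:50) {
    f <- data.frame(intensity = sample(0:12, 3, replace = TRUE),
                    latency_s = runif(3, 0, 40))
    expect_equal(time_weighted_score(f), time_weighted_score(f[sample(3), ]))
    expect_lte(time_weighted_score(f), max(f$intensity))
  }
})

test_that("pipeline score equals a brute-force enumeration oracle", {
  eth <- default_ethogram()
  wp <- weight_params()
  set.seed(23)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    ev <- data.frame(trial_id = "T1",
                     behavior_code = sample(names(eth), n, replace = TRUE),
                     onset_s = runif(n, 0, 60), stringsAsFactors = FALSE)
    ev$offset_s <- ev$onset_s + runif(n, 0.5, 20)
    # oracle: first three distinct codes with intensity >= 1 in onset
    # order, each scored at its first onset second; max weighted score
    o <- ev[order(ev$onset_s), ]
    o <- o[!duplicated(o$behavior_code), ]
    o <- o[eth[o$behavior_code] >= 1, ][seq_len(min(3, sum(eth[o$behavior_code] >= 1))), ]
    expected <- if (nrow(o) == 0) 0 else
      max(eth[o$behavior_code] * logistic_weight(floor(o$onset_s), wp))
    got <- time_weighted_score(first_three_behaviors(ev, eth, wp), wp)
    expect_equal(got, unname(expected))
  }
})

test_that("reaction duration counts seconds of vigilance-class behavior", {
  expect_equal(reaction_duration(
    one_zero_sample(make_events(list("T1", "one ear moves", 0, 50)))), 0)
  expect_equal(reaction_duration(
    one_zero_sample(make_events(list("T1", "turns body posture", 10, 20)))), 10)
  expect_equal(reaction_duration(one_zero_sample(make_events(
    list("T1", "turns body posture", 10, 15),
    list("T1", "moves off gradually", 30, 33)))), 8)
  # overlapping vigilant bouts are not double counted
  expect_equal(reaction_duration(one_zero_sample(make_events(
    list("T1", "turns body posture", 10, 15),
    list("T1", "moves off gradually", 12, 17)))), 7)
})

test_that("score_trials assembles features per trial", {
  ev <- rbind(
    make_events(list("A", "continues feeding/ruminating", 0, 180)),
    make_events(list("B", "stops chewing/ruminating and looks", 4.5, 30),
                list("B", "turns body posture", 12, 40)))
  ft <- score_trials(ev)
  ftA <- ft[ft$trial_id == "A", ]
  expect_true(is.na(ftA$latency_first_s))
  expect_equal(ftA$reaction_intensity, 0)
  expect_equal(as.character(ftA$category), "A")
  ftB <- ft[ft$trial_id == "B", ]
  expect_equal(ftB$latency_first_s, 4)
  expect_equal(ftB$reaction_intensity, 6 * logistic_weight(4))
  expect_equal(ftB$duration_s, 36)  # union of [4,30) grid and [12,40)
  expect_equal(as.character(ftB$category), "B")
})
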