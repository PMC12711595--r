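#' Logistic time-weighting parameters
#'
#' The reaction-intensity statistic down-weights late responses with a
#' decreasing logistic function of latency centered at `center_s` seconds.
#' With the default steepness `k = log(19)/3` per second the weight is
#' exactly 0.95 at 9 s and 0.05 at 15 s: responses within ~9 s of playback
#' onset receive essentially full weight, responses after ~15 s essentially
#' none, and a response at the 12-s center receives weight 0.5. This is the
#' tightest smooth logistic consistent with that full-weight/zero-weight
#' narrative; both parameters are exposed so an alternative calibration can
#' be supplied.
#'
#' @param center_s Latency (s) at which the weight is 0.5. Default 12.
#' @param steepness Decay rate k (per second), > 0. Default `log(19)/3`.
#' @return An object of class `weight_params`.
#' @export
weight_params <- function(center_s = 12, steepness = log(19) / 3) {
  stopifnot(steepness > 0, center_s > 0)
  structure(list(center_s = center_s, steepness = steepness),
            class = "weight_params")
}

#' Logistic latency weight
#'
#' `w(t) = 1 / (1 + exp(k * (t - t0)))`: strictly decreasing in latency,
#' with `w(t0) = 0.5`.
#'
#' @param t Latency in seconds (vectorized, must be >= 0).
#' @param params A [weight_params()] object.
#' @return Weights in (0, 1).
#' @export
#' @examples
#' logistic_weight(c(3, 12, 20))
logistic_weight <- function(t, params = weight_params()) {
  stopifnot(all(t >= 0))
  1 / (1 + exp(params$steepness * (t - params$center_s)))
}

#' Latency to first response
#'
#' The earliest second of the analysis window in which any behavior with
#' reaction intensity >= 1 is active. Intensity-0 maintenance behaviors
#' (continued feeding/ruminating and the like) do not count as a response.
#'
#' @param matrix One-zero matrix from [one_zero_sample()].
#' @param ethogram Intensity map; see [default_ethogram()].
#' @return Latency in whole seconds, or `NA` when no reaction occurred.
#' @export
latency_first_response <- function(matrix, ethogram = default_ethogram()) {
  if (nrow(matrix) == 0) return(NA_real_)
  active <- rownames(matrix)[score_behavior(rownames(matrix), ethogram) >= 1]
  if (length(active) == 0) return(NA_real_)
  hit <- colSums(matrix[active, , drop = FALSE]) > 0
  if (!any(hit)) return(NA_real_)
  as.numeric(which(hit)[1] - 1)
}

#' First three distinct reacting behaviors
#'
#' Scans the onset-ordered event stream and returns the first (up to) three
#' events with distinct behavior codes and reaction intensity >= 1. Repeat
#' bouts of an already-collected code are skipped so a single repeated
#' behavior cannot consume all three slots. Latency is the event's onset
#' second on the one-zero grid (`floor(onset_s)`).
#'
#' @param events One trial's events, sorted by onset (as from
#'   [read_events()]).
#' @param ethogram Intensity map.
#' @param params [weight_params()] for the attached weights.
#' @return Data.frame with columns `behavior_code`, `intensity`,
#'   `latency_s`, `weight`, `weighted_score` (0--3 rows).
#' @export
first_three_behaviors <- function(events, ethogram = default_ethogram(),
                                  params = weight_params()) {
  ord <- order(events$onset_s)
  ev <- events[ord, , drop = FALSE]
  out <- ev[0, c("behavior_code", "onset_s"), drop = FALSE]
  seen <- character(0)
  for (r in seq_len(nrow(ev))) {
    code <- ev$behavior_code[r]
    if (code %in% seen) next
    if (score_behavior(code, ethogram) < 1) next
    out <- rbind(out, ev[r, c("behavior_code", "onset_s")])
    seen <- c(seen, code)
    if (length(seen) == 3) break
  }
  intensity <- if (nrow(out) > 0) score_behavior(out$behavior_code, ethogram) else integer(0)
  latency <- floor(out$onset_s)
  weight <- if (nrow(out) > 0) logistic_weight(latency, params) else numeric(0)
  data.frame(behavior_code = out$behavior_code,
             intensity = intensity,
             latency_s = latency,
             weight = weight,
             weighted_score = intensity * weight,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Time-weighted reaction score
#'
#' The primary response variable: the maximum of intensity x logistic
#' latency weight over the first three distinct reacting behaviors. An
#' empty list (no reaction) scores 0.
#'
#' @param first3 Data.frame from [first_three_behaviors()], or any frame
#'   with `intensity` and `latency_s` columns (at most 3 rows).
#' @param params [weight_params()].
#' @return A real score in \[0, 12\].
#' @export
time_weighted_score <- function(first3, params = weight_params()) {
  if (nrow(first3) == 0) return(0)
  stopifnot(nrow(first3) <= 3)
  max(first3$intensity * logistic_weight(first3$latency_s, params))
}

#' Total vigilant reaction duration
#'
#' Counts the seconds of the analysis window during which any behavior at
#' or above the vigilance threshold is active. The default threshold of 6
#' corresponds to cessation of natural behavior with sustained attention
#' (the B/C score range); it is configurable because duration can also be
#' defined over any reacting behavior.
#'
#' @param matrix One-zero matrix from [one_zero_sample()].
#' @param ethogram Intensity map.
#' @param min_intensity Minimum intensity counted as vigilant (default 6).
#' @return Duration in whole seconds.
#' @export
reaction_duration <- function(matrix, ethogram = default_ethogram(),
                              min_intensity = 6) {
  if (nrow(matrix) == 0) return(0)
  vig <- rownames(matrix)[score_behavior(rownames(matrix), ethogram) >= min_intensity]
  if (length(vig) == 0) return(0)
  sum(colSums(matrix[vig, , drop = FALSE]) > 0)
}

#' Derive per-trial response features from event logs
#'
#' Runs the full scoring pipeline for each trial: one-zero sampling of the
#' event stream, latency to first response, total vigilant duration, the
#' time-weighted reaction intensity over the first three distinct reacting
#' behaviors, and the A/B/C descriptive category of the score.
#'
#' @param events Event log covering one or more trials ([read_events()]).
#' @param trial_ids Trials to score (defaults to those present in
#'   `events`); trials with no events score 0 (no reaction).
#' @param ethogram Intensity map.
#' @param params [weight_params()].
#' @param window_s Analysis window in seconds.
#' @param duration_min_intensity Vigilance threshold for duration.
#' @return Data.frame with one row per trial: `trial_id`,
#'   `latency_first_s` (NA when no reaction), `duration_s`,
#'   `reaction_intensity`, `category`.
#' @export
score_trials <- function(events, trial_ids = NULL,
                         ethogram = default_ethogram(),
                         params = weight_params(), window_s = 180,
                         duration_min_intensity = 6) {
  validate_events(events, ethogram)
  if (is.null(trial_ids)) trial_ids <- unique(events$trial_id)
  rows <- lapply(trial_ids, function(id) {
    ev <- events[events$trial_id == id, , drop = FALSE]
    ev <- ev[ev$onset_s < window_s, , drop = FALSE]
    m <- one_zero_sample(ev, window_s = window_s)
    f3 <- first_three_behaviors(ev, ethogram, params)
    score <- time_weighted_score(f3, params)
    data.frame(trial_id = id,
               latency_first_s = latency_first_response(m, ethogram),
               duration_s = reaction_duration(m, ethogram,
                                              duration_min_intensity),
               reaction_intensity = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$category <- categorize(out$reaction_intensity)
  out
}
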