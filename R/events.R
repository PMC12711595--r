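#' Read a behavioral event log
#'
#' Reads a BORIS-style export of annotated behavior bouts: one row per bout
#' with the trial it belongs to, the ethogram code, and onset/offset in
#' seconds from playback onset. Events stamped during the habituation period
#' (before playback onset) are not part of this format; negative onsets are
#' rejected because onsets are defined from playback start.
#'
#' @param path Path to a CSV or TSV file with header columns `trial_id`,
#'   `behavior`, `onset_s`, `offset_s` (delimiter inferred from the
#'   extension; `.tsv` is tab-delimited, anything else comma-delimited).
#' @param ethogram Named intensity map used to validate behavior codes; see
#'   [default_ethogram()].
#' @return A data.frame of events with columns `trial_id`, `behavior_code`,
#'   `onset_s`, `offset_s`, sorted by (`trial_id`, `onset_s`). Zero rows for
#'   a header-only file.
#' @export
read_events <- function(path, ethogram = default_ethogram()) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("trial_id", "behavior", "onset_s", "offset_s")
  if (!all(need %in% names(raw))) {
    stop("event log must have header columns: ", paste(need, collapse = ", "))
  }
  ev <- data.frame(trial_id = as.character(raw$trial_id),
                   behavior_code = as.character(raw$behavior),
                   onset_s = as.numeric(raw$onset_s),
                   offset_s = as.numeric(raw$offset_s),
                   stringsAsFactors = FALSE)
  validate_events(ev, ethogram)
  ev[order(ev$trial_id, ev$onset_s), , drop = FALSE]
}

validate_events <- function(events, ethogram) {
  if (nrow(events) == 0) return(invisible(events))
  bad_code <- !(events$behavior_code %in% names(ethogram))
  if (any(bad_code)) {
    stop("unknown behavior code(s): ",
         paste(unique(events$behavior_code[bad_code]), collapse = ", "))
  }
  if (anyNA(events$onset_s) || anyNA(events$offset_s)) {
    stop("non-numeric onset/offset at row(s) ",
         paste(which(is.na(events$onset_s) | is.na(events$offset_s)),
               collapse = ", "))
  }
  if (any(events$onset_s < 0)) {
    stop("negative onset (onsets are seconds from playback start) at row(s) ",
         paste(which(events$onset_s < 0), collapse = ", "))
  }
  bad_off <- events$offset_s < events$onset_s
  if (any(bad_off)) {
    stop("offset earlier than onset at row(s) ",
         paste(which(bad_off), collapse = ", "))
  }
  invisible(events)
}

#' One-zero sample a trial's events onto the 1-s analysis grid
#'
#' Converts a single trial's behavior bouts into a binary behavior-by-second
#' matrix over the analysis window: cell (code, i) is 1 iff the bout
#' interval overlaps the half-open second `[i, i+1)` with positive measure.
#' A zero-length touch at a bin boundary does not register. Events past the
#' window are truncated; events entirely outside contribute nothing.
#'
#' @param events Data.frame of events for one trial (as from
#'   [read_events()]).
#' @param window_s Analysis window length in seconds (default 180: 120 s of
#'   playback plus 60 s post-playback).
#' @param codes Optional character vector of behavior codes to use as rows
#'   (defaults to the codes present in `events`).
#' @return Integer matrix with one row per behavior code and `window_s`
#'   columns named `"0" ... "window_s - 1"`.
#' @export
#' @examples
#' ev <- data.frame(trial_id = "T1", behavior_code = "one ear moves",
#'                  onset_s = 2.3, offset_s = 4.8)
#' m <- one_zero_sample(ev)
#' which(m[1, ] == 1) - 1   # seconds 2, 3, 4
one_zero_sample <- function(events, window_s = 180, codes = NULL) {
  stopifnot(window_s >= 1)
  if (nrow(events) > 0 && length(unique(events$trial_id)) > 1) {
    stop("one_zero_sample expects events from a single trial")
  }
  if (is.null(codes)) codes <- unique(events$behavior_code)
  m <- matrix(0L, nrow = length(codes), ncol = window_s,
              dimnames = list(codes, as.character(seq_len(window_s) - 1L)))
  if (nrow(events) == 0 || length(codes) == 0) return(m)
  for (r in seq_len(nrow(events))) {
    on <- events$onset_s[r]
    off <- min(events$offset_s[r], window_s)
    if (on >= window_s || off <= on) next
    first <- floor(on)
    last <- if (off > floor(off) || off == 0) floor(off) else floor(off) - 1
    secs <- seq.int(first, min(last, window_s - 1))
    # positive-measure overlap only: drop the onset bin when the bout
    # starts exactly at its right edge (cannot happen with floor), and the
    # trailing bin when the bout ends exactly at its left edge (handled by
    # the `last` computation above)
    m[events$behavior_code[r], secs + 1L] <- 1L
  }
  m
}

#' Apply the trial inclusion/exclusion rules
#'
#' Trials are excluded when the focal animal stood closer than 30 m or
#' farther than 100 m from the loudspeaker (outside the calibrated,
#' non-startling audibility window), when an external disturbance drew a
#' look of at least 10 s, or when the animal moved away from the
#' disturbance. Looks of at most 5 s count as ordinary scanning and are
#' retained. Looks between 5 and 10 s fall between the two operational
#' anchors; they are retained but flagged (`flag_disturbance`) so the choice
#' is auditable downstream.
#'
#' @param trials Data.frame of trial metadata with at least
#'   `trial_id`, `speaker_distance_m`, `disturbance_look_s`,
#'   `moved_from_disturbance`.
#' @return A list with elements `included` (the retained rows plus a logical
#'   `flag_disturbance` column) and `excluded` (the dropped rows plus a
#'   `reason` code: `distance_below_30m`, `distance_above_100m`,
#'   `external_disturbance`, or `moved_from_disturbance`).
#' @export
apply_trial_filters <- function(trials) {
  need <- c("trial_id", "speaker_distance_m", "disturbance_look_s",
            "moved_from_disturbance")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) stop("trial metadata missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyNA(trials$speaker_distance_m)) {
    stop("missing speaker distance for trial(s) ",
         paste(trials$trial_id[is.na(trials$speaker_distance_m)],
               collapse = ", "), "; cannot adjudicate inclusion")
  }
  look <- ifelse(is.na(trials$disturbance_look_s), 0, trials$disturbance_look_s)
  moved <- isTRUE_vec(trials$moved_from_disturbance)
  reason <- rep(NA_character_, nrow(trials))
  reason[look >= 10] <- "external_disturbance"
  reason[moved & is.na(reason)] <- "moved_from_disturbance"
  reason[trials$speaker_distance_m < 30 & is.na(reason)] <- "distance_below_30m"
  reason[trials$speaker_distance_m > 100 & is.na(reason)] <- "distance_above_100m"
  keep <- is.na(reason)
  included <- trials[keep, , drop = FALSE]
  included$flag_disturbance <- look[keep] > 5 & look[keep] < 10
  if (any(included$flag_disturbance)) {
    warning(sum(included$flag_disturbance),
            " trial(s) retained with disturbance looks of 5-10 s (flagged)")
  }
  excluded <- trials[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(included = included, excluded = excluded)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a trial metadata table
#'
#' @param path CSV with one row per stimulus presentation and the columns
#'   `trial_id`, `giraffe_id`, `playback_event_id`, `exemplar_id`,
#'   `stimulus`, `site`, `date` (ISO-8601), `speaker_distance_m`,
#'   `wind_speed_kmh`, `group_size`, `sex`, `age_class`, and optionally
#'   `order_in_session`, `disturbance_look_s`, `moved_from_disturbance`.
#' @return Data.frame with parsed `date` (class `Date`) and validated enums.
#' @export
read_trials <- function(path) {
  stopifnot(file.exists(path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "giraffe_id", "playback_event_id", "exemplar_id",
            "stimulus", "site", "date", "speaker_distance_m",
            "wind_speed_kmh", "group_size", "sex", "age_class")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) stop("trial metadata missing column(s): ",
                             paste(miss, collapse = ", "))
  tr$date <- as.Date(tr$date)
  if (anyNA(tr$date)) stop("unparseable date(s) in trial metadata")
  validate_trials(tr)
  if (is.null(tr$disturbance_look_s)) tr$disturbance_look_s <- 0
  if (is.null(tr$moved_from_disturbance)) tr$moved_from_disturbance <- FALSE
  tr
}

validate_trials <- function(tr) {
  chk <- function(col, levels) {
    bad <- setdiff(unique(tr[[col]]), levels)
    if (length(bad) > 0) stop("invalid ", col, " value(s): ",
                              paste(bad, collapse = ", "))
  }
  chk("stimulus", c("dove", "drone", "vehicle", "talking"))
  chk("site", c("low_exposure", "moderate_exposure", "high_exposure"))
  chk("sex", c("female", "male"))
  chk("age_class", c("subadult", "adult"))
  if (any(tr$group_size < 1)) {
    stop("group_size must be >= 1 (the focal animal is included)")
  }
  if (anyDuplicated(tr$trial_id)) stop("duplicated trial_id in metadata")
  invisible(tr)
}
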