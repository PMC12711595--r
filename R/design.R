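#' Standardize a numeric vector to mean 0, SD 1
#'
#' Uses the population SD convention (divide by n). Constant or singleton
#' input yields all zeros with a warning, so degenerate strata propagate as
#' neutral covariate values rather than NaN.
#'
#' @param values Numeric vector, length >= 1.
#' @return Standardized vector of the same length.
#' @export
#' @examples
#' zscore(c(2, 4, 6))   # -1.2247, 0, 1.2247
zscore <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    warning("constant or singleton input; returning zeros")
    return(rep(0, length(values)))
  }
  (values - m) / s
}

#' Standardize trial dates within site x stimulus strata
#'
#' Dates are mapped to integer day offsets from the earliest trial date,
#' then z-scored separately within each (site, stimulus) stratum so that
#' systematic temporal variation is expressed relative to when that
#' stimulus was run at that site. Singleton or single-date strata get 0.
#'
#' @param trials Trial metadata with `date` (Date), `site`, `stimulus`.
#' @return Numeric vector `date_z`, aligned with `trials` rows.
#' @export
standardize_date_within <- function(trials) {
  stopifnot(inherits(trials$date, "Date"))
  day <- as.numeric(trials$date - min(trials$date))
  out <- numeric(nrow(trials))
  for (stratum in split(seq_len(nrow(trials)),
                        list(trials$site, trials$stimulus), drop = TRUE)) {
    out[stratum] <- suppressWarnings(zscore(day[stratum]))
  }
  out
}

#' Combine sex and age class into the 4-level demographic factor
#'
#' @param sex `"female"` or `"male"`.
#' @param age_class `"subadult"` or `"adult"`.
#' @param ref Reference level (default `"adult_female"`).
#' @return Factor with levels `adult_female`, `adult_male`,
#'   `subadult_female`, `subadult_male` (reference first).
#' @export
encode_sexage <- function(sex, age_class, ref = "adult_female") {
  ok_sex <- sex %in% c("female", "male")
  ok_age <- age_class %in% c("subadult", "adult")
  if (!all(ok_sex) || !all(ok_age)) {
    stop("invalid sex/age combination: ",
         paste(unique(paste(sex, age_class)[!(ok_sex & ok_age)]),
               collapse = ", "))
  }
  levs <- c("adult_female", "adult_male", "subadult_female", "subadult_male")
  stopifnot(ref %in% levs)
  factor(paste(age_class, sex, sep = "_"),
         levels = c(ref, setdiff(levs, ref)))
}

#' Build the fixed-effect design for the vigilance models
#'
#' Assembles the analysis frame the hierarchical model consumes: treatment
#' -coded stimulus (reference dove) crossed with site, the 4-level sex-age
#' factor, standardized group size, wind speed and date (the latter within
#' site x stimulus strata), and a degree-2 polynomial in standardized
#' speaker distance (raw `z` and `z^2`; sound attenuation with distance is
#' non-linear). Covariates are standardized over the supplied analysis set
#' with the population-SD convention.
#'
#' @param trials Trial metadata (post-filter; see [apply_trial_filters()]).
#' @param features Per-trial features from [score_trials()] (or the
#'   simulator); must cover every trial.
#' @param response Which feature is the model response:
#'   `"reaction_intensity"` (default) or `"duration_s"`.
#' @param ref_sound,ref_site,ref_sexage Reference levels for the treatment
#'   coding. Contrasts computed downstream are invariant to these.
#' @return A list of class `vig_design`: `frame` (analysis data.frame with
#'   factors, z-covariates and id columns), `X` (fixed-effect model
#'   matrix), `y` (response vector), `formula`, `xlevels`.
#' @export
build_design <- function(trials, features, response = "reaction_intensity",
                         ref_sound = "dove", ref_site = "low_exposure",
                         ref_sexage = "adult_female") {
  response <- match.arg(response, c("reaction_intensity", "duration_s"))
  idx <- match(trials$trial_id, features$trial_id)
  if (anyNA(idx)) {
    stop("no features for trial(s): ",
         paste(trials$trial_id[is.na(idx)], collapse = ", "))
  }
  covar <- c("speaker_distance_m", "wind_speed_kmh", "group_size")
  for (cv in covar) {
    if (anyNA(trials[[cv]])) {
      stop("missing ", cv, " for trial(s): ",
           paste(trials$trial_id[is.na(trials[[cv]])], collapse = ", "))
    }
  }
  sound_levs <- c(ref_sound, setdiff(c("dove", "drone", "vehicle", "talking"),
                                     ref_sound))
  site_levs <- c(ref_site, setdiff(c("low_exposure", "moderate_exposure",
                                     "high_exposure"), ref_site))
  frame <- data.frame(
    trial_id = trials$trial_id,
    giraffe_id = trials$giraffe_id,
    playback_event_id = trials$playback_event_id,
    exemplar_id = trials$exemplar_id,
    sound = factor(trials$stimulus, levels = intersect(sound_levs,
                                                       unique(trials$stimulus))),
    site = factor(trials$site, levels = intersect(site_levs,
                                                  unique(trials$site))),
    sexage = encode_sexage(trials$sex, trials$age_class, ref = ref_sexage),
    group_size_z = suppressWarnings(zscore(trials$group_size)),
    wind_z = suppressWarnings(zscore(trials$wind_speed_kmh)),
    dist_z = suppressWarnings(zscore(trials$speaker_distance_m)),
    date_z = standardize_date_within(trials),
    stringsAsFactors = FALSE
  )
  frame$sexage <- droplevels(frame$sexage)
  frame$dist_z2 <- frame$dist_z^2
  # single-level factors carry no information and would break the
  # treatment coding; their terms collapse into the intercept
  fac_terms <- c(
    if (nlevels(frame$sound) > 1 && nlevels(frame$site) > 1) "sound * site"
    else c(if (nlevels(frame$sound) > 1) "sound",
           if (nlevels(frame$site) > 1) "site"),
    if (nlevels(frame$sexage) > 1) "sexage")
  form <- stats::reformulate(c(fac_terms, "group_size_z", "wind_z",
                               "dist_z", "dist_z2", "date_z"))
  X <- stats::model.matrix(form, frame)
  structure(list(frame = frame, X = X, y = features[[response]][idx],
                 response = response, formula = form,
                 xlevels = list(sound = levels(frame$sound),
                                site = levels(frame$site),
                                sexage = levels(frame$sexage))),
            class = "vig_design")
}

#' Fixed-effect row for a reference-grid cell
#'
#' Builds the model-matrix row for a (site, sound, sexage) cell with all
#' standardized covariates held at 0 (their sample means). Used by the
#' contrast and partial-dependence machinery.
#'
#' @param design A `vig_design`.
#' @param site,sound,sexage Factor levels (must exist in the design).
#' @return Numeric vector matching `colnames(design$X)`.
#' @keywords internal
cell_row <- function(design, site, sound, sexage) {
  xl <- design$xlevels
  if (!(sound %in% xl$sound)) stop("unknown sound level: ", sound)
  if (!(site %in% xl$site)) stop("unknown site level: ", site)
  if (!(sexage %in% xl$sexage)) stop("unknown sexage level: ", sexage)
  nd <- data.frame(sound = factor(sound, levels = xl$sound),
                   site = factor(site, levels = xl$site),
                   sexage = factor(sexage, levels = xl$sexage),
                   group_size_z = 0, wind_z = 0, dist_z = 0, dist_z2 = 0,
                   date_z = 0)
  drop(stats::model.matrix(design$formula, nd))
}
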