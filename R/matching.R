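#' Configuration of the matched pseudo-control analysis
#'
#' Anthropogenic test trials are paired to the most similar available
#' control (dove) trial of the same individual, where similarity is a
#' weighted Mahalanobis distance over standardized wind speed, speaker
#' distance, group size and date. Date is weighted most heavily
#' (`date_weight` > 1) to prioritize temporally close trials: its
#' standardized difference is multiplied by `date_weight` before the
#' quadratic form is evaluated, while the metric's covariance is estimated
#' from the unweighted pooled covariate matrix (so the weight is not
#' absorbed by rescaling).
#'
#' @param covariates Ordered covariate columns entering the distance.
#' @param date_weight Multiplicative weight (>= 1) on the standardized date
#'   difference. Default 3.
#' @param within_individual Restrict candidate controls to the same focal
#'   individual (default TRUE). When disabled, sex-age becomes an
#'   exact-match constraint instead, since it is then no longer constant
#'   within candidate sets.
#' @param replacement Allow one control trial to anchor several test trials
#'   (default TRUE). When FALSE, matching is greedy in lexicographic test
#'   trial order and each control is used at most once.
#' @return An object of class `match_config`.
#' @export
match_config <- function(covariates = c("wind_z", "dist_z", "group_size_z",
                                        "date_z"),
                         date_weight = 3, within_individual = TRUE,
                         replacement = TRUE) {
  stopifnot(length(covariates) >= 1, date_weight >= 1)
  structure(list(covariates = covariates, date_weight = date_weight,
                 within_individual = within_individual,
                 replacement = replacement),
            class = "match_config")
}

#' Mahalanobis distance between two covariate vectors
#'
#' `sqrt((x - y)' S^{-1} (x - y))` for a symmetric positive-definite
#' covariance inverse `cov_inv`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param cov_inv Inverse covariance matrix (symmetric positive-definite).
#' @return Non-negative distance.
#' @export
#' @examples
#' mahalanobis_distance(c(1, 1), c(0, 0),
#'                      solve(matrix(c(2, 0, 0, 0.5), 2)))  # 1.5811
mahalanobis_distance <- function(x, y, cov_inv) {
  stopifnot(length(x) == length(y),
            nrow(cov_inv) == length(x), ncol(cov_inv) == length(x))
  if (max(abs(cov_inv - t(cov_inv))) > 1e-8 ||
      any(eigen(cov_inv, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("cov_inv must be symmetric positive-definite")
  }
  d <- x - y
  sqrt(max(drop(t(d) %*% cov_inv %*% d), 0))
}

match_covariates <- function(trials, config) {
  z <- data.frame(
    wind_z = suppressWarnings(zscore(trials$wind_speed_kmh)),
    dist_z = suppressWarnings(zscore(trials$speaker_distance_m)),
    group_size_z = suppressWarnings(zscore(trials$group_size)),
    date_z = suppressWarnings(zscore(as.numeric(trials$date -
                                                  min(trials$date))))
  )
  as.matrix(z[, config$covariates, drop = FALSE])
}

#' Match anthropogenic test trials to dove pseudo-controls
#'
#' For every non-control trial, selects the candidate control trial
#' minimizing the weighted Mahalanobis distance in standardized covariate
#' space. Covariates are standardized and the metric's covariance estimated
#' (with a 1e-8 ridge for numerical positive-definiteness) on the pooled
#' analysis set. Ties are broken by smaller absolute date difference, then
#' by lexicographic control trial id, making the matching fully
#' deterministic. Test trials with no admissible control are reported
#' unmatched and excluded.
#'
#' @param trials Pooled trial metadata (test and control trials together).
#' @param config A [match_config()].
#' @param control Stimulus level treated as control (default `"dove"`).
#' @return List with `pairs` (data.frame `test_trial_id`,
#'   `control_trial_id`, `distance`) and `unmatched` (data.frame
#'   `trial_id`, `reason`).
#' @export
match_controls <- function(trials, config = match_config(),
                           control = "dove") {
  if (nrow(trials) < 2) stop("need at least 2 pooled trials to estimate the covariance")
  Zm <- match_covariates(trials, config)
  S <- stats::cov(Zm) + diag(1e-8, ncol(Zm))
  S_inv <- solve(S)
  wvec <- rep(1, length(config$covariates))
  wvec[config$covariates == "date_z"] <- config$date_weight
  day <- as.numeric(trials$date - min(trials$date))

  is_control <- trials$stimulus == control
  test_idx <- which(!is_control)
  test_idx <- test_idx[order(trials$trial_id[test_idx])]
  avail <- which(is_control)
  pairs <- list()
  unmatched <- list()
  for (i in test_idx) {
    cand <- avail
    if (config$within_individual) {
      cand <- cand[trials$giraffe_id[cand] == trials$giraffe_id[i]]
      reason <- "no_same_individual_control"
    } else {
      same_sa <- trials$sex[cand] == trials$sex[i] &
        trials$age_class[cand] == trials$age_class[i]
      cand <- cand[same_sa]
      reason <- "no_same_sexage_control"
    }
    if (length(cand) == 0) {
      unmatched[[length(unmatched) + 1]] <-
        data.frame(trial_id = trials$trial_id[i], reason = reason,
                   stringsAsFactors = FALSE)
      next
    }
    dvec <- vapply(cand, function(j) {
      delta <- (Zm[i, ] - Zm[j, ]) * wvec
      sqrt(max(drop(t(delta) %*% S_inv %*% delta), 0))
    }, 0)
    datediff <- abs(day[cand] - day[i])
    ord <- order(dvec, datediff, trials$trial_id[cand])
    best <- cand[ord[1]]
    pairs[[length(pairs) + 1]] <-
      data.frame(test_trial_id = trials$trial_id[i],
                 control_trial_id = trials$trial_id[best],
                 distance = dvec[ord[1]], stringsAsFactors = FALSE)
    if (!config$replacement) avail <- setdiff(avail, best)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(test_trial_id = character(0),
                    control_trial_id = character(0), distance = numeric(0)),
       unmatched = if (length(unmatched)) do.call(rbind, unmatched) else
         data.frame(trial_id = character(0), reason = character(0)))
}

#' Difference scores for matched pairs
#'
#' Subtracts the control trial's reaction intensity from the test trial's:
#' positive values mean a stronger response to the anthropogenic sound.
#'
#' @param pairs Data.frame from [match_controls()]`$pairs`.
#' @param features Per-trial features ([score_trials()]).
#' @return `pairs` with an added `diff_score` column.
#' @export
difference_scores <- function(pairs, features) {
  it <- match(pairs$test_trial_id, features$trial_id)
  ic <- match(pairs$control_trial_id, features$trial_id)
  bad <- is.na(it) | is.na(ic)
  if (any(bad)) {
    stop("missing features for pair(s): ",
         paste(paste0(pairs$test_trial_id[bad], "/",
                      pairs$control_trial_id[bad]), collapse = ", "))
  }
  pairs$diff_score <- features$reaction_intensity[it] -
    features$reaction_intensity[ic]
  pairs
}

#' Fit the matched-design difference-score model
#'
#' Bayesian model of the matched difference scores with a mean for every
#' populated sound x site cell (cell-means coding), additive sex-age
#' effects, and a random intercept for the focal individual. The reported
#' effect for an anthropogenic sound within a site is the model-predicted
#' mean difference versus its matched controls, marginalized equally over
#' sex-age; its 95% credible interval excluding zero indicates support.
#' Cells with no pairs are absent from the output (not zero).
#'
#' @param pairs Matched pairs with `diff_score` ([difference_scores()]).
#' @param trials Trial metadata (for the test trials' context).
#' @param spec A [model_spec()]; the random structure is fixed to
#'   `giraffe_id`.
#' @param include_covariate_diffs Add test-minus-control standardized
#'   covariate differences (wind, distance, group size) as fixed effects.
#' @return List with `effects` (data.frame `sound`, `site`, `beta`,
#'   `cri_low`, `cri_high`, `supported`, `n_pairs`) and `fit` (the
#'   underlying `vig_fit`).
#' @export
fit_matched_model <- function(pairs, trials, spec = model_spec(),
                              include_covariate_diffs = FALSE) {
  if (nrow(pairs) < 1) stop("no matched pairs to model")
  it <- match(pairs$test_trial_id, trials$trial_id)
  ic <- match(pairs$control_trial_id, trials$trial_id)
  stopifnot(!anyNA(it), !anyNA(ic))
  fr <- data.frame(
    trial_id = pairs$test_trial_id,
    giraffe_id = trials$giraffe_id[it],
    cell = interaction(trials$stimulus[it], trials$site[it],
                       sep = ":", drop = TRUE),
    sexage = droplevels(encode_sexage(trials$sex[it],
                                      trials$age_class[it])),
    stringsAsFactors = FALSE
  )
  form <- if (nlevels(fr$sexage) > 1) ~ 0 + cell + sexage else ~ 0 + cell
  if (include_covariate_diffs) {
    Zt <- match_covariates(trials, match_config())
    for (cv in c("wind_z", "dist_z", "group_size_z")) {
      fr[[paste0("d_", cv)]] <- Zt[it, cv] - Zt[ic, cv]
    }
    form <- stats::update(form, ~ . + d_wind_z + d_dist_z + d_group_size_z)
  }
  X <- stats::model.matrix(form, fr)
  design <- structure(list(frame = fr, X = X, y = pairs$diff_score,
                           response = "diff_score", formula = form,
                           xlevels = list(cell = levels(fr$cell),
                                          sexage = levels(fr$sexage))),
                      class = "vig_design")
  spec$random <- "giraffe_id"
  fit <- fit_lmm(design, pairs$diff_score, spec)
  # per-cell prediction marginalized equally over observed sex-age levels
  B <- fit$draws[, seq_len(fit$n_fixed), drop = FALSE]
  sa_cols <- grep("^sexage", colnames(X))
  sa_mean <- if (length(sa_cols) > 0) {
    rowMeans(cbind(0, B[, sa_cols, drop = FALSE]))
  } else 0
  rows <- lapply(levels(fr$cell), function(cl) {
    d <- B[, paste0("cell", cl)] + sa_mean
    ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    parts <- strsplit(cl, ":", fixed = TRUE)[[1]]
    data.frame(sound = parts[1], site = parts[2], beta = mean(d),
               cri_low = ci[1], cri_high = ci[2],
               supported = ci[1] > 0 || ci[2] < 0,
               n_pairs = sum(fr$cell == cl), stringsAsFactors = FALSE)
  })
  list(effects = do.call(rbind, rows), fit = fit)
}
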