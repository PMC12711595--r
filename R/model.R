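#' Specification of the Bayesian mixed-model fit
#'
#' Holds the sampler settings and prior scales for [fit_lmm()]. The model is
#' a Gaussian linear mixed model with additive crossed random intercepts for
#' the focal individual, the playback event (video), and the sound exemplar:
#' these grouping factors are not nested, each contributes an additive
#' intercept. Priors are weakly informative and internally rescaled by the
#' response: fixed effects get Normal(0, (prior_scale * sd(y) / sd(x_j))^2),
#' the intercept Normal(mean(y), (prior_scale * sd(y))^2), and every
#' variance-component SD (three random-intercept SDs and the residual SD)
#' a half-Student-t(3) scaled by sd(y).
#'
#' @param chains Number of MCMC chains (>= 2 for diagnostics). Default 4.
#' @param iter Total iterations per chain. Default 2000.
#' @param warmup Burn-in iterations discarded per chain. Default `iter / 2`.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param random Names of the random-intercept columns expected in the
#'   design frame.
#' @param prior_scale Multiplier for the fixed-effect prior SDs. Default 2.5.
#' @param sd_prior_df,sd_prior_scale Degrees of freedom and scale multiplier
#'   (times sd(y)) of the half-t priors on SD components.
#' @param mh_substeps Metropolis sub-steps on the variance components per
#'   coefficient draw. Default 4.
#' @param rhat_max Split-Rhat threshold above which the fit is declared
#'   non-converged. Default 1.01.
#' @param retry Refit once with doubled iterations when the Rhat check
#'   fails before erroring. Default TRUE.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(chains = 4, iter = 2000, warmup = floor(iter / 2),
                       seed = 1,
                       random = c("giraffe_id", "playback_event_id",
                                  "exemplar_id"),
                       prior_scale = 2.5, sd_prior_df = 3, sd_prior_scale = 1,
                       mh_substeps = 4, rhat_max = 1.01, retry = TRUE) {
  stopifnot(chains >= 2, iter > warmup, warmup >= 1, length(random) >= 1,
            mh_substeps >= 1)
  structure(list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                 random = random, prior_scale = prior_scale,
                 sd_prior_df = sd_prior_df, sd_prior_scale = sd_prior_scale,
                 mh_substeps = mh_substeps, rhat_max = rhat_max,
                 retry = retry),
            class = "model_spec")
}

#' Fit the Bayesian crossed-random-intercepts model
#'
#' Fits `y = X beta + sum_f Z_f u_f + e` by a marginal blocked sampler:
#' the variance-component SDs move by adaptive random-walk Metropolis
#' (on the natural SD scale, folded at zero) under the *marginal*
#' posterior (all coefficients
#' integrated out analytically via the normal-normal conjugacy), and the
#' coefficients (fixed effects and every random intercept) are then drawn
#' jointly from their exact multivariate-normal conditional. Integrating
#' the coefficients out of the variance update avoids the slow
#' centered-parameterization mixing that afflicts vanilla Gibbs when a
#' variance component is weakly identified (e.g. the playback-event SD
#' against the residual SD when most events contribute 1-3 observations).
#' Random factors with fewer than 2 levels are dropped with a warning.
#' After sampling, split-Rhat is checked for every reported parameter; a
#' non-converged fit is retried once with doubled iterations and then
#' fails with its diagnostics attached.
#'
#' @param design A `vig_design` from [build_design()] (or
#'   [matched_design()]).
#' @param response Response vector; defaults to `design$y`.
#' @param spec A [model_spec()].
#' @return An object of class `vig_fit` with elements `draws` (matrix,
#'   kept draws x parameters: fixed effects then `sd_<factor>` and
#'   `sd_residual`), `chain` (chain index per draw), `n_fixed`, `design`,
#'   `spec`, and `summary` (a data.frame of posterior mean, 95% credible
#'   interval, split-Rhat and MCSE per parameter).
#' @export
fit_lmm <- function(design, response = design$y, spec = model_spec()) {
  X <- design$X
  y <- as.numeric(response)
  stopifnot(nrow(X) == length(y))
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient; check factor coverage")
  }
  groups <- list()
  for (f in spec$random) {
    g <- factor(design$frame[[f]])
    if (nlevels(g) < 2) {
      warning("random factor '", f, "' has < 2 levels and was dropped")
      next
    }
    groups[[f]] <- g
  }
  fit <- gibbs_lmm(X, y, groups, spec)
  bad <- rhat_violations(fit, spec$rhat_max, y)
  if (any(bad, na.rm = TRUE) && spec$retry) {
    spec2 <- spec
    spec2$iter <- spec$iter * 2L
    spec2$warmup <- spec$warmup * 2L
    fit <- gibbs_lmm(X, y, groups, spec2)
    bad <- rhat_violations(fit, spec2$rhat_max, y)
  }
  if (any(bad, na.rm = TRUE)) {
    stop("MCMC did not converge (split-Rhat > ", spec$rhat_max, ") for: ",
         paste(fit$summary$parameter[bad], collapse = ", "),
         " [max Rhat = ", round(max(fit$summary$rhat, na.rm = TRUE), 4), "]")
  }
  fit$design <- design
  fit
}

# Rhat check, ignoring SD components that have collapsed to a numerically
# negligible scale (their chains sit on different sides of ~0 and Rhat is
# meaningless there)
rhat_violations <- function(fit, rhat_max, y) {
  bad <- fit$summary$rhat > rhat_max
  scale_y <- max(stats::sd(y), 1e-12)
  is_sd <- startsWith(fit$summary$parameter, "sd_")
  collapsed <- is_sd & fit$summary$cri_high < 1e-3 * scale_y
  bad & !collapsed
}

gibbs_lmm <- function(X, y, groups, spec) {
  n <- length(y)
  p <- ncol(X)
  sdy <- stats::sd(y)
  if (sdy == 0) sdy <- 1
  Zs <- lapply(groups, function(g) {
    Z <- matrix(0, n, nlevels(g))
    Z[cbind(seq_len(n), as.integer(g))] <- 1
    Z
  })
  qs <- vapply(Zs, ncol, 0L)
  W <- do.call(cbind, c(list(X), Zs))
  d <- ncol(W)
  C <- crossprod(W)
  Wty <- drop(crossprod(W, y))

  # fixed-effect prior: autoscaled normal
  sdx <- apply(X, 2, stats::sd)
  prior_sd <- ifelse(sdx > 0, spec$prior_scale * sdy / sdx,
                     spec$prior_scale * sdy)
  prior_mean <- rep(0, p)
  is_int <- colnames(X) == "(Intercept)"
  prior_mean[is_int] <- mean(y)
  fixed_prec <- 1 / prior_sd^2
  mu0 <- c(prior_mean, rep(0, d - p))
  r0 <- y - as.numeric(W %*% mu0)
  Wtr0 <- drop(crossprod(W, r0))
  r0r0 <- sum(r0^2)

  nu <- spec$sd_prior_df
  A <- spec$sd_prior_scale * sdy
  # rough residual scale from the fixed-effects OLS fit; sizes the
  # initial values and proposal steps even when noise is far below sd(y)
  ols <- stats::lm.fit(X, y)
  ols_sd <- sqrt(sum(ols$residuals^2) / max(n - p, 1))
  base_scale <- max(ols_sd, 1e-6 * sdy, 1e-12)
  nf <- length(Zs)
  nsd <- nf + 1                   # random-intercept SDs + residual SD
  blk <- if (nf > 0) rep(seq_len(nf), qs) else integer(0)

  # Schur elimination of the largest random-effect block: its columns are
  # disjoint indicators, so its cross-product block is diagonal and the
  # remaining factorization is small (fixed effects + smaller factors)
  f_big <- if (nf > 0) which.max(qs) else 0L
  ie <- if (nf > 0) p + which(blk == f_big) else integer(0)
  ia <- setdiff(seq_len(d), ie)
  Caa <- C[ia, ia, drop = FALSE]
  Cae <- C[ia, ie, drop = FALSE]
  cnt_e <- diag(C)[ie]
  na <- length(ia)

  # factorization of the coefficient precision at given variance
  # components, in eliminated form; prec = prior precisions for all coords
  factorize <- function(prec, sig2_e) {
    Pee <- cnt_e / sig2_e + prec[ie]
    M <- sweep(Cae, 2, Pee, "/")
    S <- Caa / sig2_e - (M %*% t(Cae)) / sig2_e^2
    diag(S) <- diag(S) + prec[ia]
    US <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(US)) return(NULL)
    list(US = US, Pee = Pee,
         logdet = sum(log(Pee)) + 2 * sum(log(diag(US))),
         sig2_e = sig2_e)
  }
  fsolve <- function(fac, v) {
    ve <- v[ie] / fac$Pee
    rhs_a <- v[ia] - drop(Cae %*% ve) / fac$sig2_e
    ma <- backsolve(fac$US, backsolve(fac$US, rhs_a, transpose = TRUE))
    me <- ve - drop(crossprod(Cae, ma)) / (fac$sig2_e * fac$Pee)
    m <- numeric(length(v))
    m[ia] <- ma
    m[ie] <- me
    m
  }

  # marginal log posterior of the SD parameters (coefficients integrated
  # out); eta = the SD vector itself (factor SDs ..., residual SD); the
  # random walk runs on this natural scale with reflection at 0, so the
  # weakly-identified near-zero region of a variance component is a finite
  # stretch the walker crosses quickly instead of an infinite log-scale tail
  log_post <- function(eta) {
    sig2_f <- eta[seq_len(nf)]^2
    sig2_e <- eta[nsd]^2
    if (sig2_e <= 0) return(list(lp = -Inf))
    prec <- c(fixed_prec, if (nf > 0) 1 / pmax(sig2_f[blk], 1e-12))
    fac <- factorize(prec, sig2_e)
    if (is.null(fac)) return(list(lp = -Inf))
    bt <- Wtr0 / sig2_e
    mt <- fsolve(fac, bt)
    ll <- -0.5 * (n * log(sig2_e) + fac$logdet +
                    sum(log(1 / prec)) + r0r0 / sig2_e - sum(bt * mt))
    # half-t(nu, A) prior on each SD
    lprior <- sum(-(nu + 1) / 2 * log1p(eta^2 / (nu * A^2)))
    list(lp = ll + lprior, fac = fac, prec = prec)
  }

  keep <- spec$iter - spec$warmup
  par_names <- c(colnames(X),
                 if (nf > 0) paste0("sd_", names(Zs)), "sd_residual")
  draws <- matrix(NA_real_, keep * spec$chains, p + nsd,
                  dimnames = list(NULL, par_names))
  chain_id <- rep(seq_len(spec$chains), each = keep)

  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch)
    eta <- c(rep(base_scale * stats::runif(1, 0.3, 0.9), nf),
             base_scale * stats::runif(1, 0.7, 1.2))
    cur <- log_post(eta)
    # adaptive random-walk Metropolis on eta during warmup
    prop_chol <- diag(0.3 * base_scale, nsd)
    eta_hist <- matrix(NA_real_, spec$warmup, nsd)
    log_scale <- 0
    n_acc <- 0
    for (it in seq_len(spec$iter)) {
      for (sub in seq_len(spec$mh_substeps)) {
        eta_p <- abs(eta + exp(log_scale) * drop(prop_chol %*% stats::rnorm(nsd)))
        cand <- log_post(eta_p)
        if (stats::runif(1) < exp(cand$lp - cur$lp)) {
          eta <- eta_p
          cur <- cand
          n_acc <- n_acc + 1
        }
      }
      if (it <= spec$warmup) {
        eta_hist[it, ] <- eta
        acc_rate <- n_acc / (spec$mh_substeps * it)
        log_scale <- log_scale + (acc_rate - 0.3) / sqrt(it)
        if (it >= 50 && it %% 25 == 0) {
          S <- stats::cov(eta_hist[seq_len(it), , drop = FALSE]) +
            diag(1e-6, nsd)
          prop_chol <- t(chol(2.38^2 / nsd * S))
        }
      } else {
        # joint draw of all coefficients given the SDs
        fac <- cur$fac
        b <- Wty / fac$sig2_e + cur$prec * mu0
        m <- fsolve(fac, b)
        th_a <- m[ia] + backsolve(fac$US, stats::rnorm(na))
        th_e <- m[ie] -
          drop(crossprod(Cae, th_a - m[ia])) / (fac$sig2_e * fac$Pee) +
          stats::rnorm(length(ie)) / sqrt(fac$Pee)
        theta <- numeric(d)
        theta[ia] <- th_a
        theta[ie] <- th_e
        draws[(ch - 1) * keep + it - spec$warmup, ] <-
          c(theta[seq_len(p)], eta)
      }
    }
  }
  diag_tab <- diagnostics(draws, chain_id)
  summ <- data.frame(parameter = par_names,
                     mean = colMeans(draws),
                     cri_low = apply(draws, 2, stats::quantile, 0.025),
                     cri_high = apply(draws, 2, stats::quantile, 0.975),
                     rhat = diag_tab$rhat,
                     mcse = diag_tab$mcse,
                     row.names = NULL)
  structure(list(draws = draws, chain = chain_id, n_fixed = p,
                 par_names = par_names, spec = spec, summary = summ,
                 dropped = setdiff(spec$random, names(Zs))),
            class = "vig_fit")
}

#' @export
print.vig_fit <- function(x, ...) {
  cat("Bayesian crossed-random-intercepts LMM (", x$spec$chains, " chains x ",
      x$spec$iter, " iterations, ", sum(x$chain == 1), " kept each)\n\n",
      sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' MCMC convergence diagnostics
#'
#' Computes split-Rhat (potential scale reduction over half-chains),
#' effective sample size from the chain-combined autocorrelation sequence
#' (Geyer initial positive-sequence truncation), and Monte Carlo standard
#' error `MCSE = posterior SD / sqrt(ESS)` for each parameter.
#'
#' @param draws Matrix of posterior draws (rows) by parameters (columns).
#' @param chain Integer vector assigning each row to a chain (>= 2 chains).
#' @return Data.frame with columns `parameter`, `rhat`, `ess`, `mcse`.
#' @export
diagnostics <- function(draws, chain) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) == length(chain))
  if (length(unique(chain)) < 2) {
    stop("diagnostics require at least 2 chains")
  }
  rhat <- unname(apply(draws, 2, split_rhat, chain = chain))
  ess <- unname(apply(draws, 2, ess_acf, chain = chain))
  sds <- unname(apply(draws, 2, stats::sd))
  mcse <- ifelse(ess > 0, sds / sqrt(ess), 0)
  data.frame(parameter = colnames(draws), rhat = rhat, ess = ess,
             mcse = mcse, row.names = NULL)
}

split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[seq.int(h + 1, 2 * h)])
  })
  chains <- unlist(halves, recursive = FALSE)
  m <- length(chains)
  n <- length(chains[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  Wv <- mean(vars)
  Bv <- n * stats::var(means)
  if (Wv == 0) return(1)
  sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
}

ess_acf <- function(x, chain) {
  xs <- split(x, chain)
  m <- length(xs)
  n <- min(lengths(xs))
  xs <- lapply(xs, function(v) v[seq_len(n)])
  Wv <- mean(vapply(xs, stats::var, 0))
  Bv <- n * stats::var(vapply(xs, mean, 0))
  varplus <- (n - 1) / n * Wv + Bv / n
  if (varplus == 0 || Wv == 0) return(0)
  # chain-averaged autocovariances
  acov <- vapply(xs, function(v) {
    stats::acf(v, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(n))
  rho <- 1 - (Wv - rowMeans(acov)) / varplus
  # Geyer: sum consecutive pairs while positive
  tau <- 1
  t <- 1
  while (t + 1 < length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1e-12)
}
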