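#' Posterior draws of the expected response in a reference-grid cell
#'
#' Linear predictor at a (site, sound) cell with standardized covariates at
#' 0 (their sample means), averaged with equal weights over the four sex-age
#' levels unless a single level is fixed. Equal weighting is the
#' reference-grid convention: the prediction describes an average animal of
#' unspecified demography rather than the sample's demographic mix.
#'
#' @param fit A `vig_fit`.
#' @param site,sound Factor levels.
#' @param sexage Optional single sex-age level; default averages equally.
#' @return Numeric vector of posterior draws.
#' @keywords internal
cell_draws <- function(fit, site, sound, sexage = NULL) {
  design <- fit$design
  levs <- if (is.null(sexage)) design$xlevels$sexage else sexage
  x <- rowMeans(vapply(levs, function(sa) cell_row(design, site, sound, sa),
                       numeric(fit$n_fixed)))
  as.numeric(fit$draws[, seq_len(fit$n_fixed), drop = FALSE] %*% x)
}

check_cell_observed <- function(fit, site, sound) {
  fr <- fit$design$frame
  if (!any(fr$site == site & fr$sound == sound)) {
    stop("no observations for sound '", sound, "' at site '", site,
         "' in the design")
  }
}

summarize_contrast <- function(label, d) {
  ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  structure(list(label = label, mu_diff = mean(d),
                 cri_low = ci[1], cri_high = ci[2],
                 supported = ci[1] > 0 || ci[2] < 0,
                 draws = d),
            class = "vig_contrast")
}

#' @export
print.vig_contrast <- function(x, ...) {
  cat(sprintf("%s: mu_diff = %.3f, 95%% CrI [%.3f, %.3f]%s\n", x$label,
              x$mu_diff, x$cri_low, x$cri_high,
              if (x$supported) " *" else ""))
  invisible(x)
}

#' Within-site pairwise contrast between two sounds
#'
#' Posterior distribution of `E[Y | site, sound_a] - E[Y | site, sound_b]`
#' at that site, with standardized covariates held at their means and
#' averaging equally over the sex-age levels. Derived draw-by-draw from the
#' full sound x site interaction model, so contrasts at different sites are
#' not separate analyses. Statistical support is declared when the 95%
#' credible interval excludes zero.
#'
#' @param fit A `vig_fit` of the full interaction model.
#' @param site Site at which to contrast.
#' @param sound_a,sound_b Sound levels (a minus b).
#' @return A `vig_contrast`: `label`, `mu_diff` (posterior mean of the
#'   difference), `cri_low`, `cri_high`, `supported`, and the raw `draws`.
#' @export
within_site_contrast <- function(fit, site, sound_a, sound_b) {
  check_cell_observed(fit, site, sound_a)
  check_cell_observed(fit, site, sound_b)
  d <- cell_draws(fit, site, sound_a) - cell_draws(fit, site, sound_b)
  summarize_contrast(paste0(site, ": ", sound_a, " - ", sound_b), d)
}

#' Between-site contrast for one sound
#'
#' Posterior distribution of `E[Y | site_a, sound] - E[Y | site_b, sound]`,
#' covariates at means, sex-age averaged equally.
#'
#' @param fit A `vig_fit`.
#' @param sound Sound level held fixed.
#' @param site_a,site_b Sites (a minus b).
#' @return A `vig_contrast`.
#' @export
between_site_contrast <- function(fit, sound, site_a, site_b) {
  check_cell_observed(fit, site_a, sound)
  check_cell_observed(fit, site_b, sound)
  d <- cell_draws(fit, site_a, sound) - cell_draws(fit, site_b, sound)
  summarize_contrast(paste0(sound, ": ", site_a, " - ", site_b), d)
}

#' All within- and between-site contrasts against a reference sound
#'
#' Convenience wrapper producing the standard contrast table: each
#' anthropogenic sound minus the control within every site, pairwise
#' contrasts among anthropogenic sounds within every site, and between-site
#' contrasts of every sound.
#'
#' @param fit A `vig_fit`.
#' @param control Reference (control) sound, default `"dove"`.
#' @return Data.frame with columns `type`, `label`, `mu_diff`, `cri_low`,
#'   `cri_high`, `supported`.
#' @export
contrast_table <- function(fit, control = "dove") {
  xl <- fit$design$xlevels
  fr <- fit$design$frame
  rows <- list()
  add <- function(type, cr) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, label = cr$label, mu_diff = cr$mu_diff,
      cri_low = cr$cri_low, cri_high = cr$cri_high,
      supported = cr$supported, stringsAsFactors = FALSE)
  }
  anthro <- setdiff(xl$sound, control)
  for (site in xl$site) {
    present <- xl$sound[vapply(xl$sound, function(s)
      any(fr$site == site & fr$sound == s), TRUE)]
    for (s in intersect(anthro, present)) {
      if (control %in% present) {
        add("within_site", within_site_contrast(fit, site, s, control))
      }
    }
    pairs <- utils::combn(intersect(anthro, present), 2, simplify = FALSE)
    if (length(intersect(anthro, present)) >= 2) {
      for (pr in pairs) {
        add("within_site_anthro",
            within_site_contrast(fit, site, pr[2], pr[1]))
      }
    }
  }
  for (s in xl$sound) {
    sites <- xl$site[vapply(xl$site, function(st)
      any(fr$site == st & fr$sound == s), TRUE)]
    if (length(sites) >= 2) {
      for (pr in utils::combn(sites, 2, simplify = FALSE)) {
        add("between_site", between_site_contrast(fit, s, pr[1], pr[2]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Partial-dependence predictions over a reference grid
#'
#' Posterior mean and 95% credible interval of the expected response
#' (linear predictor) for each requested (site, sound) cell, with
#' continuous covariates held at their sample means. When the grid omits
#' `sexage`, predictions are marginalized over the four sex-age levels with
#' equal weights; a `sexage` column fixes the level per row.
#'
#' @param fit A `vig_fit`.
#' @param grid Data.frame with columns `site` and `sound`, optionally
#'   `sexage`. Defaults to all observed site x sound cells.
#' @return The grid with added `estimate`, `cri_low`, `cri_high` columns,
#'   one row per requested cell.
#' @export
partial_dependence <- function(fit, grid = NULL) {
  if (is.null(grid)) {
    xl <- fit$design$xlevels
    grid <- expand.grid(site = xl$site, sound = xl$sound,
                        stringsAsFactors = FALSE)
    fr <- fit$design$frame
    grid <- grid[mapply(function(st, so) any(fr$site == st & fr$sound == so),
                        grid$site, grid$sound), , drop = FALSE]
    rownames(grid) <- NULL
  }
  est <- matrix(NA_real_, nrow(grid), 3,
                dimnames = list(NULL, c("estimate", "cri_low", "cri_high")))
  for (r in seq_len(nrow(grid))) {
    sa <- if ("sexage" %in% names(grid)) grid$sexage[r] else NULL
    d <- cell_draws(fit, grid$site[r], grid$sound[r], sa)
    est[r, ] <- c(mean(d), stats::quantile(d, c(0.025, 0.975), names = FALSE))
  }
  cbind(grid, as.data.frame(est))
}
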