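# Seeded generator of synthetic titration studies: a primary growth-type
# response following the linear-logistic curve, and a companion
# physiological response (milk yield, plasma AA, antibody titre, ...) that
# rises toward an anchor dose and plateaus there. All generators are pure
# functions of (design, params, seed).

# Evaluate code under a temporary RNG state; restores .Random.seed after.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Design of a synthetic titration study
#'
#' Describes the experimental layout the generators emulate: a handful of
#' graded dose levels, a few replicates per level, and additive Gaussian
#' noise. The default mirrors the densest published broiler-type design:
#' 6 uniformly spaced levels over a digestible arginine-to-lysine ratio of
#' 77-127, 8 replicates per level, and a noise standard deviation of 3% of
#' the noiseless response range.
#'
#' @param dose_min,dose_max Dose range endpoints (`dose_min < dose_max`).
#' @param n_levels Number of dose levels (>= 4).
#' @param reps_per_level Replicates per level (>= 1).
#' @param noise_sd Noise standard deviation: a fraction of the noiseless
#'   response range when `noise_type = "fraction_of_range"` (default), or
#'   in response units when `"absolute"`.
#' @param noise_type `"fraction_of_range"` or `"absolute"`.
#' @param seed Integer seed used by the generators.
#' @param spacing `"uniform"` or a custom numeric vector of dose levels
#'   (overrides `dose_min`/`dose_max`/`n_levels`).
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(dose_min = 77, dose_max = 127, n_levels = 6,
                             reps_per_level = 8, noise_sd = 0.03,
                             noise_type = c("fraction_of_range", "absolute"),
                             seed = 1L, spacing = "uniform") {
  noise_type <- match.arg(noise_type)
  if (is.numeric(spacing)) {
    levels <- sort(as.numeric(spacing))
    dose_min <- min(levels); dose_max <- max(levels)
    n_levels <- length(levels)
  } else {
    if (!identical(spacing, "uniform"))
      stop("`spacing` must be \"uniform\" or a numeric vector of levels",
           call. = FALSE)
    if (!(dose_min < dose_max))
      stop("`dose_min` must be smaller than `dose_max`", call. = FALSE)
    levels <- seq(dose_min, dose_max, length.out = n_levels)
  }
  if (n_levels < 4L) stop("`n_levels` must be at least 4", call. = FALSE)
  if (reps_per_level < 1L) stop("`reps_per_level` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(dose_min = dose_min, dose_max = dose_max,
                 n_levels = as.integer(n_levels), levels = levels,
                 reps_per_level = as.integer(reps_per_level),
                 noise_sd = noise_sd, noise_type = noise_type,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Default generating parameters for the synthetic study
#'
#' A linear-logistic truth scaled to the default ratio-axis design (77-127):
#' slope 0.1 response units per ratio point, dip amplitude 4, logistic
#' midpoint at dose 107 with rate 0.2. This places the growth maximum Rmax
#' near 98 and the functional minimum Rmin near 116, both interior to the
#' dose range, as required for an informative titration.
#'
#' @return A [linlog_params] object.
#' @export
default_truth_params <- function() {
  linlog_params(a = 30, b = 0.1, c = 4, f = 0.2, log_d = 0.2 * 107)
}

noise_sd_absolute <- function(design, mu) {
  if (design$noise_type == "absolute") return(design$noise_sd)
  design$noise_sd * max(diff(range(mu)), 0)
}

#' Generate a synthetic primary (growth-type) titration response
#'
#' Draws `reps_per_level` observations at each dose level around the
#' linear-logistic mean curve, with iid Gaussian noise. Deterministic given
#' the seed. By default the generating parameters must put both stationary
#' doses inside the design's dose range (otherwise the rise-dip-rise
#' pattern the study is designed to detect does not exist there); pass
#' `require_inflection = FALSE` to generate from monotone parameters.
#'
#' @param design A [synthetic_design].
#' @param params Generating [linlog_params] (default [default_truth_params()]).
#' @param seed Overrides `design$seed` when given.
#' @param require_inflection Require Rmax and Rmin to exist and lie within
#'   the dose range (default `TRUE`).
#' @return A [dose_response] table with attribute `truth`: list of `params`,
#'   `rmax`, `rmin`, `regime`, `noise_sd` (absolute), `seed`.
#' @export
generate_primary <- function(design, params = default_truth_params(),
                             seed = NULL, require_inflection = TRUE) {
  stopifnot(inherits(design, "synthetic_design"))
  params <- as_linlog_params(params)
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  st <- stationary_points(params)
  if (require_inflection) {
    if (st$regime != "two_points")
      stop("generating parameters are ", st$regime,
           ": the discriminant condition c*f > 4b fails, so the curve has ",
           "no interior maximum/minimum; pass require_inflection = FALSE ",
           "to generate anyway", call. = FALSE)
    if (st$rmax < design$dose_min || st$rmin > design$dose_max)
      stop(sprintf(paste0(
        "stationary doses (Rmax = %.4g, Rmin = %.4g) fall outside the ",
        "design range [%g, %g]"), st$rmax, st$rmin,
        design$dose_min, design$dose_max), call. = FALSE)
  }
  dose <- rep(design$levels, each = design$reps_per_level)
  mu_level <- linlog_eval(params, design$levels)
  mu <- rep(mu_level, each = design$reps_per_level)
  sd_abs <- noise_sd_absolute(design, mu_level)
  response <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd_abs))
  tab <- dose_response(dose, response,
                       replicate_id = rep(seq_len(design$reps_per_level),
                                          times = design$n_levels))
  attr(tab, "truth") <- list(params = params, rmax = st$rmax, rmin = st$rmin,
                             regime = st$regime, noise_sd = sd_abs,
                             seed = seed)
  tab
}

#' Generate a synthetic companion (physiological) response
#'
#' Emulates the companion responses seen alongside growth in titration
#' studies -- milk production, litter size, immunoglobulin titres, survival,
#' tight-junction gene expression, plasma amino-acid concentration -- whose
#' noiseless mean rises with dose and levels off at an anchor dose
#' (typically the primary response's Rmin). Two shapes are available:
#' a continuous linear-plateau with its breakpoint at the anchor, and a
#' logistic rise with its midpoint at the anchor.
#'
#' @param design A [synthetic_design] (dose grid, replication, noise, seed).
#' @param anchor Dose at which the mean curve breaks/centres; must lie
#'   within the design's dose range.
#' @param shape `"plateau-at-anchor"` (default) or `"logistic-rise-at-anchor"`.
#' @param amplitude Total rise of the mean curve (response units; non-zero).
#' @param baseline Mean response at the low end (default 0).
#' @param noise_sd Overrides the design's noise (same `noise_type`
#'   convention) when not `NULL`.
#' @param seed Overrides `design$seed + 1` when given. The default offset
#'   keeps a paired primary and companion from sharing a noise stream.
#' @return A [dose_response] table with a `truth` attribute: `anchor`,
#'   `shape`, `amplitude`, `baseline`, `noise_sd`, `seed`.
#' @export
generate_companion <- function(design, anchor,
                               shape = c("plateau-at-anchor",
                                         "logistic-rise-at-anchor"),
                               amplitude = 1, baseline = 0,
                               noise_sd = NULL, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(inherits(design, "synthetic_design"))
  if (!is.numeric(anchor) || length(anchor) != 1L || !is.finite(anchor))
    stop("`anchor` must be a single finite dose", call. = FALSE)
  if (anchor < design$dose_min || anchor > design$dose_max)
    stop(sprintf("`anchor` (%g) must lie within the dose range [%g, %g]",
                 anchor, design$dose_min, design$dose_max), call. = FALSE)
  if (amplitude == 0)
    stop("`amplitude` must be non-zero (a flat companion is degenerate)",
         call. = FALSE)
  seed <- if (is.null(seed)) design$seed + 1L else as.integer(seed)
  mu_of <- switch(shape,
    "plateau-at-anchor" = {
      slope <- amplitude / max(anchor - design$dose_min,
                               1e-8 * (design$dose_max - design$dose_min))
      function(x) baseline + slope * (pmin(x, anchor) - design$dose_min)
    },
    "logistic-rise-at-anchor" = {
      rate <- 10 / (design$dose_max - design$dose_min)
      function(x) baseline + amplitude * stats::plogis(rate * (x - anchor))
    })
  dose <- rep(design$levels, each = design$reps_per_level)
  mu_level <- mu_of(design$levels)
  mu <- rep(mu_level, each = design$reps_per_level)
  nd <- design
  if (!is.null(noise_sd)) nd$noise_sd <- noise_sd
  sd_abs <- noise_sd_absolute(nd, mu_level)
  response <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd_abs))
  tab <- dose_response(dose, response,
                       replicate_id = rep(seq_len(design$reps_per_level),
                                          times = design$n_levels))
  attr(tab, "truth") <- list(anchor = anchor, shape = shape,
                             amplitude = amplitude, baseline = baseline,
                             noise_sd = sd_abs, seed = seed)
  tab
}

#' Generate a paired primary + companion synthetic study
#'
#' Convenience wrapper producing the paired-panel structure of published
#' reanalyses: a growth-type primary response following the linear-logistic
#' curve, and a companion response whose plateau breakpoint sits at the
#' primary's true Rmin (or Rmax, or any explicit dose).
#'
#' @param design A [synthetic_design].
#' @param params Generating [linlog_params] for the primary response.
#' @param anchor `"rmin"` (default), `"rmax"`, or a numeric dose.
#' @param amplitude,shape,companion_noise_sd Passed to [generate_companion()].
#' @param seed Overrides `design$seed`.
#' @return List of class `synthetic_pair` with `primary`, `companion`,
#'   `truth` (generating parameters, true Rmax/Rmin, companion anchor,
#'   noise levels, seeds).
#' @export
generate_pair <- function(design, params = default_truth_params(),
                          anchor = "rmin", amplitude = 1,
                          shape = "plateau-at-anchor",
                          companion_noise_sd = NULL, seed = NULL) {
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  primary <- generate_primary(design, params, seed = seed)
  tr <- attr(primary, "truth")
  anchor_dose <- if (is.character(anchor)) {
    switch(match.arg(anchor, c("rmin", "rmax")),
           rmin = tr$rmin, rmax = tr$rmax)
  } else as.numeric(anchor)
  companion <- generate_companion(design, anchor_dose, shape = shape,
                                  amplitude = amplitude,
                                  noise_sd = companion_noise_sd,
                                  seed = seed + 1L)
  structure(list(primary = primary, companion = companion,
                 truth = c(tr, list(anchor = anchor_dose,
                                    companion = attr(companion, "truth")))),
            class = "synthetic_pair")
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates paired titration studies under one or more designs,
#' refits the linear-logistic model to the primary response and the
#' segmented model to the companion, and summarises estimation quality per
#' design cell: bias and RMSE of the estimated Rmax, Rmin and companion
#' breakpoint, and (optionally) empirical coverage of bootstrap percentile
#' intervals for Rmin. Fully seeded: simulation `i` of cell `j` uses a seed
#' derived deterministically from `seed`.
#'
#' @param designs A [synthetic_design] or list of them (the design grid).
#' @param params Generating [linlog_params].
#' @param n_sims Simulations per cell (>= 10).
#' @param seed Root integer seed.
#' @param coverage If `TRUE`, also run a bootstrap per simulation and report
#'   empirical coverage of the Rmin interval.
#' @param B,alpha Bootstrap replicates and level used when `coverage = TRUE`.
#' @return A data.frame with one row per design cell: design descriptors,
#'   number of usable fits, `failed` count, bias/RMSE for `rmax`, `rmin`
#'   and `breakpoint` (dose units), and `rmin_coverage` when requested.
#' @export
recovery_study <- function(designs, params = default_truth_params(),
                           n_sims = 200, seed = 1L, coverage = FALSE,
                           B = 200, alpha = 0.10) {
  if (inherits(designs, "synthetic_design")) designs <- list(designs)
  if (n_sims < 10) stop("`n_sims` must be at least 10", call. = FALSE)
  params <- as_linlog_params(params)
  truth <- stationary_points(params)
  if (truth$regime != "two_points")
    stop("recovery_study needs generating parameters with two stationary ",
         "points", call. = FALSE)

  rows <- list()
  for (j in seq_along(designs)) {
    des <- designs[[j]]
    cell_seeds <- with_seed(seed + j,
                            sample.int(.Machine$integer.max, n_sims))
    est <- matrix(NA_real_, nrow = n_sims, ncol = 3,
                  dimnames = list(NULL, c("rmax", "rmin", "breakpoint")))
    covered <- rep(NA, n_sims)
    failed <- 0L
    for (i in seq_len(n_sims)) {
      pair <- generate_pair(des, params, anchor = "rmin",
                            seed = cell_seeds[i])
      fitp <- tryCatch(fit_linlog(pair$primary), error = function(e) NULL)
      fitc <- tryCatch(fit_segmented(pair$companion,
                                     orientation = "ascending-plateau"),
                       error = function(e) NULL)
      ok <- !is.null(fitp) && !is.null(fitc) &&
        fitp$stationary$regime == "two_points"
      if (!ok) { failed <- failed + 1L; next }
      est[i, ] <- c(fitp$stationary$rmax, fitp$stationary$rmin,
                    fitc$breakpoint)
      if (coverage) {
        bs <- bootstrap_ci(pair$primary, fit = "linlog", B = B,
                           alpha = alpha, seed = cell_seeds[i],
                           warm_start = fitp)
        ci <- bs$ci["rmin", ]
        covered[i] <- is.finite(ci[["low"]]) &&
          ci[["low"]] <= truth$rmin && truth$rmin <= ci[["high"]]
      }
    }
    ok_rows <- stats::complete.cases(est)
    err <- sweep(est[ok_rows, , drop = FALSE], 2,
                 c(truth$rmax, truth$rmin, truth$rmin))
    row <- data.frame(
      dose_min = des$dose_min, dose_max = des$dose_max,
      n_levels = des$n_levels, reps_per_level = des$reps_per_level,
      noise_sd = des$noise_sd, noise_type = des$noise_type,
      n_sims = n_sims, n_ok = sum(ok_rows), failed = failed,
      bias_rmax = mean(err[, "rmax"]), rmse_rmax = sqrt(mean(err[, "rmax"]^2)),
      bias_rmin = mean(err[, "rmin"]), rmse_rmin = sqrt(mean(err[, "rmin"]^2)),
      bias_breakpoint = mean(err[, "breakpoint"]),
      rmse_breakpoint = sqrt(mean(err[, "breakpoint"]^2))
    )
    if (coverage) row$rmin_coverage <- mean(covered, na.rm = TRUE)
    rows[[j]] <- row
  }
  do.call(rbind, rows)
}
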