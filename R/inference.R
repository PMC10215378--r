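# Uncertainty for the derived doses (Rmax, Rmin, segmented breakpoint) via
# a case-resampling bootstrap stratified by dose level, and the headline
# comparison: does a companion response's breakpoint coincide with the
# primary response's Rmin rather than its Rmax.

boot_quantities <- list(
  linlog = c("rmax", "rmin"),
  segmented = "breakpoint"
)

# one stratified case resample: within each dose level, draw row indices
# with replacement, keeping the per-level counts
stratified_resample_idx <- function(dose) {
  idx <- unlist(lapply(split(seq_along(dose), dose), function(ix) {
    ix[sample.int(length(ix), length(ix), replace = TRUE)]
  }), use.names = FALSE)
  sort(idx)
}

#' Bootstrap confidence intervals for derived doses
#'
#' Case-resampling bootstrap stratified by dose level (rows are resampled
#' with replacement within each level, preserving the design's per-level
#' replication), with percentile intervals. For the linear-logistic fit the
#' bootstrapped quantities are Rmax and Rmin; replicates whose refit lands
#' in a monotone or degenerate regime carry no stationary doses and are
#' counted as failed, never silently dropped into the quantiles. For the
#' segmented fit the quantity is the breakpoint.
#'
#' Replicate refits are warm-started from the point estimate (plus one
#' near-linear fallback start), which keeps the bootstrap fast without
#' changing the estimator. One root seed drives everything: per-replicate
#' seeds are drawn once from the root, so results are reproducible and
#' independent of evaluation order.
#'
#' @param data A [dose_response] table.
#' @param fit `"linlog"` or `"segmented"`: which fitting procedure to
#'   bootstrap.
#' @param B Number of bootstrap replicates (>= 50; default 1000).
#' @param alpha Interval level: percentile interval at
#'   `(alpha/2, 1 - alpha/2)` (default 0.05 for 95% intervals).
#' @param seed Root integer seed.
#' @param orientation Passed to [fit_segmented()] when `fit = "segmented"`.
#' @param warm_start Optional precomputed point fit (matching `fit`) to
#'   skip the initial full fit.
#' @return An object of class `bootstrap_result`: `point` (named vector),
#'   `ci` (matrix with rows per quantity, columns `low`/`high`),
#'   `replicates` (matrix of per-replicate estimates, `NA` for failures),
#'   `B`, `alpha`, `failed_replicates`, `unreliable` (TRUE when more than
#'   half the replicates failed), `seed`.
#' @export
bootstrap_ci <- function(data, fit = c("linlog", "segmented"), B = 1000,
                         alpha = 0.05, seed = 1L,
                         orientation = "auto", warm_start = NULL) {
  fit <- match.arg(fit)
  data <- as_dose_response(data)
  if (B < 50) stop("`B` must be at least 50", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)

  point_fit <- if (!is.null(warm_start)) warm_start else switch(fit,
    linlog = fit_linlog(data),
    segmented = fit_segmented(data, orientation = orientation))

  qty <- boot_quantities[[fit]]
  point <- switch(fit,
    linlog = c(rmax = point_fit$stationary$rmax,
               rmin = point_fit$stationary$rmin),
    segmented = c(breakpoint = point_fit$breakpoint))

  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, B))
  reps <- matrix(NA_real_, nrow = B, ncol = length(qty),
                 dimnames = list(NULL, qty))
  for (b in seq_len(B)) {
    idx <- with_seed(rep_seeds[b], stratified_resample_idx(data$dose))
    boot_data <- dose_response(data$dose[idx], data$response[idx])
    est <- tryCatch(switch(fit,
      linlog = {
        f <- fit_linlog(boot_data, start = point_fit$params)
        if (f$stationary$regime != "two_points") NULL
        else c(f$stationary$rmax, f$stationary$rmin)
      },
      segmented = fit_segmented(boot_data,
                                orientation = point_fit$orientation)$breakpoint
    ), error = function(e) NULL)
    if (!is.null(est)) reps[b, ] <- est
  }
  failed <- sum(!stats::complete.cases(reps))
  ci <- t(apply(reps, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) return(c(low = NA_real_, high = NA_real_))
    stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                    type = 7)
  }))
  colnames(ci) <- c("low", "high")
  structure(list(point = point, ci = ci, replicates = reps, B = B,
                 alpha = alpha, failed_replicates = failed,
                 unreliable = failed > B / 2, seed = as.integer(seed),
                 fit = fit),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Stratified case bootstrap (%s fit): B = %d, alpha = %g, seed = %d\n",
              x$fit, x$B, x$alpha, x$seed))
  for (q in names(x$point))
    cat(sprintf("  %-10s point = %g, %g%% CI [%g, %g]\n", q, x$point[[q]],
                100 * (1 - x$alpha), x$ci[q, "low"], x$ci[q, "high"]))
  cat(sprintf("  failed replicates: %d%s\n", x$failed_replicates,
              if (x$unreliable) " (UNRELIABLE: >50% failed)" else ""))
  invisible(x)
}

#' Does a companion response's breakpoint coincide with Rmin or Rmax?
#'
#' Fits the linear-logistic model to the primary (growth-type) response and
#' a segmented linear-plateau model to the companion (physiological)
#' response, then reports which of the primary's two stationary doses the
#' companion's breakpoint falls nearer to. This operationalises
#' "coincides with Rmin" as nearest-inflection by absolute dose distance;
#' when a treatment grid is supplied, the Rmin estimate is additionally
#' mapped to its nearest treatment level.
#'
#' If the primary fit is monotone (no dip), the rise-dip-rise pattern is
#' undetectable in these data and the report says so: `nearest_inflection`
#' and the distances are `NA`.
#'
#' @param primary [dose_response] table of the growth-type response.
#' @param companion [dose_response] table of the physiological response,
#'   on the same dose unit.
#' @param treatments Optional numeric vector of treatment doses.
#' @param orientation Companion segmented-fit orientation (default
#'   `"auto"`).
#' @return An object of class `coincidence_report`: `rmax`, `rmin`,
#'   `regime`, `breakpoint`, `distance_to_rmin`, `distance_to_rmax`,
#'   `nearest_inflection` (`"Rmin"`, `"Rmax"` or `NA`),
#'   `nearest_treatment_of_rmin` (if a grid is given), plus the two fits.
#' @export
compare_rmin_to_breakpoint <- function(primary, companion,
                                       treatments = NULL,
                                       orientation = "auto") {
  primary <- as_dose_response(primary)
  companion <- as_dose_response(companion)
  pu <- attr(primary, "dose_unit"); cu <- attr(companion, "dose_unit")
  if (nzchar(pu) && nzchar(cu) && !identical(pu, cu))
    stop(sprintf("dose unit mismatch: primary is \"%s\", companion is \"%s\"",
                 pu, cu), call. = FALSE)

  fitp <- fit_linlog(primary)
  fitc <- fit_segmented(companion, orientation = orientation)
  st <- fitp$stationary

  if (st$regime != "two_points") {
    rep <- list(rmax = NA_real_, rmin = NA_real_, regime = st$regime,
                breakpoint = fitc$breakpoint,
                distance_to_rmin = NA_real_, distance_to_rmax = NA_real_,
                nearest_inflection = NA_character_,
                nearest_treatment_of_rmin = NA_real_,
                primary_fit = fitp, companion_fit = fitc)
    return(structure(rep, class = "coincidence_report"))
  }
  d_min <- abs(fitc$breakpoint - st$rmin)
  d_max <- abs(fitc$breakpoint - st$rmax)
  nearest <- if (d_min <= d_max) "Rmin" else "Rmax"
  nt <- if (!is.null(treatments)) nearest_treatment(st$rmin, treatments)
        else NA_real_
  structure(list(rmax = st$rmax, rmin = st$rmin, regime = st$regime,
                 breakpoint = fitc$breakpoint,
                 distance_to_rmin = d_min, distance_to_rmax = d_max,
                 nearest_inflection = nearest,
                 nearest_treatment_of_rmin = nt,
                 primary_fit = fitp, companion_fit = fitc),
            class = "coincidence_report")
}

#' @export
print.coincidence_report <- function(x, ...) {
  cat("Companion breakpoint vs primary stationary doses\n")
  if (x$regime != "two_points") {
    cat(sprintf("  primary fit is %s: no Rmax/Rmin exist; the rise-dip-rise pattern is not detectable in these data\n",
                x$regime))
    cat(sprintf("  companion breakpoint = %g\n", x$breakpoint))
    return(invisible(x))
  }
  cat(sprintf("  primary: Rmax = %g, Rmin = %g\n", x$rmax, x$rmin))
  cat(sprintf("  companion breakpoint = %g\n", x$breakpoint))
  cat(sprintf("  |breakpoint - Rmin| = %g, |breakpoint - Rmax| = %g -> nearest inflection: %s\n",
              x$distance_to_rmin, x$distance_to_rmax, x$nearest_inflection))
  if (is.finite(x$nearest_treatment_of_rmin))
    cat(sprintf("  nearest treatment level to Rmin: %g\n",
                x$nearest_treatment_of_rmin))
  invisible(x)
}
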