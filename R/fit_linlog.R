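# Multi-start nonlinear least-squares fitting of the linear-logistic model.
#
# The 5-parameter surface is multi-modal, so the fitter launches
# Levenberg-Marquardt from a deterministic grid of starting values and keeps
# the best local optimum. Doses are standardised to [0, 1] internally for
# conditioning (titration axes range from ~0.5 % of diet to ratios ~100);
# reported coefficients are back-transformed to the caller's dose scale.
# Positivity of (b, c, d, f) is enforced by optimizing their logs.

# Small-sample-corrected information criterion for a least-squares fit.
# k counts mean-model parameters plus the error variance.
aicc_ls <- function(rss, n, k_mean) {
  k <- k_mean + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n + 1e-300) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

r_squared <- function(response, rss) {
  tss <- sum((response - mean(response))^2)
  if (tss == 0) return(NA_real_)
  1 - rss / tss
}

# theta = (a, log b, log c, log d, log f) on the standardised dose scale.
linlog_theta_resid <- function(theta, xs, y) {
  a <- theta[1]; b <- exp(theta[2]); cc <- exp(theta[3])
  logd <- theta[4]; f <- exp(theta[5])
  y - (a + b * xs - cc * stats::plogis(f * xs - logd))
}

# Deterministic multi-start grid on the standardised scale.
# b, a: OLS on the upper third of doses (the post-dip rise); c: 1-3x the
# maximum dip of residuals below that line; logistic midpoint log(d)/f at
# interior dose quantiles; rate f at {2, 5, 10} per unit range.
linlog_start_grid <- function(xs, y) {
  ord <- order(xs)
  xs_o <- xs[ord]; y_o <- y[ord]
  n <- length(xs_o)
  hi <- xs_o >= stats::quantile(xs_o, 2 / 3, names = FALSE)
  if (sum(hi) < 2) hi <- seq_len(n) > n - 2
  cf_hi <- stats::coef(stats::lm.fit(cbind(1, xs_o[hi]), y_o[hi]))
  a0 <- cf_hi[1]; b0 <- max(cf_hi[2], 1e-3 * max(diff(range(y)), 1e-12))
  dip <- max(a0 + b0 * xs - y, na.rm = TRUE)      # depth below the line
  dip <- max(dip, 0.05 * max(diff(range(y)), 1e-12))
  mids <- stats::quantile(xs, c(0.25, 0.4, 0.5, 0.6, 0.75), names = FALSE)
  starts <- list()
  for (cmul in c(1, 2, 3)) {
    for (m in mids) {
      for (f0 in c(2, 5, 10)) {
        starts[[length(starts) + 1L]] <-
          c(a0, log(b0), log(cmul * dip), f0 * m, log(f0))
      }
    }
  }
  # near-linear start: tiny dip, midpoint centred
  cf_all <- stats::coef(stats::lm.fit(cbind(1, xs), y))
  b_all <- max(cf_all[2], 1e-6)
  starts[[length(starts) + 1L]] <-
    c(cf_all[1], log(b_all), log(1e-4 * dip), 2 * 0.5, log(2))
  starts
}

# Box constraints on theta (standardised scale) keep LM away from regions
# where the back-transform would be meaningless.
linlog_theta_bounds <- function(y_scale) {
  list(lower = c(-Inf, log(1e-12 * y_scale), log(1e-12 * y_scale), -60, log(0.05)),
       upper = c(Inf, log(1e12 * y_scale), log(1e12 * y_scale), 200, log(200)))
}

fit_linlog_one_start <- function(theta0, xs, y, bounds) {
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = pmin(pmax(theta0, bounds$lower), bounds$upper),
      fn = linlog_theta_resid, xs = xs, y = y,
      lower = bounds$lower, upper = bounds$upper,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(theta = fit$par, rss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

#' Fit the linear-logistic model to titration data
#'
#' Least-squares estimation of the five linear-logistic coefficients under
#' the sign convention `b, d, f > 0`, `c >= 0`, by Levenberg-Marquardt
#' launched from a deterministic multi-start grid (the surface is
#' multi-modal; single starts routinely land in the pure-linear basin).
#' Doses are rescaled to `[0, 1]` internally and coefficients
#' back-transformed, so the reported fit is invariant to the dose unit.
#' Stationary doses Rmax/Rmin are derived from the winning coefficients via
#' [stationary_points()].
#'
#' @param data A [dose_response] table (or data.frame with `dose` and
#'   `response` columns) with at least 5 observations and 4 distinct doses.
#' @param collapse_reps If `TRUE`, fit per-dose means instead of individual
#'   replicate observations (default `FALSE`: replicates enter as rows,
#'   preserving the error structure for resampling).
#' @param start Optional [linlog_params] used as the only start (plus the
#'   grid's near-linear fallback); used internally for warm-started
#'   bootstrap refits.
#' @return An object of class `linlog_fit`: list with `params`
#'   ([linlog_params]), `stationary` ([stationary_points]), `fitted`,
#'   `residuals`, `rss`, `r2`, `aicc`, `n`, `n_starts_tried`, `converged`,
#'   `dose_scale` (the internal `(shift, scale)` applied), `data`.
#' @examples
#' p <- linlog_params(0, 1, 10, 100, 1)
#' x <- seq(0.5, 6, by = 0.5)
#' d <- dose_response(x, linlog_eval(p, x))
#' fit <- fit_linlog(d)
#' fit$stationary
#' @export
fit_linlog <- function(data, collapse_reps = FALSE, start = NULL) {
  data <- as_dose_response(data)
  if (collapse_reps) data <- collapse_to_means(data)
  x <- data$dose; y <- data$response
  n <- length(x)
  if (n < 5L)
    stop("fit_linlog needs at least 5 observations (5 parameters); got ", n,
         call. = FALSE)
  if (n_distinct_doses(data) < 4L)
    stop("fit_linlog needs at least 4 distinct dose levels", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("response is constant; the linear-logistic model is not identifiable",
         call. = FALSE)

  xmin <- min(x); xr <- diff(range(x))
  xs <- (x - xmin) / xr
  y_scale <- max(diff(range(y)), 1e-12)
  bounds <- linlog_theta_bounds(y_scale)

  starts <- if (!is.null(start)) {
    p <- as_linlog_params(start)
    # forward-transform to the standardised scale
    th <- c(p$a + p$b * xmin, log(p$b * xr), log(max(p$c, 1e-12 * y_scale)),
            p$log_d - p$f * xmin, log(p$f * xr))
    c(list(th), utils::tail(linlog_start_grid(xs, y), 1L))
  } else {
    linlog_start_grid(xs, y)
  }

  best <- NULL
  any_converged <- FALSE
  for (th0 in starts) {
    res <- fit_linlog_one_start(th0, xs, y, bounds)
    if (is.null(res)) next
    any_converged <- any_converged || res$converged
    if (is.null(best) || res$rss < best$rss) best <- res
  }
  if (is.null(best))
    stop("fit_linlog: every start failed", call. = FALSE)

  th <- best$theta
  # back-transform to the caller's dose scale
  b <- exp(th[2]) / xr
  f <- exp(th[5]) / xr
  log_d <- th[4] + f * xmin
  a <- th[1] - b * xmin
  params <- linlog_params(a = a, b = b, c = exp(th[3]), f = f, log_d = log_d)

  fitted <- linlog_eval(params, x)
  resid <- y - fitted
  rss <- sum(resid^2)
  structure(list(
    params = params,
    stationary = stationary_points(params),
    fitted = fitted,
    residuals = resid,
    rss = rss,
    r2 = r_squared(y, rss),
    aicc = aicc_ls(rss, n, 5),
    n = n,
    n_starts_tried = length(starts),
    converged = any_converged,
    dose_scale = c(shift = xmin, scale = xr),
    data = data
  ), class = "linlog_fit")
}

#' @export
print.linlog_fit <- function(x, ...) {
  cat(sprintf("Linear-logistic fit (n = %d, %d start(s), converged = %s)\n",
              x$n, x$n_starts_tried, x$converged))
  print(x$params)
  cat(sprintf("  RSS = %g, R^2 = %.6g, AICc = %.6g\n", x$rss, x$r2, x$aicc))
  print(x$stationary)
  invisible(x)
}

#' Predictions from a linear-logistic fit
#' @param object A `linlog_fit`.
#' @param newdata Optional numeric vector of doses (default: the fitted doses).
#' @param ... Unused.
#' @export
predict.linlog_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  linlog_eval(object$params, newdata)
}
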