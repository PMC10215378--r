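# Exact mathematics of the linear-logistic dose-response model:
#   y = a + b*x - c / (1 + d * exp(-f*x))
# a rising line minus a sigmoidal drop. For c*f > 4b the curve has a local
# maximum at the dose Rmax and a local minimum at the larger dose Rmin.

#' Linear-logistic model parameters
#'
#' Construct and validate the five coefficients of the linear-logistic
#' dose-response model \eqn{y = a + bx - c/(1 + d e^{-fx})}: a rising line
#' (intercept `a`, slope `b`) from which a logistic drop of amplitude `c`,
#' offset `d` and rate `f` is subtracted. The sign convention `b > 0`,
#' `c >= 0`, `d > 0`, `f > 0` fixes the rise-dip-rise geometry; `c = 0` gives
#' the degenerate pure-linear case.
#'
#' For numerical work at large dose scales the logistic offset is carried
#' internally on the log scale: `log_d` may be supplied instead of `d`, and
#' all model evaluation uses `log(d)`, so offsets far beyond the double
#' overflow threshold of `exp()` remain usable.
#'
#' @param a Intercept, in response units.
#' @param b Linear slope, response units per dose unit. Must be positive.
#' @param c Logistic amplitude, response units. Must be non-negative.
#' @param d Logistic offset (dimensionless, positive). Ignored when `log_d`
#'   is given.
#' @param f Logistic rate, per dose unit. Must be positive.
#' @param log_d Optional natural log of `d`; use for very large offsets.
#' @return An object of class `linlog_params`: a named list with fields
#'   `a`, `b`, `c`, `d`, `f`, `log_d`.
#' @examples
#' p <- linlog_params(a = 0, b = 1, c = 10, d = 100, f = 1)
#' linlog_eval(p, c(0, 2.5, 10))
#' stationary_points(p)
#' @export
linlog_params <- function(a, b, c, d = NULL, f, log_d = NULL) {
  if (is.null(log_d)) {
    if (is.null(d)) stop("one of `d` or `log_d` must be supplied", call. = FALSE)
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
      stop("`d` must be a single finite positive number", call. = FALSE)
    log_d <- log(d)
  } else {
    if (!is.numeric(log_d) || length(log_d) != 1L || !is.finite(log_d))
      stop("`log_d` must be a single finite number", call. = FALSE)
    d <- exp(log_d)
  }
  for (nm in c("a", "b", "c", "f")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  if (b <= 0) stop("`b` must be positive (rising linear component)", call. = FALSE)
  if (c < 0) stop("`c` must be non-negative (logistic amplitude)", call. = FALSE)
  if (f <= 0) stop("`f` must be positive (logistic rate)", call. = FALSE)
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         d = as.numeric(d), f = as.numeric(f), log_d = as.numeric(log_d)),
    class = "linlog_params"
  )
}

#' @export
print.linlog_params <- function(x, ...) {
  cat("Linear-logistic parameters: y = a + b*x - c / (1 + d*exp(-f*x))\n")
  cat(sprintf("  a = %g, b = %g, c = %g, d = %g (log d = %g), f = %g\n",
              x$a, x$b, x$c, x$d, x$log_d, x$f))
  invisible(x)
}

as_linlog_params <- function(params) {
  if (inherits(params, "linlog_params")) return(params)
  if (is.list(params) || is.numeric(params)) {
    p <- as.list(params)
    if (!is.null(p$log_d))
      return(linlog_params(p$a, p$b, p$c, f = p$f, log_d = p$log_d))
    return(linlog_params(p$a, p$b, p$c, p$d, p$f))
  }
  stop("cannot interpret `params` as linlog_params", call. = FALSE)
}

# Logistic drop term c / (1 + d*exp(-f*x)), overflow-safe for any f*x:
# equals c * plogis(f*x - log(d)), which saturates instead of overflowing.
logistic_term <- function(params, x) {
  params$c * stats::plogis(params$f * x - params$log_d)
}

#' Evaluate the linear-logistic model
#'
#' Computes \eqn{a + bx - c/(1 + d e^{-fx})}, vectorised over `x`. The
#' logistic term is evaluated through [stats::plogis()] on the shifted
#' logit scale \eqn{fx - \log d}, so large `|f*x|` neither overflows nor
#' underflows: the term tends to 0 as `x -> -Inf` and to `c` as `x -> Inf`.
#'
#' @param params A [linlog_params] object (or coercible list).
#' @param x Numeric vector of doses; all values must be finite.
#' @return Numeric vector of responses, same length as `x`.
#' @export
linlog_eval <- function(params, x) {
  params <- as_linlog_params(params)
  if (!is.numeric(x) || length(x) == 0L)
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop("`x` contains non-finite values", call. = FALSE)
  params$a + params$b * x - logistic_term(params, x)
}

#' Slope (first derivative) of the linear-logistic model
#'
#' Computes \eqn{b - c d f e^{-fx} / (1 + d e^{-fx})^2}. Writing
#' \eqn{p = \mathrm{plogis}(fx - \log d)}, the logistic part equals
#' \eqn{c f \, p (1-p)}, which is the overflow-safe form used here.
#'
#' @inheritParams linlog_eval
#' @return Numeric vector of slopes (response units per dose unit).
#' @export
linlog_slope <- function(params, x) {
  params <- as_linlog_params(params)
  if (!is.numeric(x) || length(x) == 0L)
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop("`x` contains non-finite values", call. = FALSE)
  p <- stats::plogis(params$f * x - params$log_d)
  params$b - params$c * params$f * p * (1 - p)
}

# Relative tolerance deciding when c*f == 4b is treated as a double root.
DISCRIMINANT_RTOL <- 1e-10

#' Stationary doses Rmax and Rmin of the linear-logistic curve
#'
#' Solves `linlog_slope(params, x) = 0` in closed form. Substituting
#' \eqn{u = e^{-fx}} turns the slope equation into the quadratic
#' \eqn{b(1+du)^2 = cdfu}, with discriminant \eqn{\Delta = cf(cf - 4b)}.
#' When \eqn{\Delta > 0} the two roots
#' \eqn{u_\pm = (cf - 2b \pm \sqrt\Delta)/(2bd)} give the local maximum
#' `rmax = -log(u+)/f` (the smaller dose) and the local minimum
#' `rmin = -log(u-)/f` (the larger dose). When \eqn{cf = 4b} (within a
#' relative tolerance of 1e-10) both collapse to the single saddle
#' `log(d)/f`; when \eqn{cf < 4b} (or `c = 0`) the curve is strictly
#' increasing and no stationary point exists.
#'
#' Because \eqn{u_+ u_- = 1/d^2}, the two doses always satisfy
#' `rmax + rmin == 2*log(d)/f`.
#'
#' @param params A [linlog_params] object.
#' @return An object of class `stationary_points`: list with `regime`
#'   (`"two_points"`, `"degenerate"` or `"monotone"`), `rmax`, `rmin`
#'   (dose units; `NA` unless applicable).
#' @examples
#' stationary_points(linlog_params(0, 1, 10, 100, 1))
#' @export
stationary_points <- function(params) {
  params <- as_linlog_params(params)
  b <- params$b; cc <- params$c; f <- params$f; logd <- params$log_d
  cf <- cc * f
  out <- function(regime, rmax = NA_real_, rmin = NA_real_) {
    structure(list(regime = regime, rmax = rmax, rmin = rmin),
              class = "stationary_points")
  }
  if (cc == 0) return(out("monotone"))
  if (abs(cf - 4 * b) <= DISCRIMINANT_RTOL * max(cf, 4 * b)) {
    xm <- logd / f
    return(out("degenerate", rmax = xm, rmin = xm))
  }
  if (cf < 4 * b) return(out("monotone"))
  disc <- cf * (cf - 4 * b)
  s <- sqrt(disc)
  # u_pm = (cf - 2b +/- s) / (2 b d); work with log(u * d) to stay stable
  # for huge d. cf - 2b > s > 0 here since cf > 4b ensures (cf-2b)^2 > disc.
  log_u_plus <- log((cf - 2 * b + s) / (2 * b)) - logd
  log_u_minus <- log((cf - 2 * b - s) / (2 * b)) - logd
  stopifnot(is.finite(log_u_plus), is.finite(log_u_minus))
  out("two_points", rmax = -log_u_plus / f, rmin = -log_u_minus / f)
}

#' @export
print.stationary_points <- function(x, ...) {
  switch(x$regime,
    two_points = cat(sprintf(
      "Stationary doses: Rmax = %g (local maximum), Rmin = %g (local minimum)\n",
      x$rmax, x$rmin)),
    degenerate = cat(sprintf(
      "Degenerate saddle: single stationary dose at %g (c*f = 4b)\n", x$rmax)),
    monotone = cat("Monotone curve: no stationary doses (c*f < 4b)\n")
  )
  invisible(x)
}

#' Classify the regime of a linear-logistic parameter set
#'
#' Convenience wrapper over [stationary_points()] returning only the regime
#' label: `"two_points"` when the curve has distinct Rmax and Rmin,
#' `"degenerate"` at the boundary `c*f = 4b`, `"monotone"` otherwise.
#'
#' @inheritParams stationary_points
#' @return Character scalar regime label.
#' @export
classify_regime <- function(params) {
  stationary_points(params)$regime
}
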