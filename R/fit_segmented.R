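# Segmented (broken-line / linear-plateau) regression: the classical
# requirement-estimation model, a continuous two-phase line with one
# breakpoint. For a fixed breakpoint the model is linear, so the breakpoint
# is profiled over a dense candidate grid and then polished by local
# 1-D optimisation within the best bracket.

seg_design_col <- function(x, bp, orientation) {
  switch(orientation,
    "ascending-plateau" = pmin(x, bp),  # rises, then flat
    "plateau-ascending" = pmax(x, bp))  # flat, then rises
}

seg_rss_at <- function(bp, x, y, orientation) {
  z <- seg_design_col(x, bp, orientation)
  if (stats::sd(z) == 0) {
    mu <- mean(y)
    return(list(rss = sum((y - mu)^2), coef = c(mu, 0)))
  }
  fit <- stats::lm.fit(cbind(1, z), y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

profile_breakpoint <- function(x, y, orientation, n_grid = 512L) {
  lo <- min(x); hi <- max(x)
  cand <- sort(unique(c(seq(lo, hi, length.out = n_grid),
                        (utils::head(sort(unique(x)), -1) +
                         utils::tail(sort(unique(x)), -1)) / 2)))
  rss <- vapply(cand, function(bp) seg_rss_at(bp, x, y, orientation)$rss,
                numeric(1))
  i <- which.min(rss)
  # polish within the bracketing interval around the best grid candidate
  bracket <- c(cand[max(1L, i - 1L)], cand[min(length(cand), i + 1L)])
  bp <- cand[i]; best_rss <- rss[i]
  if (bracket[1] < bracket[2]) {
    opt <- stats::optimize(function(b) seg_rss_at(b, x, y, orientation)$rss,
                           interval = bracket, tol = 1e-10)
    if (opt$objective <= best_rss) {
      bp <- opt$minimum; best_rss <- opt$objective
    }
  }
  list(breakpoint = min(max(bp, lo), hi), rss = best_rss)
}

#' Fit a segmented (linear-plateau) regression
#'
#' Continuous two-phase fit: one linear phase and one flat plateau joined at
#' a breakpoint, the classical broken-line model used to declare a nutrient
#' requirement. `orientation = "ascending-plateau"` rises then flattens
#' (growth-type responses); `"plateau-ascending"` is flat then rises
#' (plasma-metabolite-type responses); `"auto"` fits both and keeps the one
#' with lower residual sum of squares.
#'
#' The breakpoint is profiled over a dense grid (512 points plus all
#' midpoints between adjacent observed doses) and polished by golden-section
#' search in the winning bracket, so the reported optimum is at least as
#' good as any grid search of comparable resolution.
#'
#' @param data A [dose_response] table with >= 4 observations and >= 3
#'   distinct doses.
#' @param orientation `"auto"` (default), `"ascending-plateau"` or
#'   `"plateau-ascending"`.
#' @param collapse_reps Fit per-dose means instead of raw rows.
#' @return An object of class `segmented_fit`: `breakpoint`, `intercept`,
#'   `pre_slope` (slope of the non-flat phase), `plateau` (plateau response
#'   level), `orientation`, `fitted`, `residuals`, `rss`, `r2`, `aicc`,
#'   `n`, `degenerate` (TRUE when the response is constant), `data`.
#' @examples
#' x <- c(1:8); y <- pmin(x, 5)
#' fit_segmented(dose_response(x, y))
#' @export
fit_segmented <- function(data, orientation = c("auto", "ascending-plateau",
                                                "plateau-ascending"),
                          collapse_reps = FALSE) {
  orientation <- match.arg(orientation)
  data <- as_dose_response(data)
  if (collapse_reps) data <- collapse_to_means(data)
  x <- data$dose; y <- data$response
  n <- length(x)
  if (n < 4L)
    stop("fit_segmented needs at least 4 observations; got ", n, call. = FALSE)
  if (n_distinct_doses(data) < 3L)
    stop("fit_segmented needs at least 3 distinct dose levels", call. = FALSE)

  degenerate <- stats::sd(y) == 0
  orients <- if (orientation == "auto")
    c("ascending-plateau", "plateau-ascending") else orientation
  best <- NULL
  for (o in orients) {
    pr <- profile_breakpoint(x, y, o)
    if (is.null(best) || pr$rss < best$rss) {
      best <- pr; best$orientation <- o
    }
  }
  sol <- seg_rss_at(best$breakpoint, x, y, best$orientation)
  b0 <- unname(sol$coef[1]); b1 <- unname(sol$coef[2])
  # value of the flat phase: the design column equals bp on the flat side
  # in either orientation, so the plateau level is b0 + b1*bp
  plateau <- b0 + b1 * best$breakpoint
  fitted <- b0 + b1 * seg_design_col(x, best$breakpoint, best$orientation)
  resid <- y - fitted
  rss <- sum(resid^2)
  structure(list(
    breakpoint = best$breakpoint,
    intercept = b0,
    pre_slope = b1,
    plateau = plateau,
    orientation = best$orientation,
    fitted = fitted,
    residuals = resid,
    rss = rss,
    r2 = r_squared(y, rss),
    aicc = aicc_ls(rss, n, 3),
    n = n,
    degenerate = degenerate,
    data = data
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented (linear-plateau) fit, orientation = %s\n",
              x$orientation))
  cat(sprintf("  breakpoint = %g, slope = %g, plateau level = %g\n",
              x$breakpoint, x$pre_slope, x$plateau))
  cat(sprintf("  RSS = %g, R^2 = %.6g, AICc = %.6g (n = %d)\n",
              x$rss, x$r2, x$aicc, x$n))
  if (x$degenerate) cat("  note: constant response; plateau-only fit\n")
  invisible(x)
}

#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  object$intercept + object$pre_slope *
    seg_design_col(newdata, object$breakpoint, object$orientation)
}

# ---- other candidate models for fit_candidates --------------------------

fit_quadratic <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  rss <- sum(fit$residuals^2)
  list(model = "quadratic", rss = rss, r2 = r_squared(y, rss),
       aicc = aicc_ls(rss, length(y), 3), k = 3,
       coef = fit$coefficients)
}

fit_quadratic_plateau <- function(x, y) {
  # quadratic phase then flat plateau, continuous at the breakpoint;
  # breakpoint profiled like the linear-plateau model
  rss_at <- function(bp) {
    z <- pmin(x, bp)
    X <- cbind(1, z, z^2)
    if (qr(X)$rank < 3) return(list(rss = Inf, coef = rep(NA_real_, 3)))
    fit <- stats::lm.fit(X, y)
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  lo <- min(x); hi <- max(x)
  cand <- seq(lo, hi, length.out = 256L)
  rss <- vapply(cand, function(b) rss_at(b)$rss, numeric(1))
  i <- which.min(rss)
  bracket <- c(cand[max(1L, i - 1L)], cand[min(length(cand), i + 1L)])
  opt <- stats::optimize(function(b) rss_at(b)$rss, interval = bracket,
                         tol = 1e-9)
  bp <- if (opt$objective < rss[i]) opt$minimum else cand[i]
  sol <- rss_at(bp)
  list(model = "quadratic-plateau", rss = sol$rss,
       r2 = r_squared(y, sol$rss), aicc = aicc_ls(sol$rss, length(y), 4),
       k = 4, coef = c(sol$coef, breakpoint = bp))
}

fit_simple_logistic <- function(x, y) {
  # y = a + c * plogis(f*x - log d): a sigmoid rise with a floor
  xmin <- min(x); xr <- diff(range(x)); xs <- (x - xmin) / xr
  resid_fn <- function(th)
    y - (th[1] + exp(th[2]) * stats::plogis(exp(th[4]) * xs - th[3]))
  amp0 <- max(diff(range(y)), 1e-12)
  best <- NULL
  for (m in c(0.25, 0.5, 0.75)) {
    for (f0 in c(2, 5, 10)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(min(y), log(amp0), f0 * m, log(f0)),
                           fn = resid_fn,
                           lower = c(-Inf, log(1e-8 * amp0), -60, log(0.05)),
                           upper = c(Inf, log(1e8 * amp0), 200, log(200)),
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, par = fit$par)
    }
  }
  if (is.null(best))
    return(list(model = "simple-logistic", rss = Inf, r2 = NA_real_,
                aicc = Inf, k = 4, coef = NULL))
  list(model = "simple-logistic", rss = best$rss,
       r2 = r_squared(y, best$rss), aicc = aicc_ls(best$rss, length(y), 4),
       k = 4, coef = best$par)
}

CANDIDATE_MODELS <- c("linear-logistic", "linear-plateau",
                      "quadratic-plateau", "simple-logistic", "quadratic")

# minimum observations for each candidate (mean parameters + 2 so AICc is
# finite)
candidate_min_n <- c("linear-logistic" = 7, "linear-plateau" = 5,
                     "quadratic-plateau" = 6, "simple-logistic" = 6,
                     "quadratic" = 5)

#' Fit and rank a set of candidate dose-response models
#'
#' Fits each requested model to the same data and ranks them by AICc (the
#' small-sample-corrected information criterion), reporting the winner and
#' its margin over the runner-up. Candidates with too few observations for a
#' finite AICc are skipped and recorded. AICc ties (difference below 1e-6)
#' are broken toward the model with fewer parameters, then alphabetically.
#'
#' @param data A [dose_response] table.
#' @param candidates Character vector from `"linear-logistic"`,
#'   `"linear-plateau"`, `"quadratic-plateau"`, `"simple-logistic"`,
#'   `"quadratic"` (default: all five).
#' @param collapse_reps Fit per-dose means instead of raw rows.
#' @return An object of class `model_selection`: data.frame `candidates`
#'   (model, k, rss, r2, aicc), `winner`, `delta_aicc` (winner to runner-up;
#'   `NA` with a single candidate), `skipped`.
#' @export
fit_candidates <- function(data, candidates = CANDIDATE_MODELS,
                           collapse_reps = FALSE) {
  if (length(candidates) == 0L)
    stop("`candidates` must not be empty", call. = FALSE)
  bad <- setdiff(candidates, CANDIDATE_MODELS)
  if (length(bad) > 0L)
    stop("unknown candidate model(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  data <- as_dose_response(data)
  if (collapse_reps) data <- collapse_to_means(data)
  x <- data$dose; y <- data$response
  n <- length(x)

  rows <- list(); skipped <- character(0)
  for (m in unique(candidates)) {
    if (n < candidate_min_n[[m]]) {
      skipped <- c(skipped, m)
      next
    }
    res <- switch(m,
      "linear-logistic" = {
        fit <- tryCatch(fit_linlog(data), error = function(e) NULL)
        if (is.null(fit)) NULL
        else list(model = m, rss = fit$rss, r2 = fit$r2, aicc = fit$aicc,
                  k = 5)
      },
      "linear-plateau" = {
        fit <- tryCatch(fit_segmented(data), error = function(e) NULL)
        if (is.null(fit)) NULL
        else list(model = m, rss = fit$rss, r2 = fit$r2, aicc = fit$aicc,
                  k = 3)
      },
      "quadratic-plateau" = fit_quadratic_plateau(x, y),
      "simple-logistic" = fit_simple_logistic(x, y),
      "quadratic" = fit_quadratic(x, y))
    if (is.null(res)) {
      skipped <- c(skipped, m)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(model = res$model, k = res$k, rss = res$rss,
                 r2 = res$r2, aicc = res$aicc)
  }
  if (length(rows) == 0L)
    stop("no candidate model could be fitted (n = ", n, ")", call. = FALSE)
  tab <- do.call(rbind, rows)
  # rank: aicc, ties (< 1e-6) by fewer parameters then name
  ord <- order(tab$aicc, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  ties <- which(tab$aicc - tab$aicc[1] < 1e-6)
  winner <- tab$model[ties[order(tab$k[ties], tab$model[ties])[1]]]
  delta <- if (nrow(tab) > 1L) tab$aicc[2] - tab$aicc[1] else NA_real_
  rownames(tab) <- NULL
  structure(list(candidates = tab, winner = winner, delta_aicc = delta,
                 skipped = skipped),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AICc\n")
  print(x$candidates, row.names = FALSE)
  cat(sprintf("  winner: %s", x$winner))
  if (!is.na(x$delta_aicc))
    cat(sprintf(" (delta AICc to runner-up = %.4g)", x$delta_aicc))
  cat("\n")
  if (length(x$skipped) > 0L)
    cat("  skipped (insufficient n or fit failure):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
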