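# Fit reports on disk: nested JSON at full precision (round-trips
# bit-for-bit through jsonlite) plus a flat TSV summary for spreadsheets.

report_list <- function(x) UseMethod("report_list")

#' @export
report_list.linlog_fit <- function(x) {
  list(
    model = "linear-logistic",
    params = list(a = x$params$a, b = x$params$b, c = x$params$c,
                  d = x$params$d, f = x$params$f, log_d = x$params$log_d),
    stationary = list(regime = x$stationary$regime,
                      rmax = x$stationary$rmax, rmin = x$stationary$rmin),
    rss = x$rss, r2 = x$r2, aicc = x$aicc, n = x$n,
    n_starts_tried = x$n_starts_tried, converged = x$converged,
    dose_scale = as.list(x$dose_scale),
    residuals = x$residuals
  )
}

#' @export
report_list.segmented_fit <- function(x) {
  list(
    model = "linear-plateau",
    breakpoint = x$breakpoint, intercept = x$intercept,
    pre_slope = x$pre_slope, plateau = x$plateau,
    orientation = x$orientation,
    rss = x$rss, r2 = x$r2, aicc = x$aicc, n = x$n,
    degenerate = x$degenerate, residuals = x$residuals
  )
}

#' @export
report_list.model_selection <- function(x) {
  list(model = "model-selection", winner = x$winner,
       delta_aicc = x$delta_aicc, skipped = x$skipped,
       candidates = x$candidates)
}

#' @export
report_list.bootstrap_result <- function(x) {
  list(model = paste0("bootstrap-", x$fit), point = as.list(x$point),
       ci = apply(x$ci, 1, as.list, simplify = FALSE),
       B = x$B, alpha = x$alpha, failed_replicates = x$failed_replicates,
       unreliable = x$unreliable, seed = x$seed)
}

#' @export
report_list.coincidence_report <- function(x) {
  list(model = "coincidence",
       rmax = x$rmax, rmin = x$rmin, regime = x$regime,
       breakpoint = x$breakpoint,
       distance_to_rmin = x$distance_to_rmin,
       distance_to_rmax = x$distance_to_rmax,
       nearest_inflection = x$nearest_inflection,
       nearest_treatment_of_rmin = x$nearest_treatment_of_rmin,
       primary_fit = report_list(x$primary_fit),
       companion_fit = report_list(x$companion_fit))
}

summary_rows <- function(x) UseMethod("summary_rows")

#' @export
summary_rows.linlog_fit <- function(x) {
  data.frame(model = "linear-logistic", n = x$n, rss = x$rss, r2 = x$r2,
             aicc = x$aicc, rmax = x$stationary$rmax,
             rmin = x$stationary$rmin, breakpoint = NA_real_)
}

#' @export
summary_rows.segmented_fit <- function(x) {
  data.frame(model = "linear-plateau", n = x$n, rss = x$rss, r2 = x$r2,
             aicc = x$aicc, rmax = NA_real_, rmin = NA_real_,
             breakpoint = x$breakpoint)
}

#' @export
summary_rows.model_selection <- function(x) {
  out <- x$candidates
  out$rmax <- NA_real_; out$rmin <- NA_real_; out$breakpoint <- NA_real_
  out
}

#' @export
summary_rows.bootstrap_result <- function(x) {
  data.frame(model = paste0("bootstrap-", x$fit),
             quantity = names(x$point), point = as.numeric(x$point),
             ci_low = x$ci[, "low"], ci_high = x$ci[, "high"],
             B = x$B, alpha = x$alpha, failed = x$failed_replicates)
}

#' @export
summary_rows.coincidence_report <- function(x) {
  data.frame(model = "coincidence", rmax = x$rmax, rmin = x$rmin,
             breakpoint = x$breakpoint,
             nearest_inflection = if (is.na(x$nearest_inflection))
               "none" else x$nearest_inflection,
             nearest_treatment_of_rmin = x$nearest_treatment_of_rmin)
}

signif_df <- function(df, digits = 6) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}

#' Write a fit report to disk (JSON + TSV)
#'
#' Writes two files: `<prefix>.json` holding the full nested result at full
#' double precision (re-reading it reproduces every number bit-for-bit),
#' and `<prefix>.tsv` holding a flat one-row-per-model summary rounded to 6
#' significant digits for display.
#'
#' @param result A `linlog_fit`, `segmented_fit`, `model_selection`,
#'   `bootstrap_result` or `coincidence_report`.
#' @param prefix Output path prefix (directories are created as needed).
#' @return Invisibly, the two paths written (named `json`, `tsv`).
#' @export
write_report <- function(result, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, ".tsv")
  # digits = I(17): 17 significant digits, enough for doubles to
  # round-trip bit-for-bit through fromJSON
  jsonlite::write_json(report_list(result), json_path, auto_unbox = TRUE,
                       digits = I(17), na = "null", null = "null")
  utils::write.table(signif_df(summary_rows(result)), tsv_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
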