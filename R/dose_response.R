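# Tabular container for titration data: one dose column, one response
# column, optional replicate labels, free-text unit metadata.

#' Construct a dose-response table
#'
#' Validated container for titration data: graded doses of one nutrient and
#' a matching response (weight gain, N retention, plasma concentration,
#' antibody titre, ...). Replicates are ordinary repeated rows at the same
#' dose; `replicate_id` is an optional grouping label carried through for
#' bookkeeping.
#'
#' @param dose Numeric vector of dose values (any consistent unit: g/d,
#'   % of diet, amino-acid ratio, ...).
#' @param response Numeric vector of responses, same length as `dose`.
#' @param replicate_id Optional vector of replicate labels, same length.
#' @param dose_unit,response_unit Free-text unit metadata (default `""`).
#' @return A `data.frame` of class `dose_response` with columns `dose`,
#'   `response` (and `replicate_id` if given) and attributes `dose_unit`,
#'   `response_unit`.
#' @examples
#' dr <- dose_response(c(1, 2, 3, 4, 5), c(2.1, 3.9, 6.2, 7.8, 10.1))
#' @export
dose_response <- function(dose, response, replicate_id = NULL,
                          dose_unit = "", response_unit = "") {
  if (!is.numeric(dose) || !is.numeric(response))
    stop("`dose` and `response` must be numeric", call. = FALSE)
  if (length(dose) != length(response))
    stop("`dose` and `response` must have equal length", call. = FALSE)
  if (length(dose) == 0L)
    stop("dose-response table must contain at least one row", call. = FALSE)
  if (any(!is.finite(dose)))
    stop("`dose` contains non-finite values", call. = FALSE)
  if (any(!is.finite(response)))
    stop("`response` contains non-finite values", call. = FALSE)
  df <- data.frame(dose = as.numeric(dose), response = as.numeric(response))
  if (!is.null(replicate_id)) {
    if (length(replicate_id) != length(dose))
      stop("`replicate_id` must match the length of `dose`", call. = FALSE)
    df$replicate_id <- replicate_id
  }
  structure(df,
            dose_unit = as.character(dose_unit),
            response_unit = as.character(response_unit),
            class = c("dose_response", "data.frame"))
}

as_dose_response <- function(data) {
  if (inherits(data, "dose_response")) return(data)
  if (is.data.frame(data) && all(c("dose", "response") %in% names(data)))
    return(dose_response(data$dose, data$response,
                         replicate_id = data[["replicate_id"]]))
  stop("`data` must be a dose_response table or a data.frame with ",
       "`dose` and `response` columns", call. = FALSE)
}

n_distinct_doses <- function(data) length(unique(data$dose))

# Collapse replicate rows to per-dose means (used by the fitters'
# collapse_reps option).
collapse_to_means <- function(data) {
  mu <- tapply(data$response, data$dose, mean)
  dose_response(as.numeric(names(mu)), as.numeric(mu),
                dose_unit = attr(data, "dose_unit"),
                response_unit = attr(data, "response_unit"))
}

#' Read a dose-response table from delimited text
#'
#' Reads a CSV or TSV file with a header row (the delimiter is auto-detected
#' from the header line), extracts the named dose/response columns, drops
#' rows with missing values in either (reporting the count via `message()`),
#' and returns a validated [dose_response] table.
#'
#' @param path Path to a CSV/TSV file.
#' @param dose_col,response_col Column names holding dose and response
#'   (defaults `"dose"`, `"response"`).
#' @param replicate_col Optional column name for replicate labels.
#' @param dose_unit,response_unit Unit metadata to attach.
#' @return A [dose_response] table.
#' @export
read_dose_response <- function(path, dose_col = "dose",
                               response_col = "response",
                               replicate_col = NULL,
                               dose_unit = "", response_unit = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(dose_col, response_col, replicate_col)) {
    if (!col %in% names(raw))
      stop(sprintf("column `%s` not found in %s (columns: %s)",
                   col, path, paste(names(raw), collapse = ", ")),
           call. = FALSE)
  }
  dose <- suppressWarnings(as.numeric(raw[[dose_col]]))
  response <- suppressWarnings(as.numeric(raw[[response_col]]))
  keep <- is.finite(dose) & is.finite(response)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(sprintf("read_dose_response: dropped %d row(s) with missing or non-numeric dose/response", n_drop))
  if (!any(keep))
    stop("no usable rows after dropping missing values: ", path, call. = FALSE)
  rep_id <- if (!is.null(replicate_col)) raw[[replicate_col]][keep] else NULL
  dose_response(dose[keep], response[keep], replicate_id = rep_id,
                dose_unit = dose_unit, response_unit = response_unit)
}

#' Normalize a dietary concentration to a relative dose
#'
#' Expresses an amino-acid concentration as a percentage of its requirement:
#' `100 * concentration / requirement`. This puts studies on different
#' absolute scales onto a common relative-dose axis (100 = exactly at
#' requirement).
#'
#' @param concentration Numeric vector of concentrations (e.g. % of diet).
#' @param requirement Positive scalar (or vector) on the same scale.
#' @return Numeric vector of relative doses, in percent.
#' @examples
#' normalize_dose(0.8, 1.0)  # 80
#' @export
normalize_dose <- function(concentration, requirement) {
  if (!is.numeric(concentration) || !is.numeric(requirement))
    stop("inputs must be numeric", call. = FALSE)
  if (any(!is.finite(requirement)) || any(requirement <= 0))
    stop("`requirement` must be positive", call. = FALSE)
  100 * concentration / requirement
}

#' Map a dose to the nearest treatment level
#'
#' Returns the element of `treatments` closest to `value` in absolute dose
#' distance. Ties are broken toward the larger level, on the reasoning that
#' doses above the growth maximum are the ones carrying functional benefit,
#' so rounding up is the conservative recommendation.
#'
#' @param value Numeric scalar dose (e.g. an estimated Rmin).
#' @param treatments Non-empty numeric vector of treatment doses.
#' @return The nearest treatment level (scalar).
#' @examples
#' nearest_treatment(116.2, c(77, 87, 97, 107, 117, 127))  # 117
#' @export
nearest_treatment <- function(value, treatments) {
  if (length(treatments) == 0L)
    stop("`treatments` must be non-empty", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("`value` must be a single finite number", call. = FALSE)
  if (any(!is.finite(treatments)))
    stop("`treatments` contains non-finite values", call. = FALSE)
  dist <- abs(treatments - value)
  best <- which(dist <= min(dist) + 0)
  max(treatments[best])  # tie -> larger level
}
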