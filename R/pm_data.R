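#' Longitudinal patient-visit data for benefit models
#'
#' Validates and packages long-format clinical-trial data: one row per
#' patient-visit with a treatment phase label, time on treatment (weeks),
#' a continuous response, and zero or more binary patient-level covariates.
#' Baseline visits carry `time = 0`; treatment visits carry the elapsed
#' treatment time.  Covariates must be constant within a patient, since they
#' encode time-independent characteristics (diagnosis subtype, sex, ...).
#'
#' @param df data frame with columns `patient_id`, `phase`
#'   (`"baseline"`/`"treatment"`), `time`, `response`, plus any number of
#'   binary covariate columns.
#' @param covariates character vector naming the covariate columns; by default
#'   every column other than the four reserved ones.
#' @return an object of class `pm_data`: the validated data frame (rows
#'   ordered by patient then time) with attributes `covariates` (column
#'   names) and `patients` (unique ids, in order of first appearance).
#' @export
pm_data <- function(df, covariates = NULL) {
  df <- as.data.frame(df)
  reserved <- c("patient_id", "phase", "time", "response")
  miss <- setdiff(reserved, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df), reserved)
  if (nrow(df) == 0) stop("dataset is empty")

  bad_phase <- which(!df$phase %in% c("baseline", "treatment"))
  if (length(bad_phase) > 0)
    stop("invalid phase at row(s) ", paste(utils::head(bad_phase, 5), collapse = ", "),
         ": must be 'baseline' or 'treatment'")
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time < 0))
    stop("'time' must be non-negative and non-missing")
  bad_t0 <- which(df$phase == "baseline" & df$time != 0)
  if (length(bad_t0) > 0)
    stop("baseline rows must have time = 0; offending row(s): ",
         paste(utils::head(bad_t0, 5), collapse = ", "))
  if (!is.numeric(df$response) || anyNA(df$response))
    stop("'response' must be numeric and non-missing")

  for (cv in covariates) {
    bad <- which(!df[[cv]] %in% c(0, 1))
    if (length(bad) > 0)
      stop("covariate '", cv, "' must be 0/1; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }

  sp <- split(df, df$patient_id)
  for (pid in names(sp)) {
    d <- sp[[pid]]
    if (!any(d$phase == "baseline") || !any(d$phase == "treatment"))
      stop("patient '", pid, "' lacks a baseline or a treatment row")
    for (cv in covariates)
      if (length(unique(d[[cv]])) > 1)
        stop("covariate '", cv, "' varies within patient '", pid, "'")
  }

  patients <- unique(df$patient_id)
  df <- df[order(match(df$patient_id, patients), df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, covariates = covariates, patients = patients,
            class = c("pm_data", "data.frame"))
}

#' @export
print.pm_data <- function(x, ...) {
  cat("Longitudinal benefit-model dataset:",
      length(attr(x, "patients")), "patients,", nrow(x), "visits\n")
  cv <- attr(x, "covariates")
  cat("covariates:", if (length(cv)) paste(cv, collapse = ", ") else "(none)", "\n")
  cat("max treatment time:", max(x$time), "\n")
  NextMethod()
}

#' Read / write long-format benefit-model CSV
#'
#' The CSV has header `patient_id,phase,time,response,<covariates...>`.
#' All dataset invariants are enforced on read with row-numbered messages.
#'
#' @param path file path.
#' @return `read_pm_data`: a [pm_data] object.
#' @export
read_pm_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pm_data(df)
}

#' @rdname read_pm_data
#' @param data a [pm_data] object.
#' @export
write_pm_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Distinct covariate patterns of a dataset
#'
#' Patients are partitioned into groups by their (binary) covariate pattern.
#' Group labels are the patterns pasted with "/" (e.g. `"1"` or `"0/1"`);
#' ordering is lexicographic so group 1 is the all-zero pattern when present.
#'
#' @param data a [pm_data] object.
#' @return data frame with one row per patient: `patient_id`, `group`
#'   (integer), `label`, and the covariate columns.
#' @export
covariate_groups <- function(data) {
  cv <- attr(data, "covariates")
  patients <- attr(data, "patients")
  first <- data[!duplicated(data$patient_id), , drop = FALSE]
  first <- first[match(patients, first$patient_id), , drop = FALSE]
  if (length(cv) == 0) {
    lab <- rep("(all)", nrow(first))
  } else {
    lab <- apply(first[, cv, drop = FALSE], 1, paste, collapse = "/")
  }
  levs <- sort(unique(lab))
  out <- data.frame(patient_id = first$patient_id,
                    group = match(lab, levs),
                    label = lab,
                    stringsAsFactors = FALSE)
  if (length(cv) > 0) out <- cbind(out, first[, cv, drop = FALSE])
  rownames(out) <- NULL
  out
}
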