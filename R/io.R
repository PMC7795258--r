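#' Read long-format laboratory observations
#'
#' Reads a comma-separated file with header columns `patient_id`,
#' `loinc_code`, `value` and `observed_at` (ISO-8601 date). Rows whose value
#' cell is not a finite number are dropped with a logged count; repeated
#' same-day draws are allowed and retained.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `patient_id` (character), `loinc_code`
#'   (character), `value` (double) and `observed_at` (Date).
#' @export
read_lab_observations <- function(path) {
  if (!file.exists(path)) stop("lab observation file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("patient_id", "loinc_code", "value", "observed_at")
  missing_col <- setdiff(required, names(raw))
  if (length(missing_col) > 0) {
    stop("lab observation file is missing required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(raw$value))
  date <- as.Date(raw$observed_at)
  keep <- is.finite(val) & !is.na(date)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message("read_lab_observations: dropped ", dropped, " malformed row(s)")
  }
  tibble::tibble(
    patient_id = raw$patient_id[keep],
    loinc_code = raw$loinc_code[keep],
    value = val[keep],
    observed_at = date[keep]
  )
}

#' Read diagnosis records
#'
#' Accepts either dialect: a CSV with columns `patient_id`, `icd_code`,
#' `occurrences`, or one with `patient_id`, `icd_code`, `event_date` (one row
#' per dated event). The dated-event dialect is collapsed to per-(patient,
#' code) occurrence counts.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `patient_id`, `icd_code`, `occurrences`.
#' @export
read_diagnoses <- function(path) {
  if (!file.exists(path)) stop("diagnosis file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("patient_id", "icd_code")
  missing_col <- setdiff(required, names(raw))
  if (length(missing_col) > 0) {
    stop("diagnosis file is missing required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  if ("occurrences" %in% names(raw)) {
    out <- tibble::tibble(
      patient_id = raw$patient_id,
      icd_code = raw$icd_code,
      occurrences = suppressWarnings(as.integer(raw$occurrences))
    )
    bad <- is.na(out$occurrences) | out$occurrences < 1
    if (any(bad)) message("read_diagnoses: dropped ", sum(bad), " malformed row(s)")
    out[!bad, ]
  } else if ("event_date" %in% names(raw)) {
    tibble::tibble(patient_id = raw$patient_id, icd_code = raw$icd_code) |>
      dplyr::count(.data$patient_id, .data$icd_code, name = "occurrences") |>
      dplyr::mutate(occurrences = as.integer(.data$occurrences))
  } else {
    stop("diagnosis file must have either an 'occurrences' or an 'event_date' column",
         call. = FALSE)
  }
}

#' Write / read an evaluation report
#'
#' Serializes the RMSE-difference report (one row per method x cluster count x
#' abstraction level x missingness batch) as CSV. `read_report()` reproduces
#' the written report to full double precision.
#'
#' @param report An `evaluation_report` (see [run_experiment()]) or a plain
#'   data frame with the report columns.
#' @param path Output CSV path.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   a tibble.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write report: directory does not exist: ", dir, call. = FALSE)
  readr::write_csv(tibble::as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(
    method = readr::col_character(),
    cluster_count = readr::col_integer(),
    abstraction_level = readr::col_character(),
    missingness_batch = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write / read a patient-by-lab matrix as CSV
#'
#' Patients are rows (first column `patient_id`), labs are columns; an empty
#' cell encodes a missing value.
#'
#' @param x A `lab_matrix`.
#' @param path CSV path.
#' @return `write_lab_matrix()` returns `path` invisibly; `read_lab_matrix()`
#'   returns a `lab_matrix`.
#' @export
write_lab_matrix <- function(x, path) {
  stopifnot(inherits(x, "lab_matrix"))
  df <- tibble::as_tibble(unclass(x), rownames = "patient_id")
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_lab_matrix
#' @export
read_lab_matrix <- function(path) {
  if (!file.exists(path)) stop("lab matrix file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[setdiff(names(df), "patient_id")])
  rownames(m) <- df$patient_id
  new_lab_matrix(m)
}
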