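# The patient x lab matrix being imputed: a numeric matrix with patient ids
# as rownames, LOINC codes as colnames, and NA marking missing cells.

new_lab_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  structure(values, class = c("lab_matrix", "matrix", "array"))
}

#' Per-lab missingness fractions
#'
#' @param x A `lab_matrix`.
#' @return A tibble with columns `loinc_code`, `n_observed`, `missingness`.
#' @export
lab_missingness <- function(x) {
  stopifnot(inherits(x, "lab_matrix"))
  n_obs <- colSums(!is.na(x))
  tibble::tibble(
    loinc_code = colnames(x),
    n_observed = as.integer(n_obs),
    missingness = unname(1 - n_obs / nrow(x))
  )
}

#' Aggregate laboratory observations to patient medians
#'
#' Each cell of the returned matrix is the median of all values recorded for
#' that patient and lab (the mean of the two central values for even counts);
#' cells with no observation are missing. Labs whose missingness exceeds
#' `max_missingness` (more than 75% of patients unmeasured, by default) are
#' excluded, mirroring the usual inclusion rule for sparse laboratory codes.
#'
#' @param observations A tibble of lab observations (see
#'   [read_lab_observations()]).
#' @param patients,labs Optional rosters fixing row/column order; default to
#'   the sorted distinct ids/codes present in `observations`.
#' @param max_missingness Labs with missingness strictly above this fraction
#'   are dropped (default 0.75). Use `Inf` to keep all labs.
#' @return A `lab_matrix`.
#' @export
aggregate_median <- function(observations, patients = NULL, labs = NULL,
                             max_missingness = 0.75) {
  stopifnot(is.data.frame(observations))
  if (is.null(patients)) patients <- sort(unique(observations$patient_id))
  if (is.null(labs)) labs <- sort(unique(observations$loinc_code))
  if (length(patients) == 0 || length(labs) == 0) {
    stop("aggregate_median: patient and lab rosters must be non-empty", call. = FALSE)
  }
  med <- observations |>
    dplyr::filter(.data$patient_id %in% patients, .data$loinc_code %in% labs) |>
    dplyr::group_by(.data$patient_id, .data$loinc_code) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  m <- matrix(NA_real_, nrow = length(patients), ncol = length(labs),
              dimnames = list(patients, labs))
  m[cbind(match(med$patient_id, patients), match(med$loinc_code, labs))] <- med$value
  miss <- 1 - colSums(!is.na(m)) / nrow(m)
  drop <- miss > max_missingness
  if (any(drop)) {
    message("aggregate_median: excluded ", sum(drop), " lab(s) with missingness > ",
            max_missingness)
    if (all(drop)) stop("aggregate_median: no lab passes the missingness exclusion rule",
                        call. = FALSE)
    m <- m[, !drop, drop = FALSE]
  }
  new_lab_matrix(m)
}

#' Restrict a lab matrix to a missingness batch
#'
#' Keeps the labs whose missingness is at most `threshold` (the 25%/50%/75%
#' analysis batches); the patient roster is unchanged.
#'
#' @param x A `lab_matrix`.
#' @param threshold One of 0.25, 0.50, 0.75.
#' @return A `lab_matrix` with a subset of the columns.
#' @export
select_batch <- function(x, threshold) {
  stopifnot(inherits(x, "lab_matrix"))
  if (!threshold %in% c(0.25, 0.50, 0.75)) {
    stop("select_batch: threshold must be one of 0.25, 0.50, 0.75", call. = FALSE)
  }
  miss <- lab_missingness(x)$missingness
  keep <- miss <= threshold
  if (!any(keep)) {
    stop("select_batch: no lab has missingness <= ", threshold, call. = FALSE)
  }
  new_lab_matrix(x[, keep, drop = FALSE])
}

#' Descriptive missingness profile of a cohort
#'
#' Per lab: the missingness fraction, the fraction of measured patients with
#' exactly one measurement, and (among patients with two or more
#' measurements) the mean first-to-last observation window in years and the
#' mean measurement count. Labs with no measured patient report `NA` for the
#' observation-derived statistics.
#'
#' @param observations A tibble of dated lab observations.
#' @param x The `lab_matrix` aggregated from the same observations (fixes the
#'   patient denominator and the lab roster).
#' @return A tibble, one row per lab, class `missingness_profile`.
#' @export
profile_missingness <- function(observations, x) {
  stopifnot(is.data.frame(observations), inherits(x, "lab_matrix"))
  miss <- lab_missingness(x)
  per_pat <- observations |>
    dplyr::filter(.data$loinc_code %in% colnames(x),
                  .data$patient_id %in% rownames(x)) |>
    dplyr::group_by(.data$loinc_code, .data$patient_id) |>
    dplyr::summarise(
      n_meas = dplyr::n(),
      window_years = as.numeric(max(.data$observed_at) - min(.data$observed_at)) / 365.25,
      .groups = "drop"
    )
  stats <- per_pat |>
    dplyr::group_by(.data$loinc_code) |>
    dplyr::summarise(
      single_measurement_fraction = mean(.data$n_meas == 1),
      mean_window_years = mean(.data$window_years[.data$n_meas >= 2]),
      mean_measurement_count = mean(.data$n_meas[.data$n_meas >= 2]),
      .groups = "drop"
    )
  out <- miss |>
    dplyr::left_join(stats, by = "loinc_code")
  class(out) <- c("missingness_profile", class(out))
  out
}

#' @export
tidy.lab_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "patient_id") |>
    tidyr::pivot_longer(-"patient_id", names_to = "loinc_code", values_to = "value") |>
    dplyr::mutate(missing = is.na(.data$value))
}

#' @export
print.lab_matrix <- function(x, ...) {
  miss <- 1 - sum(!is.na(x)) / length(x)
  cat(sprintf("<lab_matrix> %d patients x %d labs, %.1f%% cells missing\n",
              nrow(x), ncol(x), 100 * miss))
  invisible(x)
}

#' Plot a missingness profile
#'
#' Mirrors the usual descriptive panels for EHR laboratory sparsity: the
#' single-measurement fraction, the mean observation window and the mean
#' measurement frequency, each against per-lab missingness.
#'
#' @param object A `missingness_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.missingness_profile <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      c("single_measurement_fraction", "mean_window_years", "mean_measurement_count"),
      names_to = "panel", values_to = "stat"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$missingness, y = .data$stat)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "missingness fraction", y = NULL)
}
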