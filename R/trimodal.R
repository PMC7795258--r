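# Tri-modal Gaussian QC for laboratory values. EHR lab orders are missing
# not at random: a test is typically resulted for patients with low, average
# or high values of the analyte, so a single-normal outlier rule is
# miscalibrated. Each lab's patient-median distribution is fitted with a
# three-component Gaussian mixture and outlier cut-offs are derived from the
# component means and standard deviations.

#' Fit a three-component Gaussian mixture to laboratory values
#'
#' Fits `f = N(mu1, sigma1^2) + N(mu2, sigma2^2) + N(mu3, sigma3^2)` by EM.
#' Mixing weights are estimated (a proper likelihood requires them) but the
#' derived outlier cut-offs use only the component means and SDs.
#'
#' Initialization is deterministic and mode-seeking: means at the 10th, 50th
#' and 90th percentiles, all SDs at the sample SD, equal weights. Component
#' variances are floored at `1e-6` times the sample variance so no component
#' can collapse onto a single point. Columns with fewer than 30 values or
#' fewer than 10 distinct values fall back to a single normal replicated into
#' all three components.
#'
#' @param values Numeric vector of observed lab values (finite).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @return A `trimodal_fit`: components sorted by mean, with fields `mean`,
#'   `sd`, `weight`, the final `loglik`, the per-iteration log-likelihood
#'   trace, and a `fallback` flag.
#' @export
fit_trimodal <- function(values, max_iter = 500, tol = 1e-6) {
  values <- values[is.finite(values)]
  n <- length(values)
  n_distinct <- length(unique(values))
  if (n_distinct < 2) {
    stop("fit_trimodal: need at least 2 distinct values, got ", n_distinct, call. = FALSE)
  }
  if (n < 30 || n_distinct < 10) {
    mu <- mean(values)
    sd0 <- stats::sd(values)
    fit <- list(
      mean = rep(mu, 3), sd = rep(sd0, 3), weight = rep(1 / 3, 3),
      loglik = sum(stats::dnorm(values, mu, sd0, log = TRUE)),
      loglik_trace = numeric(0), iterations = 0L, converged = TRUE,
      fallback = TRUE, n = n
    )
    class(fit) <- "trimodal_fit"
    return(fit)
  }

  var_floor <- 1e-6 * stats::var(values)
  mu <- as.numeric(stats::quantile(values, c(0.10, 0.50, 0.90), names = FALSE))
  sg <- rep(stats::sd(values), 3)
  w <- rep(1 / 3, 3)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step
    dens <- vapply(1:3, function(k) w[k] * stats::dnorm(values, mu[k], sg[k]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    resp <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * values) / nk
    v <- vapply(1:3, function(k) sum(resp[, k] * (values - mu[k])^2) / nk[k],
                numeric(1))
    sg <- sqrt(pmax(v, var_floor))
  }
  ord <- order(mu)
  fit <- list(
    mean = mu[ord], sd = sg[ord], weight = w[ord],
    loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
    iterations = iter, converged = converged, fallback = FALSE, n = n
  )
  class(fit) <- "trimodal_fit"
  fit
}

#' Outlier cut-offs from a tri-modal fit
#'
#' The accepted range is
#' `c_low = max(min_i(mu_i - 3 sigma_i), 0)` and
#' `c_high = max_i(mu_i + 3 sigma_i)`. Mixture weights do not enter the
#' cut-offs. The lower cut-off is clamped at zero for every lab.
#'
#' @param fit A `trimodal_fit`, or a list with numeric `mean` and `sd` of
#'   length 3.
#' @return A one-row tibble with columns `c_low`, `c_high`.
#' @export
outlier_bounds <- function(fit) {
  stopifnot(length(fit$mean) == 3, length(fit$sd) == 3)
  tibble::tibble(
    c_low = max(min(fit$mean - 3 * fit$sd), 0),
    c_high = max(fit$mean + 3 * fit$sd)
  )
}

#' Per-lab tri-modal fits and outlier cut-offs
#'
#' Fits each lab column of a matrix and derives its accepted range. Labs
#' whose columns are degenerate (fewer than 2 distinct observed values) get
#' `(-Inf, Inf)` bounds, i.e. no filtering.
#'
#' @param x A `lab_matrix`.
#' @return A tibble with one row per lab: `loinc_code`, `c_low`, `c_high`,
#'   plus the fitted component means/SDs/weights as list-columns in `fit`.
#' @export
lab_outlier_bounds <- function(x) {
  stopifnot(inherits(x, "lab_matrix"))
  purrr::map_dfr(colnames(x), function(lab) {
    v <- x[, lab]
    v <- v[!is.na(v)]
    if (length(unique(v)) < 2) {
      return(tibble::tibble(loinc_code = lab, c_low = -Inf, c_high = Inf,
                            fit = list(NULL)))
    }
    f <- fit_trimodal(v)
    b <- outlier_bounds(f)
    tibble::tibble(loinc_code = lab, c_low = b$c_low, c_high = b$c_high, fit = list(f))
  })
}

#' Mask out-of-range laboratory values
#'
#' Cells with a value strictly below `c_low` or strictly above `c_high` for
#' their lab become missing; values exactly at a cut-off are retained (closed
#' accepted interval). Never unmasks a cell or alters an in-range value.
#'
#' @param x A `lab_matrix`.
#' @param bounds A tibble with columns `loinc_code`, `c_low`, `c_high`
#'   (see [lab_outlier_bounds()]). Labs absent from `bounds` are untouched.
#' @return The filtered `lab_matrix`.
#' @export
apply_outlier_filter <- function(x, bounds) {
  stopifnot(inherits(x, "lab_matrix"), is.data.frame(bounds))
  m <- unclass(x)
  for (i in seq_len(nrow(bounds))) {
    lab <- bounds$loinc_code[i]
    if (!lab %in% colnames(m)) next
    v <- m[, lab]
    out <- !is.na(v) & (v < bounds$c_low[i] | v > bounds$c_high[i])
    m[out, lab] <- NA_real_
  }
  new_lab_matrix(m)
}

#' Fit, bound and filter in one step
#'
#' @param x A `lab_matrix`.
#' @return A list with `matrix` (the filtered `lab_matrix`), `bounds` (the
#'   per-lab cut-off tibble) and `n_filtered` (cells masked).
#' @export
filter_outliers <- function(x) {
  bounds <- lab_outlier_bounds(x)
  filtered <- apply_outlier_filter(x, bounds)
  n_filtered <- sum(!is.na(x)) - sum(!is.na(filtered))
  if (n_filtered > 0) {
    message("filter_outliers: masked ", n_filtered, " out-of-range cell(s)")
  }
  list(matrix = filtered, bounds = bounds, n_filtered = n_filtered)
}

#' @export
tidy.trimodal_fit <- function(x, ...) {
  tibble::tibble(component = 1:3, mean = x$mean, sd = x$sd, weight = x$weight)
}

#' @export
glance.trimodal_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, fallback = x$fallback, n_obs = x$n)
}

#' @export
print.trimodal_fit <- function(x, ...) {
  cat("<trimodal_fit>", if (x$fallback) "(single-normal fallback)" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' Plot a tri-modal fit with its outlier cut-offs
#'
#' Histogram of the values with the fitted mixture density and dashed lines
#' at the accepted-range boundaries.
#'
#' @param object A `trimodal_fit`.
#' @param values The numeric values the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trimodal_fit <- function(object, values, ...) {
  b <- outlier_bounds(object)
  grid <- seq(min(values), max(values), length.out = 400)
  dens <- rowSums(vapply(
    1:3,
    function(k) object$weight[k] * stats::dnorm(grid, object$mean[k], object$sd[k]),
    numeric(length(grid))
  ))
  ggplot2::ggplot(tibble::tibble(value = values), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 50, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = tibble::tibble(value = grid, density = dens),
                       ggplot2::aes(y = .data$density), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = c(b$c_low, b$c_high), linetype = "dashed") +
    ggplot2::labs(x = "value", y = "density")
}
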