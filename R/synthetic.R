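# Synthetic EHR cohort generator. The real study data (health-system EHR)
# are private, so the package ships a generator that emulates their
# structure: latent patient groups with group-specific comorbidity and lab
# profiles, repeated dated measurements, per-lab missingness calibrated to
# targets, a measurement mechanism that is missing not at random (patients
# with low, average or high values are measured preferentially as the MNAR
# strength grows), and injected gross outliers. Ground truth is returned for
# every quantity so recovery can be scored.

#' Construct a synthetic-cohort specification
#'
#' @param n_patients,n_labs,n_icd Cohort dimensions.
#' @param k_true Number of planted patient groups.
#' @param mixing Mixing proportions (length `k_true`, sums to 1).
#' @param prevalence `k_true x n_icd` matrix of per-group ICD prevalences in
#'   `[0, 1]`.
#' @param icd_rate `k_true x n_icd` matrix of zero-truncated Poisson rates
#'   for occurrence counts of present codes.
#' @param lab_mean,lab_sd `k_true x n_labs` matrices of per-group lab value
#'   means and SDs (SDs > 0).
#' @param miss_target Length-`n_labs` vector of target missingness fractions
#'   in `[0, 0.9]`.
#' @param gamma MNAR strength (>= 0): the measurement propensity rises with
#'   the absolute standardized deviation of the true value from the
#'   population mean.
#' @param cluster_offset Length-`k_true` additive group offsets on the
#'   measurement-propensity logit.
#' @param outlier_rate Fraction of measured cells whose recorded values are
#'   multiplied by 10 (in `[0, 0.05]`).
#' @param nb_size,nb_mu Length-`n_labs` negative-binomial parameters for
#'   per-(patient, lab) measurement counts (zero-truncated: a measured
#'   patient has at least one draw).
#' @param informative_fraction Fraction of labs whose means separate the
#'   groups (bookkeeping; the separation itself lives in `lab_mean`).
#' @param seed Default generation seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, n_labs, n_icd, k_true, mixing,
                        prevalence, icd_rate, lab_mean, lab_sd, miss_target,
                        gamma = 0, cluster_offset = rep(0, k_true),
                        outlier_rate = 0, nb_size = rep(1, n_labs),
                        nb_mu = rep(5, n_labs), informative_fraction = NA_real_,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients), n_labs = as.integer(n_labs),
    n_icd = as.integer(n_icd), k_true = as.integer(k_true),
    mixing = as.numeric(mixing), prevalence = prevalence, icd_rate = icd_rate,
    lab_mean = lab_mean, lab_sd = lab_sd, miss_target = as.numeric(miss_target),
    gamma = gamma, cluster_offset = as.numeric(cluster_offset),
    outlier_rate = outlier_rate, nb_size = as.numeric(nb_size),
    nb_mu = as.numeric(nb_mu), informative_fraction = informative_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    spec$n_patients >= 1, spec$n_labs >= 1, spec$n_icd >= 1, spec$k_true >= 1,
    length(spec$mixing) == spec$k_true,
    abs(sum(spec$mixing) - 1) < 1e-9,
    all(dim(spec$prevalence) == c(spec$k_true, spec$n_icd)),
    all(spec$prevalence >= 0 & spec$prevalence <= 1),
    all(dim(spec$icd_rate) == c(spec$k_true, spec$n_icd)),
    all(spec$icd_rate > 0),
    all(dim(spec$lab_mean) == c(spec$k_true, spec$n_labs)),
    all(dim(spec$lab_sd) == c(spec$k_true, spec$n_labs)),
    all(spec$lab_sd > 0),
    length(spec$miss_target) == spec$n_labs,
    all(spec$miss_target >= 0 & spec$miss_target <= 0.9),
    spec$gamma >= 0,
    length(spec$cluster_offset) == spec$k_true,
    spec$outlier_rate >= 0, spec$outlier_rate <= 0.05,
    all(spec$nb_size > 0), all(spec$nb_mu > 0)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Default synthetic-cohort specifications
#'
#' `"tiny"` (300 patients x 8 labs x 40 ICD codes) is sized for unit tests;
#' `"standard"` (2000 patients x 20 labs x 200 ICD codes) is the study
#' condition used for pipeline evaluation. Both plant `k_true = 4` equal
#' groups; half the labs are group-informative with between-group mean
#' separation of two within-group SDs; per-lab missingness targets are
#' spread over 0.10-0.75; measurement counts are overdispersed (negative
#' binomial) with sparser labs drawing fewer repeats, so high-missingness
#' labs show many single-measurement patients.
#'
#' @param scale `"tiny"` or `"standard"`.
#' @return A `cohort_spec`.
#' @export
default_spec <- function(scale = c("standard", "tiny")) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    tiny = list(n = 300L, labs = 8L, icd = 40L),
    standard = list(n = 2000L, labs = 20L, icd = 200L)
  )
  k <- 4L
  n_labs <- dims$labs
  n_icd <- dims$icd
  n_informative <- ceiling(n_labs / 2)

  lab_mean <- matrix(10, k, n_labs)
  for (c in seq_len(k)) {
    lab_mean[c, seq_len(n_informative)] <- 10 + 2 * (c - (k + 1) / 2)
  }
  lab_sd <- matrix(1, k, n_labs)

  # ICD blocks: a common background block plus group-specific blocks with
  # elevated prevalence and recording rates; off-group codes keep a low rate
  # so single recordings occur and the rule of 2 is exercised.
  n_common <- max(4L, round(0.1 * n_icd))
  prevalence <- matrix(0.02, k, n_icd)
  prevalence[, seq_len(n_common)] <- 0.4
  icd_rate <- matrix(1.2, k, n_icd)
  icd_rate[, seq_len(n_common)] <- 2.5
  specific <- (n_common + 1):n_icd
  owner <- ((specific - n_common - 1) %% k) + 1
  for (c in seq_len(k)) {
    own <- specific[owner == c]
    prevalence[c, own] <- 0.30
    icd_rate[c, own] <- 3
  }

  miss_target <- seq(0.10, 0.75, length.out = n_labs)
  cohort_spec(
    n_patients = dims$n, n_labs = n_labs, n_icd = n_icd, k_true = k,
    mixing = rep(1 / k, k), prevalence = prevalence, icd_rate = icd_rate,
    lab_mean = lab_mean, lab_sd = lab_sd, miss_target = miss_target,
    gamma = 1, cluster_offset = seq(0.5, -0.5, length.out = k),
    outlier_rate = 0.01, nb_size = rep(1, n_labs),
    nb_mu = 1 + 9 * (1 - miss_target),
    informative_fraction = n_informative / n_labs,
    seed = 101L
  )
}

# inverse-CDF draw from a zero-truncated Poisson / negative binomial
rztpois <- function(u, lambda) {
  f0 <- stats::dpois(0, lambda)
  stats::qpois(pmin(f0 + u * (1 - f0), 1 - 1e-12), lambda)
}
rztnbinom <- function(u, size, mu) {
  f0 <- stats::pnbinom(0, size = size, mu = mu)
  stats::qnbinom(pmin(f0 + u * (1 - f0), 1 - 1e-12), size = size, mu = mu)
}

#' Generate a synthetic EHR cohort
#'
#' Draws group labels, per-group ICD occurrence counts, true lab values, a
#' missing-not-at-random measurement mask calibrated per lab to the target
#' missingness, repeated dated measurements, and injected outliers. The
#' per-lab propensity intercept is found by bisection against the realized
#' measurement indicator, so the realized missingness matches the target
#' within the calibration contract at any seed.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A `cohort` list: `lab_observations` (long tibble), `diagnoses`
#'   (occurrence-count tibble), `truth` (list of ground-truth tibbles:
#'   `clusters`, `true_values`, `propensity`, `outliers`,
#'   `realized_missingness`), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  k <- spec$k_true
  patients <- sprintf("P%05d", seq_len(n))
  labs <- sprintf("%04d-1", 1000 + seq_len(spec$n_labs))
  codes <- sprintf("C%03d", seq_len(spec$n_icd))

  withr::with_seed(seed, {
    cl <- sample.int(k, n, replace = TRUE, prob = spec$mixing)

    # diagnoses: presence ~ Bernoulli(prevalence), occurrences ~ ZT-Poisson
    prev <- spec$prevalence[cl, , drop = FALSE]
    present <- matrix(stats::runif(n * spec$n_icd), n) < prev
    lam <- spec$icd_rate[cl, , drop = FALSE]
    occ_u <- stats::runif(sum(present))
    occ <- rztpois(occ_u, lam[present])
    idx <- which(present, arr.ind = TRUE)
    diagnoses <- tibble::tibble(
      patient_id = patients[idx[, 1]],
      icd_code = codes[idx[, 2]],
      occurrences = as.integer(occ)
    ) |> dplyr::arrange(.data$patient_id, .data$icd_code)

    # true latent lab values
    true_mat <- matrix(stats::rnorm(n * spec$n_labs,
                                    mean = spec$lab_mean[cl, , drop = FALSE],
                                    sd = spec$lab_sd[cl, , drop = FALSE]), n)

    # MNAR measurement propensity: logit(P(measured)) = alpha_j +
    # group offset + gamma * |z|, z the standardized deviation from the
    # population mean of the lab
    pop_mean <- colSums(spec$mixing * spec$lab_mean)
    pop_var <- colSums(spec$mixing * (spec$lab_sd^2 + spec$lab_mean^2)) - pop_mean^2
    zstd <- abs(sweep(sweep(true_mat, 2, pop_mean), 2, sqrt(pop_var), "/"))
    shift <- spec$cluster_offset[cl] + spec$gamma * zstd
    u_meas <- matrix(stats::runif(n * spec$n_labs), n)
    measured <- matrix(FALSE, n, spec$n_labs)
    alpha <- numeric(spec$n_labs)
    for (j in seq_len(spec$n_labs)) {
      target <- spec$miss_target[j]
      realized_miss <- function(a) mean(u_meas[, j] > stats::plogis(a + shift[, j]))
      lo <- -40; hi <- 40
      for (step in seq_len(60)) {
        mid <- (lo + hi) / 2
        if (realized_miss(mid) > target) lo <- mid else hi <- mid
      }
      alpha[j] <- (lo + hi) / 2
      if (abs(realized_miss(alpha[j]) - target) > 0.03) {
        stop("generate_cohort: cannot calibrate missingness for lab ", labs[j],
             " (target ", target, ")", call. = FALSE)
      }
      measured[, j] <- u_meas[, j] <= stats::plogis(alpha[j] + shift[, j])
    }

    # measurement counts (zero-truncated NB) and outlier cells
    cells <- which(measured, arr.ind = TRUE)
    counts <- rztnbinom(stats::runif(nrow(cells)),
                        size = spec$nb_size[cells[, 2]],
                        mu = spec$nb_mu[cells[, 2]])
    is_outlier_cell <- stats::runif(nrow(cells)) < spec$outlier_rate

    # repeated measurements: true value + 10% noise, dated uniformly over a
    # 10-year window; outlier cells have all their recorded values x10
    rep_idx <- rep(seq_len(nrow(cells)), counts)
    noise_sd <- 0.1 * spec$lab_sd[cbind(cl[cells[, 1]], cells[, 2])]
    vals <- true_mat[cells][rep_idx] +
      stats::rnorm(length(rep_idx), 0, noise_sd[rep_idx])
    vals[is_outlier_cell[rep_idx]] <- vals[is_outlier_cell[rep_idx]] * 10
    dates <- as.Date("2010-01-01") + sample.int(3652, length(rep_idx), replace = TRUE) - 1
    observations <- tibble::tibble(
      patient_id = patients[cells[rep_idx, 1]],
      loinc_code = labs[cells[rep_idx, 2]],
      value = vals,
      observed_at = dates
    ) |> dplyr::arrange(.data$patient_id, .data$loinc_code, .data$observed_at)

    truth <- list(
      clusters = tibble::tibble(patient_id = patients, cluster = as.integer(cl)),
      true_values = tibble::tibble(
        patient_id = rep(patients, spec$n_labs),
        loinc_code = rep(labs, each = n),
        true_value = as.numeric(true_mat)
      ),
      propensity = tibble::tibble(
        patient_id = rep(patients, spec$n_labs),
        loinc_code = rep(labs, each = n),
        p_measured = as.numeric(stats::plogis(
          matrix(alpha, n, spec$n_labs, byrow = TRUE) + shift
        ))
      ),
      outliers = tibble::tibble(
        patient_id = patients[cells[is_outlier_cell, 1]],
        loinc_code = labs[cells[is_outlier_cell, 2]]
      ),
      realized_missingness = tibble::tibble(
        loinc_code = labs,
        target = spec$miss_target,
        realized = 1 - colSums(measured) / n
      )
    )
  })

  structure(
    list(lab_observations = observations, diagnoses = diagnoses,
         truth = truth, spec = spec, seed = seed),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d labs, %d ICD codes, %d planted group(s); %d observations\n",
              x$spec$n_patients, x$spec$n_labs, x$spec$n_icd, x$spec$k_true,
              nrow(x$lab_observations)))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `lab_observations.csv` and `diagnoses.csv` in the dialects the
#' package readers accept, the ground-truth tables as
#' `truth_<name>.csv`, and the specification as `spec.yaml`. All files are
#' plainly labelled as synthetic by provenance (they come from
#' [generate_cohort()]).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$lab_observations, file.path(dir, "lab_observations.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$diagnoses, file.path(dir, "diagnoses.csv"), progress = FALSE)
  for (nm in names(cohort$truth)) {
    readr::write_csv(cohort$truth[[nm]], file.path(dir, paste0("truth_", nm, ".csv")),
                     progress = FALSE)
  }
  spec_list <- lapply(unclass(cohort$spec), function(x) {
    if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE) else x
  })
  yaml::write_yaml(spec_list, file.path(dir, "spec.yaml"))
  invisible(dir)
}
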