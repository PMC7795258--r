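# Evaluation of the hybrid (cluster-wise) strategy against global
# imputation: withhold observed cells per lab, impute with both arms on the
# same masked matrix, and compare per-lab RMSE. Negative differences
# (hybrid - standard) mean the cluster-wise strategy imputes better.

#' Withhold observed cells for evaluation
#'
#' For every lab, masks `min(holdout_per_lab, observed - 1)` observed cells,
#' chosen uniformly at random without replacement; at least one observed
#' value always remains per lab (donor-based models need a donor). The
#' withheld cells are disjoint from originally-missing cells by
#' construction, and the plan is identical under seed reuse.
#'
#' @param x A `lab_matrix`; every lab must have at least 2 observed values.
#' @param holdout_per_lab Cells to withhold per lab (default 100).
#' @param seed Integer seed for the masking stream.
#' @return A list with `masked` (the `lab_matrix` with withheld cells set
#'   missing) and `plan` (a `mask_plan` tibble: `patient_id`, `loinc_code`,
#'   `true_value`).
#' @export
make_mask <- function(x, holdout_per_lab = 100, seed) {
  stopifnot(inherits(x, "lab_matrix"))
  if (holdout_per_lab < 1) stop("make_mask: holdout_per_lab must be >= 1", call. = FALSE)
  m <- unclass(x)
  n_obs <- colSums(!is.na(m))
  low <- colnames(m)[n_obs < 2]
  if (length(low) > 0) {
    stop("make_mask: lab(s) with fewer than 2 observed values: ",
         paste(low, collapse = ", "), call. = FALSE)
  }
  plan_rows <- vector("list", ncol(m))
  withr::with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      obs_idx <- which(!is.na(m[, j]))
      k <- min(holdout_per_lab, length(obs_idx) - 1L)
      pick <- obs_idx[sample.int(length(obs_idx), k)]
      plan_rows[[j]] <- tibble::tibble(
        patient_id = rownames(m)[pick],
        loinc_code = colnames(m)[j],
        true_value = m[pick, j]
      )
      m[pick, j] <- NA_real_
    }
  })
  plan <- dplyr::bind_rows(plan_rows)
  attr(plan, "seed") <- seed
  class(plan) <- c("mask_plan", class(plan))
  list(masked = new_lab_matrix(m), plan = plan)
}

#' Cluster-wise (hybrid) imputation
#'
#' Partitions the patients by cluster label and runs [mice_impute()] on each
#' sub-matrix with its own derived substream (label `"cluster<k>"`), then
#' reassembles the completions in the original patient order. Clusters
#' smaller than `max(30, 2 * n_labs)` are too small for stable conditional
#' models and fall back to the global model (substream `"global"`); a
#' variable that is all-missing inside a cluster falls back to the global
#' observed pool for its donor draws.
#'
#' @param masked A `lab_matrix`.
#' @param clusters A `cluster_assignment` covering exactly the matrix
#'   patients.
#' @param method,iterations,donors,rf_trees,matching Passed to
#'   [mice_impute()].
#' @param seed Master seed; per-cluster seeds are derived with
#'   [rng_substream()].
#' @return A `clusterwise_result`: `data` (completed `lab_matrix`),
#'   `cluster_sizes`, `fallback_clusters`, `seed`.
#' @export
clusterwise_impute <- function(masked, clusters, method = c("pmm", "rf"),
                               iterations = 5, donors = 5, rf_trees = 10,
                               seed = 1L, matching = c("type1", "point")) {
  method <- match.arg(method)
  matching <- match.arg(matching)
  stopifnot(inherits(masked, "lab_matrix"), is.data.frame(clusters))
  if (!setequal(clusters$patient_id, rownames(masked))) {
    stop("clusterwise_impute: cluster assignment must cover exactly the matrix patients",
         call. = FALSE)
  }
  lab_of <- clusters$cluster[match(rownames(masked), clusters$patient_id)]
  labels <- sort(unique(lab_of))
  sizes <- vapply(labels, function(l) sum(lab_of == l), integer(1))
  names(sizes) <- paste0("cluster", labels)
  floor_n <- max(30, 2 * ncol(masked))
  fallback <- labels[sizes < floor_n]
  global_pool <- lapply(seq_len(ncol(masked)), function(j) {
    v <- masked[, j]
    v[!is.na(v)]
  })
  names(global_pool) <- colnames(masked)
  completed <- unclass(masked)
  global_res <- NULL
  if (length(fallback) > 0) {
    message("clusterwise_impute: cluster(s) ", paste(fallback, collapse = ", "),
            " below the size floor (", floor_n, "); imputed by the global model")
    global_res <- mice_impute(masked, method = method, iterations = iterations,
                              donors = donors, rf_trees = rf_trees,
                              seed = rng_substream(seed, "global"),
                              matching = matching)
  }
  for (l in labels) {
    rows <- which(lab_of == l)
    if (l %in% fallback) {
      completed[rows, ] <- unclass(global_res$data)[rows, ]
    } else {
      sub <- new_lab_matrix(unclass(masked)[rows, , drop = FALSE])
      res <- mice_impute(sub, method = method, iterations = iterations,
                         donors = donors, rf_trees = rf_trees,
                         seed = rng_substream(seed, paste0("cluster", l)),
                         matching = matching, fallback_pool = global_pool)
      completed[rows, ] <- unclass(res$data)
    }
  }
  structure(
    list(data = new_lab_matrix(completed), cluster_sizes = sizes,
         fallback_clusters = fallback, method = method, seed = seed),
    class = "clusterwise_result"
  )
}

#' Per-lab RMSE on withheld cells
#'
#' @param plan A `mask_plan` from [make_mask()].
#' @param completed A completed matrix: a `lab_matrix`, numeric matrix,
#'   `mice_result` or `clusterwise_result`.
#' @return A tibble with columns `loinc_code`, `rmse`, `n_cells`.
#' @export
rmse_by_lab <- function(plan, completed) {
  if (inherits(completed, c("mice_result", "clusterwise_result"))) {
    completed <- completed$data
  }
  stopifnot(is.matrix(completed), is.data.frame(plan))
  idx <- cbind(match(plan$patient_id, rownames(completed)),
               match(plan$loinc_code, colnames(completed)))
  imputed <- completed[idx]
  if (anyNA(imputed)) stop("rmse_by_lab: some withheld cells were not imputed", call. = FALSE)
  tibble::tibble(loinc_code = plan$loinc_code,
                 err2 = (imputed - plan$true_value)^2) |>
    dplyr::group_by(.data$loinc_code) |>
    dplyr::summarise(rmse = sqrt(mean(.data$err2)), n_cells = dplyr::n(),
                     .groups = "drop")
}

#' Construct and validate a single run configuration
#'
#' One row of the experiment grid together with the engine settings: the
#' abstraction level g, the cluster count K, the conditional model, donor
#' count, sweep count, forest size, missingness batch, holdout size, repeat
#' count and master seed. Invalid combinations error immediately.
#'
#' @param abstraction_level Positive integer or `"full"`.
#' @param cluster_count Positive integer K.
#' @param mice_method `"pmm"` or `"rf"`.
#' @param donors Donor-set size (>= 1, default 5).
#' @param mice_iterations Sweeps (>= 1, default 5).
#' @param rf_trees Trees for the rf model (default 10).
#' @param missingness_batch One of 0.25, 0.50, 0.75.
#' @param holdout_per_lab Withheld cells per lab (default 100).
#' @param repeats Mask/impute repeats (>= 1, default 10).
#' @param seed Integer master seed.
#' @return A one-row `run_config` tibble; rows from several calls can be
#'   bound together and passed to [run_experiment()] as the grid.
#' @export
run_config <- function(abstraction_level = "full", cluster_count = 4,
                       mice_method = c("pmm", "rf"), donors = 5,
                       mice_iterations = 5, rf_trees = 10,
                       missingness_batch = 0.75, holdout_per_lab = 100,
                       repeats = 10, seed = 1L) {
  mice_method <- match.arg(mice_method)
  if (!identical(abstraction_level, "full")) {
    g <- suppressWarnings(as.numeric(abstraction_level))
    if (is.na(g) || g <= 0 || g != floor(g)) {
      stop("run_config: abstraction_level must be a positive integer or \"full\"",
           call. = FALSE)
    }
  }
  stopifnot(cluster_count >= 1, donors >= 1, mice_iterations >= 1,
            rf_trees >= 1, repeats >= 1, holdout_per_lab >= 1)
  if (!missingness_batch %in% c(0.25, 0.50, 0.75)) {
    stop("run_config: missingness_batch must be one of 0.25, 0.50, 0.75",
         call. = FALSE)
  }
  out <- tibble::tibble(
    method = mice_method, cluster_count = as.integer(cluster_count),
    abstraction_level = as.character(abstraction_level),
    missingness_batch = as.numeric(missingness_batch),
    donors = as.integer(donors), mice_iterations = as.integer(mice_iterations),
    rf_trees = as.integer(rf_trees),
    holdout_per_lab = as.integer(holdout_per_lab),
    repeats = as.integer(repeats), seed = as.integer(seed)
  )
  class(out) <- c("run_config", class(out))
  out
}

#' Build an experiment configuration grid
#'
#' @param methods Character vector from `c("pmm", "rf")`.
#' @param cluster_counts Integer vector of K values.
#' @param abstraction_levels Vector of g values (integers and/or `"full"`).
#' @param batches Numeric vector from `c(0.25, 0.50, 0.75)`.
#' @return A tibble with one row per combination.
#' @export
experiment_grid <- function(methods = "pmm", cluster_counts = 4,
                            abstraction_levels = "full", batches = 0.75) {
  tidyr::crossing(
    method = methods,
    cluster_count = as.integer(cluster_counts),
    abstraction_level = as.character(abstraction_levels),
    missingness_batch = as.numeric(batches)
  )
}

#' Run the hybrid-vs-standard imputation experiment
#'
#' For each repeat, one mask plan is drawn per missingness batch; every grid
#' configuration then imputes the SAME masked matrix twice — the hybrid arm
#' cluster-wise on the latent-comorbidity clusters for its (g, K), the
#' standard arm globally — with independent derived substreams, and per-lab
#' RMSEs on the withheld cells are recorded. The report averages per-lab
#' RMSEs over repeats and emits one mean RMSE difference (hybrid minus
#' standard) per (method, K, g, batch); negative values mean the hybrid
#' strategy imputes better. The standard arm is independent of (g, K) and is
#' shared across grid cells of the same method, batch and repeat.
#'
#' @param matrix A `lab_matrix` (patient medians, post-QC).
#' @param diagnoses Diagnosis records tibble (for the comorbidity embedding).
#' @param grid A configuration grid (see [experiment_grid()]).
#' @param seed Master seed; all stage streams derive from it.
#' @param holdout_per_lab Withheld cells per lab per repeat (default 100).
#' @param repeats Number of mask/impute repeats (default 10).
#' @param iterations,donors,rf_trees,matching Engine settings, shared by both
#'   arms.
#' @return An `evaluation_report` tibble (one row per configuration) with a
#'   `per_lab` attribute holding the repeat-averaged per-lab RMSE table.
#' @export
run_experiment <- function(matrix, diagnoses, grid, seed,
                           holdout_per_lab = 100, repeats = 10,
                           iterations = 5, donors = 5, rf_trees = 10,
                           matching = "type1") {
  stopifnot(inherits(matrix, "lab_matrix"), is.data.frame(diagnoses),
            is.data.frame(grid), repeats >= 1)
  grid <- tibble::as_tibble(grid)
  grid$abstraction_level <- as.character(grid$abstraction_level)
  grid$cluster_count <- as.integer(grid$cluster_count)

  A <- rule_of_two(diagnoses, patients = rownames(matrix))
  fact <- svd_factorize(A)
  rank_avail <- length(fact$d)
  latent_of <- function(g_label) {
    g <- if (identical(g_label, "full")) "full" else as.numeric(g_label)
    if (is.numeric(g) && g > rank_avail) {
      message("run_experiment: g = ", g, " exceeds rank ", rank_avail,
              "; using full rank")
      g <- "full"
    }
    noise_reduce(abstraction(fact, g))
  }
  latents <- lapply(unique(grid$abstraction_level), latent_of)
  names(latents) <- unique(grid$abstraction_level)

  combos <- unique(grid[c("abstraction_level", "cluster_count")])
  clus <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$abstraction_level[i]
    K <- combos$cluster_count[i]
    clus[[paste(g, K)]] <- cluster_patients(
      latents[[g]], K, seed = rng_substream(seed, sprintf("kmeans/g%s/K%d", g, K))
    )
  }

  per_repeat <- list()
  for (b in unique(grid$missingness_batch)) {
    Mb <- select_batch(matrix, b)
    grid_b <- grid[grid$missingness_batch == b, ]
    for (r in seq_len(repeats)) {
      mask <- make_mask(Mb, holdout_per_lab,
                        seed = rng_substream(seed, sprintf("mask/b%s/r%d", b, r)))
      std_cache <- list()
      for (i in seq_len(nrow(grid_b))) {
        cfg <- grid_b[i, ]
        if (is.null(std_cache[[cfg$method]])) {
          std <- mice_impute(mask$masked, method = cfg$method,
                             iterations = iterations, donors = donors,
                             rf_trees = rf_trees, matching = matching,
                             seed = rng_substream(seed, sprintf("std/%s/b%s/r%d",
                                                                cfg$method, b, r)))
          std_cache[[cfg$method]] <- rmse_by_lab(mask$plan, std)
        }
        if (cfg$cluster_count == 1L) {
          # a single cluster IS the global algorithm: share the standard
          # arm's stream so the difference is exactly zero
          rh <- std_cache[[cfg$method]]
        } else {
          hyb <- clusterwise_impute(
            mask$masked, clus[[paste(cfg$abstraction_level, cfg$cluster_count)]],
            method = cfg$method, iterations = iterations, donors = donors,
            rf_trees = rf_trees, matching = matching,
            seed = rng_substream(seed, sprintf("hyb/%s/K%d/g%s/b%s/r%d", cfg$method,
                                               cfg$cluster_count,
                                               cfg$abstraction_level, b, r))
          )
          rh <- rmse_by_lab(mask$plan, hyb)
        }
        rs <- std_cache[[cfg$method]]
        per_repeat[[length(per_repeat) + 1]] <- dplyr::tibble(
          method = cfg$method, cluster_count = cfg$cluster_count,
          abstraction_level = cfg$abstraction_level, missingness_batch = b,
          repeat_index = r, loinc_code = rh$loinc_code,
          rmse_hybrid = rh$rmse, rmse_standard = rs$rmse
        )
      }
    }
  }
  long <- dplyr::bind_rows(per_repeat)
  per_lab <- long |>
    dplyr::group_by(.data$method, .data$cluster_count, .data$abstraction_level,
                    .data$missingness_batch, .data$loinc_code) |>
    dplyr::summarise(rmse_hybrid = mean(.data$rmse_hybrid),
                     rmse_standard = mean(.data$rmse_standard),
                     .groups = "drop") |>
    dplyr::mutate(rmse_difference = .data$rmse_hybrid - .data$rmse_standard)
  report <- per_lab |>
    dplyr::group_by(.data$method, .data$cluster_count, .data$abstraction_level,
                    .data$missingness_batch) |>
    dplyr::summarise(mean_rmse_hybrid = mean(.data$rmse_hybrid),
                     mean_rmse_standard = mean(.data$rmse_standard),
                     .groups = "drop") |>
    dplyr::mutate(mean_rmse_difference = .data$mean_rmse_hybrid - .data$mean_rmse_standard,
                  repeats = as.integer(repeats))
  attr(report, "per_lab") <- per_lab
  attr(report, "per_repeat") <- long
  attr(report, "seed") <- seed
  class(report) <- c("evaluation_report", class(report))
  report
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    n_configurations = nrow(x),
    n_improved = sum(x$mean_rmse_difference < 0),
    best_difference = min(x$mean_rmse_difference),
    repeats = x$repeats[1],
    seed = attr(x, "seed")
  )
}

#' RMSE-difference plot for an evaluation report
#'
#' Per-lab RMSE differences (hybrid minus standard) as violins, one panel per
#' missingness batch, coloured by method. Values below zero favour the
#' hybrid strategy.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  per_lab <- attr(object, "per_lab")
  per_lab$config <- sprintf("K=%d g=%s", per_lab$cluster_count,
                            per_lab$abstraction_level)
  ggplot2::ggplot(per_lab,
                  ggplot2::aes(x = .data$config, y = .data$rmse_difference,
                               fill = .data$method)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~missingness_batch, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "RMSE difference (hybrid - standard)")
}
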