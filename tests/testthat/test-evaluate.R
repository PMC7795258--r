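test_that("make_mask withholds the right number of observed cells per lab", {
  withr::with_seed(51, {
    m <- lab_matrix_from(matrix(rnorm(300), 150, 2))
    m[sample.int(150, 10), 2] <- NA # lab2: 140 observed
  })
  mk <- make_mask(m, 100, seed = 3)
  per_lab <- table(mk$plan$loinc_code)
  expect_equal(unname(per_lab[["lab1"]]), 100)
  expect_equal(unname(per_lab[["lab2"]]), 100)

  small <- lab_matrix_from(matrix(rnorm(160), 80, 2))
  mk2 <- make_mask(small, 100, seed = 3)
  expect_equal(unname(table(mk2$plan$loinc_code)[["lab1"]]), 79) # clamp rule
  expect_equal(sum(!is.na(mk2$masked[, "lab1"])), 1)
})

test_that("mask plans are disjoint from prior missingness and reproducible", {
  qc <- tiny_qc_matrix()
  mk <- make_mask(qc, 30, seed = 12)
  originally_missing <- which(is.na(unclass(qc)), arr.ind = TRUE)
  orig_keys <- paste(rownames(qc)[originally_missing[, 1]],
                     colnames(qc)[originally_missing[, 2]])
  plan_keys <- paste(mk$plan$patient_id, mk$plan$loinc_code)
  expect_length(intersect(plan_keys, orig_keys), 0)
  expect_false(anyNA(mk$plan$true_value))

  mk_again <- make_mask(qc, 30, seed = 12)
  expect_identical(mk$plan, mk_again$plan)
  expect_identical(unclass(mk$masked), unclass(mk_again$masked))

  degenerate <- lab_matrix_from(cbind(a = c(1, 2, 3), b = c(4, NA, NA)))
  expect_error(make_mask(degenerate, 1, seed = 1), "b")
})

test_that("rmse_by_lab computes the root mean square error per lab", {
  m <- lab_matrix_from(cbind(a = c(1, 2, 5), b = c(0, 0, 1)))
  plan <- tibble::tibble(
    patient_id = c("p1", "p2", "p1", "p2"),
    loinc_code = c("a", "a", "b", "b"),
    true_value = c(1, 2, 3, 4)
  )
  r <- rmse_by_lab(plan, m)
  expect_equal(r$rmse[r$loinc_code == "a"], 0)
  expect_equal(r$rmse[r$loinc_code == "b"], sqrt(25 / 2), tolerance = 1e-12)

  single <- rmse_by_lab(tibble::tibble(patient_id = "p3", loinc_code = "a",
                                       true_value = 3), m)
  expect_equal(single$rmse, 2)
})

test_that("K=1 cluster-wise imputation is bit-identical to the global model", {
  qc <- tiny_qc_matrix()
  mk <- make_mask(qc, 25, seed = 21)
  one <- tibble::tibble(patient_id = rownames(qc), cluster = 0L)
  hy <- suppressMessages(clusterwise_impute(mk$masked, one, "pmm", seed = 77))
  glob <- mice_impute(mk$masked, "pmm", seed = rng_substream(77, "cluster0"))
  expect_identical(unclass(hy$data), unclass(glob$data))
  d <- rmse_by_lab(mk$plan, hy)$rmse - rmse_by_lab(mk$plan, glob)$rmse
  expect_identical(d, rep(0, length(d)))
})

test_that("cluster-wise pmm draws donors from within the cluster", {
  withr::with_seed(52, {
    n <- 80
    # two blocks with disjoint value ranges in both labs
    v1 <- c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 100, 0.1))
    v2 <- c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 100, 0.1))
    m <- cbind(a = v1, b = v2)
    mask <- sample.int(n, 20)
    m[mask, "b"] <- NA
  })
  lm <- lab_matrix_from(m)
  cl <- tibble::tibble(patient_id = rownames(lm),
                       cluster = rep(0:1, each = 40))
  hy <- clusterwise_impute(lm, cl, "pmm", seed = 5)
  for (i in mask) {
    own_rows <- setdiff(which(cl$cluster == cl$cluster[i]), mask)
    expect_true(hy$data[i, "b"] %in% m[own_rows, "b"])
  }
})

test_that("clusters below the size floor fall back to the global model", {
  qc <- tiny_qc_matrix()
  mk <- make_mask(qc, 10, seed = 31)
  n <- nrow(qc)
  cl <- tibble::tibble(
    patient_id = rownames(qc),
    cluster = c(rep(0L, n - 3), rep(1L, 3)) # cluster 1 has 3 patients
  )
  expect_message(
    hy <- clusterwise_impute(mk$masked, cl, "pmm", seed = 41),
    "below the size floor"
  )
  glob <- mice_impute(mk$masked, "pmm", seed = rng_substream(41, "global"))
  small_rows <- which(cl$cluster == 1L)
  expect_identical(unclass(hy$data)[small_rows, ], unclass(glob$data)[small_rows, ])
})

test_that("run_experiment emits one row per configuration and pairs the arms", {
  co <- tiny_cohort()
  qc <- tiny_qc_matrix()
  grid <- experiment_grid(methods = "pmm", cluster_counts = c(1, 2),
                          abstraction_levels = c("5", "full"), batches = 0.75)
  rep <- suppressMessages(run_experiment(qc, co$diagnoses, grid, seed = 6,
                                         holdout_per_lab = 10, repeats = 2))
  expect_equal(nrow(rep), 4)
  expect_equal(rep$mean_rmse_difference,
               rep$mean_rmse_hybrid - rep$mean_rmse_standard, tolerance = 1e-12)
  per_lab <- attr(rep, "per_lab")
  per_repeat <- attr(rep, "per_repeat")
  expect_equal(nrow(per_lab), 4 * ncol(qc))
  # report means are arithmetic means of repeat-averaged per-lab RMSEs
  manual <- per_repeat |>
    dplyr::group_by(.data$cluster_count, .data$abstraction_level) |>
    dplyr::summarise(h = mean(.data$rmse_hybrid), s = mean(.data$rmse_standard),
                     .groups = "drop")
  expect_equal(sort(rep$mean_rmse_hybrid), sort(manual$h), tolerance = 1e-12)
  # paired masking: both arms scored the same withheld cells
  expect_true(all(table(per_repeat$repeat_index) == ncol(qc) * 4))
})

test_that("a K=1-only grid yields exactly zero RMSE differences", {
  co <- tiny_cohort()
  qc <- tiny_qc_matrix()
  grid <- experiment_grid("pmm", 1, "full", 0.75)
  rep <- suppressMessages(run_experiment(qc, co$diagnoses, grid, seed = 9,
                                         holdout_per_lab = 10, repeats = 1))
  expect_equal(nrow(rep), 1)
  expect_identical(rep$mean_rmse_difference, 0)
})

test_that("run_config validates its fields and feeds run_experiment", {
  cfg <- run_config(abstraction_level = "5", cluster_count = 2,
                    mice_method = "pmm", missingness_batch = 0.75, seed = 3)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$cluster_count, 2L)
  expect_error(run_config(donors = 0), "donors")
  expect_error(run_config(missingness_batch = 0.6), "missingness_batch")
  expect_error(run_config(abstraction_level = "-3"), "abstraction_level")

  co <- tiny_cohort()
  qc <- tiny_qc_matrix()
  rep <- suppressMessages(run_experiment(qc, co$diagnoses, cfg, seed = cfg$seed,
                                         holdout_per_lab = cfg$holdout_per_lab,
                                         repeats = 1))
  expect_equal(nrow(rep), 1)
})

test_that("experiment reports round-trip through write_report", {
  co <- tiny_cohort()
  qc <- tiny_qc_matrix()
  grid <- experiment_grid("pmm", 2, "full", 0.75)
  rep <- suppressMessages(run_experiment(qc, co$diagnoses, grid, seed = 10,
                                         holdout_per_lab = 5, repeats = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$mean_rmse_difference, rep$mean_rmse_difference, tolerance = 1e-12)
})
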