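dx_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    icd_code = vapply(rows, `[[`, "", 2),
    occurrences = as.integer(vapply(rows, `[[`, "", 3))
  )
}

test_that("rule_of_two thresholds at 2 recordings and drops empty codes", {
  dx <- dx_tbl(list("p1", "E11.9", "1"), list("p1", "I10", "4"),
               list("p2", "I10", "1"))
  A <- rule_of_two(dx, patients = c("p1", "p2"))
  expect_equal(colnames(A), "I10") # E11.9 recorded once -> dropped
  expect_equal(unname(A[, "I10"]), c(1, 0))

  A2 <- rule_of_two(dx_tbl(list("p1", "E11.9", "2")), patients = "p1")
  expect_equal(unname(A2["p1", "E11.9"]), 1)

  expect_error(rule_of_two(dx_tbl(list("p1", "A", "1"))), "at least twice")
  expect_error(rule_of_two(dx[0, ]), "empty")
})

test_that("rule_of_two is binary and monotone in occurrences", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- 12
      dx <- tibble::tibble(
        patient_id = sample(sprintf("p%d", 1:6), n, replace = TRUE),
        icd_code = sample(c("A", "B", "C"), n, replace = TRUE),
        occurrences = sample.int(4, n, replace = TRUE)
      )
      A <- tryCatch(rule_of_two(dx), error = function(e) NULL)
      if (is.null(A)) next
      expect_true(all(A %in% c(0, 1)))
      dx_up <- dx
      dx_up$occurrences <- dx_up$occurrences + sample(0:2, n, replace = TRUE)
      A_up <- rule_of_two(dx_up, patients = rownames(A))
      shared <- intersect(colnames(A), colnames(A_up))
      expect_true(all(A_up[, shared] >= A[, shared]))
    }
  })
})

test_that("svd_factorize satisfies the factorization invariants", {
  A <- diag(2)
  dimnames(A) <- list(c("p1", "p2"), c("c1", "c2"))
  f <- svd_factorize(A)
  expect_equal(f$d, c(1, 1))

  withr::with_seed(32, {
    B <- matrix(rbinom(50 * 40, 1, 0.2), 50, 40)
    dimnames(B) <- list(sprintf("p%d", 1:50), sprintf("c%d", 1:40))
    fb <- svd_factorize(B)
    expect_equal(fb$u %*% diag(fb$d) %*% t(fb$v), unname(B),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(fb$d) <= 1e-12))
    expect_equal(crossprod(fb$u), diag(40), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(crossprod(fb$v), diag(40), tolerance = 1e-8, ignore_attr = TRUE)
  })
  expect_error(svd_factorize(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))),
               "all-zero")
})

test_that("abstraction returns the Eckart-Young optimal low-rank matrix", {
  D <- diag(c(2, 1))
  dimnames(D) <- list(c("p1", "p2"), c("c1", "c2"))
  f <- svd_factorize(D)
  expect_equal(abstraction(f, "full"), D, tolerance = 1e-8, ignore_attr = TRUE)
  A1 <- abstraction(f, 1)
  expect_equal(unname(A1), matrix(c(2, 0, 0, 0), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(abstraction(f, 0), "positive")
  expect_error(abstraction(f, 3), "rank")

  # Frobenius residual equals the discarded squared singular values, with the
  # singular values obtained from an independent eigendecomposition of A'A
  withr::with_seed(33, {
    M <- matrix(rbinom(20 * 10, 1, 0.3), 20, 10)
    dimnames(M) <- list(sprintf("p%d", 1:20), sprintf("c%d", 1:10))
    ev <- sort(eigen(crossprod(M), symmetric = TRUE)$values, decreasing = TRUE)
    fM <- svd_factorize(M)
    for (g in c(2, 5, 9)) {
      Ag <- abstraction(fM, g)
      expect_equal(sum((M - Ag)^2), sum(ev[-seq_len(g)]), tolerance = 1e-8)
    }
  })
})

test_that("row distances of A_g match the score representation", {
  withr::with_seed(34, {
    M <- matrix(rbinom(30 * 15, 1, 0.25), 30, 15)
    dimnames(M) <- list(sprintf("p%d", 1:30), sprintf("c%d", 1:15))
    f <- svd_factorize(M)
    Ag <- abstraction(f, 5)
    d_full <- dist(Ag)
    d_scores <- dist(attr(Ag, "scores"))
    expect_equal(as.numeric(d_full), as.numeric(d_scores), tolerance = 1e-8)
  })
})

test_that("noise_reduce drops columns with sum below 1 and keeps exactly 1", {
  M <- cbind(a = c(1.6, 1.6), b = c(0.2, 0.2), c = c(-0.05, -0.05), d = c(0.4, 0.4))
  rownames(M) <- c("p1", "p2")
  L <- noise_reduce(M)
  expect_equal(colnames(L), "a")
  expect_equal(attr(L, "dropped_codes"), c("b", "c", "d"))

  M1 <- cbind(a = c(0.5, 0.5), b = c(2, 2))
  rownames(M1) <- c("p1", "p2")
  expect_equal(colnames(noise_reduce(M1)), c("a", "b")) # sum exactly 1 kept

  all_ok <- cbind(a = c(1, 1), b = c(2, 3))
  rownames(all_ok) <- c("p1", "p2")
  expect_identical(unclass(noise_reduce(all_ok))[, ], all_ok[, ])

  expect_error(noise_reduce(cbind(a = c(0.1, 0.1))), "sum < 1")
})

test_that("full-rank abstraction plus noise_reduce is the identity on rich matrices", {
  withr::with_seed(35, {
    A <- matrix(rbinom(40 * 12, 1, 0.5), 40, 12)
    A[1, ] <- 1 # ensure every column sum >= 1
    dimnames(A) <- list(sprintf("p%d", 1:40), sprintf("c%d", 1:12))
    stopifnot(all(colSums(A) >= 1))
    L <- noise_reduce(abstraction(svd_factorize(A), "full"))
    expect_equal(unclass(L)[, ], A[, ], tolerance = 1e-8)
  })
})

test_that("k-means separates point masses and respects K", {
  X <- rbind(matrix(0, 10, 3), matrix(9, 10, 3))
  rownames(X) <- sprintf("p%d", 1:20)
  cl <- cluster_patients(X, 2, seed = 5)
  expect_equal(attr(cl, "inertia"), 0)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[11])

  one <- cluster_patients(X, 1, seed = 5)
  expect_equal(unique(one$cluster), 0L)
  expect_error(cluster_patients(X, 0, seed = 5), "positive")
  expect_error(cluster_patients(X, 21, seed = 5), "exceeds")
})

test_that("clustering is deterministic given the seed", {
  withr::with_seed(36, X <- matrix(rnorm(60 * 4), 60, 4))
  rownames(X) <- sprintf("p%d", 1:60)
  a <- cluster_patients(X, 3, seed = 9)
  b <- cluster_patients(X, 3, seed = 9)
  expect_identical(a$cluster, b$cluster)
})

test_that("the latent pipeline recovers planted groups on the tiny cohort better than chance", {
  co <- tiny_cohort()
  L <- suppressMessages(latent_comorbidities(co$diagnoses, 20,
                                             patients = co$truth$clusters$patient_id))
  cl <- cluster_patients(L, 4, seed = 3)
  truth <- co$truth$clusters$cluster[match(cl$patient_id, co$truth$clusters$patient_id)]
  expect_gt(ari(cl$cluster, truth), 0)
})
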