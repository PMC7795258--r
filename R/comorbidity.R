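# Latent-comorbidity embedding: binary patient x ICD matrix (rule of 2),
# truncated SVD abstraction A_g = U_g S_g V_g', column-sum noise reduction,
# and k-means patient clustering on the resulting latent matrix.

#' Build the binary comorbidity matrix (rule of 2)
#'
#' An entry (patient, code) is 1 only if the code was recorded at least twice
#' in that patient's chart; a single recording is treated as noise. Codes
#' whose column is all-zero after thresholding are dropped. Occurrence counts
#' beyond the threshold are discarded: the matrix is presence/absence, since
#' recording frequency does not reliably track severity or duration.
#'
#' @param records A tibble of diagnosis records with columns `patient_id`,
#'   `icd_code`, `occurrences` (see [read_diagnoses()]).
#' @param patients Optional patient roster fixing row order (patients with no
#'   qualifying code keep an all-zero row); defaults to the sorted distinct
#'   patients in `records`.
#' @return A binary `comorbidity_matrix` (patients x codes).
#' @export
rule_of_two <- function(records, patients = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("rule_of_two: empty diagnosis record set", call. = FALSE)
  if (is.null(patients)) patients <- sort(unique(records$patient_id))
  qualifying <- records |>
    dplyr::filter(.data$patient_id %in% patients) |>
    dplyr::group_by(.data$patient_id, .data$icd_code) |>
    dplyr::summarise(occurrences = sum(.data$occurrences), .groups = "drop") |>
    dplyr::filter(.data$occurrences >= 2)
  codes <- sort(unique(qualifying$icd_code))
  if (length(codes) == 0) {
    stop("rule_of_two: no ICD code recorded at least twice for any patient", call. = FALSE)
  }
  m <- matrix(0, nrow = length(patients), ncol = length(codes),
              dimnames = list(patients, codes))
  m[cbind(match(qualifying$patient_id, patients),
          match(qualifying$icd_code, codes))] <- 1
  structure(m, class = c("comorbidity_matrix", "matrix", "array"))
}

#' Singular value decomposition of the comorbidity matrix
#'
#' Computes `A = U S V'` with singular values sorted descending. The sign of
#' each singular-vector pair is fixed so that the largest-magnitude entry of
#' each column of `V` is positive, making the factorization deterministic
#' across platforms.
#'
#' @param A A `comorbidity_matrix` (or any numeric matrix).
#' @return An `svd_factorization`: list with `u`, `d`, `v` and the row/column
#'   ids.
#' @export
svd_factorize <- function(A) {
  stopifnot(is.matrix(A), is.numeric(A))
  if (all(A == 0)) stop("svd_factorize: all-zero matrix", call. = FALSE)
  s <- svd(A)
  for (j in seq_along(s$d)) {
    i_max <- which.max(abs(s$v[, j]))
    if (s$v[i_max, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  structure(
    list(u = s$u, d = s$d, v = s$v,
         patients = rownames(A), codes = colnames(A)),
    class = "svd_factorization"
  )
}

#' Rank-g abstraction of the comorbidity matrix
#'
#' Reconstructs `A_g = U_g S_g V_g'` from the top `g` singular triplets — the
#' best rank-`g` approximation of the binary comorbidity matrix in Frobenius
#' norm. `g = "full"` reproduces the input matrix (up to numerical error).
#'
#' @param fact An `svd_factorization`.
#' @param g Positive integer abstraction level, or `"full"`.
#' @return A numeric patients x codes matrix with attributes `g` (as
#'   requested) and `scores` (the `U_g S_g` score representation, patients x
#'   g, which carries the same pairwise row geometry).
#' @export
abstraction <- function(fact, g) {
  stopifnot(inherits(fact, "svd_factorization"))
  r <- length(fact$d)
  if (identical(g, "full")) {
    g_eff <- r
  } else {
    if (!is.numeric(g) || length(g) != 1 || g <= 0 || g != floor(g)) {
      stop("abstraction: g must be a positive integer or \"full\"", call. = FALSE)
    }
    if (g > r) {
      stop("abstraction: g = ", g, " exceeds the available rank ", r, call. = FALSE)
    }
    g_eff <- as.integer(g)
  }
  idx <- seq_len(g_eff)
  scores <- fact$u[, idx, drop = FALSE] %*% diag(fact$d[idx], nrow = g_eff)
  A_g <- scores %*% t(fact$v[, idx, drop = FALSE])
  dimnames(A_g) <- list(fact$patients, fact$codes)
  rownames(scores) <- fact$patients
  attr(A_g, "g") <- g
  attr(A_g, "scores") <- scores
  A_g
}

#' Noise reduction on the latent comorbidity matrix
#'
#' Drops every code column whose (signed) sum over patients is less than 1 —
#' columns dominated by very rare comorbidities carry noise rather than
#' structure after the low-rank reconstruction. A column sum of exactly 1 is
#' retained. No re-factorization is performed afterwards; this is the final
#' step of the abstraction, and its output is the latent-comorbidity matrix
#' used for clustering.
#'
#' @param A_g A patients x codes matrix from [abstraction()].
#' @return A `latent_comorbidity` matrix with attributes `g`, `dropped_codes`
#'   and `scores`.
#' @export
noise_reduce <- function(A_g) {
  stopifnot(is.matrix(A_g), is.numeric(A_g))
  sums <- colSums(A_g)
  keep <- sums >= 1
  if (!any(keep)) stop("noise_reduce: every code column has sum < 1", call. = FALSE)
  out <- A_g[, keep, drop = FALSE]
  attr(out, "g") <- attr(A_g, "g")
  attr(out, "scores") <- attr(A_g, "scores")
  attr(out, "dropped_codes") <- colnames(A_g)[!keep]
  class(out) <- c("latent_comorbidity", "matrix", "array")
  out
}

#' Full latent-comorbidity pipeline
#'
#' Convenience composition: [rule_of_two()] (if given diagnosis records),
#' [svd_factorize()], [abstraction()], [noise_reduce()].
#'
#' @param x Diagnosis records tibble or a `comorbidity_matrix`.
#' @param g Abstraction level (positive integer or `"full"`). An integer `g`
#'   larger than the available rank is clamped to full rank with a message.
#' @param patients Optional patient roster (when `x` is a tibble).
#' @return A `latent_comorbidity` matrix.
#' @export
latent_comorbidities <- function(x, g, patients = NULL) {
  A <- if (is.data.frame(x)) rule_of_two(x, patients) else x
  fact <- svd_factorize(A)
  if (is.numeric(g) && g > length(fact$d)) {
    message("latent_comorbidities: g = ", g, " exceeds rank ", length(fact$d),
            "; using full rank")
    g <- "full"
  }
  noise_reduce(abstraction(fact, g))
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[k, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  centers
}

# Lloyd iterations with an explicit empty-cluster safeguard: an emptied
# centroid is reseeded at the point farthest from its current centroid.
lloyd <- function(X, centers, max_iter = 100) {
  n <- nrow(X)
  K <- nrow(centers)
  xsq <- rowSums(X^2)
  assign_old <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign_new <- max.col(-d2, ties.method = "first")
    empties <- setdiff(seq_len(K), unique(assign_new))
    if (length(empties) > 0) {
      nearest <- d2[cbind(seq_len(n), assign_new)]
      for (k in empties) {
        far <- which.max(nearest)
        centers[k, ] <- X[far, ]
        assign_new[far] <- k
        nearest[far] <- 0
      }
      message("cluster_patients: reseeded ", length(empties), " empty cluster(s)")
    }
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (k in seq_len(K)) {
      members <- assign_new == k
      if (any(members)) centers[k, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  inertia <- sum(pmax(d2[cbind(seq_len(n), assign_old)], 0))
  list(assignment = assign_old, centers = centers, inertia = inertia)
}

#' Cluster patients on their latent comorbidities
#'
#' Standard Euclidean k-means on the rows of the latent-comorbidity matrix:
#' k-means++ initialization, 10 restarts, best within-cluster sum of squares
#' kept. Deterministic given the seed. Labels are 0-based (`0 .. K-1`).
#'
#' @param L A `latent_comorbidity` matrix (or any numeric matrix with patient
#'   rownames).
#' @param K Number of clusters (positive integer, at most the patient count).
#' @param seed Integer seed for the clustering stream.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A `cluster_assignment` tibble with columns `patient_id`,
#'   `cluster`, and attributes `K`, `inertia`, `seed`.
#' @export
cluster_patients <- function(L, K, seed, restarts = 10) {
  stopifnot(is.matrix(L), is.numeric(L))
  if (!is.numeric(K) || K < 1 || K != floor(K)) {
    stop("cluster_patients: K must be a positive integer", call. = FALSE)
  }
  if (K > nrow(L)) stop("cluster_patients: K exceeds the number of patients", call. = FALSE)
  X <- unclass(L)
  attributes(X)[setdiff(names(attributes(X)), c("dim", "dimnames"))] <- NULL
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd(X, kmeanspp_centers(X, K))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  out <- tibble::tibble(
    patient_id = rownames(L),
    cluster = as.integer(best$assignment - 1L)
  )
  attr(out, "K") <- as.integer(K)
  attr(out, "inertia") <- best$inertia
  attr(out, "seed") <- seed
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(K = attr(x, "K"), inertia = attr(x, "inertia"),
                 n_patients = nrow(x), seed = attr(x, "seed"))
}
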