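# Chained-equations (fully conditional specification) imputation engine.
# Each incomplete variable gets its own conditional model; sweeps re-impute
# variable by variable against the current completed data. Both conditional
# models are donor-based: an imputed value is always drawn from the
# variable's observed values, never predicted directly.

# Donor selection shared by the pmm path: given predicted means for observed
# and missing cases, pick among the `donors` observed cases with the closest
# predicted mean, uniformly at random. Boundary ties are broken by the
# random stream. When the observed predictions are (numerically) constant,
# every observed case is an equally good donor and the draw is uniform over
# all of them.
select_donors <- function(yhat_obs, yhat_mis, y_obs, donors) {
  n_obs <- length(y_obs)
  d <- min(donors, n_obs)
  n_mis <- length(yhat_mis)
  span <- max(yhat_obs) - min(yhat_obs)
  if (span <= 1e-10 * max(1, abs(mean(yhat_obs)))) {
    return(y_obs[sample.int(n_obs, n_mis, replace = TRUE)])
  }
  o <- order(yhat_obs)
  ys <- yhat_obs[o]
  pos <- findInterval(yhat_mis, ys)
  out <- numeric(n_mis)
  for (i in seq_len(n_mis)) {
    lo <- max(1L, pos[i] - d)
    hi <- min(n_obs, pos[i] + d + 1L)
    cand <- lo:hi
    dist <- abs(ys[cand] - yhat_mis[i])
    ord <- order(dist, stats::runif(length(cand)))
    k <- min(d, length(cand))
    out[i] <- y_obs[o[cand[ord[sample.int(k, 1)]]]]
  }
  out
}

#' Predictive-mean-matching imputation of one variable
#'
#' Fits a ridge-stabilized linear model of the observed responses on the
#' predictors. Predicted means for the observed cases use the point-estimate
#' coefficients; predicted means for the missing cases use, under type-1
#' matching, coefficients perturbed by a multivariate normal draw scaled by
#' the estimated coefficient covariance (`matching = "point"` skips the
#' perturbation). Each missing case is imputed by a uniform random draw from
#' the `donors` observed values with the closest predicted mean.
#'
#' @param y_obs Numeric vector of observed responses (length >= 2).
#' @param X_obs,X_mis Numeric predictor matrices for the observed and missing
#'   cases.
#' @param donors Donor-set size (default 5; clamped to the observed count).
#' @param matching `"type1"` (default) or `"point"`.
#' @param seed Optional integer seed; by default draws come from the current
#'   RNG state (as when called from [mice_impute()]).
#' @return Numeric vector of imputations, one per row of `X_mis`; every value
#'   is a member of `y_obs`.
#' @export
pmm_impute_variable <- function(y_obs, X_obs, X_mis, donors = 5,
                                matching = c("type1", "point"), seed = NULL) {
  matching <- match.arg(matching)
  if (donors < 1) stop("pmm_impute_variable: donors must be >= 1", call. = FALSE)
  if (length(y_obs) < 2) stop("pmm_impute_variable: need >= 2 observed values", call. = FALSE)
  X_obs <- as.matrix(X_obs)
  X_mis <- as.matrix(X_mis)
  run <- function() {
    Xd_obs <- cbind(1, X_obs)
    Xd_mis <- cbind(1, X_mis)
    p <- ncol(Xd_obs)
    XtX <- crossprod(Xd_obs)
    lambda <- 1e-5 * sum(diag(XtX)) / p
    Ainv <- solve(XtX + diag(lambda, p))
    beta <- drop(Ainv %*% crossprod(Xd_obs, y_obs))
    yhat_obs <- drop(Xd_obs %*% beta)
    beta_star <- beta
    if (matching == "type1") {
      sigma2 <- sum((y_obs - yhat_obs)^2) / max(length(y_obs) - p, 1)
      covB <- sigma2 * (Ainv + t(Ainv)) / 2
      jitter <- 1e-12 * max(diag(covB), 0) + 1e-300
      R <- chol(covB + diag(jitter, p))
      beta_star <- beta + drop(t(R) %*% stats::rnorm(p))
    }
    yhat_mis <- drop(Xd_mis %*% beta_star)
    select_donors(yhat_obs, yhat_mis, y_obs, donors)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random-forest imputation of one variable
#'
#' Fits a bootstrap-aggregated regression forest (via \pkg{ranger}) on the
#' observed cases. Each missing case is routed through one uniformly chosen
#' tree to its terminal node, and imputed by a uniform random draw among the
#' observed responses falling in that node — so imputations are restricted
#' to observed values, exactly as in predictive mean matching.
#'
#' @param y_obs Numeric vector of observed responses (length >= 2).
#' @param X_obs,X_mis Numeric predictor matrices.
#' @param trees Number of trees (default 10).
#' @param seed Optional integer seed (default: current RNG state).
#' @return Numeric vector of imputations, members of `y_obs`.
#' @export
rf_impute_variable <- function(y_obs, X_obs, X_mis, trees = 10, seed = NULL) {
  if (trees < 1) stop("rf_impute_variable: trees must be >= 1", call. = FALSE)
  if (length(y_obs) < 2) stop("rf_impute_variable: need >= 2 observed values", call. = FALSE)
  X_obs <- as.matrix(X_obs)
  X_mis <- as.matrix(X_mis)
  p <- ncol(X_obs)
  if (p < 1) stop("rf_impute_variable: need at least one predictor", call. = FALSE)
  run <- function() {
    df_obs <- as.data.frame(X_obs)
    df_mis <- as.data.frame(X_mis)
    names(df_obs) <- names(df_mis) <- paste0("x", seq_len(p))
    rf_seed <- sample.int(2147483646L, 1)
    fit <- ranger::ranger(
      y = y_obs, x = df_obs, num.trees = trees, min.node.size = 5,
      mtry = max(1, ceiling(p / 3)), replace = TRUE,
      seed = rf_seed, num.threads = 1
    )
    nodes_obs <- as.matrix(stats::predict(fit, data = df_obs, type = "terminalNodes",
                                          num.threads = 1)$predictions)
    nodes_mis <- as.matrix(stats::predict(fit, data = df_mis, type = "terminalNodes",
                                          num.threads = 1)$predictions)
    n_mis <- nrow(df_mis)
    tree_pick <- sample.int(trees, n_mis, replace = TRUE)
    out <- numeric(n_mis)
    for (i in seq_len(n_mis)) {
      cand <- which(nodes_obs[, tree_pick[i]] == nodes_mis[i, tree_pick[i]])
      if (length(cand) == 0) cand <- seq_along(y_obs)
      out[i] <- y_obs[cand[sample.int(length(cand), 1)]]
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Chained-equations imputation of a lab matrix
#'
#' Initial fill draws each variable's missing cells at random from its
#' observed values; then `iterations` sweeps visit the incomplete variables
#' in ascending-missingness order, re-imputing each from all other
#' variables' current values with the chosen conditional model. One
#' completed dataset is returned. Observed cells are never modified.
#'
#' A variable with zero observed values is imputable only if
#' `fallback_pool` supplies a donor pool for it (its cells keep initial-fill
#' draws from that pool); otherwise it is an error.
#'
#' @param x A `lab_matrix` (or numeric matrix with dimnames), `NA` = missing.
#' @param method `"pmm"` or `"rf"`.
#' @param iterations Number of sweeps (default 5).
#' @param donors pmm donor-set size (default 5).
#' @param rf_trees Trees per forest for `method = "rf"` (default 10).
#' @param seed Integer seed for the imputation stream.
#' @param matching pmm matching type, `"type1"` (default) or `"point"`.
#' @param fallback_pool Optional named list of numeric donor pools for
#'   variables with no observed values.
#' @return A `mice_result`: `data` (completed `lab_matrix`), `trace` (tibble
#'   of per-variable per-sweep imputed-value means), and the configuration.
#' @export
mice_impute <- function(x, method = c("pmm", "rf"), iterations = 5, donors = 5,
                        rf_trees = 10, seed = 1L,
                        matching = c("type1", "point"), fallback_pool = NULL) {
  method <- match.arg(method)
  matching <- match.arg(matching)
  stopifnot(is.matrix(x), is.numeric(x), !is.null(colnames(x)), !is.null(rownames(x)))
  if (ncol(x) < 2) stop("mice_impute: need at least 2 variables", call. = FALSE)
  if (iterations < 1) stop("mice_impute: iterations must be >= 1", call. = FALSE)
  m <- unclass(x)
  obs_mask <- !is.na(m)
  n_obs_col <- colSums(obs_mask)
  for (v in colnames(m)[n_obs_col == 0]) {
    if (length(fallback_pool[[v]]) == 0) {
      stop("mice_impute: variable '", v,
           "' has no observed values and no fallback pool", call. = FALSE)
    }
  }
  n_missing <- sum(!obs_mask)
  trace <- tibble::tibble(variable = character(), sweep = integer(),
                          mean_imputed = double())
  if (n_missing > 0) {
    withr::with_seed(seed, {
      for (j in seq_len(ncol(m))) {
        mis <- which(!obs_mask[, j])
        if (length(mis) == 0) next
        pool <- if (n_obs_col[j] > 0) m[obs_mask[, j], j] else fallback_pool[[colnames(m)[j]]]
        m[mis, j] <- pool[sample.int(length(pool), length(mis), replace = TRUE)]
      }
      n_mis_col <- colSums(!obs_mask)
      visit <- order(n_mis_col)
      visit <- visit[n_mis_col[visit] > 0]
      fittable <- n_obs_col >= 2
      rows <- vector("list", iterations * length(visit))
      ri <- 0L
      for (s in seq_len(iterations)) {
        for (j in visit) {
          mis <- which(!obs_mask[, j])
          if (fittable[j]) {
            y_obs <- m[obs_mask[, j], j]
            X_obs <- m[obs_mask[, j], -j, drop = FALSE]
            X_mis <- m[mis, -j, drop = FALSE]
            m[mis, j] <- if (method == "pmm") {
              pmm_impute_variable(y_obs, X_obs, X_mis, donors, matching)
            } else {
              rf_impute_variable(y_obs, X_obs, X_mis, rf_trees)
            }
          }
          ri <- ri + 1L
          rows[[ri]] <- tibble::tibble(variable = colnames(m)[j], sweep = s,
                                       mean_imputed = mean(m[mis, j]))
        }
      }
      trace <- dplyr::bind_rows(rows)
    })
  }
  structure(
    list(data = new_lab_matrix(m), trace = trace, method = method,
         iterations = iterations, donors = donors, rf_trees = rf_trees,
         matching = matching, seed = seed, n_imputed = n_missing),
    class = "mice_result"
  )
}

#' @export
tidy.mice_result <- function(x, ...) {
  m <- x$data
  long <- tidy.lab_matrix(m)
  long$missing <- NULL
  long
}

#' @export
glance.mice_result <- function(x, ...) {
  tibble::tibble(method = x$method, iterations = x$iterations,
                 donors = x$donors, rf_trees = x$rf_trees,
                 matching = x$matching, n_imputed = x$n_imputed, seed = x$seed)
}

#' @export
print.mice_result <- function(x, ...) {
  cat(sprintf("<mice_result> method=%s, %d sweep(s), %d cell(s) imputed\n",
              x$method, x$iterations, x$n_imputed))
  invisible(x)
}

#' Convergence-trace plot for a chained-equations run
#'
#' One line per incomplete variable: the mean of its imputed cells after each
#' sweep.
#'
#' @param object A `mice_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mice_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$sweep, y = .data$mean_imputed,
                               colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sweep", y = "mean imputed value")
}
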