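#' Bayesian information criterion
#'
#' `BIC = ln(N) q - 2 ln(L)` where `q` is the number of free parameters,
#' `N` the sample size, and `ln(L)` the maximized log-likelihood. Smaller
#' is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters `q`.
#' @param n_obs Sample size `N`.
#' @return The BIC score.
#' @export
bic_score <- function(loglik, n_params, n_obs) {
  log(n_obs) * n_params - 2 * loglik
}

# Number of free parameters of a K-component bivariate mixture with
# diagonal covariances: K-1 weights + 2K means + 2K variances.
mixture_n_params <- function(K, d = 2) K - 1 + 2 * d * K

# Log-density of each observation under each component (n x K matrix).
# Components are independent normals per axis (diagonal covariance).
.component_logdens <- function(data, mu, sigma2) {
  n <- nrow(data); K <- nrow(mu)
  ld <- matrix(-log(2 * pi), n, K)
  for (k in seq_len(K)) {
    ld[, k] <- ld[, k] -
      0.5 * ((data[, 1] - mu[k, 1])^2 / sigma2[k, 1] + log(sigma2[k, 1])) -
      0.5 * ((data[, 2] - mu[k, 2])^2 / sigma2[k, 2] + log(sigma2[k, 2]))
  }
  ld
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# One EM run from a given hard initialization (cluster assignment).
.em_run <- function(data, K, init_cluster, max_iter, tol, var_floor) {
  n <- nrow(data)
  resp <- matrix(1e-10, n, K)
  resp[cbind(seq_len(n), init_cluster)] <- 1
  resp <- resp / rowSums(resp)
  lambda <- rep(1 / K, K)
  mu <- matrix(0, K, 2)
  sigma2 <- matrix(1, K, 2)
  loglik <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)          # collapsed component
    lambda <- nk / n
    for (d in 1:2) {
      mu[, d] <- colSums(resp * data[, d]) / nk
      dev2 <- (matrix(data[, d], n, K) -
                 matrix(mu[, d], n, K, byrow = TRUE))^2
      sigma2[, d] <- colSums(resp * dev2) / nk
    }
    sigma2 <- pmax(sigma2, var_floor)
    # E step
    lp <- sweep(.component_logdens(data, mu, sigma2), 2, log(lambda), "+")
    lse <- .logsumexp_rows(lp)
    new_loglik <- sum(lse)
    resp <- exp(lp - lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < tol * max(1, abs(new_loglik))) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  list(lambda = lambda, mu = mu, sigma2 = sigma2,
       loglik = loglik, trace = trace, resp = resp)
}

# Fit a K-component diagonal-covariance bivariate normal mixture by EM with
# k-means initialization and multiple restarts; degenerate runs (vanishing
# variance / collapsed weight) are retried from a jittered initialization.
fit_mixture_k <- function(data, K, n_restarts = 5, max_iter = 500,
                          tol = 1e-6, seed = NULL) {
  n <- nrow(data)
  var_floor <- max(1e-10, 1e-6 * mean(apply(data, 2, var)))
  with_seed(seed, {
    best <- NULL
    attempts <- 0
    for (r in seq_len(n_restarts)) {
      init <- tryCatch(
        kmeans(data, centers = K, nstart = 1, iter.max = 50)$cluster,
        error = function(e) sample.int(K, n, replace = TRUE))
      fit <- .em_run(data, K, init, max_iter, tol, var_floor)
      attempts <- attempts + 1
      if (is.null(fit)) {
        # collapsed: retry once from a jittered random assignment
        init <- sample.int(K, n, replace = TRUE)
        fit <- .em_run(data, K, init, max_iter, tol, var_floor)
        attempts <- attempts + 1
      }
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (is.null(best)) {
      qm_stop(sprintf("EM failed for K = %d after %d attempts", K, attempts),
              "qmosaic_fit_error")
    }
    best
  })
}

#' Fit a mixture model over expression and spatial context
#'
#' Fits K-component bivariate normal mixtures with diagonal covariances to
#' the paired observations `(X, Y)` — log clonal-marker level and local
#' spatial context — by expectation maximization, for every K in `k_range`,
#' and returns the model minimizing the Bayesian information criterion.
#' On the original intensity scale each component is a bivariate lognormal.
#'
#' @param X Numeric vector: natural log of the clonal-marker level per cell.
#' @param Y Numeric vector: spatial context (mean `X` over a neighborhood).
#' @param k_range Integer vector of component counts to scan.
#' @param n_restarts EM restarts per K (k-means initializations).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed Optional RNG seed controlling the initializations.
#' @return A `mixture_model` with fields `K`, `lambda`, `mu` (K x 2),
#'   `sigma2` (K x 2), `loglik`, `bic`, `trace` (per-iteration
#'   log-likelihood of the selected fit) and `bic_by_k`.
#' @export
fit_mixture <- function(X, Y, k_range = 3:8, n_restarts = 5,
                        max_iter = 500, tol = 1e-6, seed = NULL) {
  data <- cbind(X, Y)
  if (any(!is.finite(data))) {
    qm_stop("non-finite values in (X, Y)", "qmosaic_fit_error")
  }
  if (nrow(data) < 10 * max(k_range)) {
    qm_stop(sprintf("need at least %d observations for K up to %d",
                    10 * max(k_range), max(k_range)),
            "qmosaic_fit_error")
  }
  seeds <- if (is.null(seed)) rep(list(NULL), length(k_range)) else
    as.list(seed + seq_along(k_range))
  fits <- vector("list", length(k_range))
  bics <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fits[[i]] <- fit_mixture_k(data, K, n_restarts, max_iter, tol,
                               seed = seeds[[i]])
    bics[i] <- bic_score(fits[[i]]$loglik, mixture_n_params(K), nrow(data))
  }
  best <- which.min(bics)
  f <- fits[[best]]
  structure(list(K = k_range[best], lambda = f$lambda, mu = f$mu,
                 sigma2 = f$sigma2, loglik = f$loglik, bic = bics[best],
                 trace = f$trace,
                 bic_by_k = setNames(bics, k_range)),
            class = "mixture_model")
}

#' Component posteriors of a fitted mixture
#'
#' `posterior()` evaluates `p(k | X, Y)` for the full bivariate model;
#' `posterior_marginal()` evaluates `p(k | X)` using only the X-axis
#' marginal of each component (the marginal classifier's quantities).
#'
#' @param model A `mixture_model`.
#' @param X,Y Observation vectors.
#' @return An `n x K` matrix of posterior probabilities (rows sum to 1).
#' @export
posterior <- function(model, X, Y) {
  lp <- sweep(.component_logdens(cbind(X, Y), model$mu, model$sigma2),
              2, log(model$lambda), "+")
  exp(lp - .logsumexp_rows(lp))
}

#' @rdname posterior
#' @export
posterior_marginal <- function(model, X) {
  K <- model$K
  lp <- matrix(0, length(X), K)
  for (k in seq_len(K)) {
    lp[, k] <- dnorm(X, model$mu[k, 1], sqrt(model$sigma2[k, 1]),
                     log = TRUE) + log(model$lambda[k])
  }
  exp(lp - .logsumexp_rows(lp))
}

#' Map mixture components to gene dosages
#'
#' Clusters the K components into `n_labels` groups by (1-dimensional)
#' k-means on their mean expression levels `exp(mu_X)`, then orders the
#' groups by ascending mean so that the dimmest group maps to dosage 0 and
#' the brightest to `n_labels - 1`. The resulting map is onto whenever
#' `K >= n_labels`.
#'
#' @param model A `mixture_model`.
#' @param n_labels Number of dosage labels (3 for ternary mosaics, 2 for
#'   binary mutant/non-mutant labeling).
#' @return Integer vector `f` of length K: `f[k]` is the dosage of
#'   component k.
#' @export
map_components <- function(model, n_labels = 3) {
  K <- model$K
  if (K < n_labels) {
    qm_stop(sprintf("model has %d components; need at least %d", K, n_labels),
            "qmosaic_insufficient_components_error")
  }
  centers <- exp(model$mu[, 1])
  if (length(unique(centers)) < n_labels) {
    # tied means: group by rank of the unique values
    grp <- match(centers, sort(unique(centers)))
    return(pmin(grp, n_labels) - 1L)
  }
  if (K == n_labels) {
    # one component per group: ordering by mean is the unique partition
    return(as.integer(rank(centers) - 1L))
  }
  km <- kmeans(centers, centers = n_labels, nstart = 50)
  ord <- order(km$centers[, 1])
  f <- integer(K)
  for (g in seq_len(n_labels)) f[km$cluster == ord[g]] <- g - 1L
  f
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Mixture model: K = %d, loglik = %.2f, BIC = %.2f\n",
              x$K, x$loglik, x$bic))
  tab <- data.frame(lambda = round(x$lambda, 4),
                    mean_level = round(exp(x$mu[, 1]), 4),
                    mu_X = round(x$mu[, 1], 4),
                    mu_Y = round(x$mu[, 2], 4),
                    var_X = round(x$sigma2[, 1], 4),
                    var_Y = round(x$sigma2[, 2], 4))
  print(tab)
  invisible(x)
}
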