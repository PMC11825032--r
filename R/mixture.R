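# Univariate Gaussian mixture fitting (EM) and BIC model selection.

#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a `k`-component Gaussian mixture to a numeric vector by
#' expectation-maximisation.  For `k = 1` the closed-form maximum-likelihood
#' mean and standard deviation are returned without iteration.  For
#' `k >= 2` the fit is run from a deterministic quantile-based initialisation
#' (component means at `k` evenly spaced sample quantiles, pooled standard
#' deviation, equal weights), a k-means-based start, and `n_restarts`
#' randomly perturbed restarts drawn from a stream seeded by `seed`.  All
#' starts get a short EM run; the one reaching the highest log-likelihood
#' is polished to full tolerance.  Components in the returned fit are ordered by
#' ascending mean, so the result does not depend on initial component labels.
#'
#' A variance floor (`var_floor` times the sample standard deviation) is
#' enforced at every M-step so that no component can collapse onto a single
#' observation.
#'
#' @param x Numeric vector of finite observations, `length(x) >= 10 * k`.
#' @param k Number of components (1, 2 or 3).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param n_restarts Number of perturbed restarts (in addition to the
#'   deterministic start).
#' @param var_floor Standard-deviation floor as a fraction of the sample
#'   standard deviation.
#' @param seed Integer seed for the restart perturbation stream.  The fit is
#'   fully deterministic given `x` and `seed`.
#' @param init Optional list with elements `weight`, `mean`, `sd` giving a
#'   single explicit initialisation; when supplied, restarts are skipped.
#'
#' @return An object of class `gmm_fit`: a list with elements `k`, `weight`,
#'   `mean`, `sd` (each ordered by ascending mean), `loglik`, `n`, `bic`
#'   (`-2 loglik + (3k - 1) log n`), `converged`, `n_iter`, `restarts_used`,
#'   `loglik_trace` (per-iteration log-likelihood of the winning start) and
#'   `responsibilities` (n-by-k matrix of posterior component memberships).
#' @seealso [select_gmm()] for BIC-based choice of `k`,
#'   [thresholds_from_selection()] for mode-intersection thresholds.
#' @examples
#' x <- c(rnorm(100, 0, 0.2), rnorm(100, 2, 0.2))
#' fit <- fit_gmm(x, k = 2)
#' tidy(fit)
#' @export
fit_gmm <- function(x, k, tol = 1e-8, max_iter = 500L, n_restarts = 10L,
                    var_floor = 1e-3, seed = 1L, init = NULL) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) {
    rlang::abort("`x` must be finite and free of missing values.")
  }
  k <- as.integer(k)
  if (k < 1L || k > 3L) {
    rlang::abort("`k` must be 1, 2 or 3; larger mixtures are not supported.")
  }
  n <- length(x)
  # the closed-form k = 1 fit only needs two points; EM fits need 10 per
  # component
  n_min <- if (k == 1L) 2L else 10L * k
  if (n < n_min) {
    rlang::abort(sprintf(
      "Too few observations: n = %d but at least %d are required for k = %d.",
      n, n_min, k
    ))
  }

  # ML (divide-by-n) scale, consistent with the mixture likelihood
  sd_hat <- sqrt(mean((x - mean(x))^2))

  if (k == 1L) {
    mu <- mean(x)
    loglik <- sum(stats::dnorm(x, mu, sd_hat, log = TRUE))
    return(new_gmm_fit(
      k = 1L, weight = 1, mean = mu, sd = sd_hat, loglik = loglik, n = n,
      converged = TRUE, n_iter = 0L, restarts_used = 0L,
      loglik_trace = loglik,
      responsibilities = matrix(1, nrow = n, ncol = 1)
    ))
  }

  if (sd_hat == 0) {
    rlang::abort(paste(
      "Degenerate data: all values are identical, so a mixture with k >= 2",
      "components cannot be fitted."
    ))
  }
  sd_floor <- var_floor * sd_hat

  base_mu <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7)
  inits <- list(list(weight = rep(1 / k, k), mean = base_mu,
                     sd = rep(sd_hat, k)))
  # tail-anchored starts: place a component mean in each extreme tail so
  # that a low-weight, well-separated mode is found even when it is too
  # small to attract a quantile or k-means start
  anchor_probs <- if (k == 2L) {
    list(c(0.02, 0.55), c(0.45, 0.98))
  } else if (k == 3L) {
    list(c(0.02, 0.50, 0.98), c(0.02, 0.30, 0.65), c(0.35, 0.70, 0.98))
  } else list()
  for (p in anchor_probs) {
    inits <- c(inits, list(list(
      weight = rep(1 / k, k),
      mean = stats::quantile(x, p, names = FALSE, type = 7),
      sd = pmax(rep(sd_hat / 3, k), sd_floor)
    )))
  }
  restarts_used <- 0L
  if (!is.null(init)) {
    stopifnot(length(init$weight) == k, length(init$mean) == k,
              length(init$sd) == k)
    inits <- list(list(weight = init$weight / sum(init$weight),
                       mean = as.numeric(init$mean),
                       sd = as.numeric(init$sd)))
  } else if (n_restarts > 0L) {
    restarts_used <- as.integer(n_restarts)
    extra <- withr::with_seed(seed, {
      # k-means start: reliably locates small, well-separated modes that a
      # quantile start can miss
      km <- tryCatch(
        stats::kmeans(x, centers = k, nstart = 10L, iter.max = 50L),
        error = function(e) NULL
      )
      km_init <- if (!is.null(km)) {
        list(list(
          weight = pmax(km$size, 1) / sum(pmax(km$size, 1)),
          mean = as.numeric(km$centers),
          sd = pmax(sqrt(km$withinss / pmax(km$size, 1)), sd_floor)
        ))
      } else list()
      perturbed <- lapply(seq_len(n_restarts), function(r) {
        w <- stats::runif(k, 0.5, 1.5)
        list(
          weight = w / sum(w),
          mean = sort(sample(x, k)) + stats::rnorm(k, 0, sd_hat / 4),
          sd = pmax(sd_hat * stats::runif(k, 0.3, 1.2), sd_floor)
        )
      })
      c(km_init, perturbed)
    })
    inits <- c(inits, extra)
  }

  # short EM runs from every start, then polish the winner to full tolerance
  short_tol <- max(tol, 1e-5)
  short_iter <- min(as.integer(max_iter), 40L)
  best <- NULL
  for (ini in inits) {
    res <- if (length(inits) > 1L) {
      em_gauss_cpp(x, ini$weight, ini$mean, ini$sd, short_tol, short_iter,
                   sd_floor)
    } else {
      em_gauss_cpp(x, ini$weight, ini$mean, ini$sd, tol,
                   as.integer(max_iter), sd_floor)
    }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (length(inits) > 1L) {
    best <- em_gauss_cpp(x, best$weight, best$mean, best$sd, tol,
                         as.integer(max_iter), sd_floor)
  }

  ord <- order(best$mean)
  new_gmm_fit(
    k = k, weight = best$weight[ord], mean = best$mean[ord],
    sd = best$sd[ord], loglik = best$loglik, n = n,
    converged = best$converged, n_iter = best$n_iter,
    restarts_used = restarts_used, loglik_trace = best$loglik_trace,
    responsibilities = best$responsibilities[, ord, drop = FALSE]
  )
}

#' Construct a mixture fit from known parameters
#'
#' Low-level constructor used to build a `gmm_fit` directly from component
#' parameters, e.g. the generating components of a synthetic cohort.  The
#' log-likelihood (and hence BIC) is evaluated at the supplied parameters if
#' data are given, otherwise recorded as `NA`.
#'
#' @param weight,mean,sd Component parameters (equal length, 1 to 3).
#' @param x Optional data vector on which to evaluate the log-likelihood.
#' @return A `gmm_fit` object with components ordered by ascending mean.
#' @export
gmm_fit <- function(weight, mean, sd, x = NULL) {
  k <- length(mean)
  stopifnot(length(weight) == k, length(sd) == k, k >= 1, k <= 3,
            all(sd > 0), all(weight > 0))
  weight <- weight / sum(weight)
  ord <- order(mean)
  weight <- weight[ord]; mean <- mean[ord]; sd <- sd[ord]
  if (!is.null(x)) {
    n <- length(x)
    loglik <- sum(log(gmm_density(x, weight, mean, sd)))
  } else {
    n <- NA_integer_
    loglik <- NA_real_
  }
  new_gmm_fit(k = as.integer(k), weight = weight, mean = mean, sd = sd,
              loglik = loglik, n = n, converged = TRUE, n_iter = 0L,
              restarts_used = 0L, loglik_trace = loglik,
              responsibilities = NULL)
}

new_gmm_fit <- function(k, weight, mean, sd, loglik, n, converged, n_iter,
                        restarts_used, loglik_trace, responsibilities) {
  structure(
    list(
      k = k, weight = weight, mean = mean, sd = sd, loglik = loglik, n = n,
      bic = gmm_bic(loglik, k, n), converged = converged, n_iter = n_iter,
      restarts_used = restarts_used, loglik_trace = loglik_trace,
      responsibilities = responsibilities
    ),
    class = "gmm_fit"
  )
}

# BIC with p = 3k - 1 free parameters (k means, k sds, k - 1 weights)
gmm_bic <- function(loglik, k, n) {
  -2 * loglik + (3 * k - 1) * log(n)
}

# mixture density at the given parameters
gmm_density <- function(x, weight, mean, sd) {
  dens <- 0
  for (j in seq_along(weight)) {
    dens <- dens + weight[j] * stats::dnorm(x, mean[j], sd[j])
  }
  dens
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture fit: k = %d, n = %d, loglik = %.4f, BIC = %.4f%s\n",
    x$k, x$n, x$loglik, x$bic,
    if (isTRUE(x$converged)) "" else " (not converged)"
  ))
  print(tidy(x))
  invisible(x)
}

#' Fit mixtures with one to `k_max` components and pick the best by BIC
#'
#' Fits Gaussian mixtures with `k = 1, ..., k_max` components to the same
#' data and selects the component count with the lowest BIC among converged
#' fits.  BIC ties (within `1e-9`) are broken toward the smaller `k`.
#'
#' @inheritParams fit_gmm
#' @param k_max Largest number of components to consider (at most 3).
#' @param metric,treatment Optional labels carried into the result, used by
#'   the reporting and plotting helpers.
#' @param ... Passed on to [fit_gmm()] (`tol`, `max_iter`, `n_restarts`,
#'   `var_floor`, `seed`).
#' @return An object of class `gmm_selection`: a list with `fits` (one
#'   `gmm_fit` per `k`), `best_k`, `metric`, `treatment`, `n` and the data
#'   `x`.
#' @examples
#' x <- c(rnorm(200, 0, 0.3), rnorm(200, 3, 0.3))
#' sel <- select_gmm(x)
#' sel$best_k
#' @export
select_gmm <- function(x, k_max = 3L, metric = NULL, treatment = NULL, ...) {
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > 3L) {
    rlang::abort("`k_max` must be between 1 and 3.")
  }
  fits <- lapply(seq_len(k_max), function(k) fit_gmm(x, k, ...))
  bics <- vapply(fits, function(f) {
    if (isTRUE(f$converged)) f$bic else Inf
  }, numeric(1))
  if (all(!is.finite(bics))) {
    rlang::abort("No mixture fit converged for any number of components.")
  }
  # ties within 1e-9 resolve to the smaller k (parsimony)
  best_k <- which(bics <= min(bics) + 1e-9)[1]
  structure(
    list(fits = fits, best_k = as.integer(best_k), metric = metric,
         treatment = treatment, n = length(x), x = as.numeric(x)),
    class = "gmm_selection"
  )
}

#' @export
print.gmm_selection <- function(x, ...) {
  lab <- paste(c(x$treatment, x$metric), collapse = " ")
  if (nzchar(lab)) lab <- paste0(" [", lab, "]")
  cat(sprintf("Mixture model selection%s: n = %d, best k = %d\n",
              lab, x$n, x$best_k))
  print(glance(x))
  invisible(x)
}
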