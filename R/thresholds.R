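# Decision thresholds at the intersections of adjacent weighted component
# densities of a fitted mixture.

#' Intersection of two weighted Gaussian densities
#'
#' Finds the value `x` at which the weighted densities of two mixture
#' components are equal, `w_lo * phi(x; mu_lo, sd_lo) = w_hi * phi(x; mu_hi,
#' sd_hi)`, restricted to the open interval between the component means.
#' This is the classification threshold separating the two modes.
#'
#' Equating the log weighted densities gives a quadratic in `x` (linear when
#' the two standard deviations are equal).  When more than one root lies
#' between the means, the root at which classification flips from the lower
#' to the upper component as `x` increases is chosen.  When no real root
#' lies in the interval (possible under extreme weight imbalance), the
#' threshold falls back to the in-interval argmin of the absolute weighted
#' density difference on a fine grid and the result is flagged
#' `method = "fallback"`.
#'
#' @param w_lo,mean_lo,sd_lo Weight, mean and standard deviation of the
#'   lower-mean component.
#' @param w_hi,mean_hi,sd_hi Parameters of the higher-mean component;
#'   `mean_lo < mean_hi` is required.
#' @param grid_n Number of grid points used by the fallback search.
#' @return A list with `value` (the threshold) and `method`
#'   (`"analytic"` or `"fallback"`).
#' @examples
#' component_intersection(0.5, 0, 1, 0.5, 2, 1)$value # exactly 1
#' component_intersection(0.8, 0, 1, 0.2, 2, 1)$value # 1 + log(4) / 2
#' @export
component_intersection <- function(w_lo, mean_lo, sd_lo, w_hi, mean_hi, sd_hi,
                                   grid_n = 200001L) {
  pars <- c(w_lo, mean_lo, sd_lo, w_hi, mean_hi, sd_hi)
  if (any(!is.finite(pars))) {
    rlang::abort("All component parameters must be finite.")
  }
  if (sd_lo <= 0 || sd_hi <= 0 || w_lo <= 0 || w_hi <= 0) {
    rlang::abort("Component weights and standard deviations must be positive.")
  }
  if (mean_lo >= mean_hi) {
    rlang::abort("`mean_lo` must be strictly less than `mean_hi`.")
  }

  # f(x) = log[w_lo phi_lo(x)] - log[w_hi phi_hi(x)] = A x^2 + B x + C
  A <- 1 / (2 * sd_hi^2) - 1 / (2 * sd_lo^2)
  B <- mean_lo / sd_lo^2 - mean_hi / sd_hi^2
  C <- mean_hi^2 / (2 * sd_hi^2) - mean_lo^2 / (2 * sd_lo^2) +
    log(w_lo * sd_hi / (w_hi * sd_lo))

  roots <- if (abs(A) < 1e-14 * max(1 / sd_lo^2, 1 / sd_hi^2)) {
    if (B == 0) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else {
      (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
  }
  inside <- roots[roots > mean_lo & roots < mean_hi]

  if (length(inside) >= 1L) {
    if (length(inside) > 1L) {
      # prefer the root where f is decreasing: lower component dominates on
      # the left, the upper on the right
      slope <- 2 * A * inside + B
      dec <- inside[slope < 0]
      inside <- if (length(dec) >= 1L) dec else inside
    }
    return(list(value = min(inside), method = "analytic"))
  }

  # fallback: argmin of |weighted density difference| on a fine grid
  grid <- seq(mean_lo, mean_hi, length.out = grid_n)
  grid <- grid[-c(1L, length(grid))]
  diff_abs <- abs(w_lo * stats::dnorm(grid, mean_lo, sd_lo) -
                    w_hi * stats::dnorm(grid, mean_hi, sd_hi))
  list(value = grid[which.min(diff_abs)], method = "fallback")
}

#' Thresholds from a selected mixture fit
#'
#' Converts the best-BIC mixture fit into classification thresholds.  A
#' unimodal best fit yields no threshold (`usable = FALSE`); a bimodal fit
#' yields `threshold1` at the intersection of its two components; a trimodal
#' fit yields `threshold1` (components 1 and 2) and `threshold2` (components
#' 2 and 3).  Fits performed on the log10 scale are back-transformed so that
#' reported thresholds are on the original measurement scale.
#'
#' @param sel A `gmm_selection` (or a single `gmm_fit`, taken as the best
#'   fit).
#' @param orientation `"standard"` (values above `threshold1` gate as
#'   maturing) or `"inverted"` (values below gate; used for testis `amh`,
#'   which falls at maturation onset).
#' @param scale Scale on which the fit was performed: `"raw"` or `"log10"`.
#'   Log10-scale thresholds are reported back-transformed (`10^x`).
#' @param metric,treatment Optional labels; defaults are taken from `sel`.
#' @return A one-row tibble with columns `metric`, `treatment`, `scale`,
#'   `best_k`, `usable`, `threshold1`, `threshold2` (measurement scale),
#'   `threshold1_fit`, `threshold2_fit` (fitting scale), `orientation` and
#'   `fallback`.
#' @export
thresholds_from_selection <- function(sel, orientation = c("standard", "inverted"),
                                      scale = c("raw", "log10"),
                                      metric = NULL, treatment = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (inherits(sel, "gmm_fit")) {
    fit <- sel
  } else if (inherits(sel, "gmm_selection")) {
    fit <- sel$fits[[sel$best_k]]
    metric <- metric %||% sel$metric
    treatment <- treatment %||% sel$treatment
  } else {
    rlang::abort("`sel` must be a `gmm_selection` or `gmm_fit`.")
  }

  t1 <- t2 <- NA_real_
  fallback <- FALSE
  if (fit$k >= 2L) {
    i1 <- component_intersection(fit$weight[1], fit$mean[1], fit$sd[1],
                                 fit$weight[2], fit$mean[2], fit$sd[2])
    t1 <- i1$value
    fallback <- i1$method == "fallback"
  }
  if (fit$k == 3L) {
    i2 <- component_intersection(fit$weight[2], fit$mean[2], fit$sd[2],
                                 fit$weight[3], fit$mean[3], fit$sd[3])
    t2 <- i2$value
    fallback <- fallback || i2$method == "fallback"
  }

  back <- function(v) if (scale == "log10") 10^v else v
  tibble(
    metric = metric %||% NA_character_,
    treatment = treatment %||% NA_character_,
    scale = scale,
    best_k = fit$k,
    usable = fit$k >= 2L,
    threshold1 = back(t1),
    threshold2 = back(t2),
    threshold1_fit = t1,
    threshold2_fit = t2,
    orientation = orientation,
    fallback = fallback
  )
}

#' Fit all metrics and tabulate thresholds per treatment
#'
#' The model-fitting stage of the pipeline.  For each treatment, fork length
#' is fitted on the raw mm scale using all fish (milt-expressing males
#' included), and each maturation marker is fitted on the log10 scale using
#' males with positive, non-missing values.  Mixtures with 1 to `k_max`
#' components are compared by BIC and thresholds are computed at the mode
#' intersections of the winning fit.
#'
#' @param cohort A validated cohort tibble (see [read_cohort()]).
#' @param metrics Metrics to fit; defaults to fork length plus the six
#'   maturation markers.
#' @param k_max Largest number of mixture components considered.
#' @param seed Master seed; each (treatment, metric) fit uses a seed derived
#'   from it, so results do not depend on fit order.
#' @param min_n Minimum usable values required to fit a cell at all; cells
#'   below it are reported with `usable = FALSE` and missing BICs.
#' @param ... Further EM options passed to [fit_gmm()].
#' @return A tibble with one row per (treatment, metric): per-k BIC columns
#'   (`bic_fmm1` ... `bic_fmm3`), `best_k`, thresholds on the measurement
#'   scale, `orientation`, `usable`, `fallback` and `n_fit`.  The underlying
#'   `gmm_selection` objects are attached as attribute `"selections"`.
#' @export
threshold_table <- function(cohort, metrics = mixture_metrics(), k_max = 3L,
                            seed = 1L, min_n = 10L, ...) {
  stopifnot(is.data.frame(cohort))
  bad <- setdiff(metrics, mixture_metrics())
  if (length(bad)) {
    rlang::abort(paste0("Unknown metric(s): ", paste(bad, collapse = ", ")))
  }
  treatments <- sort(unique(cohort$treatment))
  cells <- tidyr::expand_grid(treatment = treatments, metric = metrics)

  selections <- list()
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    trt <- cells$treatment[i]
    met <- cells$metric[i]
    if (met == "fork_length") {
      vals <- cohort$fork_length[cohort$treatment == trt]
      scale <- "raw"
    } else {
      sub <- cohort[cohort$treatment == trt & cohort$sex == "male", ]
      v <- sub[[met]]
      vals <- log10(v[!is.na(v) & v > 0])
      scale <- "log10"
    }
    orientation <- if (met == "amh") "inverted" else "standard"
    cell_seed <- (as.integer(seed) %% 100000L) * 211L + i
    n_fit <- length(vals)
    if (n_fit < min_n) {
      rows[[i]] <- tibble(
        treatment = trt, metric = met, n_fit = n_fit,
        bic_fmm1 = NA_real_, bic_fmm2 = NA_real_, bic_fmm3 = NA_real_,
        best_k = NA_integer_, usable = FALSE,
        threshold1 = NA_real_, threshold2 = NA_real_,
        threshold1_fit = NA_real_, threshold2_fit = NA_real_,
        orientation = orientation, fallback = FALSE, scale = scale
      )
      next
    }
    k_cell <- min(k_max, max(1L, n_fit %/% 10L))
    sel <- select_gmm(vals, k_max = k_cell, metric = met, treatment = trt,
                      seed = cell_seed, ...)
    selections[[paste(trt, met, sep = ".")]] <- sel
    thr <- thresholds_from_selection(sel, orientation = orientation,
                                     scale = scale)
    bics <- rep(NA_real_, 3)
    bics[seq_along(sel$fits)] <- vapply(sel$fits, `[[`, numeric(1), "bic")
    rows[[i]] <- dplyr::bind_cols(
      tibble(treatment = trt, metric = met, n_fit = n_fit,
             bic_fmm1 = bics[1], bic_fmm2 = bics[2], bic_fmm3 = bics[3]),
      thr[, c("best_k", "usable", "threshold1", "threshold2",
              "threshold1_fit", "threshold2_fit", "orientation", "fallback",
              "scale")]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "selections") <- selections
  out
}
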