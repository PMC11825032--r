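# broom-style tidiers for fitted objects.

#' Tidy a mixture fit
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `weight`,
#'   `mean`, `sd`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weight, mean = x$mean,
         sd = x$sd)
}

#' Glance at a mixture fit
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `loglik`, `bic`, `n`, `converged`,
#'   `n_iter`, `restarts_used`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, bic = x$bic, n = x$n,
         converged = x$converged, n_iter = x$n_iter,
         restarts_used = x$restarts_used)
}

#' Tidy a model selection
#'
#' @param x A `gmm_selection`.
#' @param ... Unused.
#' @return Component parameters of every candidate fit, with `k` and a
#'   `best` flag.
#' @export
tidy.gmm_selection <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tidy(f) %>% mutate(k = f$k, best = f$k == x$best_k)
  })
}

#' Glance at a model selection
#'
#' @param x A `gmm_selection`.
#' @param ... Unused.
#' @return One row per candidate `k` with fit summaries and a `best` flag.
#' @export
glance.gmm_selection <- function(x, ...) {
  purrr::map_dfr(x$fits, glance) %>%
    mutate(best = .data$k == x$best_k)
}
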