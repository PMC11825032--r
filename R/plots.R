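# ggplot2 visualisations: frequency distributions with fitted components
# and threshold reference lines, and stacked status proportions.

#' Plot a mixture selection with its thresholds
#'
#' Histogram of the fitted values (density scale) overlaid with the
#' weighted component densities and the total mixture density of the
#' best-BIC fit, plus dashed reference lines at the mode-intersection
#' thresholds.
#'
#' @param object A `gmm_selection`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_selection <- function(object, bins = 60, ...) {
  fit <- object$fits[[object$best_k]]
  xs <- seq(min(object$x), max(object$x), length.out = 512)
  comp <- purrr::map_dfr(seq_len(fit$k), function(j) {
    tibble(x = xs, component = factor(j),
           density = fit$weight[j] * stats::dnorm(xs, fit$mean[j], fit$sd[j]))
  })
  total <- tibble(x = xs, density = gmm_density(xs, fit$weight, fit$mean,
                                                fit$sd))
  thr <- thresholds_from_selection(object)
  vlines <- stats::na.omit(c(thr$threshold1_fit, thr$threshold2_fit))
  lab <- paste(c(object$treatment, object$metric), collapse = " ")

  p <- ggplot2::ggplot(tibble(x = object$x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density),
                       linewidth = 0.8) +
    ggplot2::labs(x = lab, y = "density",
                  title = sprintf("Best fit: %d component(s)", fit$k)) +
    ggplot2::theme_minimal()
  if (length(vlines)) {
    p <- p + ggplot2::geom_vline(xintercept = vlines, linetype = "dashed")
  }
  p
}

#' Plot status proportions from a report
#'
#' Stacked bar chart of classified status proportions by treatment and
#' sex.
#'
#' @param object A `smolt_report`.
#' @param which Which proportions to show: `"migration"`, `"maturation"`
#'   or `"phenotype"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smolt_report <- function(object,
                                  which = c("migration", "maturation",
                                            "phenotype"), ...) {
  which <- match.arg(which)
  tab <- switch(which,
                migration = object$residual_proportions,
                maturation = object$maturation_proportions,
                phenotype = object$phenotype_proportions)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$treatment,
                                         y = .data$prop,
                                         fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(y = "proportion", x = "rearing treatment",
                  title = sprintf("%s status by treatment", which)) +
    ggplot2::theme_minimal()
  if ("sex" %in% names(tab)) {
    p <- p + ggplot2::facet_wrap(~sex)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
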