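# End-to-end orchestration: validate -> transform -> fit -> thresholds ->
# classify -> summarise -> test.

#' Default analysis configuration
#'
#' @param male_residual_rule `"or"` (default) or `"and"`; see
#'   [classify_migration()].
#' @param correct Continuity-correction policy for the test battery.
#' @param k_max Largest number of mixture components considered per metric.
#' @param metrics Metrics to fit.
#' @return A plain list of analysis options for [run_analysis()].
#' @export
default_analysis_config <- function(male_residual_rule = "or", correct = TRUE,
                                    k_max = 3L, metrics = mixture_metrics()) {
  list(male_residual_rule = male_residual_rule, correct = correct,
       k_max = k_max, metrics = metrics)
}

#' Run the full classification analysis
#'
#' Executes the pipeline stages in fixed order on a cohort: validation,
#' log10 transformation of the maturation markers, per-(treatment, metric)
#' mixture fits pooled across release years (milt-expressing males
#' included in the fits), mode-intersection thresholds, maturation and
#' migration classification, stratum proportions, and the chi-square
#' comparison battery.  The run is a pure function of (cohort, config,
#' seed).
#'
#' @param cohort A cohort tibble (see [read_cohort()]), or a path to a
#'   cohort CSV file.
#' @param config Analysis options, see [default_analysis_config()].
#' @param seed Integer seed for the mixture-fit restart streams.
#' @return An object of class `smolt_report`: a list with `thresholds`
#'   (per-treatment fit and threshold tibble), `classifications` (per-fish calls),
#'   `phenotype_proportions`, `maturation_proportions`,
#'   `residual_proportions`, `tests` (the battery), `exclusions` (values
#'   dropped before the log transform) and `meta` (seed, options, counts,
#'   warnings).
#' @examples
#' lc <- generate_cohort(seed = 7)
#' report <- run_analysis(lc$cohort, seed = 7)
#' report$thresholds
#' @export
run_analysis <- function(cohort, config = default_analysis_config(),
                         seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stage <- "validation"
  report <- tryCatch({
    cohort <- validate_cohort(cohort)

    stage <- "log10 transform"
    marker_metrics <- setdiff(config$metrics, "fork_length")
    lv <- log10_markers(cohort, marker_metrics)
    exclusions <- attr(lv, "exclusions")

    stage <- "mixture fitting"
    thresholds <- threshold_table(cohort, metrics = config$metrics,
                                  k_max = config$k_max, seed = seed)

    stage <- "classification"
    classified <- classify_cohort(cohort, thresholds,
                                  male_residual_rule = config$male_residual_rule)

    stage <- "summaries"
    has_males <- any(cohort$sex == "male")
    phen <- summarize_calls(classified, "phenotype")
    mat <- if (has_males) {
      summarize_calls(classified %>% filter(.data$sex == "male"), "maturation",
                      by = "treatment")
    } else {
      tibble(treatment = character(), status = character(),
             n = integer(), prop = numeric())
    }
    mig <- summarize_calls(classified, "migration")

    stage <- "proportion tests"
    tests <- proportion_battery(classified, correct = config$correct)

    warnings <- character(0)
    fb <- thresholds %>% filter(.data$fallback)
    if (nrow(fb)) {
      warnings <- c(warnings, sprintf(
        "fallback threshold used for %s",
        paste(fb$treatment, fb$metric, collapse = ", ")
      ))
    }
    n_unknown <- sum(classified$maturation_status == "unknown", na.rm = TRUE)
    if (n_unknown > 0) {
      warnings <- c(warnings, sprintf(
        "%d male(s) with unknown maturation status (no usable marker)",
        n_unknown
      ))
    }
    if (!is.null(exclusions) && nrow(exclusions)) {
      warnings <- c(warnings, sprintf(
        "%d non-positive marker value(s) excluded before log transform",
        sum(exclusions$n_excluded)
      ))
    }

    structure(
      list(
        thresholds = thresholds, classifications = classified,
        phenotype_proportions = phen, maturation_proportions = mat,
        residual_proportions = mig, tests = tests, exclusions = exclusions,
        meta = list(seed = as.integer(seed), options = config,
                    version = as.character(utils::packageVersion("smoltsort")),
                    n = nrow(cohort),
                    n_by_treatment = table(cohort$treatment),
                    provenance = attr(cohort, "provenance"),
                    warnings = warnings)
      ),
      class = "smolt_report"
    )
  }, error = function(e) {
    rlang::abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)), parent = e)
  })
  report
}

#' @export
print.smolt_report <- function(x, ...) {
  cat("Life-history classification report\n")
  cat(sprintf("  fish: %d (seed %d)\n", x$meta$n, x$meta$seed))
  cat("\nThresholds (measurement scale):\n")
  print(x$thresholds %>%
          select("treatment", "metric", "best_k", "threshold1", "threshold2",
                 "orientation", "usable"), n = Inf)
  cat("\nPredicted residual proportions:\n")
  print(x$residual_proportions, n = Inf)
  if (length(x$meta$warnings)) {
    cat("\nWarnings:\n")
    cat(paste(" -", x$meta$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

fmt_thr <- function(x, metric) {
  if_else(is.na(x), NA_character_,
          if_else(metric == "fork_length", sprintf("%.1f", x),
                  if_else(metric == "gsi", sprintf("%.3f", x),
                          sprintf("%.2f", x))))
}

#' Write a report to disk
#'
#' Writes `thresholds.csv`, `classifications.csv`, `proportions.csv`,
#' `tests.csv` and a human-readable `report.md` into a directory.  Numbers
#' in `report.md` are printed at conventional reporting precisions
#' (thresholds to 0.1 mm / 0.001 GSI-%, chi-square statistics to 3
#' decimals, proportions to 0.1%); the CSV files carry full machine
#' precision.  Output is byte-identical for identical reports.
#'
#' @param report A `smolt_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "smolt_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$thresholds, file.path(dir, "thresholds.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(report$classifications,
                   file.path(dir, "classifications.csv"), na = "",
                   progress = FALSE)
  props <- dplyr::bind_rows(
    report$phenotype_proportions %>% mutate(kind = "phenotype"),
    report$maturation_proportions %>% mutate(kind = "maturation"),
    report$residual_proportions %>% mutate(kind = "migration")
  )
  readr::write_csv(props, file.path(dir, "proportions.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(report$tests, file.path(dir, "tests.csv"), na = "",
                   progress = FALSE)

  thr <- report$thresholds %>%
    mutate(t1 = fmt_thr(.data$threshold1, .data$metric),
           t2 = fmt_thr(.data$threshold2, .data$metric))
  lines <- c(
    "# Life-history classification report", "",
    sprintf("Fish analysed: %d; seed: %d.", report$meta$n, report$meta$seed),
    "", "## Thresholds (best-BIC mixture fits, measurement scale)", "",
    "| Treatment | Metric | Best fit | Threshold 1 | Threshold 2 |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | fmm %s | %s | %s |", thr$treatment, thr$metric,
            thr$best_k, if_else(is.na(thr$t1), "-", thr$t1),
            if_else(is.na(thr$t2), "-", thr$t2)),
    "", "## Predicted residual proportions", "",
    "| Treatment | Sex | Status | n | % |", "|---|---|---|---|---|",
    with(report$residual_proportions,
         sprintf("| %s | %s | %s | %d | %.1f |", treatment, sex, status, n,
                 100 * prop)),
    "", "## Equality-of-proportions tests", "",
    "| Comparison | X2 | df | N | p | Result |", "|---|---|---|---|---|---|",
    with(report$tests,
         sprintf("| %s | %s | %d | %d | %s | %s |", label,
                 if_else(is.na(statistic), "-", sprintf("%.3f", statistic)),
                 df, n,
                 if_else(is.na(p_value), "-",
                         if_else(p_value < 0.001, "< 0.001",
                                 sprintf("%.4f", p_value))),
                 result))
  )
  if (length(report$meta$warnings)) {
    lines <- c(lines, "", "## Warnings", "",
               paste("-", report$meta$warnings))
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
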