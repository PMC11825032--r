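# Pearson chi-square tests for equality of two proportions, and the
# standard battery of group comparisons run on a classified cohort.

#' Pearson chi-square test for equality of two proportions
#'
#' Tests whether two groups share the same success proportion from a 2x2
#' table of counts: group 1 with `a` successes and `b` failures, group 2
#' with `c` successes and `d` failures.  The uncorrected statistic is
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; with Yates continuity
#' correction `|ad - bc|` is replaced by `max(|ad - bc| - N/2, 0)`.  The
#' p-value comes from the chi-square distribution with one degree of
#' freedom.
#'
#' @param a,b Successes and failures in group 1 (non-negative integers).
#' @param c,d Successes and failures in group 2.
#' @param correct Apply the Yates continuity correction?
#' @return A one-row tibble of class `prop_test_2x2`: `statistic`, `df`,
#'   `p_value`, `corrected`, `n`, `prop1`, `prop2`.
#' @examples
#' prop_test_2x2(370, 2646, 115, 2888, correct = FALSE)
#' @export
prop_test_2x2 <- function(a, b, c, d, correct = TRUE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("Counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n <= 0) rlang::abort("The table total must be positive.")
  margins <- c(`row 1 (group 1)` = a + b, `row 2 (group 2)` = c + d,
               `column 1 (successes)` = a + c, `column 2 (failures)` = b + d)
  if (any(margins == 0)) {
    rlang::abort(sprintf("Degenerate margin: %s is zero.",
                         names(margins)[which(margins == 0)[1]]))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - n / 2, 0)
  statistic <- n * num^2 / prod(margins)
  out <- tibble(
    statistic = statistic, df = 1L,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    corrected = correct, n = as.integer(n),
    prop1 = a / (a + b), prop2 = c / (c + d)
  )
  class(out) <- c("prop_test_2x2", class(out))
  out
}

# -- battery ----------------------------------------------------------------

# A comparison row: each group is a subset of fish (treatment and/or sex)
# and the outcome is membership in one category of a classification column.
battery_row <- function(label, outcome_col, outcome_value,
                        trt1, sex1, trt2, sex2) {
  tibble(label = label, outcome_col = outcome_col,
         outcome_value = outcome_value,
         trt1 = trt1, sex1 = sex1, trt2 = trt2, sex2 = sex2)
}

#' Default comparison battery
#'
#' The standard set of equality-of-proportions comparisons run on a
#' classified cohort: male vs female within each treatment for every smolt
#' phenotype class and for predicted residuals; S1 vs S2 for every
#' phenotype class (mature males included), for immature and maturing
#' males, and for residuals by sex and overall.
#'
#' @return A tibble of comparison definitions for [proportion_battery()].
#' @export
default_battery <- function() {
  ALL <- NA_character_
  rows <- list()
  for (trt in c("S1", "S2")) {
    for (ph in c("parr", "transitional", "smolt")) {
      rows <- c(rows, list(battery_row(
        sprintf("%s male %s vs. %s female %s", trt, ph, trt, ph),
        "phenotype_class", ph, trt, "male", trt, "female"
      )))
    }
  }
  rows <- c(rows, list(
    battery_row("S1 mature male vs. S2 mature male", "phenotype_class",
                "mature male", "S1", ALL, "S2", ALL)
  ))
  for (ph in c("parr", "transitional", "smolt")) {
    rows <- c(rows, list(battery_row(
      sprintf("S1 %s vs. S2 %s", ph, ph), "phenotype_class", ph,
      "S1", ALL, "S2", ALL
    )))
  }
  rows <- c(rows, list(
    battery_row("S1 immature males vs. S2 immature males",
                "maturation_status", "immature", "S1", "male", "S2", "male"),
    battery_row("S1 maturing males vs. S2 maturing males",
                "maturation_status", "maturing", "S1", "male", "S2", "male"),
    battery_row("S1 male residuals vs. S1 female residuals",
                "migration_status", "residual", "S1", "male", "S1", "female"),
    battery_row("S2 male residuals vs. S2 female residuals",
                "migration_status", "residual", "S2", "male", "S2", "female"),
    battery_row("S1 male residuals vs. S2 male residuals",
                "migration_status", "residual", "S1", "male", "S2", "male"),
    battery_row("S1 female residuals vs. S2 female residuals",
                "migration_status", "residual", "S1", "female", "S2", "female"),
    battery_row("S1 residuals vs. S2 residuals",
                "migration_status", "residual", "S1", ALL, "S2", ALL)
  ))
  dplyr::bind_rows(rows)
}

battery_counts <- function(classified, outcome_col, outcome_value, trt, sex) {
  sub <- classified %>% filter(.data$treatment == .env$trt)
  if (!is.na(sex)) sub <- sub %>% filter(.data$sex == .env$sex)
  hit <- !is.na(sub[[outcome_col]]) & sub[[outcome_col]] == outcome_value
  c(success = sum(hit), failure = sum(!hit))
}

#' Run the comparison battery on a classified cohort
#'
#' For every comparison definition, builds the 2x2 count table from the
#' classified cohort and runs [prop_test_2x2()].  A comparison with an
#' empty group is emitted with `computable = FALSE` rather than an error.
#' Significance is called at `alpha` with the direction of the difference
#' (`NS`, `greater`, `less` for group 1 relative to group 2).
#'
#' @param classified A classified cohort (see [classify_cohort()]).
#' @param comparisons Comparison definitions; defaults to
#'   [default_battery()].
#' @param correct Continuity-correction policy: a single logical recycled
#'   across rows, or a logical vector with one entry per comparison.
#' @param alpha Significance level for the direction call.
#' @return A tibble with one row per comparison: `label`, the four counts,
#'   `corrected`, `statistic`, `df`, `n`, `p_value`, `result`,
#'   `computable`.
#' @export
proportion_battery <- function(classified, comparisons = default_battery(),
                               correct = TRUE, alpha = 0.05) {
  correct <- rep_len(correct, nrow(comparisons))
  rows <- vector("list", nrow(comparisons))
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    g1 <- battery_counts(classified, cmp$outcome_col, cmp$outcome_value,
                         cmp$trt1, cmp$sex1)
    g2 <- battery_counts(classified, cmp$outcome_col, cmp$outcome_value,
                         cmp$trt2, cmp$sex2)
    base <- tibble(label = cmp$label, a = g1[["success"]], b = g1[["failure"]],
                   c = g2[["success"]], d = g2[["failure"]],
                   corrected = correct[i])
    ok_margins <- sum(g1) > 0 && sum(g2) > 0 &&
      (g1[["success"]] + g2[["success"]]) > 0 &&
      (g1[["failure"]] + g2[["failure"]]) > 0
    if (!ok_margins) {
      rows[[i]] <- base %>% mutate(statistic = NA_real_, df = 1L,
                                   n = sum(g1) + sum(g2), p_value = NA_real_,
                                   result = "not computable",
                                   computable = FALSE)
      next
    }
    tst <- prop_test_2x2(g1[["success"]], g1[["failure"]], g2[["success"]],
                         g2[["failure"]], correct = correct[i])
    result <- if (tst$p_value >= alpha) "NS" else {
      if (tst$prop1 > tst$prop2) "greater" else "less"
    }
    rows[[i]] <- base %>% mutate(statistic = tst$statistic, df = tst$df,
                                 n = tst$n, p_value = tst$p_value,
                                 result = result, computable = TRUE)
  }
  dplyr::bind_rows(rows)
}
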