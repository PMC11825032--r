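# Gating rules: maturation status for males, migrant/residual status for
# every fish.

#' Gonadosomatic index
#'
#' GSI as a percentage: `100 * gonad_weight / body_weight`.
#'
#' @param gonad_weight,body_weight Weights in grams; both must be positive.
#'   Missing values propagate.
#' @return Numeric vector of GSI percentages.
#' @examples
#' compute_gsi(0.05, 50) # 0.1 %
#' @export
compute_gsi <- function(gonad_weight, body_weight) {
  if (any(gonad_weight <= 0, na.rm = TRUE) ||
      any(body_weight <= 0, na.rm = TRUE)) {
    rlang::abort("Gonad and body weights must be positive.")
  }
  100 * gonad_weight / body_weight
}

# verdict for one marker column against its (per-treatment) threshold row;
# an exact tie is not "exceeding" the gate in either orientation, so it is
# labelled with the non-gating side
marker_verdict <- function(value, threshold1, usable, orientation) {
  case_when(
    !usable ~ "unusable",
    is.na(value) ~ "missing",
    value > threshold1 ~ "above",
    value < threshold1 ~ "below",
    orientation == "inverted" ~ "above",
    TRUE ~ "below"
  )
}

#' Classify male maturation status from the marker panel
#'
#' Applies the gating rules to every male in the cohort.  A milt-expressing
#' male is `mature` unconditionally.  Otherwise the male is `maturing` if at
#' least one usable, present marker is past its gate -- strictly above
#' `threshold1` for standard-orientation markers, strictly below for the
#' inverted marker (`amh`, whose expression falls at maturation onset).  A
#' male with at least one usable evaluated marker and none past its gate is
#' `immature`; with no usable marker at all it is `unknown`.  Values exactly
#' equal to a threshold are not past the gate.  Markers whose best fit was
#' unimodal (`usable = FALSE`) contribute nothing, as do missing values.
#' Fork length is never consulted.
#'
#' @param cohort A validated cohort tibble.
#' @param thresholds A threshold table (see [threshold_table()]) with rows
#'   for every treatment present in the cohort.
#' @return A tibble with one row per male: `fish_id`, `treatment`,
#'   `maturation_status` (immature/maturing/mature/unknown),
#'   `n_markers_used`, and one verdict column `ev_<marker>` per maturation
#'   marker (above/below/missing/unusable).
#' @export
classify_maturation <- function(cohort, thresholds) {
  males <- cohort %>% filter(.data$sex == "male")
  miss_trt <- setdiff(unique(males$treatment), unique(thresholds$treatment))
  if (length(miss_trt)) {
    rlang::abort(paste0("No thresholds supplied for treatment(s): ",
                        paste(miss_trt, collapse = ", ")))
  }
  out <- males %>% select("fish_id", "treatment", "milt_expressed")
  gated_any <- rep(FALSE, nrow(males))
  n_used <- rep(0L, nrow(males))
  for (mk in maturation_markers()) {
    thr <- thresholds %>% filter(.data$metric == mk)
    idx <- match(males$treatment, thr$treatment)
    t1 <- thr$threshold1[idx]
    usable <- thr$usable[idx] & !is.na(t1)
    usable[is.na(usable)] <- FALSE
    orientation <- thr$orientation[idx]
    v <- marker_verdict(males[[mk]], t1, usable, orientation)
    gate <- (orientation == "standard" & v == "above") |
      (orientation == "inverted" & v == "below")
    gated_any <- gated_any | gate
    n_used <- n_used + as.integer(v %in% c("above", "below"))
    out[[paste0("ev_", mk)]] <- v
  }
  out %>%
    mutate(
      maturation_status = case_when(
        .data$milt_expressed ~ "mature",
        gated_any ~ "maturing",
        n_used >= 1L ~ "immature",
        TRUE ~ "unknown"
      ),
      n_markers_used = n_used
    ) %>%
    select("fish_id", "treatment", "maturation_status", "n_markers_used",
           dplyr::starts_with("ev_"))
}

#' Classify migration status (migrant vs residual)
#'
#' Applies the sex-specific residual rules.  Females are residual exactly
#' when their fork length fails to exceed the treatment's fork-length
#' threshold (none of them mature).  Males are, under the default `"or"`
#' rule, residual when they are below the fork-length threshold *or* are
#' maturing/mature; under the `"and"` rule both conditions are required.
#' Males of unknown maturation status are treated as immature for this rule
#' and flagged.
#'
#' @param cohort A validated cohort tibble.
#' @param maturation Output of [classify_maturation()].
#' @param thresholds Threshold table containing `fork_length` rows for every
#'   treatment in the cohort.
#' @param male_residual_rule `"or"` (default; a precociously maturing or
#'   mature male of any size is a predicted residual) or `"and"`.
#' @return A tibble with one row per fish: `fish_id`, `migration_status`
#'   (migrant/residual), `basis` (`length_only`, `maturation_only` or
#'   `both` for residuals; `NA` for migrants) and `maturation_unknown`.
#' @export
classify_migration <- function(cohort, maturation, thresholds,
                               male_residual_rule = c("or", "and")) {
  male_residual_rule <- match.arg(male_residual_rule)
  fl_thr <- thresholds %>% filter(.data$metric == "fork_length")
  idx <- match(cohort$treatment, fl_thr$treatment)
  t_fl <- fl_thr$threshold1[idx]
  if (anyNA(t_fl)) {
    rlang::abort("A usable fork-length threshold is required for every treatment.")
  }
  mat <- maturation$maturation_status[match(cohort$fish_id, maturation$fish_id)]
  unknown <- cohort$sex == "male" & !is.na(mat) & mat == "unknown"
  small <- cohort$fork_length < t_fl
  maturing <- !is.na(mat) & mat %in% c("maturing", "mature")

  residual <- if_else(
    cohort$sex == "female",
    small,
    if (male_residual_rule == "or") small | maturing else small & maturing
  )
  basis <- case_when(
    !residual ~ NA_character_,
    cohort$sex == "female" ~ "length_only",
    small & maturing ~ "both",
    small ~ "length_only",
    TRUE ~ "maturation_only"
  )
  tibble(
    fish_id = cohort$fish_id,
    migration_status = if_else(residual, "residual", "migrant"),
    basis = basis,
    maturation_unknown = unknown
  )
}

#' Classify a whole cohort
#'
#' Convenience wrapper running [classify_maturation()] and
#' [classify_migration()] and joining the calls onto the cohort.  Females
#' are recorded as `immature` (precocious maturation is not observed in
#' juvenile females) and the phenotype category column folds milt-expressing
#' males into a `mature male` class, mirroring how proportions are reported.
#'
#' @inheritParams classify_migration
#' @param thresholds Threshold table for the cohort's treatments.
#' @return The cohort tibble with added columns `maturation_status`,
#'   `n_markers_used`, `migration_status`, `basis`, `maturation_unknown`
#'   and `phenotype_class`.
#' @export
classify_cohort <- function(cohort, thresholds,
                            male_residual_rule = c("or", "and")) {
  male_residual_rule <- match.arg(male_residual_rule)
  maturation <- classify_maturation(cohort, thresholds)
  migration <- classify_migration(cohort, maturation, thresholds,
                                  male_residual_rule)
  cohort %>%
    left_join(maturation %>% select("fish_id", "maturation_status",
                                    "n_markers_used"),
              by = "fish_id") %>%
    mutate(
      maturation_status = if_else(.data$sex == "female", "immature",
                                  .data$maturation_status),
      n_markers_used = if_else(is.na(.data$n_markers_used), 0L,
                               .data$n_markers_used),
      phenotype_class = if_else(.data$milt_expressed, "mature male",
                                .data$smolt_phenotype)
    ) %>%
    left_join(migration, by = "fish_id")
}

#' Summarise classification calls as stratum proportions
#'
#' Tabulates counts and within-stratum proportions of a status column by
#' treatment and sex.  Proportions sum to one within each (treatment, sex)
#' stratum; empty strata are absent from the output, never reported as 0/0.
#'
#' @param classified A classified cohort (see [classify_cohort()]).
#' @param status Which status to tabulate: `"migration"`, `"maturation"` or
#'   `"phenotype"`.
#' @param by Stratifying columns (default treatment and sex).
#' @return A tibble with the strata, `status`, `n` and `prop`.
#' @export
summarize_calls <- function(classified,
                            status = c("migration", "maturation", "phenotype"),
                            by = c("treatment", "sex")) {
  status <- match.arg(status)
  col <- switch(status, migration = "migration_status",
                maturation = "maturation_status",
                phenotype = "phenotype_class")
  classified %>%
    group_by(across(dplyr::all_of(by))) %>%
    count(status = .data[[col]]) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
}
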