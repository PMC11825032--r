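# Reading, validating and transforming per-fish cohort tables.
#
# The on-disk convention is a UTF-8 comma-separated file with one header
# row, "." as decimal mark and empty cells for missing values.

cohort_columns <- function() {
  c(
    fish_id = "c", release_year = "i", treatment = "c", sex = "c",
    fork_length_mm = "d", body_weight_g = "d", gill_atpase = "d",
    smolt_phenotype = "c", milt_expressed = "l", gonad_weight_g = "d",
    fshb = "d", lhb = "d", amh = "d", igf3 = "d", kt11 = "d", gsi_pct = "d"
  )
}

# internal (analysis) names for the measured columns
cohort_rename <- function() {
  c(fork_length = "fork_length_mm", body_weight = "body_weight_g",
    gonad_weight = "gonad_weight_g", gsi = "gsi_pct")
}

#' Read and validate a per-fish cohort table
#'
#' Reads a CSV cohort file (columns `fish_id`, `release_year`, `treatment`,
#' `sex`, `fork_length_mm`, `body_weight_g`, `gill_atpase`,
#' `smolt_phenotype`, `milt_expressed`, `gonad_weight_g`, `fshb`, `lhb`,
#' `amh`, `igf3`, `kt11`, `gsi_pct`) and validates it.  Empty cells are
#' missing values and are preserved as `NA`, never coerced to zero.
#'
#' If `gsi_pct` is absent (or entirely missing) it is derived as
#' `100 * gonad_weight_g / body_weight_g`.  If both a `gsi_pct` value and
#' the two weights are present they must agree to within `1e-6` relative,
#' otherwise validation fails: the gonad and body weights are the single
#' source of truth.
#'
#' @param path Path to a CSV file.
#' @param derive_gsi Derive missing GSI values from the weights?
#' @return A validated cohort tibble (internal column names `fork_length`,
#'   `body_weight`, `gonad_weight`, `gsi`), with attribute `provenance` set
#'   to the source path.
#' @seealso [write_cohort()], [validate_cohort()], [generate_cohort()]
#' @export
read_cohort <- function(path, derive_gsi = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Cohort file not found: %s", path))
  }
  cols <- cohort_columns()
  header <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  missing_cols <- setdiff(setdiff(names(cols), "gsi_pct"), header)
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  spec <- do.call(readr::cols_only, as.list(
    stats::setNames(cols[names(cols) %in% header], names(cols)[names(cols) %in% header])
  ))
  df <- readr::read_csv(path, col_types = spec, na = "",
                        locale = readr::locale(decimal_mark = "."),
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    rlang::abort(paste0(
      "Unparseable cells:\n",
      paste(sprintf("  row %d, column %s: expected %s, got '%s'",
                    probs$row, probs$col, probs$expected, probs$actual),
            collapse = "\n")
    ))
  }
  if (!"gsi_pct" %in% header) df$gsi_pct <- NA_real_
  ren <- cohort_rename()
  names(df)[match(ren, names(df))] <- names(ren)
  cohort <- validate_cohort(df, derive_gsi = derive_gsi)
  attr(cohort, "provenance") <- path
  cohort
}

#' Validate a cohort table
#'
#' Checks the hard invariants of a cohort table and aborts with row-indexed
#' diagnostics when any is violated: unique `fish_id`; `treatment` in
#' S1/S2; `sex` in male/female; positive fork length and body weight;
#' `smolt_phenotype` in parr/transitional/smolt; females never
#' milt-expressing and never carrying gonad-marker fields (`gonad_weight`,
#' `gsi`, `fshb`, `lhb`, `amh`, `igf3`, `kt11`); all present marker values
#' finite and positive where required; GSI consistent with the weights.
#'
#' @param df A data frame using the internal column names (as returned by
#'   [read_cohort()] or [generate_cohort()]).
#' @param derive_gsi Derive missing GSI from gonad and body weight?
#' @return The validated tibble, invisibly classed as before.
#' @export
validate_cohort <- function(df, derive_gsi = TRUE) {
  df <- as_tibble(df)
  errs <- character(0)
  bad_rows <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      sprintf("%s (rows %s)", what,
              paste(head(which(idx), 10), collapse = ", "))
    } else character(0)
  }

  if (anyDuplicated(df$fish_id)) {
    dup <- unique(df$fish_id[duplicated(df$fish_id)])
    errs <- c(errs, sprintf("Duplicate fish_id: %s",
                            paste(head(dup, 5), collapse = ", ")))
  }
  errs <- c(errs, bad_rows(!df$treatment %in% c("S1", "S2"),
                           "treatment must be 'S1' or 'S2'"))
  errs <- c(errs, bad_rows(!df$sex %in% c("male", "female"),
                           "sex must be 'male' or 'female'"))
  errs <- c(errs, bad_rows(
    !df$smolt_phenotype %in% c("parr", "transitional", "smolt"),
    "smolt_phenotype must be parr/transitional/smolt"
  ))
  errs <- c(errs, bad_rows(is.na(df$fork_length) | df$fork_length <= 0,
                           "fork_length must be present and > 0"))
  errs <- c(errs, bad_rows(is.na(df$body_weight) | df$body_weight <= 0,
                           "body_weight must be present and > 0"))
  errs <- c(errs, bad_rows(is.na(df$milt_expressed),
                           "milt_expressed must be present"))

  fem <- df$sex == "female"
  errs <- c(errs, bad_rows(fem & df$milt_expressed,
                           "females cannot be milt-expressing"))
  gonad_cols <- c("gonad_weight", "gsi", "fshb", "lhb", "amh", "igf3", "kt11")
  for (col in gonad_cols) {
    errs <- c(errs, bad_rows(
      fem & !is.na(df[[col]]),
      sprintf("females cannot carry gonad-marker field '%s'", col)
    ))
  }
  for (col in c(gonad_cols, "gill_atpase")) {
    errs <- c(errs, bad_rows(!is.na(df[[col]]) & !is.finite(df[[col]]),
                             sprintf("non-finite value in '%s'", col)))
  }

  # GSI: derive from weights where absent; cross-check where both present
  gsi_calc <- 100 * df$gonad_weight / df$body_weight
  both <- !is.na(df$gsi) & !is.na(gsi_calc)
  mism <- both & abs(df$gsi - gsi_calc) > 1e-6 * pmax(abs(gsi_calc), 1e-12)
  errs <- c(errs, bad_rows(
    mism, "gsi_pct disagrees with 100 * gonad_weight_g / body_weight_g"
  ))
  if (length(errs)) {
    rlang::abort(paste0("Cohort validation failed:\n",
                        paste("-", errs, collapse = "\n")))
  }
  if (derive_gsi) {
    df$gsi <- ifelse(is.na(df$gsi), gsi_calc, df$gsi)
  }
  df
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes the on-disk column names with empty
#' cells for missing values.  Numeric fields round-trip exactly at the
#' precision they carry.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  ren <- cohort_rename()
  out <- cohort[, names(cohort) %in% c(names(cohort_columns()), names(ren))]
  names(out)[match(names(ren), names(out))] <- ren
  out <- out[, intersect(names(cohort_columns()), names(out))]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Log10-transform maturation markers
#'
#' Applies the log10 transformation used before all mixture fitting to the
#' selected maturation markers.  Only strictly positive, non-missing values
#' are usable; the rest are excluded and counted.  Fork length is never
#' transformed (it is fitted, and its thresholds reported, on the raw mm
#' scale).
#'
#' @param cohort A cohort tibble.
#' @param markers Markers to transform; a subset of [maturation_markers()].
#' @return A tibble with columns `fish_id`, `treatment`, `sex`, `marker`,
#'   `value` (log10 scale), one row per usable (fish, marker) value.  The
#'   attribute `"exclusions"` is a tibble counting excluded non-positive
#'   values per (treatment, marker); missing values are not exclusions.
#' @examples
#' cohort <- generate_cohort(seed = 1)$cohort
#' lv <- log10_markers(cohort, c("gsi", "kt11"))
#' attr(lv, "exclusions")
#' @export
log10_markers <- function(cohort, markers = maturation_markers()) {
  bad <- setdiff(markers, maturation_markers())
  if (length(bad)) {
    rlang::abort(paste0(
      "Unknown marker name(s): ", paste(bad, collapse = ", "),
      ". Markers must be among: ", paste(maturation_markers(), collapse = ", ")
    ))
  }
  if (length(markers) == 0L) {
    out <- tibble(fish_id = character(), treatment = character(),
                  sex = character(), marker = character(), value = numeric())
    attr(out, "exclusions") <- tibble(treatment = character(),
                                      marker = character(),
                                      n_excluded = integer())
    return(out)
  }
  long <- cohort %>%
    select(dplyr::all_of(c("fish_id", "treatment", "sex", markers))) %>%
    tidyr::pivot_longer(dplyr::all_of(markers), names_to = "marker",
                        values_to = "raw") %>%
    filter(!is.na(.data$raw))
  excl <- long %>%
    filter(.data$raw <= 0) %>%
    count(.data$treatment, .data$marker, name = "n_excluded")
  out <- long %>%
    filter(.data$raw > 0) %>%
    mutate(value = log10(.data$raw)) %>%
    select(-"raw")
  attr(out, "exclusions") <- excl
  out
}
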