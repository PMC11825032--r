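# Maturation gating and migration rules.

test_that("compute_gsi follows the percentage formula", {
  expect_equal(compute_gsi(0.05, 50), 0.1)
  expect_equal(compute_gsi(50, 50), 100)
  expect_equal(compute_gsi(0.627, 100), 0.627)
  expect_error(compute_gsi(0, 50), "positive")
  expect_error(compute_gsi(0.1, -2), "positive")
})

test_that("milt expression forces mature status regardless of markers", {
  thr <- toy_thresholds()
  # all markers missing
  m <- classify_maturation(one_male(milt = TRUE), thr)
  expect_identical(m$maturation_status, "mature")
  # all markers below their gates
  m2 <- classify_maturation(
    one_male(milt = TRUE, fshb = 10, lhb = 10, amh = 10, igf3 = 1,
             gsi = 0.01, kt11 = 0.1), thr)
  expect_identical(m2$maturation_status, "mature")
})

test_that("amh below its threshold gates as maturing (inverted orientation)", {
  thr <- toy_thresholds()
  # amh 1.0 < 2.7 while every other marker is below its standard gate
  rec <- one_male(fshb = 100, lhb = 50, amh = 1.0, igf3 = 3, gsi = 0.03,
                  kt11 = 0.5)
  m <- classify_maturation(rec, thr)
  expect_identical(m$maturation_status, "maturing")
  expect_identical(m$ev_amh, "below")
  # amh above its threshold does not gate
  rec2 <- one_male(fshb = 100, lhb = 50, amh = 8, igf3 = 3, gsi = 0.03,
                   kt11 = 0.5)
  expect_identical(classify_maturation(rec2, thr)$maturation_status,
                   "immature")
})

test_that("a male with only unusable markers is unknown", {
  thr <- toy_thresholds()
  thr$usable[thr$metric %in% c("fshb", "amh") & thr$treatment == "S1"] <- FALSE
  thr$threshold1[thr$metric %in% c("fshb", "amh") & thr$treatment == "S1"] <- NA
  rec <- one_male(treatment = "S1", fshb = 1e6, amh = 1e-6)
  m <- classify_maturation(rec, thr)
  expect_identical(m$maturation_status, "unknown")
  expect_identical(m$n_markers_used, 0L)
  expect_identical(m$ev_fshb, "unusable")
})

test_that("boundary-equal values are not gated", {
  thr <- toy_thresholds()
  rec <- one_male(gsi = 0.056)          # exactly at threshold1
  expect_identical(classify_maturation(rec, thr)$maturation_status,
                   "immature")
  rec2 <- one_male(amh = 2.7)           # exactly at the inverted threshold
  expect_identical(classify_maturation(rec2, thr)$maturation_status,
                   "immature")
})

test_that("the gating truth table matches an independent oracle", {
  thr <- toy_thresholds()
  thr$usable[thr$treatment == "S1" & thr$metric %in% c("fshb", "amh")] <- FALSE
  thr$threshold1[thr$treatment == "S1" &
                   thr$metric %in% c("fshb", "amh")] <- NA

  # marker states: below gate, above gate, missing (igf3 standard, amh
  # inverted, fshb standard); crossed with milt and treatment
  state_value <- function(state, marker) {
    t1 <- c(fshb = 270, amh = 2.7, igf3 = 6.2)[[marker]]
    inverted <- marker == "amh"
    switch(state,
      gated = if (inverted) t1 / 2 else t1 * 2,
      ungated = if (inverted) t1 * 2 else t1 / 2,
      missing = NA_real_
    )
  }
  states <- c("gated", "ungated", "missing")
  grid <- expand.grid(fshb = states, amh = states, igf3 = states,
                      milt = c(FALSE, TRUE), treatment = c("S1", "S2"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- one_male(treatment = g$treatment, milt = g$milt,
                    fshb = state_value(g$fshb, "fshb"),
                    amh = state_value(g$amh, "amh"),
                    igf3 = state_value(g$igf3, "igf3"))
    got <- classify_maturation(rec, thr)$maturation_status

    # oracle: written directly from the stated rule
    usable <- c(fshb = g$treatment == "S2", amh = g$treatment == "S2",
                igf3 = TRUE)
    st <- c(fshb = g$fshb, amh = g$amh, igf3 = g$igf3)
    evaluated <- usable & st != "missing"
    want <- if (g$milt) "mature"
    else if (any(evaluated & st == "gated")) "maturing"
    else if (any(evaluated)) "immature"
    else "unknown"
    expect_identical(got, want,
                     label = paste(g$treatment, g$fshb, g$amh, g$igf3,
                                   "milt:", g$milt))
  }
})

test_that("migration follows the sex-specific rules", {
  thr <- toy_thresholds()
  coh <- dplyr::bind_rows(
    one_male(fork_length = 140),                          # small immature
    one_male(fork_length = 200) |>
      dplyr::mutate(fish_id = "M2", lhb = 500),           # large maturing
    one_male(fork_length = 200) |> dplyr::mutate(fish_id = "M3"),
    tibble::tibble(fish_id = c("W1", "W2"), release_year = 2011L,
                   treatment = "S2", sex = "female",
                   fork_length = c(140, 200), body_weight = 40,
                   gill_atpase = NA_real_, smolt_phenotype = "smolt",
                   milt_expressed = FALSE, gonad_weight = NA_real_,
                   fshb = NA_real_, lhb = NA_real_, amh = NA_real_,
                   igf3 = NA_real_, kt11 = NA_real_, gsi = NA_real_)
  )
  coh$lhb[coh$fish_id == "M3"] <- 50  # evaluated, below gate: immature
  cl <- classify_cohort(coh, thr)
  get <- function(id, col) cl[[col]][cl$fish_id == id]
  expect_identical(get("W1", "migration_status"), "residual") # 140 < 146.6
  expect_identical(get("W2", "migration_status"), "migrant")
  expect_identical(get("M1", "migration_status"), "residual") # small male
  expect_identical(get("M1", "basis"), "length_only")
  expect_identical(get("M2", "migration_status"), "residual") # big but maturing
  expect_identical(get("M2", "basis"), "maturation_only")
  expect_identical(get("M3", "migration_status"), "migrant")  # big immature
  expect_true(is.na(get("M3", "basis")))

  # under the "and" rule a large maturing male migrates
  cl_and <- classify_cohort(coh, thr, male_residual_rule = "and")
  expect_identical(cl_and$migration_status[cl_and$fish_id == "M2"],
                   "migrant")
})

test_that("unknown males are treated as immature for migration, flagged", {
  thr <- toy_thresholds()
  thr$usable[thr$treatment == "S1"] <- FALSE
  thr$threshold1[thr$treatment == "S1" & thr$metric != "fork_length"] <- NA
  thr$usable[thr$treatment == "S1" & thr$metric == "fork_length"] <- TRUE
  rec <- one_male(treatment = "S1", fork_length = 200)
  cl <- classify_cohort(rec, thr)
  expect_identical(cl$maturation_status, "unknown")
  expect_identical(cl$migration_status, "migrant")
  expect_true(cl$maturation_unknown)
})

test_that("increasing fork length never turns a migrant into a residual", {
  thr <- toy_thresholds()
  set.seed(4)
  for (i in 1:40) {
    fl <- runif(1, 80, 250)
    lhb <- sample(c(NA, 10, 500), 1)
    rec <- one_male(fork_length = fl, lhb = lhb)
    rec2 <- rec |> dplyr::mutate(fork_length = fl + runif(1, 1, 60))
    s1 <- classify_cohort(rec, thr)$migration_status
    s2 <- classify_cohort(rec2, thr)$migration_status
    expect_false(s1 == "migrant" && s2 == "residual")
  }
})

test_that("gating one additional marker never demotes maturing to immature", {
  thr <- toy_thresholds()
  set.seed(6)
  for (i in 1:30) {
    base <- one_male(lhb = sample(c(NA, 10, 500), 1),
                     gsi = sample(c(NA, 0.01, 0.5), 1))
    more <- base |> dplyr::mutate(kt11 = 5)  # above its gate
    s1 <- classify_maturation(base, thr)$maturation_status
    s2 <- classify_maturation(more, thr)$maturation_status
    if (s1 == "maturing") expect_identical(s2, "maturing")
    if (s1 %in% c("immature", "unknown")) {
      expect_identical(s2, "maturing")
    }
  }
})

test_that("summaries match an independent per-record tally", {
  lc <- generate_cohort(default_cohort_config(c(S1 = 400, S2 = 400)),
                        seed = 17)
  cl <- classify_cohort(lc$cohort, lc$thresholds)
  sm <- summarize_calls(cl, "migration")
  # brute-force oracle
  for (i in seq_len(nrow(sm))) {
    rows <- cl[cl$treatment == sm$treatment[i] & cl$sex == sm$sex[i], ]
    expect_equal(sm$n[i],
                 sum(rows$migration_status == sm$status[i]))
    expect_equal(sm$prop[i],
                 mean(rows$migration_status == sm$status[i]))
  }
  # proportions sum to one per stratum
  tot <- sm |> dplyr::group_by(treatment, sex) |>
    dplyr::summarise(p = sum(prop), .groups = "drop")
  expect_equal(tot$p, rep(1, nrow(tot)), tolerance = 1e-12)
})

test_that("degenerate summaries: all migrants, and absent strata", {
  thr <- toy_thresholds()
  coh <- tibble::tibble(
    fish_id = sprintf("W%d", 1:10), release_year = 2011L, treatment = "S2",
    sex = "female", fork_length = 200 + 1:10, body_weight = 80,
    gill_atpase = NA_real_, smolt_phenotype = "smolt",
    milt_expressed = FALSE, gonad_weight = NA_real_, fshb = NA_real_,
    lhb = NA_real_, amh = NA_real_, igf3 = NA_real_, kt11 = NA_real_,
    gsi = NA_real_
  )
  cl <- classify_cohort(coh, thr)
  sm <- summarize_calls(cl, "migration")
  expect_identical(unique(sm$status), "migrant")
  expect_equal(sm$prop, 1)
  # no male stratum appears (absent, not 0/0)
  expect_false("male" %in% sm$sex)
})

test_that("classification with generating thresholds equals ground truth", {
  lc <- generate_cohort(default_cohort_config(c(S1 = 600, S2 = 600)),
                        seed = 23)
  cl <- classify_cohort(lc$cohort, lc$thresholds)
  expect_identical(cl$migration_status,
                   lc$truth$true_migration[match(cl$fish_id,
                                                 lc$truth$fish_id)])
})
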