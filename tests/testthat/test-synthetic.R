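# The synthetic cohort generator.

small_cfg <- function(n = 600) default_cohort_config(c(S1 = n, S2 = n))

test_that("generation is byte-identical for the same config and seed", {
  lc1 <- generate_cohort(small_cfg(), seed = 8)
  lc2 <- generate_cohort(small_cfg(), seed = 8)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(lc1$cohort, p1)
  write_cohort(lc2$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(lc1$truth, lc2$truth)
  # a different seed gives different values
  lc3 <- generate_cohort(small_cfg(), seed = 9)
  expect_false(identical(lc1$cohort$fork_length, lc3$cohort$fork_length))
})

test_that("treatment counts and structural missingness match the design", {
  lc <- generate_cohort(small_cfg(500), seed = 3)
  coh <- lc$cohort
  expect_equal(sum(coh$treatment == "S1"), 500)
  expect_equal(sum(coh$treatment == "S2"), 500)
  # testis markers only in the first two release years
  late <- coh$release_year >= 2013
  expect_true(all(is.na(coh$amh[late])))
  expect_true(all(is.na(coh$igf3[late])))
  early_males <- coh$release_year <= 2012 & coh$sex == "male" &
    !coh$milt_expressed
  expect_true(mean(!is.na(coh$amh[early_males])) > 0.95)
  # no gill samples in the first year, about a third afterwards
  expect_true(all(is.na(coh$gill_atpase[coh$release_year == 2011])))
  frac <- mean(!is.na(coh$gill_atpase[coh$release_year > 2011]))
  expect_gt(frac, 0.2); expect_lt(frac, 0.5)
  # mature males keep no testis mRNA and lose GSI in the last two years
  mm <- coh$milt_expressed
  expect_true(all(is.na(coh$amh[mm])))
  expect_true(all(is.na(coh$igf3[mm])))
  expect_true(all(is.na(coh$gsi[mm & coh$release_year >= 2014])))
})

test_that("milt fraction and component occupancy match the configuration", {
  cfg <- default_cohort_config()          # 1500 per treatment
  lc <- generate_cohort(cfg, seed = 21)
  coh <- lc$cohort

  # empirical S2 milt fraction within 3 binomial SE of the configured rate
  s2m <- coh$sex == "male" & coh$treatment == "S2"
  p <- cfg$status_rates$S2$mature
  se <- sqrt(p * (1 - p) / sum(s2m))
  expect_lt(abs(mean(coh$milt_expressed[s2m]) - p), 3 * se)

  # fork-length component occupancy vs configured weights
  for (trt in c("S1", "S2")) {
    w <- cfg$markers[[trt]]$fork_length$weight
    comp <- lc$truth$comp_fork_length[lc$truth$treatment == trt]
    n <- length(comp)
    for (j in seq_along(w)) {
      se <- sqrt(w[j] * (1 - w[j]) / n)
      expect_lt(abs(mean(comp == j) - w[j]), 3 * se + 0.01,
                label = paste(trt, "component", j))
    }
  }
})

test_that("generating thresholds equal an independent intersection oracle", {
  cfg <- small_cfg()
  thr <- generating_thresholds(cfg)
  for (trt in c("S1", "S2")) {
    for (mk in c("fork_length", "lhb", "gsi")) {
      spec <- cfg$markers[[trt]][[mk]]
      if (length(spec$mean) < 2) next
      row <- thr[thr$treatment == trt & thr$metric == mk, ]
      want <- uniroot_intersection(spec$weight[1], spec$mean[1], spec$sd[1],
                                   spec$weight[2], spec$mean[2], spec$sd[2])
      expect_equal(row$threshold1_fit, want, tolerance = 1e-9,
                   label = paste(trt, mk))
      # thresholds sit strictly between the adjacent generating means
      expect_gt(row$threshold1_fit, spec$mean[1])
      expect_lt(row$threshold1_fit, spec$mean[2])
    }
  }
})

test_that("default config intersections sit at the documented values", {
  thr <- generating_thresholds(default_cohort_config())
  g <- function(trt, mk, col = "threshold1") {
    thr[[col]][thr$treatment == trt & thr$metric == mk]
  }
  expect_equal(g("S1", "fork_length"), 146.6, tolerance = 2 / 146.6)
  expect_equal(g("S2", "fork_length"), 147.6, tolerance = 2 / 147.6)
  expect_equal(g("S1", "igf3"), 6.2, tolerance = 0.5 / 6.2)
  expect_equal(g("S2", "igf3"), 6.2, tolerance = 0.5 / 6.2)
  expect_equal(g("S1", "gsi"), 0.051, tolerance = 1e-6)
  expect_equal(g("S1", "gsi", "threshold2"), 0.627, tolerance = 1e-6)
  expect_equal(g("S2", "amh"), 2.7, tolerance = 1e-6)
  # unimodal S1 fshb and amh: no threshold at all
  expect_false(thr$usable[thr$treatment == "S1" & thr$metric == "fshb"])
  expect_false(thr$usable[thr$treatment == "S1" & thr$metric == "amh"])
})

test_that("missingness masks never alter retained values", {
  cfg <- small_cfg()
  cfg$extra_missingness <- list(lhb = 0.3, kt11 = 0.2)
  with_miss <- generate_cohort(cfg, seed = 12)$cohort
  cfg2 <- cfg
  cfg2$apply_missingness <- FALSE
  without <- generate_cohort(cfg2, seed = 12)$cohort
  for (mk in c("lhb", "kt11", "fshb")) {
    kept <- !is.na(with_miss[[mk]])
    expect_identical(with_miss[[mk]][kept], without[[mk]][kept], label = mk)
  }
  for (mk in c("lhb", "kt11")) {
    expect_gt(sum(is.na(with_miss[[mk]])), sum(is.na(without[[mk]])))
  }
})

test_that("a degenerate config yields all-immature males, length-only truth", {
  cfg <- small_cfg(300)
  for (trt in c("S1", "S2")) {
    cfg$status_rates[[trt]]$mature <- 0
    cfg$status_rates[[trt]]$maturing <- 0
    # all marker mass in a single bottom component: unimodal, no gates
    for (mk in maturation_markers()) {
      spec <- cfg$markers[[trt]][[mk]]
      cfg$markers[[trt]][[mk]] <- marker_spec(
        mk, spec$scale, 1, spec$mean[1], spec$sd[1],
        orientation = spec$orientation
      )
    }
  }
  lc <- generate_cohort(cfg, seed = 2)
  expect_true(all(lc$truth$true_status == "immature"))
  expect_false(any(lc$cohort$milt_expressed))
  # migration truth must then be pure fork-length thresholding
  thr <- lc$thresholds
  fl <- thr$threshold1[match(paste(lc$cohort$treatment, "fork_length"),
                             paste(thr$treatment, thr$metric))]
  want <- ifelse(lc$cohort$fork_length < fl, "residual", "migrant")
  expect_identical(lc$truth$true_migration, want)
})

test_that("more than three components is rejected", {
  expect_error(
    marker_spec("gsi", "log10", rep(0.25, 4), 1:4, rep(0.1, 4)),
    "3 components"
  )
})

test_that("truth_summary matches a brute-force tally with absent strata", {
  cfg <- small_cfg(200)
  cfg$sex_ratio <- 0  # all female
  lc <- generate_cohort(cfg, seed = 30)
  ts <- truth_summary(lc)
  expect_false("male" %in% ts$sex)
  tot <- ts |> dplyr::group_by(treatment, sex, kind) |>
    dplyr::summarise(p = sum(prop), .groups = "drop")
  expect_equal(tot$p, rep(1, nrow(tot)), tolerance = 1e-12)
  # independent tally
  row <- ts[ts$treatment == "S1" & ts$kind == "migration" &
              ts$status == "residual", ]
  want <- sum(lc$truth$true_migration == "residual" &
                lc$truth$treatment == "S1")
  if (nrow(row)) expect_equal(row$n, want)
})

test_that("a config survives a YAML round trip", {
  cfg <- small_cfg(100)
  path <- withr::local_tempfile(fileext = ".yml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n_per_treatment, cfg$n_per_treatment)
  expect_equal(back$markers$S2$gsi$mean, cfg$markers$S2$gsi$mean)
  expect_equal(back$markers$S2$amh$orientation, "inverted")
  lc1 <- generate_cohort(cfg, seed = 4)
  lc2 <- generate_cohort(back, seed = 4)
  expect_identical(lc1$cohort, lc2$cohort)
})
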