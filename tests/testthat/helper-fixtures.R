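# Small in-code fixtures shared across tests.

# a hand-built, fully valid six-fish cohort covering both treatments,
# both sexes, missing optional markers, and a milt-expressing male
toy_cohort <- function() {
  tibble::tibble(
    fish_id = sprintf("F%02d", 1:6),
    release_year = c(2011L, 2011L, 2012L, 2012L, 2013L, 2013L),
    treatment = c("S1", "S1", "S1", "S2", "S2", "S2"),
    sex = c("male", "female", "male", "male", "female", "male"),
    fork_length = c(150, 140, 172, 210, 190, 131),
    body_weight = c(35.2, 28.1, 52.7, 95.3, 70.4, 22.9),
    gill_atpase = c(4.1, NA, 6.2, 5.5, NA, 3.3),
    smolt_phenotype = c("transitional", "parr", "smolt", "smolt",
                        "transitional", "parr"),
    milt_expressed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    gonad_weight = c(0.007, NA, 0.012, 2.51, NA, 0.005),
    fshb = c(55.2, NA, 81.5, 5120, NA, 44.1),
    lhb = c(21.7, NA, 260.2, 60310, NA, 18.8),
    amh = c(3.42, NA, 4.1, NA, NA, 1.05),
    igf3 = c(2.8, NA, 9.4, NA, NA, 2.2),
    kt11 = c(0.41, NA, 2.75, 38.2, NA, 0.3),
    gsi = 100 * c(0.007, NA, 0.012, 2.51, NA, 0.005) /
      c(35.2, 28.1, 52.7, 95.3, 70.4, 22.9)
  )
}

# a hand-built threshold table on the measurement scale (S2-like: every
# marker usable except where stated)
toy_thresholds <- function(treatments = c("S1", "S2")) {
  purrr::map_dfr(treatments, function(trt) {
    tibble::tibble(
      treatment = trt,
      metric = c("fork_length", "fshb", "lhb", "amh", "igf3", "gsi", "kt11"),
      best_k = c(2L, 2L, 2L, 2L, 3L, 3L, 3L),
      usable = TRUE,
      threshold1 = c(146.6, 270, 94.9, 2.7, 6.2, 0.056, 0.97),
      threshold2 = c(NA, NA, 11306.5, NA, 16.6, 0.962, 15.81),
      orientation = c("standard", "standard", "standard", "inverted",
                      "standard", "standard", "standard"),
      fallback = FALSE
    )
  })
}

# a single-male cohort with chosen marker values (NA = missing)
one_male <- function(treatment = "S2", fork_length = 180, milt = FALSE,
                     fshb = NA, lhb = NA, amh = NA, igf3 = NA, gsi = NA,
                     kt11 = NA) {
  gw <- if (is.na(gsi)) NA_real_ else gsi * 50 / 100
  tibble::tibble(
    fish_id = "M1", release_year = 2011L, treatment = treatment,
    sex = "male", fork_length = fork_length, body_weight = 50,
    gill_atpase = NA_real_, smolt_phenotype = "transitional",
    milt_expressed = milt, gonad_weight = gw, fshb = fshb, lhb = lhb,
    amh = amh, igf3 = igf3, kt11 = kt11, gsi = gsi
  )
}

# brute-force mixture log-likelihood, independent of the fitting code
brute_loglik <- function(x, weight, mean, sd) {
  sum(log(vapply(x, function(xi) {
    sum(weight * stats::dnorm(xi, mean, sd))
  }, numeric(1))))
}

# independent intersection oracle: sign-change bracket + uniroot on the
# weighted log-density difference
uniroot_intersection <- function(w1, m1, s1, w2, m2, s2) {
  f <- function(x) {
    log(w1) + stats::dnorm(x, m1, s1, log = TRUE) -
      log(w2) - stats::dnorm(x, m2, s2, log = TRUE)
  }
  stats::uniroot(f, c(m1, m2), tol = 1e-12)$root
}
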