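# Synthetic cohort generator: per-treatment Gaussian mixtures on the
# analysis scale with known component parameters and known ground-truth
# labels, so that every downstream stage can be tested for recovery.

#' Component specification for one metric
#'
#' @param marker Metric name (`fork_length` or a maturation marker).
#' @param scale `"raw"` (fork length, mm) or `"log10"` (markers).
#' @param weight,mean,sd Component parameters on the `scale`; one to three
#'   components, ordered by ascending mean, weights summing to one.
#' @param orientation `"standard"`, or `"inverted"` (only for `amh`).
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(marker, scale = c("log10", "raw"), weight, mean, sd,
                        orientation = c("standard", "inverted")) {
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  k <- length(mean)
  if (k < 1 || k > 3) {
    rlang::abort("Marker specs support 1 to 3 components only.")
  }
  if (abs(sum(weight) - 1) > 1e-12) {
    rlang::abort(sprintf("Weights for '%s' must sum to 1 (got %.15f).",
                         marker, sum(weight)))
  }
  if (any(sd <= 0)) rlang::abort("Component sds must be positive.")
  if (is.unsorted(mean, strictly = TRUE)) {
    rlang::abort("Component means must be strictly increasing.")
  }
  if (orientation == "inverted" && marker != "amh") {
    rlang::abort("Only 'amh' may use the inverted orientation.")
  }
  structure(list(marker = marker, scale = scale, weight = as.numeric(weight),
                 mean = as.numeric(mean), sd = as.numeric(sd),
                 orientation = orientation),
            class = "marker_spec")
}

#' Default synthetic-cohort configuration
#'
#' A fully populated configuration emulating the sampling-day structure of
#' a paired two-treatment hatchery programme: five release years, roughly
#' equal sex ratio, treatment-specific mixtures for fork length (bimodal,
#' raw mm) and the six maturation markers (log10 scale; unimodal S1 `fshb`
#' and `amh`, bimodal S2 `fshb` and inverted `amh`, bimodal S1 / trimodal
#' S2 `lhb`, trimodal `igf3`, GSI and 11KT), rare milt-expressing males
#' under S1 versus about 9% of S2 males, and structural missingness (gill
#' ATPase on a subsample in four of five years; testis mRNA in two years
#' only; mature-male gonad weights absent in the last two years).
#'
#' Component means were solved analytically so that the intersections of
#' adjacent weighted component densities sit exactly at the intended
#' thresholds (146.6 / 147.6 mm fork length; GSI 0.051 / 0.627 and
#' 0.056 / 0.962 %; 11KT 0.88 / 23.08 and 0.97 / 15.81 ng/ml; `lhb` 44.7
#' and 94.9 / 11306.5; S2 `fshb` 270; S2 `amh` 2.7 inverted; `igf3` 6.2 in
#' both treatments).  Weights are tied to the status mix: a quarter of
#' males maturing in both treatments, mature-male rates 3/1496 (S1) and
#' 133/1497 (S2).
#'
#' @param n_per_treatment Named counts of fish per treatment.
#' @return A `cohort_config` list; see [generate_cohort()].
#' @export
default_cohort_config <- function(n_per_treatment = c(S1 = 1500, S2 = 1500)) {
  p_mat_s1 <- 3 / 1496
  p_mat_s2 <- 133 / 1497
  p_ming <- 0.25
  # measured-male component weights implied by the status mix; testis
  # markers exclude mature males (not measurable in spermiating males)
  w3 <- function(p_mat) c(1 - p_ming - p_mat, p_ming, p_mat)
  w_igf <- function(p_mat) {
    c(1 - p_ming - p_mat, p_ming * 0.65, p_ming * 0.35) / (1 - p_mat)
  }

  s1 <- list(
    fork_length = marker_spec("fork_length", "raw", c(0.20, 0.80),
                              c(128.35419961797436, 186), c(13, 20)),
    fshb = marker_spec("fshb", "log10", 1, 1.8, 0.35),
    lhb = marker_spec("lhb", "log10", c(1 - p_ming - p_mat_s1, p_ming + p_mat_s1),
                      c(1, 2.208537914191508), c(0.30, 0.40)),
    amh = marker_spec("amh", "log10", 1, 0.55, 0.30,
                      orientation = "inverted"),
    igf3 = marker_spec("igf3", "log10", w_igf(p_mat_s1),
                       c(0.40075806473460202, 0.95, 1.3833517031642579),
                       c(0.18, 0.09, 0.10)),
    gsi = marker_spec("gsi", "log10", w3(p_mat_s1),
                      c(-1.750612091679304, -0.92, 0.0086933166637285786),
                      c(0.20, 0.22, 0.18)),
    kt11 = marker_spec("kt11", "log10", w3(p_mat_s1),
                       c(-0.61837393904912652, 0.42, 1.556698102541562),
                       c(0.25, 0.30, 0.25))
  )
  s2 <- list(
    fork_length = marker_spec("fork_length", "raw", c(0.04, 0.96),
                              c(131.98378488934361, 208), c(11, 23)),
    fshb = marker_spec("fshb", "log10",
                       c(1 - p_ming - p_mat_s2, p_ming + p_mat_s2),
                       c(1.75, 3.1267463279471217), c(0.30, 0.38)),
    lhb = marker_spec("lhb", "log10", w3(p_mat_s2),
                      c(1.1371641041335776, 2.9, 4.8367677920615684),
                      c(0.30, 0.40, 0.30)),
    amh = marker_spec("amh", "log10",
                      c(p_ming, 1 - p_ming - p_mat_s2) / (1 - p_mat_s2),
                      c(-0.039914623517513848, 0.95), c(0.22, 0.20),
                      orientation = "inverted"),
    igf3 = marker_spec("igf3", "log10", w_igf(p_mat_s2),
                       c(0.41110419728083125, 0.95, 1.4950336754915985),
                       c(0.18, 0.09, 0.10)),
    gsi = marker_spec("gsi", "log10", w3(p_mat_s2),
                      c(-1.8170108337592497, -0.68, 0.51027184344436372),
                      c(0.20, 0.24, 0.22)),
    kt11 = marker_spec("kt11", "log10", w3(p_mat_s2),
                       c(-0.61709259515944093, 0.55, 1.6301019276776907),
                       c(0.25, 0.30, 0.25))
  )

  config <- list(
    n_per_treatment = n_per_treatment,
    years = 2011:2015,
    sex_ratio = 0.5,
    status_rates = list(
      S1 = list(maturing = p_ming, mature = p_mat_s1),
      S2 = list(maturing = p_ming, mature = p_mat_s2)
    ),
    igf3_upper_split = 0.35,
    markers = list(S1 = s1, S2 = s2),
    year_effects = list(
      fork_length = c(-4, -2, 0, 2, 4),
      log_marker = c(-0.03, -0.015, 0, 0.015, 0.03)
    ),
    phenotype_probs = list(
      S1 = rbind(c(parr = 0.52, transitional = 0.43, smolt = 0.05),
                 c(parr = 0.030, transitional = 0.600, smolt = 0.370)),
      S2 = rbind(c(parr = 0.45, transitional = 0.50, smolt = 0.05),
                 c(parr = 0.022, transitional = 0.633, smolt = 0.345))
    ),
    condition_factor = c(mean = 1.0, sd = 0.05),
    gill = list(mean = 5, sd = 1.5, years = 2012:2015, sample_rate = 1 / 3),
    testis_years = 2011:2012,
    mature_gsi_missing_years = 2014:2015,
    extra_missingness = list(),
    apply_missingness = TRUE
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
}

#' Validate a synthetic-cohort configuration
#'
#' @param config A `cohort_config` list.
#' @return The config, invisibly classed, or an error.
#' @export
validate_cohort_config <- function(config) {
  if (any(config$n_per_treatment <= 0)) {
    rlang::abort("Per-treatment counts must be positive.")
  }
  rates <- unlist(config$status_rates)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("Status rates must lie in [0, 1].")
  }
  for (trt in names(config$markers)) {
    for (ms in config$markers[[trt]]) {
      if (!inherits(ms, "marker_spec")) {
        rlang::abort("Every marker entry must be a `marker_spec`.")
      }
      if (length(ms$mean) > 3) {
        rlang::abort("The pipeline supports at most 3 components per metric.")
      }
    }
  }
  extra <- unlist(config$extra_missingness)
  if (length(extra) && any(extra < 0 | extra > 1)) {
    rlang::abort("Missingness rates must lie in [0, 1].")
  }
  invisible(config)
}

# seed for a named generation block, stable under adding markers
block_seed <- function(seed, name) {
  metrics <- mixture_metrics()
  registry <- c(
    paste0("structure-", c("S1", "S2")),
    paste0("weight-", c("S1", "S2")),
    paste0("phenotype-", c("S1", "S2")),
    paste0("gill-", c("S1", "S2")),
    paste0("missing-", c("S1", "S2")),
    paste0(rep(c("S1", "S2"), each = length(metrics)), "-",
           rep(metrics, times = 2))
  )
  idx <- match(name, registry)
  if (is.na(idx)) rlang::abort(sprintf("Unknown generation block '%s'.", name))
  (as.integer(seed) %% 1048576L) * 1024L + idx
}

# map a latent status to the component index it draws from
status_component <- function(status, spec, igf3_split_draw = NULL) {
  k <- length(spec$mean)
  if (k == 1L) return(rep(1L, length(status)))
  if (spec$orientation == "inverted") {
    # amh: maturing males sit in the lower mode, immature in the upper
    return(if_else(status == "immature", 2L, 1L))
  }
  if (spec$marker == "igf3") {
    # trimodal igf3: maturing males split between middle and upper modes
    comp <- rep(1L, length(status))
    comp[status == "maturing"] <- if_else(
      igf3_split_draw[status == "maturing"], 3L, 2L
    )
    return(comp)
  }
  if (k == 2L) {
    return(if_else(status == "immature", 1L, 2L))
  }
  c(immature = 1L, maturing = 2L, mature = 3L)[status]
}

#' Generate a labelled synthetic cohort
#'
#' Draws a cohort from the configured per-treatment mixtures with every
#' fish's latent component, true status and true migration call recorded.
#' Generation is fully deterministic given `seed`; each (treatment, metric)
#' uses its own named random stream derived from the master seed, so adding
#' a marker never perturbs the values of another.  Missingness is applied
#' after generation and never alters retained values.
#'
#' Males receive a latent status (immature / maturing / mature) at the
#' configured rates; milt expression marks the mature males, whose marker
#' values are drawn from the top component of trimodal markers (testis
#' mRNA, unmeasurable in spermiating males, is missing for them).  The
#' true migration status is obtained by applying the classification rules
#' with the *generating* thresholds — the analytic intersections of the
#' generating components (see [generating_thresholds()]).
#'
#' @param config A `cohort_config`; defaults to [default_cohort_config()].
#' @param seed Integer master seed.
#' @return A `labeled_cohort`: list with `cohort` (a validated cohort
#'   tibble), `truth` (per-fish latent components, `true_status`,
#'   `true_migration`), `thresholds` (the generating threshold table),
#'   `config` and `seed`.
#' @examples
#' lc <- generate_cohort(seed = 42)
#' truth_summary(lc)
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  years <- config$years
  parts <- lapply(names(config$n_per_treatment), function(trt) {
    n <- config$n_per_treatment[[trt]]
    specs <- config$markers[[trt]]
    rates <- config$status_rates[[trt]]
    year <- sort(rep(years, length.out = n))
    yr_idx <- match(year, years)

    st <- withr::with_seed(block_seed(seed, paste0("structure-", trt)), {
      sex <- if_else(stats::runif(n) < config$sex_ratio, "male", "female")
      u <- stats::runif(n)
      status <- case_when(
        sex == "female" ~ "immature",
        u < rates$mature ~ "mature",
        u < rates$mature + rates$maturing ~ "maturing",
        TRUE ~ "immature"
      )
      fl_spec <- specs$fork_length
      k_fl <- length(fl_spec$mean)
      comp_fl <- sample.int(k_fl, n, replace = TRUE, prob = fl_spec$weight)
      comp_fl[status == "mature"] <- k_fl
      list(sex = sex, status = status, comp_fl = comp_fl)
    })

    fl_shift <- config$year_effects$fork_length[yr_idx]
    fork_length <- withr::with_seed(block_seed(seed, paste0(trt, "-fork_length")), {
      fl_spec <- specs$fork_length
      round(stats::rnorm(n, fl_spec$mean[st$comp_fl] + fl_shift,
                         fl_spec$sd[st$comp_fl]))
    })
    fork_length <- pmax(fork_length, 40)

    body_weight <- withr::with_seed(block_seed(seed, paste0("weight-", trt)), {
      kf <- stats::rnorm(n, config$condition_factor[["mean"]],
                         config$condition_factor[["sd"]])
      round(pmax(kf, 0.7) * fork_length^3 / 1e5, 1)
    })

    phenotype <- withr::with_seed(block_seed(seed, paste0("phenotype-", trt)), {
      probs <- config$phenotype_probs[[trt]]
      vapply(seq_len(n), function(i) {
        sample(colnames(probs), 1L, prob = probs[min(st$comp_fl[i], nrow(probs)), ])
      }, character(1))
    })

    gill_blk <- withr::with_seed(block_seed(seed, paste0("gill-", trt)), {
      list(value = round(pmax(stats::rnorm(n, config$gill$mean,
                                           config$gill$sd), 0.3), 1),
           mask_u = stats::runif(n))
    })
    gill <- gill_blk$value

    log_shift <- config$year_effects$log_marker[yr_idx]
    marker_vals <- list()
    marker_comp <- list()
    for (mk in maturation_markers()) {
      spec <- specs[[mk]]
      res <- withr::with_seed(block_seed(seed, paste0(trt, "-", mk)), {
        split_draw <- stats::runif(n) < config$igf3_upper_split
        comp <- status_component(st$status, spec, split_draw)
        v <- stats::rnorm(n, spec$mean[comp] + log_shift, spec$sd[comp])
        list(comp = comp, value = 10^v)
      })
      marker_comp[[mk]] <- res$comp
      marker_vals[[mk]] <- res$value
    }

    # extra (configured) missingness masks, drawn before structural masks so
    # that toggling structural rules never perturbs them
    extra_mask <- withr::with_seed(block_seed(seed, paste0("missing-", trt)), {
      lapply(maturation_markers(), function(mk) {
        rate <- config$extra_missingness[[mk]] %||% 0
        stats::runif(n) < rate
      })
    })
    names(extra_mask) <- maturation_markers()

    male <- st$sex == "male"
    mature <- st$status == "mature"
    testis_ok <- year %in% config$testis_years
    gsi_ok <- !(mature & year %in% config$mature_gsi_missing_years)
    keep <- list(
      fshb = male, lhb = male, kt11 = male,
      amh = male & testis_ok & !mature,
      igf3 = male & testis_ok & !mature,
      gsi = male & gsi_ok
    )
    for (mk in maturation_markers()) {
      mask <- !keep[[mk]]
      if (config$apply_missingness) mask <- mask | extra_mask[[mk]]
      mask <- mask | !male # females never carry gonad markers
      marker_vals[[mk]][mask] <- NA_real_
      marker_comp[[mk]][!male | (mature & mk %in% c("amh", "igf3"))] <- NA_integer_
    }
    gill_keep <- if (config$apply_missingness) {
      (year %in% config$gill$years) & (gill_blk$mask_u < config$gill$sample_rate)
    } else {
      rep(TRUE, n)
    }
    gill[!gill_keep] <- NA_real_

    gonad_weight <- ifelse(
      is.na(marker_vals$gsi), NA_real_,
      pmax(round(marker_vals$gsi * body_weight / 100, 3), 0.001)
    )
    gsi <- 100 * gonad_weight / body_weight

    cohort <- tibble(
      fish_id = sprintf("%s-%04d", trt, seq_len(n)),
      release_year = as.integer(year),
      treatment = trt,
      sex = st$sex,
      fork_length = as.numeric(fork_length),
      body_weight = body_weight,
      gill_atpase = gill,
      smolt_phenotype = phenotype,
      milt_expressed = mature,
      gonad_weight = gonad_weight,
      fshb = signif(marker_vals$fshb, 6),
      lhb = signif(marker_vals$lhb, 6),
      amh = signif(marker_vals$amh, 6),
      igf3 = signif(marker_vals$igf3, 6),
      kt11 = round(marker_vals$kt11, 3),
      gsi = gsi
    )
    truth <- tibble(
      fish_id = cohort$fish_id, treatment = trt, sex = st$sex,
      release_year = as.integer(year), true_status = st$status,
      comp_fork_length = st$comp_fl
    )
    for (mk in maturation_markers()) {
      truth[[paste0("comp_", mk)]] <- marker_comp[[mk]]
    }
    list(cohort = cohort, truth = truth)
  })

  cohort <- dplyr::bind_rows(lapply(parts, `[[`, "cohort"))
  truth <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  cohort <- validate_cohort(cohort)
  attr(cohort, "provenance") <- sprintf("synthetic(seed=%d)", as.integer(seed))

  gen_thr <- generating_thresholds(config)
  mat <- classify_maturation(cohort, gen_thr)
  mig <- classify_migration(cohort, mat, gen_thr)
  truth$true_maturation <- if_else(
    truth$sex == "female", "immature",
    mat$maturation_status[match(truth$fish_id, mat$fish_id)]
  )
  truth$true_migration <- mig$migration_status[match(truth$fish_id, mig$fish_id)]

  structure(list(cohort = cohort, truth = truth, thresholds = gen_thr,
                 config = config, seed = as.integer(seed)),
            class = "labeled_cohort")
}

#' Analytic thresholds of the generating components
#'
#' Computes the thresholds a perfect fit would recover: the intersections
#' of adjacent weighted generating components of each configured metric,
#' back-transformed to the measurement scale for log10-scale markers.
#'
#' @param config A `cohort_config`.
#' @return A threshold table with the same columns used by the
#'   classification functions.
#' @export
generating_thresholds <- function(config) {
  rows <- list()
  for (trt in names(config$markers)) {
    for (spec in config$markers[[trt]]) {
      k <- length(spec$mean)
      fit <- gmm_fit(spec$weight, spec$mean, spec$sd)
      rows[[paste(trt, spec$marker)]] <- thresholds_from_selection(
        fit, orientation = spec$orientation, scale = spec$scale,
        metric = spec$marker, treatment = trt
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic labelled cohort: %d fish (%s), seed %d\n",
    nrow(x$cohort),
    paste(sprintf("%s: %d", names(x$config$n_per_treatment),
                  x$config$n_per_treatment), collapse = ", "),
    x$seed
  ))
  print(truth_summary(x))
  invisible(x)
}

#' True status proportions of a labelled cohort
#'
#' Tallies the ground-truth maturation and migration labels by treatment
#' and sex.  Proportions sum to one within each (treatment, sex, kind)
#' stratum; empty strata are absent.
#'
#' @param labeled A `labeled_cohort` from [generate_cohort()].
#' @return A tibble with `treatment`, `sex`, `kind`
#'   (`maturation`/`migration`), `status`, `n`, `prop`.
#' @export
truth_summary <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_cohort"))
  long <- labeled$truth %>%
    select("treatment", "sex", maturation = "true_status",
           migration = "true_migration") %>%
    tidyr::pivot_longer(c("maturation", "migration"), names_to = "kind",
                        values_to = "status")
  long %>%
    group_by(.data$treatment, .data$sex, .data$kind) %>%
    count(.data$status) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Write or read a cohort configuration as YAML
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns the validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  # named atomic vectors become maps, matrices row-wise lists, so names
  # and component (row) structure survive the YAML round trip
  plain$n_per_treatment <- as.list(config$n_per_treatment)
  plain$condition_factor <- as.list(config$condition_factor)
  plain$phenotype_probs <- lapply(config$phenotype_probs, function(m) {
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  })
  yaml::write_yaml(plain, path, precision = 17L)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) as.numeric(unlist(x))
  for (trt in names(raw$markers)) {
    raw$markers[[trt]] <- lapply(raw$markers[[trt]], function(ms) {
      marker_spec(ms$marker, ms$scale, num(ms$weight), num(ms$mean),
                  num(ms$sd), ms$orientation)
    })
  }
  raw$n_per_treatment <- unlist(raw$n_per_treatment)
  raw$years <- as.integer(num(raw$years))
  raw$year_effects <- lapply(raw$year_effects, num)
  raw$phenotype_probs <- lapply(raw$phenotype_probs, function(p) {
    m <- do.call(rbind, lapply(p, num))
    colnames(m) <- c("parr", "transitional", "smolt")
    m
  })
  raw$condition_factor <- unlist(raw$condition_factor)
  raw$gill$years <- as.integer(num(raw$gill$years))
  raw$testis_years <- as.integer(num(raw$testis_years))
  raw$mature_gsi_missing_years <- as.integer(num(raw$mature_gsi_missing_years))
  class(raw) <- "cohort_config"
  validate_cohort_config(raw)
}
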