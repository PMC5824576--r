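# Seeded synthetic cohort generator. Emulates the statistical structure of
# a primary-debulking-surgery cohort for advanced ovarian cancer: a
# right-skewed peritoneal tumor-burden distribution (median PCI 12),
# one-sided preoperative under-reading of the intraoperative PCI, a steep
# logistic risk of suboptimal cytoreduction (SCS) centred just above
# PCI 20 giving a marginal SCS prevalence of 13.8%, visceral-resection
# counts that rise with burden (floored at 3 when PCI > 20), and a
# logistic major-complication model with a 56% marginal rate.

#' Generator configuration
#'
#' Returns the configuration list for [generate_cohort()]. All defaults
#' are frozen calibration constants chosen so the generated population
#' reproduces the study conditions: SCS prevalence 0.138, intraoperative
#' PCI median 12 (range hitting the mid-30s by n = 80), a Youden-optimal
#' SCS cutoff of PCI > 20, a 56% marginal major-complication rate, and
#' three or more visceral resections whenever the true PCI exceeds 20.
#'
#' @param n_patients Number of patients (default 80, the study size).
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(config, seed)` and uses one derived stream per patient, so earlier
#'   patients are unchanged when `n_patients` grows.
#' @param burden_mean,burden_dispersion Mean and dispersion (size) of the
#'   negative-binomial tumor-burden distribution, truncated to 0-39.
#' @param ct_miss_prob,lap_miss_prob Per-region probability that CT or
#'   laparoscopy under-reads an involved region by one point (one-sided
#'   measurement error; preoperative imaging misses implants, it does not
#'   invent them).
#' @param lap_avail_prob Probability a patient has a diagnostic
#'   laparoscopy at all (default 49/80).
#' @param scs_intercept,scs_slope Logistic coefficients of
#'   P(SCS | true PCI).
#' @param resection_base,resection_slope Poisson rate coefficients for the
#'   visceral-resection count given true PCI (rate = base + slope * PCI,
#'   truncated at `resection_max`, floored at 3 when PCI > 20).
#' @param resection_max Upper truncation of the resection count.
#' @param compl_intercept,compl_slope Logistic coefficients of
#'   P(major complication | resections).
#' @param rlcu_flag_probs Named numeric vector of per-flag probabilities
#'   for the radiologic-laparoscopic unresectability findings. The default
#'   is all zero: the emulated cohort contains only patients who passed
#'   the unresectability screen.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 80L,
                             seed = 1L,
                             burden_mean = 13.25,
                             burden_dispersion = 3.25,
                             ct_miss_prob = 0.25,
                             lap_miss_prob = 0.20,
                             lap_avail_prob = 49 / 80,
                             scs_intercept = -32.622,
                             scs_slope = 1.5,
                             resection_base = 0.8,
                             resection_slope = 0.22,
                             resection_max = 15L,
                             compl_intercept = -1.283,
                             compl_slope = 0.45,
                             rlcu_flag_probs = c(lung_mets = 0,
                                                 hepatic_segments = 0,
                                                 pedicle_severe = 0,
                                                 progression_nact = 0,
                                                 small_bowel = 0)) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              burden_mean = burden_mean, burden_dispersion = burden_dispersion,
              ct_miss_prob = ct_miss_prob, lap_miss_prob = lap_miss_prob,
              lap_avail_prob = lap_avail_prob,
              scs_intercept = scs_intercept, scs_slope = scs_slope,
              resection_base = resection_base,
              resection_slope = resection_slope,
              resection_max = as.integer(resection_max),
              compl_intercept = compl_intercept, compl_slope = compl_slope,
              rlcu_flag_probs = rlcu_flag_probs)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  probs <- c(cfg$ct_miss_prob, cfg$lap_miss_prob, cfg$lap_avail_prob,
             cfg$rlcu_flag_probs)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("all generator probabilities must lie in [0, 1]")
  }
  if (cfg$burden_mean < 0 || cfg$burden_dispersion <= 0) {
    stop("burden_mean must be >= 0 and burden_dispersion > 0")
  }
  if (cfg$resection_base < 0 || cfg$resection_slope < 0) {
    stop("resection rate coefficients must be non-negative")
  }
  if (cfg$resection_max < 3L) stop("resection_max must be >= 3")
  invisible(cfg)
}

#' Serialize / restore a generator configuration as JSON
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns the configuration.
#' @export
write_generator_config <- function(config, path) {
  out <- unclass(config)
  out$rlcu_flag_probs <- as.list(out$rlcu_flag_probs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$rlcu_flag_probs <- unlist(raw$rlcu_flag_probs)
  do.call(generator_config, raw)
}

# Probability mass function of the truncated burden distribution on 0:39.
burden_pmf <- function(config) {
  p <- stats::dnbinom(0:39, mu = config$burden_mean,
                      size = config$burden_dispersion)
  p / sum(p)
}

# Deterministic per-patient seed: mixing the root seed with the patient
# index keeps every patient on its own stream, so growing the cohort never
# perturbs earlier patients. Kept below 2^31.
patient_seed <- function(seed, i) {
  as.integer((abs(as.double(seed)) * 1000003 + as.double(i) * 7919) %%
               2147483647)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

#' Draw tumor burdens from the truncated distribution
#'
#' @param config A `generator_config`.
#' @param n Number of draws.
#' @return Integer vector of PCI totals in 0-39. Uses the current RNG
#'   stream (callers seed it; [generate_cohort()] does so per patient).
#' @export
sample_burden <- function(config, n = 1L) {
  validate_generator_config(config)
  sample(0:39, n, replace = TRUE, prob = burden_pmf(config))
}

# Spread a PCI total uniformly over the 39 region-score "slots"
# (13 regions x 3 points): exact sum, every region capped at 3.
allocate_regions <- function(total) {
  if (total == 0L) return(integer(13))
  slots <- sample.int(39L, total)
  tabulate((slots - 1L) %/% 3L + 1L, nbins = 13L)
}

#' Observe a true region-score vector through a noisy modality
#'
#' One-sided under-reading: each involved region is read one point low
#' with probability `miss_prob`, never high, so the observed total is
#' always at most the true total.
#'
#' @param true_regions Integer vector of 13 true region scores (0-3).
#' @param miss_prob Per-region under-read probability in \[0,1\].
#' @return List with `region_scores` (13 observed scores) and `total`.
#' @export
observe_modality <- function(true_regions, miss_prob) {
  stopifnot(length(true_regions) == 13L, miss_prob >= 0, miss_prob <= 1)
  miss <- stats::rbinom(13L, 1L, miss_prob)
  obs <- pmax(true_regions - miss, 0L)
  list(region_scores = as.integer(obs), total = as.integer(sum(obs)))
}

#' Draw the surgical outcome, resections and complication for one patient
#'
#' SCS follows a logistic model in the true PCI; residual tumor size is
#' drawn consistently with the outcome class (SCS uniform on (1,5] cm,
#' otherwise complete cytoreduction with probability 64/69 else optimal
#' with residual uniform on (0,1]). Visceral resections are Poisson with
#' rate `resection_base + resection_slope * pci_true`, truncated at
#' `resection_max` and floored at 3 whenever the true PCI exceeds 20.
#' Major complications follow a logistic model in the resection count and
#' receive a Clavien-Dindo grade II-IV.
#'
#' @param pci_true True (intraoperative) PCI total.
#' @param config A `generator_config`.
#' @return List with `scs_true`, `residual_tumor_cm`,
#'   `visceral_resections`, `clavien_dindo_grade`, `duration_min`.
#' @export
sample_outcome_and_care <- function(pci_true, config) {
  scs <- stats::runif(1) < stats::plogis(config$scs_intercept +
                                           config$scs_slope * pci_true)
  if (scs) {
    residual <- stats::runif(1, 1, 5)
  } else if (stats::runif(1) < 64 / 69) {
    residual <- 0
  } else {
    residual <- stats::runif(1, 0, 1)
  }
  res <- stats::rpois(1, config$resection_base +
                        config$resection_slope * pci_true)
  if (pci_true > 20 && res < 3L) res <- 3L
  res <- min(res, config$resection_max)
  major <- stats::runif(1) < stats::plogis(config$compl_intercept +
                                             config$compl_slope * res)
  grade <- if (major) {
    sample(c("II", "III", "IV"), 1, prob = c(0.27, 0.58, 0.15))
  } else {
    sample(c("NONE", "I"), 1, prob = c(0.6, 0.4))
  }
  duration <- round(min(max(stats::rnorm(1, 360, 100), 60), 638))
  list(scs_true = scs, residual_tumor_cm = residual,
       visceral_resections = as.integer(res), clavien_dindo_grade = grade,
       duration_min = as.integer(duration))
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic for a fixed `(config, seed)`. The laparotomy assessment
#' records the true burden exactly (intraoperative inspection is the
#' reference standard); CT and laparoscopy observe it through one-sided
#' per-region under-reading, and laparoscopy is only available for a
#' subset of patients.
#'
#' @param config A `generator_config` (see [generator_config()]).
#' @return List with `cohort` (a validated `pci_cohort`) and `truth`
#'   (data frame of `patient_id`, `pci_true`, `scs_true`).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- config$n_patients
  cols <- cohort_columns()
  df <- vector("list", length(cols))
  names(df) <- cols
  for (col in cols) {
    df[[col]] <- if (col %in% c("patient_id", "figo_stage",
                                "clavien_dindo_grade")) {
      character(n)
    } else if (col == "residual_tumor_cm") numeric(n) else integer(n)
  }
  truth <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      pci_true = NA_integer_, scs_true = NA)
  ct_rc <- region_cols("ct"); lap_rc <- region_cols("lap")
  int_rc <- region_cols("intraop")
  with_preserved_rng({
    for (i in seq_len(n)) {
      set.seed(patient_seed(config$seed, i))
      pci_true <- sample_burden(config, 1L)
      regions <- allocate_regions(pci_true)
      ct <- observe_modality(regions, config$ct_miss_prob)
      lap_avail <- stats::runif(1) < config$lap_avail_prob
      lap <- observe_modality(regions, config$lap_miss_prob)
      care <- sample_outcome_and_care(pci_true, config)
      fp <- config$rlcu_flag_probs
      df$patient_id[i] <- truth$patient_id[i]
      df$age_years[i] <- round(min(max(stats::rnorm(1, 59, 12), 30), 84))
      df$figo_stage[i] <- sample(c("IIIC", "IV"), 1, prob = c(0.69, 0.31))
      df$ascites[i] <- as.integer(stats::runif(1) < 0.275)
      df$ct_pci_total[i] <- ct$total
      for (r in 1:13) df[[ct_rc[r]]][i] <- ct$region_scores[r]
      df$lap_pci_total[i] <- if (lap_avail) lap$total else NA_integer_
      for (r in 1:13) {
        df[[lap_rc[r]]][i] <- if (lap_avail) lap$region_scores[r]
        else NA_integer_
        df[[int_rc[r]]][i] <- regions[r]
      }
      df$intraop_pci_total[i] <- pci_true
      df$residual_tumor_cm[i] <- care$residual_tumor_cm
      df$visceral_resections[i] <- care$visceral_resections
      df$duration_min[i] <- care$duration_min
      df$clavien_dindo_grade[i] <- care$clavien_dindo_grade
      df$rlcu_lung_mets[i] <- as.integer(stats::runif(1) < fp[["lung_mets"]])
      df$rlcu_hepatic_segments[i] <-
        if (stats::runif(1) < fp[["hepatic_segments"]]) sample(3:8, 1) else 0L
      df$rlcu_pedicle_severe[i] <-
        as.integer(stats::runif(1) < fp[["pedicle_severe"]])
      df$rlcu_progression_nact[i] <-
        as.integer(stats::runif(1) < fp[["progression_nact"]])
      df$rlcu_small_bowel[i] <-
        as.integer(stats::runif(1) < fp[["small_bowel"]])
      truth$pci_true[i] <- pci_true
      truth$scs_true[i] <- care$scs_true
    }
  })
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  cohort <- as_cohort(df, provenance = sprintf(
    "generator_config(n_patients=%d, seed=%d)", n, config$seed))
  list(cohort = cohort, truth = truth)
}

#' Operating characteristics implied by a generator configuration
#'
#' Closed-form (numerically exact) marginals of the configured population:
#' SCS prevalence, sensitivity and specificity of the "true PCI > cutoff"
#' rule, the Youden-optimal cutoff, the resection-count distribution and
#' the marginal major-complication rate. Used to check that simulated
#' cohorts recover what the configuration implies.
#'
#' @param config A `generator_config`.
#' @param cutoff PCI cutoff for the rule characteristics (default 20).
#' @return List with `prevalence`, `sensitivity`, `specificity`,
#'   `best_cutoff`, `major_complication_rate`, `median_pci`.
#' @export
implied_characteristics <- function(config = generator_config(),
                                    cutoff = 20L) {
  pmf <- burden_pmf(config)
  x <- 0:39
  pi <- stats::plogis(config$scs_intercept + config$scs_slope * x)
  prev <- sum(pmf * pi)
  sen_at <- function(t) sum(pmf[x > t] * pi[x > t]) / prev
  spc_at <- function(t) sum(pmf[x <= t] * (1 - pi[x <= t])) / (1 - prev)
  j <- vapply(x, function(t) sen_at(t) + spc_at(t) - 1, numeric(1))
  best <- max(x[j == max(j)])
  # resection distribution: Poisson truncated at resection_max, floored at
  # 3 above the cutoff burden
  res_support <- 0:config$resection_max
  p_res <- numeric(length(res_support))
  for (k in seq_along(x)) {
    rate <- config$resection_base + config$resection_slope * x[k]
    pr <- stats::dpois(res_support, rate)
    pr[length(pr)] <- pr[length(pr)] +
      stats::ppois(config$resection_max, rate, lower.tail = FALSE)
    if (x[k] > 20) {
      pr[4] <- pr[4] + sum(pr[1:3])
      pr[1:3] <- 0
    }
    p_res <- p_res + pmf[k] * pr
  }
  compl <- sum(p_res * stats::plogis(config$compl_intercept +
                                       config$compl_slope * res_support))
  cdf <- cumsum(pmf)
  list(prevalence = prev, sensitivity = sen_at(cutoff),
       specificity = spc_at(cutoff), best_cutoff = best,
       major_complication_rate = compl,
       median_pci = x[which(cdf >= 0.5)[1]])
}
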