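# Independent oracles and shared fixtures for the test suite.

# Brute-force Clopper-Pearson: find the interval endpoints directly from
# binomial tail probabilities by bisection, without beta quantiles.
cp_bruteforce <- function(k, n, conf_level = 0.95, tol = 1e-9) {
  alpha <- 1 - conf_level
  lo <- if (k == 0) 0 else {
    # largest p with P(X >= k | p) <= alpha/2
    f <- function(p) 1 - pbinom(k - 1, n, p) - alpha / 2
    uniroot(f, c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  hi <- if (k == n) 1 else {
    # smallest p with P(X <= k | p) <= alpha/2
    f <- function(p) pbinom(k, n, p) - alpha / 2
    uniroot(f, c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  c(lo = lo, hi = hi)
}

# Direct evaluation of the rank-correlation definition: Pearson's product-
# moment formula applied to tie-averaged ranks, written out longhand.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exhaustive Youden search written independently of the package's scan.
youden_bruteforce <- function(pci, truth) {
  best_j <- -Inf; best_t <- NA_integer_
  for (t in 0:39) {
    sen <- mean(pci[truth] > t)
    spc <- mean(pci[!truth] <= t)
    j <- sen + spc - 1
    if (j > best_j || (j == best_j && t > best_t)) {
      best_j <- j; best_t <- t
    }
  }
  list(best_threshold = best_t, j = best_j)
}

# A tiny hand-built cohort (3 patients) used by IO and rule tests.
tiny_cohort_df <- function() {
  df <- as.data.frame(
    matrix(NA, nrow = 3, ncol = length(cohort_columns()),
           dimnames = list(NULL, cohort_columns())))
  df$patient_id <- c("A", "B", "C")
  df$age_years <- c(55L, 63L, NA)
  df$figo_stage <- c("IIIC", "IV", "IIIC")
  df$ascites <- c(0L, 1L, NA)
  # patient A: full region scores on all modalities, low burden
  regs_a <- c(2, 1, 0, 3, 0, 0, 1, 0, 0, 2, 0, 0, 3)   # sums to 12
  for (r in 0:12) {
    df[[paste0("ct_r", r)]][1] <- regs_a[r + 1]
    df[[paste0("intraop_r", r)]][1] <- regs_a[r + 1]
  }
  df$ct_pci_total[1] <- 12L
  df$intraop_pci_total[1] <- 12L
  # patient B: totals only, high burden, SCS
  df$ct_pci_total[2] <- 25L
  df$lap_pci_total[2] <- 23L
  df$intraop_pci_total[2] <- 30L
  # patient C: CT only
  df$ct_pci_total[3] <- 8L
  df$intraop_pci_total[3] <- 9L
  df$residual_tumor_cm <- c(0, 2.5, 0.4)
  df$visceral_resections <- c(1L, 5L, 2L)
  df$duration_min <- c(300L, 520L, NA)
  df$clavien_dindo_grade <- c("NONE", "III", "I")
  df$rlcu_lung_mets <- c(0L, 0L, 0L)
  df$rlcu_hepatic_segments <- c(0L, 0L, 0L)
  df$rlcu_pedicle_severe <- c(0L, 0L, 0L)
  df$rlcu_progression_nact <- c(0L, 0L, 0L)
  df$rlcu_small_bowel <- c(0L, 0L, 0L)
  df
}

# Shared large synthetic cohort, generated once per test run.
.cohort_cache <- new.env(parent = emptyenv())
big_cohort <- function(seed = 1L, n = 5000L) {
  key <- paste0("s", seed, "_n", n)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      generator_config(n_patients = n, seed = seed))
  }
  .cohort_cache[[key]]
}
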