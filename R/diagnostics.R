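# Diagnostic accuracy of suboptimal-cytoreduction prediction rules:
# confusion tables, sensitivity/specificity with exact Clopper-Pearson
# intervals, raw and prevalence-standardized predictive values, the
# prevalence-projection table, and Youden-index cut-off selection.

#' Build a 2x2 confusion table
#'
#' @param predicted Logical vector of rule predictions.
#' @param truth Logical vector of true SCS status, same length.
#' @return List of class `two_by_two` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length")
  }
  if (length(predicted) < 1L) stop("confusion table needs at least one case")
  if (anyNA(predicted) || anyNA(truth)) {
    stop("predicted and truth must not contain missing values")
  }
  structure(list(tp = sum(predicted & truth),
                 fp = sum(predicted & !truth),
                 fn = sum(!predicted & truth),
                 tn = sum(!predicted & !truth)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 table: tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' Endpoints from beta quantiles: the lower limit is the `alpha/2`
#' quantile of Beta(k, n-k+1) (0 when k = 0) and the upper limit the
#' `1-alpha/2` quantile of Beta(k+1, n-k) (1 when k = n).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Sensitivity and specificity with exact intervals
#'
#' Sensitivity is the fraction of true SCS patients the rule flags
#' (tp / (tp + fn)); specificity the fraction of non-SCS patients it
#' clears (tn / (tn + fp)). Intervals are exact Clopper-Pearson.
#'
#' @param t A `two_by_two`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `sen`, `sen_ci`, `spc`, `spc_ci`.
#' @export
sen_spc <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$tp + t$fn < 1L) stop("no positive (SCS) cases: sensitivity undefined")
  if (t$fp + t$tn < 1L) stop("no negative cases: specificity undefined")
  list(sen = t$tp / (t$tp + t$fn),
       sen_ci = clopper_pearson(t$tp, t$tp + t$fn, conf_level),
       spc = t$tn / (t$tn + t$fp),
       spc_ci = clopper_pearson(t$tn, t$tn + t$fp, conf_level))
}

#' Raw predictive values from counts
#'
#' PPV = tp / (tp + fp), NPV = tn / (tn + fn), at the sample's own
#' prevalence.
#'
#' @param t A `two_by_two`.
#' @return List with `ppv_raw`, `npv_raw`.
#' @export
raw_predictive_values <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$tp + t$fp < 1L) stop("no predicted positives: PPV undefined")
  if (t$tn + t$fn < 1L) stop("no predicted negatives: NPV undefined")
  list(ppv_raw = t$tp / (t$tp + t$fp), npv_raw = t$tn / (t$tn + t$fn))
}

#' Prevalence-standardized positive predictive value
#'
#' Bayes' theorem: PPV = sen * p / (sen * p + (1 - spc) * (1 - p)), giving
#' the PPV a rule with the stated sensitivity and specificity would have
#' in a population with SCS prevalence `prev`.
#'
#' @param sen,spc Sensitivity and specificity in \[0,1\].
#' @param prev Assumed prevalence in \[0,1\].
#' @return Proportion in \[0,1\].
#' @export
standardized_ppv <- function(sen, spc, prev) {
  check_prop(sen = sen, spc = spc, prev = prev)
  den <- sen * prev + (1 - spc) * (1 - prev)
  if (any(den == 0)) stop("PPV undefined: no positives at this prevalence")
  sen * prev / den
}

#' Prevalence-standardized negative predictive value
#'
#' NPV = spc * (1 - p) / (spc * (1 - p) + (1 - sen) * p).
#'
#' @inheritParams standardized_ppv
#' @return Proportion in \[0,1\].
#' @export
standardized_npv <- function(sen, spc, prev) {
  check_prop(sen = sen, spc = spc, prev = prev)
  den <- spc * (1 - prev) + (1 - sen) * prev
  if (any(den == 0)) stop("NPV undefined: no negatives at this prevalence")
  spc * (1 - prev) / den
}

check_prop <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      stop(nm, " must be a proportion in [0, 1]")
    }
  }
  invisible(TRUE)
}

#' Predictive values across a range of prevalences
#'
#' Projects a rule with fixed sensitivity and specificity onto
#' hypothetical populations: one row per prevalence with the
#' standardized PPV and NPV. When `ci_n` is given, Clopper-Pearson
#' intervals are attached by scaling the standardized cell probabilities
#' to an effective sample of `ci_n` patients (an approximation: the
#' interval a count-based study of that size would give).
#'
#' @param sen,spc Sensitivity and specificity in \[0,1\].
#' @param prevalences Strictly increasing vector of prevalences in (0,1).
#' @param ci_n Optional effective sample size for intervals.
#' @return Data frame with `prevalence`, `ppv`, `npv` and, when `ci_n`
#'   is given, `ppv_lo`, `ppv_hi`, `npv_lo`, `npv_hi`.
#' @export
predictive_value_table <- function(sen, spc, prevalences, ci_n = NULL) {
  if (any(prevalences <= 0 | prevalences >= 1)) {
    stop("prevalences must lie strictly inside (0, 1)")
  }
  if (is.unsorted(prevalences, strictly = TRUE)) {
    stop("prevalences must be strictly increasing")
  }
  ppv <- standardized_ppv(sen, spc, prevalences)
  npv <- standardized_npv(sen, spc, prevalences)
  out <- data.frame(prevalence = prevalences, ppv = ppv, npv = npv)
  if (!is.null(ci_n)) {
    pos <- sen * prevalences + (1 - spc) * (1 - prevalences)
    neg <- 1 - pos
    ci <- function(p, m) {
      n_eff <- pmax(1, round(ci_n * m))
      t(mapply(function(pp, nn) clopper_pearson(round(pp * nn), nn), p, n_eff))
    }
    pci <- ci(ppv, pos); nci <- ci(npv, neg)
    out$ppv_lo <- pci[, 1]; out$ppv_hi <- pci[, 2]
    out$npv_lo <- nci[, 1]; out$npv_hi <- nci[, 2]
  }
  out
}

#' Full diagnostic summary of a rule
#'
#' Combines the confusion counts, sensitivity/specificity with exact
#' intervals, raw predictive values, and predictive values standardized
#' to a reference prevalence.
#'
#' @param t A `two_by_two`.
#' @param prevalence Reference prevalence for standardization.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `diagnostic_summary`.
#' @export
diagnostic_summary <- function(t, prevalence, conf_level = 0.95) {
  acc <- sen_spc(t, conf_level)
  raw <- raw_predictive_values(t)
  n <- t$tp + t$fp + t$fn + t$tn
  std_ppv <- standardized_ppv(acc$sen, acc$spc, prevalence)
  std_npv <- standardized_npv(acc$sen, acc$spc, prevalence)
  # interval for the standardized values: Clopper-Pearson on the
  # standardized cell probabilities scaled to the observed sample size
  pos <- acc$sen * prevalence + (1 - acc$spc) * (1 - prevalence)
  n_pos <- max(1, round(n * pos)); n_neg <- max(1, round(n * (1 - pos)))
  structure(list(counts = t, n = n,
                 sen = acc$sen, sen_ci = acc$sen_ci,
                 spc = acc$spc, spc_ci = acc$spc_ci,
                 ppv_raw = raw$ppv_raw, npv_raw = raw$npv_raw,
                 ppv_std = std_ppv,
                 ppv_std_ci = clopper_pearson(round(std_ppv * n_pos), n_pos,
                                              conf_level),
                 npv_std = std_npv,
                 npv_std_ci = clopper_pearson(round(std_npv * n_neg), n_neg,
                                              conf_level),
                 prevalence_used = prevalence),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(p, ci) sprintf("%d%% (%d-%d)", as_pct(p),
                                 as_pct(ci[["lo"]]), as_pct(ci[["hi"]]))
  cat(sprintf("n=%d  SEN %s  SPC %s  PPV %s  NPV %s (at prevalence %.1f%%)\n",
              x$n, fmt(x$sen, x$sen_ci), fmt(x$spc, x$spc_ci),
              fmt(x$ppv_std, x$ppv_std_ci), fmt(x$npv_std, x$npv_std_ci),
              100 * x$prevalence_used))
  invisible(x)
}

#' Rule predictions and truth for a cohort
#'
#' Extracts, for one of the four SCS prediction rules, the logical
#' prediction vector and the matching surgical truth (residual tumor
#' > 1 cm), restricted to patients with the assessments the rule needs
#' and a recorded surgical outcome.
#'
#' @param cohort A `pci_cohort`.
#' @param rule One of "ct", "laparoscopy", "laparotomy", "combined".
#' @param cutoff Integer PCI cutoff (default 20).
#' @return List with `predicted`, `truth`, `patient_id`.
#' @export
rule_predictions <- function(cohort,
                             rule = c("ct", "laparoscopy", "laparotomy",
                                      "combined"),
                             cutoff = 20L) {
  rule <- match.arg(rule)
  stopifnot(inherits(cohort, "pci_cohort"))
  has_outcome <- !is.na(cohort$residual_tumor_cm)
  keep <- switch(rule,
                 ct = !is.na(cohort$ct_pci_total),
                 laparoscopy = !is.na(cohort$lap_pci_total),
                 laparotomy = !is.na(cohort$intraop_pci_total),
                 combined = !is.na(cohort$ct_pci_total) &
                   !is.na(cohort$lap_pci_total)) & has_outcome
  if (!any(keep)) stop("no patients with the assessments required for the ",
                       rule, " rule")
  sub <- cohort[keep, ]
  predicted <- switch(rule,
                      ct = predict_scs(sub$ct_pci_total, cutoff),
                      laparoscopy = predict_scs(sub$lap_pci_total, cutoff),
                      laparotomy = predict_scs(sub$intraop_pci_total, cutoff),
                      combined = predict_scs_combined(sub$ct_pci_total,
                                                      sub$lap_pci_total,
                                                      cutoff))
  truth <- classify_outcome(sub$residual_tumor_cm) == "SCS"
  list(predicted = predicted, truth = truth, patient_id = sub$patient_id)
}

#' Diagnostic summaries for every rule on a cohort
#'
#' @param cohort A `pci_cohort`.
#' @param cutoff Integer PCI cutoff (default 20).
#' @param prevalence Reference prevalence for standardized predictive
#'   values; defaults to the cohort's empirical SCS prevalence.
#' @return Named list of `diagnostic_summary` objects (rules whose
#'   required assessments are absent are dropped with a warning).
#' @export
cohort_diagnostics <- function(cohort, cutoff = 20L, prevalence = NULL) {
  if (is.null(prevalence)) {
    oc <- classify_outcome(
      cohort$residual_tumor_cm[!is.na(cohort$residual_tumor_cm)])
    prevalence <- mean(oc == "SCS")
  }
  out <- list()
  for (rule in c("ct", "laparoscopy", "laparotomy", "combined")) {
    rp <- tryCatch(rule_predictions(cohort, rule, cutoff),
                   error = function(e) NULL)
    if (is.null(rp)) {
      warning("rule '", rule, "' unavailable for this cohort")
      next
    }
    out[[rule]] <- diagnostic_summary(confusion(rp$predicted, rp$truth),
                                      prevalence)
  }
  out
}

#' Youden-index scan over all PCI cutoffs
#'
#' Evaluates the rule "positive iff PCI > t" for every threshold
#' t = 0..39 and selects the threshold maximizing Youden's
#' J = sen + spc - 1. Ties are resolved toward the larger threshold
#' (the more specific rule, conservative toward surgery).
#'
#' @param pci_totals Integer vector of PCI totals.
#' @param scs_truth Logical vector of true SCS status.
#' @return List of class `cutoff_scan` with `scan` (data frame of
#'   `threshold`, `sen`, `spc`, `youden_j`) and `best_threshold`.
#' @export
roc_best_cutoff <- function(pci_totals, scs_truth) {
  if (length(pci_totals) != length(scs_truth)) {
    stop("pci_totals and scs_truth must have the same length")
  }
  if (anyNA(pci_totals) || anyNA(scs_truth)) stop("missing values not allowed")
  n_pos <- sum(scs_truth); n_neg <- sum(!scs_truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both SCS and non-SCS patients are required for a ROC scan")
  }
  thresholds <- 0:39
  sen <- vapply(thresholds,
                function(t) sum(pci_totals > t & scs_truth) / n_pos,
                numeric(1))
  spc <- vapply(thresholds,
                function(t) sum(pci_totals <= t & !scs_truth) / n_neg,
                numeric(1))
  j <- sen + spc - 1
  best <- max(thresholds[j == max(j)])
  structure(list(scan = data.frame(threshold = thresholds, sen = sen,
                                   spc = spc, youden_j = j),
                 best_threshold = best),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  i <- x$scan$threshold == x$best_threshold
  cat(sprintf(
    "Youden scan over PCI cutoffs 0-39: best rule PCI > %d (J = %.3f, sen %.1f%%, spc %.1f%%)\n",
    x$best_threshold, x$scan$youden_j[i], 100 * x$scan$sen[i],
    100 * x$scan$spc[i]))
  invisible(x)
}
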