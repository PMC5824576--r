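# Complication-risk monitoring: the CUSUM observed-minus-expected curve of
# major postoperative complications ordered by visceral-resection count,
# Spearman correlation of resections with intraoperative PCI, and report
# assembly.

#' CUSUM curve of observed minus expected major complications
#'
#' Patients are sorted by ascending visceral-resection count (stable by
#' patient_id within ties) and the running sum of
#' (observed major complication - expected rate) is accumulated, so the
#' final value equals (total observed) - n * p0 exactly.
#'
#' @param cohort A `pci_cohort`; every patient needs a resection count
#'   and a Clavien-Dindo grade.
#' @param p0 Expected major-complication rate in (0,1); defaults to the
#'   cohort's empirical rate. The study's reference value is 0.56.
#' @return List of class `cusum_series` with `p0` and `points` (data
#'   frame of `patient_id`, `visceral_resections`, `observed_major`,
#'   `cumulative`).
#' @export
cusum_curve <- function(cohort, p0 = NULL) {
  stopifnot(inherits(cohort, "pci_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  miss <- is.na(cohort$visceral_resections) | is.na(cohort$clavien_dindo_grade)
  if (any(miss)) {
    stop("missing resections or complication grade for: ",
         paste(cohort$patient_id[miss], collapse = ", "))
  }
  observed <- as.integer(is_major_complication(cohort$clavien_dindo_grade))
  if (is.null(p0)) p0 <- mean(observed)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  ord <- order(cohort$visceral_resections, cohort$patient_id)
  pts <- data.frame(patient_id = cohort$patient_id[ord],
                    visceral_resections = cohort$visceral_resections[ord],
                    observed_major = observed[ord])
  pts$cumulative <- cumsum(pts$observed_major - p0)
  structure(list(p0 = p0, points = pts), class = "cusum_series")
}

#' @export
print.cusum_series <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf(
    "CUSUM of observed - expected major complications (p0 = %.3f, n = %d)\n",
    x$p0, n))
  cat(sprintf("  final value: %.2f (= %d observed - n * p0)\n",
              x$points$cumulative[n], sum(x$points$observed_major)))
  invisible(x)
}

#' Spearman rank correlation with tie-averaged ranks
#'
#' Pearson correlation of the average ranks of `x` and `y`, with a
#' p-value from the large-sample t approximation on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rho is undefined for a constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = min(1, p), n = n)
}

#' Assemble the full analysis report for a cohort
#'
#' Produces the package's standard report: (a) a cohort summary with PCI
#' band counts and outcome counts, (b) per-rule diagnostic summaries,
#' (c) a predictive-value projection across prevalences using the
#' combined rule's estimated sensitivity and specificity, (d) the CUSUM
#' complication series, and (e) Spearman correlation of resections with
#' the intraoperative PCI. Percentages are rounded only here, at the
#' reporting layer.
#'
#' @param cohort A `pci_cohort`.
#' @param cutoff Integer PCI cutoff (default 20).
#' @param reference_prevalence Prevalence for standardized predictive
#'   values; defaults to the cohort's empirical SCS prevalence.
#' @param p0 Expected major-complication rate for the CUSUM curve;
#'   defaults to the cohort's empirical rate.
#' @param projection_prevalences Prevalence grid for the projection table.
#' @return List of class `pci_report` with elements `cohort_summary`,
#'   `diagnostics`, `projection`, `cusum`, `spearman`.
#' @export
make_report <- function(cohort, cutoff = 20L, reference_prevalence = NULL,
                        p0 = NULL,
                        projection_prevalences = seq(0.1, 0.5, 0.1)) {
  stopifnot(inherits(cohort, "pci_cohort"))
  has_outcome <- !is.na(cohort$residual_tumor_cm)
  outcomes <- classify_outcome(cohort$residual_tumor_cm[has_outcome])
  if (is.null(reference_prevalence)) {
    reference_prevalence <- mean(outcomes == "SCS")
  }
  bands <- table(categorize_pci(
    cohort$intraop_pci_total[!is.na(cohort$intraop_pci_total)]))
  summary <- list(
    n = nrow(cohort),
    pci_band_counts = as.integer(bands),
    pci_band_labels = names(bands),
    median_intraop_pci = stats::median(cohort$intraop_pci_total, na.rm = TRUE),
    pci_range = range(cohort$intraop_pci_total, na.rm = TRUE),
    outcome_counts = table(outcomes),
    scs_prevalence_pct = as_pct(mean(outcomes == "SCS")),
    major_complication_pct = as_pct(mean(is_major_complication(
      cohort$clavien_dindo_grade[!is.na(cohort$clavien_dindo_grade)]))))

  diag <- withCallingHandlers(
    cohort_diagnostics(cohort, cutoff, reference_prevalence),
    warning = function(w) invokeRestart("muffleWarning"))

  projection <- NULL
  if (!is.null(diag$combined)) {
    projection <- predictive_value_table(diag$combined$sen,
                                         diag$combined$spc,
                                         projection_prevalences,
                                         ci_n = diag$combined$n)
  }

  cusum <- NULL
  if (!anyNA(cohort$visceral_resections) &&
      !anyNA(cohort$clavien_dindo_grade)) {
    cusum <- cusum_curve(cohort, p0)
  }

  sp <- NULL
  ok <- !is.na(cohort$visceral_resections) & !is.na(cohort$intraop_pci_total)
  if (sum(ok) >= 3) {
    sp <- spearman_rho(cohort$visceral_resections[ok],
                       cohort$intraop_pci_total[ok])
  }

  structure(list(cohort_summary = summary, diagnostics = diag,
                 projection = projection, cusum = cusum, spearman = sp,
                 cutoff = cutoff,
                 reference_prevalence = reference_prevalence),
            class = "pci_report")
}

#' @export
print.pci_report <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("Cohort: n=%d, intraoperative PCI median %.0f (range %d-%d)\n",
              s$n, s$median_intraop_pci, s$pci_range[1], s$pci_range[2]))
  cat("  PCI bands: ", paste(s$pci_band_labels, s$pci_band_counts,
                             sep = "=", collapse = ", "), "\n", sep = "")
  cat("  outcomes: ", paste(names(s$outcome_counts),
                            as.integer(s$outcome_counts),
                            sep = "=", collapse = ", "),
      sprintf(" (SCS prevalence %d%%)\n", s$scs_prevalence_pct), sep = "")
  cat(sprintf("  major complications: %d%%\n", s$major_complication_pct))
  cat(sprintf("Rule diagnostics (PCI > %d, standardized to prevalence %.1f%%):\n",
              x$cutoff, 100 * x$reference_prevalence))
  for (nm in names(x$diagnostics)) {
    cat(sprintf("  %-12s", nm)); print(x$diagnostics[[nm]])
  }
  if (!is.null(x$projection)) {
    cat("Projection (combined rule):\n")
    pr <- x$projection
    for (i in seq_len(nrow(pr))) {
      cat(sprintf("  prevalence %2.0f%%: PPV %d%%, NPV %d%%\n",
                  100 * pr$prevalence[i], as_pct(pr$ppv[i]),
                  as_pct(pr$npv[i])))
    }
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("Spearman resections ~ intraoperative PCI: rho = %.2f (p = %.2g, n = %d)\n",
                x$spearman$rho, x$spearman$p_value, x$spearman$n))
  }
  if (!is.null(x$cusum)) print(x$cusum)
  invisible(x)
}

#' Write the report's tabular sections to an output directory
#'
#' Emits `summary.json`, `diagnostics.csv` (per-rule operating
#' characteristics, integer percents), `projection.csv` and `cusum.csv`.
#'
#' @param report A `pci_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pci_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- report$cohort_summary
  jsonlite::write_json(list(
    n = s$n,
    pci_bands = stats::setNames(as.list(s$pci_band_counts),
                                s$pci_band_labels),
    median_intraop_pci = s$median_intraop_pci,
    scs_prevalence_pct = s$scs_prevalence_pct,
    major_complication_pct = s$major_complication_pct,
    cutoff = report$cutoff,
    reference_prevalence = report$reference_prevalence,
    spearman = report$spearman),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (length(report$diagnostics)) {
    rows <- lapply(names(report$diagnostics), function(nm) {
      d <- report$diagnostics[[nm]]
      data.frame(rule = nm, n = d$n,
                 sen_pct = as_pct(d$sen), sen_lo = as_pct(d$sen_ci[["lo"]]),
                 sen_hi = as_pct(d$sen_ci[["hi"]]),
                 spc_pct = as_pct(d$spc), spc_lo = as_pct(d$spc_ci[["lo"]]),
                 spc_hi = as_pct(d$spc_ci[["hi"]]),
                 ppv_std_pct = as_pct(d$ppv_std),
                 npv_std_pct = as_pct(d$npv_std),
                 ppv_raw_pct = as_pct(d$ppv_raw),
                 npv_raw_pct = as_pct(d$npv_raw))
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "diagnostics.csv"), row.names = FALSE)
  }
  if (!is.null(report$projection)) {
    pr <- report$projection
    pr$ppv_pct <- as_pct(pr$ppv); pr$npv_pct <- as_pct(pr$npv)
    utils::write.csv(pr, file.path(dir, "projection.csv"), row.names = FALSE)
  }
  if (!is.null(report$cusum)) {
    utils::write.csv(report$cusum$points, file.path(dir, "cusum.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
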