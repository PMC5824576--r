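# Domain model for a primary-debulking-surgery cohort: Sugarbaker PCI
# scoring, surgical outcome classes, Clavien-Dindo complications, and the
# cohort CSV interchange format.

#' PCI band labels
#'
#' The peritoneal carcinomatosis index (PCI) is categorized into three
#' ordinal bands: 1-10, 11-20 and > 20. A total of 0 (no macroscopic
#' disease on any region) falls in the lowest band.
#'
#' @return Character vector of the three ordered band labels.
#' @export
pci_bands <- function() c("1-10", "11-20", ">20")

#' Clavien-Dindo grade labels accepted by the package
#' @return Character vector of valid grade codes.
#' @export
clavien_dindo_grades <- function() c("NONE", "I", "II", "III", "IV", "V")

#' Sum 13 Sugarbaker region scores into a PCI total
#'
#' Each of the 13 abdominopelvic regions (indexed 0-12) carries a
#' lesion-size score of 0-3; the PCI is their sum, at most 39.
#'
#' @param region_scores Integer vector of exactly 13 scores, each in 0-3.
#' @return Integer PCI total in 0-39.
#' @export
pci_total <- function(region_scores) {
  if (length(region_scores) != 13L) {
    stop("region_scores must have exactly 13 entries (got ",
         length(region_scores), ")")
  }
  bad <- which(!(region_scores %in% 0:3))
  if (length(bad)) {
    stop("region score out of range {0,1,2,3} at region index ",
         paste(bad - 1L, collapse = ", "))
  }
  as.integer(sum(region_scores))
}

#' Categorize a PCI total into its ordinal band
#'
#' @param total Integer PCI total(s) in 0-39.
#' @return Ordered factor with levels `pci_bands()`: 0-10 maps to "1-10",
#'   11-20 to "11-20", 21-39 to ">20".
#' @export
categorize_pci <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 39)) {
    stop("PCI total must be in 0-39")
  }
  cut(total, breaks = c(-0.5, 10.5, 20.5, 39.5), labels = pci_bands(),
      ordered_result = TRUE)
}

#' Classify the cytoreduction outcome from residual tumor size
#'
#' Complete cytoreduction (CCS) leaves no macroscopic residual tumor,
#' optimal (OCS) leaves residual tumor up to 1 cm, and suboptimal (SCS)
#' leaves residual tumor larger than 1 cm. Exactly 1 cm is classified OCS,
#' following the conventional <= 1 cm optimal-debulking criterion.
#'
#' @param residual_tumor_cm Non-negative numeric vector of residual tumor
#'   diameters in cm.
#' @return Factor with levels CCS, OCS, SCS.
#' @export
classify_outcome <- function(residual_tumor_cm) {
  if (any(is.na(residual_tumor_cm)) || any(residual_tumor_cm < 0)) {
    stop("residual_tumor_cm must be non-negative and non-missing")
  }
  out <- ifelse(residual_tumor_cm == 0, "CCS",
                ifelse(residual_tumor_cm <= 1, "OCS", "SCS"))
  factor(out, levels = c("CCS", "OCS", "SCS"))
}

#' Is a Clavien-Dindo grade a major complication?
#'
#' Grade II or higher counts as major.
#'
#' @param grade Character vector of grades among `clavien_dindo_grades()`.
#' @return Logical vector.
#' @export
is_major_complication <- function(grade) {
  bad <- setdiff(unique(grade), clavien_dindo_grades())
  if (length(bad)) {
    stop("unknown Clavien-Dindo grade: ", paste(bad, collapse = ", "))
  }
  grade %in% c("II", "III", "IV", "V")
}

# Column layout of the cohort CSV (one row per patient).
modality_prefixes <- function() c(ct = "ct", laparoscopy = "lap",
                                  laparotomy = "intraop")

region_cols <- function(prefix) paste0(prefix, "_r", 0:12)

rlcu_cols <- function() {
  c("rlcu_lung_mets", "rlcu_hepatic_segments", "rlcu_pedicle_severe",
    "rlcu_progression_nact", "rlcu_small_bowel")
}

#' Column names of the cohort CSV schema
#' @return Character vector of column names in canonical order.
#' @export
cohort_columns <- function() {
  c("patient_id", "age_years", "figo_stage", "ascites",
    "ct_pci_total", region_cols("ct"),
    "lap_pci_total", region_cols("lap"),
    "intraop_pci_total", region_cols("intraop"),
    "residual_tumor_cm", "visceral_resections", "duration_min",
    "clavien_dindo_grade", rlcu_cols())
}

#' Construct a validated cohort
#'
#' A cohort is a data frame in the layout of [cohort_columns()] carrying a
#' free-text provenance attribute. Validation recomputes every derived
#' quantity (per-modality totals from region scores) and cross-checks it
#' against provided values.
#'
#' @param df Data frame with the columns of [cohort_columns()].
#' @param provenance Free-text origin of the data (file path or generator
#'   configuration digest).
#' @return The validated data frame with class `pci_cohort`.
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, cohort_columns()]
  if (nrow(df) == 0L) stop("cohort must contain at least one patient")
  if (anyNA(df$patient_id) || any(df$patient_id == "")) {
    stop("patient_id must be non-missing for every row")
  }
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup)) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  }

  for (m in names(modality_prefixes())) {
    pre <- modality_prefixes()[[m]]
    tot_col <- paste0(pre, "_pci_total")
    regs <- as.matrix(df[, region_cols(pre)])
    has_regs <- rowSums(!is.na(regs)) > 0
    # region rows must be complete, in range, and agree with any total
    for (i in which(has_regs)) {
      if (anyNA(regs[i, ])) {
        stop("patient ", df$patient_id[i], ": incomplete ", m,
             " region scores (all 13 required when any is given)")
      }
      s <- pci_total(regs[i, ])
      if (!is.na(df[[tot_col]][i]) && df[[tot_col]][i] != s) {
        stop("patient ", df$patient_id[i], ": provided ", tot_col, " (",
             df[[tot_col]][i], ") disagrees with region-score sum (", s, ")")
      }
      df[[tot_col]][i] <- s
    }
    tot <- df[[tot_col]]
    if (any(!is.na(tot) & (tot < 0 | tot > 39))) {
      stop(tot_col, " out of range 0-39 for patient ",
           paste(df$patient_id[!is.na(tot) & (tot < 0 | tot > 39)],
                 collapse = ", "))
    }
  }

  has_any <- !is.na(df$ct_pci_total) | !is.na(df$lap_pci_total) |
    !is.na(df$intraop_pci_total)
  if (any(!has_any)) {
    stop("patient ", paste(df$patient_id[!has_any], collapse = ", "),
         ": no PCI assessment on any modality")
  }

  if (any(!is.na(df$residual_tumor_cm) & df$residual_tumor_cm < 0)) {
    stop("residual_tumor_cm must be non-negative")
  }
  if (any(!is.na(df$visceral_resections) &
          (df$visceral_resections < 0 |
             df$visceral_resections != round(df$visceral_resections)))) {
    stop("visceral_resections must be a non-negative integer")
  }
  known <- is.na(df$clavien_dindo_grade) |
    df$clavien_dindo_grade %in% clavien_dindo_grades()
  if (any(!known)) {
    stop("unknown clavien_dindo_grade for patient ",
         paste(df$patient_id[!known], collapse = ", "))
  }
  if (!all(is.na(df$figo_stage) | df$figo_stage %in% c("IIIC", "IV", "OTHER"))) {
    stop("figo_stage must be one of IIIC, IV, OTHER")
  }
  for (col in c("ascites", rlcu_cols()[-2])) {
    if (!all(is.na(df[[col]]) | df[[col]] %in% c(0, 1))) {
      stop(col, " must be encoded 0/1")
    }
  }
  seg <- df$rlcu_hepatic_segments
  if (any(!is.na(seg) & (seg < 0 | seg != round(seg)))) {
    stop("rlcu_hepatic_segments must be a non-negative integer count")
  }

  structure(df, class = c("pci_cohort", class(df)[class(df) != "pci_cohort"]),
            provenance = provenance)
}

#' @export
print.pci_cohort <- function(x, ...) {
  cat("PCI cohort: ", nrow(x), " patients (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  n_assessed <- vapply(names(modality_prefixes()), function(m) {
    sum(!is.na(x[[paste0(modality_prefixes()[[m]], "_pci_total")]]))
  }, integer(1))
  cat("  assessed by:", paste(names(n_assessed), n_assessed,
                              sep = "=", collapse = ", "), "\n")
  if (any(!is.na(x$residual_tumor_cm))) {
    cat("  outcomes:", paste(capture_counts(classify_outcome(
      x$residual_tumor_cm[!is.na(x$residual_tumor_cm)])), collapse = ", "),
      "\n")
  }
  invisible(x)
}

capture_counts <- function(f) {
  tb <- table(f)
  paste0(names(tb), "=", as.integer(tb))
}

#' Read a cohort CSV
#'
#' Reads the interchange format described in [cohort_columns()] (UTF-8,
#' comma separated, empty cells for missing values, booleans encoded 0/1)
#' and validates it, recomputing totals from region scores where given.
#'
#' @param path Path to the CSV file.
#' @return A `pci_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       figo_stage = "character",
                                       clavien_dindo_grade = "character"),
                        na.strings = "")
  if (nrow(df) == 0L) stop("cohort file has no data rows: ", path)
  as_cohort(df, provenance = path)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field for field.
#'
#' @param cohort A `pci_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "pci_cohort"))
  utils::write.csv(as.data.frame(cohort)[, cohort_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Round half-up to a given number of digits
#'
#' Report-layer rounding: 0.5 always rounds away from zero toward the
#' larger value (unlike base `round`'s round-half-even), so 37.5% prints
#' as 38%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Format a proportion as a rounded integer percentage
#'
#' @param p Proportion in \[0,1\].
#' @return Numeric integer percentage (half-up).
#' @export
as_pct <- function(p) round_half_up(100 * p)
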