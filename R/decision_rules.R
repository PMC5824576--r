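# Decision logic: the radiologic-laparoscopic criteria for unresectability
# (RLCU), the per-modality PCI > cutoff predictor of suboptimal
# cytoreduction, the combined CT-and-laparoscopy criterion, and the
# triage protocol routing patients to primary debulking surgery (PDS) or
# neoadjuvant chemotherapy with interval debulking (NACT/IDS).

#' Construct RLCU findings for one patient
#'
#' The unresectability screen combines CT findings (lung metastasis,
#' hepatic metastasis in three or more segments, severe hepatic pedicle
#' involvement, progression after NACT) with the laparoscopic finding of
#' diffuse serous small-bowel disease. Every field must be given
#' explicitly; there are no implicit defaults at analysis time.
#'
#' @param lung_mets Logical: lung metastasis on CT.
#' @param hepatic_mets_segments Integer count of hepatic segments with
#'   metastases.
#' @param hepatic_pedicle_severe Logical: severe hepatic pedicle
#'   involvement.
#' @param progression_after_nact Logical: disease progression after
#'   neoadjuvant chemotherapy.
#' @param diffuse_small_bowel Logical: diffuse serous small-bowel disease
#'   at laparoscopy.
#' @return A named list of class `rlcu_findings`.
#' @export
rlcu_findings <- function(lung_mets, hepatic_mets_segments,
                          hepatic_pedicle_severe, progression_after_nact,
                          diffuse_small_bowel) {
  f <- list(lung_mets = lung_mets,
            hepatic_mets_segments = hepatic_mets_segments,
            hepatic_pedicle_severe = hepatic_pedicle_severe,
            progression_after_nact = progression_after_nact,
            diffuse_small_bowel = diffuse_small_bowel)
  if (anyNA(unlist(f))) stop("all RLCU findings must be explicitly set")
  if (hepatic_mets_segments < 0 ||
      hepatic_mets_segments != round(hepatic_mets_segments)) {
    stop("hepatic_mets_segments must be a non-negative integer")
  }
  structure(f, class = "rlcu_findings")
}

#' Apply the unresectability screen
#'
#' @param findings An `rlcu_findings` object.
#' @return List with `unresectable` (logical) and `fired` (character
#'   vector of the criteria that were met, empty when resectable).
#' @export
rlcu_unresectable <- function(findings) {
  stopifnot(inherits(findings, "rlcu_findings"))
  fired <- character(0)
  if (isTRUE(findings$lung_mets)) fired <- c(fired, "lung_mets")
  if (findings$hepatic_mets_segments >= 3) {
    fired <- c(fired, "hepatic_segments")
  }
  if (isTRUE(findings$hepatic_pedicle_severe)) {
    fired <- c(fired, "pedicle_severe")
  }
  if (isTRUE(findings$progression_after_nact)) {
    fired <- c(fired, "progression_nact")
  }
  if (isTRUE(findings$diffuse_small_bowel)) fired <- c(fired, "small_bowel")
  list(unresectable = length(fired) > 0, fired = fired)
}

rlcu_from_row <- function(row) {
  rlcu_findings(lung_mets = row$rlcu_lung_mets == 1,
                hepatic_mets_segments = row$rlcu_hepatic_segments,
                hepatic_pedicle_severe = row$rlcu_pedicle_severe == 1,
                progression_after_nact = row$rlcu_progression_nact == 1,
                diffuse_small_bowel = row$rlcu_small_bowel == 1)
}

#' Predict suboptimal cytoreduction from a single PCI assessment
#'
#' Positive when the PCI total strictly exceeds the cutoff (the rule is
#' "PCI > 20", not ">= 20").
#'
#' @param total Integer PCI total(s), 0-39.
#' @param cutoff Integer cutoff (default 20).
#' @return Logical vector (NA where the assessment is missing).
#' @export
predict_scs <- function(total, cutoff = 20L) {
  if (any(!is.na(total) & (total < 0 | total > 39))) {
    stop("PCI total must be in 0-39")
  }
  total > cutoff
}

#' Combined CT-and-laparoscopy prediction of suboptimal cytoreduction
#'
#' Positive only when both modalities show a PCI above the cutoff. The
#' rule is undefined for patients missing either assessment.
#'
#' @param ct_total,lap_total Integer PCI totals for CT and laparoscopy.
#' @param cutoff Integer cutoff (default 20).
#' @return Logical vector.
#' @export
predict_scs_combined <- function(ct_total, lap_total, cutoff = 20L) {
  if (anyNA(ct_total) || anyNA(lap_total)) {
    stop("combined rule requires both CT and laparoscopy assessments")
  }
  predict_scs(ct_total, cutoff) & predict_scs(lap_total, cutoff)
}

#' Triage a cohort between primary surgery and neoadjuvant chemotherapy
#'
#' Route is NACT_IDS when any unresectability criterion fires, otherwise
#' NACT_IDS when both CT and laparoscopy show a PCI above the cutoff,
#' otherwise PDS. Requires CT and laparoscopy assessments plus RLCU
#' findings for every patient.
#'
#' @param cohort A `pci_cohort`.
#' @param cutoff Integer PCI cutoff (default 20).
#' @return Data frame with `patient_id`, `route` ("PDS" or "NACT_IDS")
#'   and `reasons` (semicolon-joined rule identifiers, empty for PDS).
#' @export
triage_cohort <- function(cohort, cutoff = 20L) {
  stopifnot(inherits(cohort, "pci_cohort"))
  missing_mod <- is.na(cohort$ct_pci_total) | is.na(cohort$lap_pci_total)
  if (any(missing_mod)) {
    stop("triage requires CT and laparoscopy for every patient; missing ",
         "for: ", paste(cohort$patient_id[missing_mod], collapse = ", "))
  }
  route <- character(nrow(cohort))
  reasons <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    scr <- rlcu_unresectable(rlcu_from_row(cohort[i, ]))
    if (scr$unresectable) {
      route[i] <- "NACT_IDS"
      reasons[i] <- paste(scr$fired, collapse = ";")
    } else if (predict_scs_combined(cohort$ct_pci_total[i],
                                    cohort$lap_pci_total[i], cutoff)) {
      route[i] <- "NACT_IDS"
      reasons[i] <- "combined_pci"
    } else {
      route[i] <- "PDS"
      reasons[i] <- ""
    }
  }
  data.frame(patient_id = cohort$patient_id, route = route,
             reasons = reasons, stringsAsFactors = FALSE)
}
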