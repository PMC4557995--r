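# The four binary fentanyl-response phenotypes, derived from symptom
# instruments: Brief Pain Inventory (BPI) average pain, Mini-Mental State
# Examination (MMSE), and EORTC QLQ-C30 symptom scales/items.

check_range <- function(x, lo, hi, what, integer_valued = FALSE) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf("%s out of range [%s, %s]: %s", what, lo, hi,
                 paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  if (integer_valued && any(!is.na(x) & x != round(x))) {
    stop(sprintf("%s must be integer-valued", what))
  }
  invisible(x)
}

#' Classify pain control from BPI average pain
#'
#' A patient is classed as having pain control when average pain on the
#' 11-point (0-10) numeric rating scale is 3 or less; higher scores are
#' unacceptable pain.
#'
#' @param bpi_average_pain Integer scores in 0..10 (NA allowed).
#' @return Logical vector (NA where the input is missing).
#' @export
classify_pain_control <- function(bpi_average_pain) {
  check_range(bpi_average_pain, 0, 10, "BPI average pain", integer_valued = TRUE)
  bpi_average_pain <= 3
}

#' Classify cognitive dysfunction from MMSE total score
#'
#' A total Mini-Mental State Examination score of 23 or less (out of 30)
#' defines cognitive dysfunction; this cut-off has high specificity in
#' cancer patient populations.
#'
#' @param mmse Integer scores in 0..30 (NA allowed).
#' @return Logical vector (NA where the input is missing).
#' @export
classify_cognitive_dysfunction <- function(mmse) {
  check_range(mmse, 0, 30, "MMSE", integer_valued = TRUE)
  mmse <= 23
}

#' Classify the sickness-response phenotype
#'
#' Sickness response requires at least two of: EORTC QLQ-C30 nausea and
#' vomiting scale >= 50, tiredness item ("Were you tired?") >= 3, and
#' depression item ("Did you feel depressed?") >= 3.
#'
#' @param nausea EORTC nausea-and-vomiting scale, 0..100.
#' @param tired_item EORTC tiredness single item, 1..4.
#' @param depressed_item EORTC depression single item, 1..4.
#' @return Logical vector; NA where any required input is missing.
#' @export
classify_sickness_response <- function(nausea, tired_item, depressed_item) {
  check_range(nausea, 0, 100, "EORTC nausea-and-vomiting scale")
  check_range(tired_item, 1, 4, "EORTC tiredness item", integer_valued = TRUE)
  check_range(depressed_item, 1, 4, "EORTC depression item", integer_valued = TRUE)
  (nausea >= 50) + (tired_item >= 3) + (depressed_item >= 3) >= 2
}

#' Classify the opioid adverse-event-complaint phenotype
#'
#' A patient is an opioid adverse-event complainer when any of the
#' following hold: nausea-and-vomiting scale >= 50, constipation scale
#' >= 50, tiredness item >= 3, or MMSE <= 23 (cognitive dysfunction).
#'
#' @param nausea EORTC nausea-and-vomiting scale, 0..100.
#' @param constipation EORTC constipation scale, 0..100.
#' @param tired_item EORTC tiredness single item, 1..4.
#' @param mmse MMSE total, 0..30.
#' @return Logical vector; NA where any required input is missing.
#' @export
classify_opioid_ae_complaint <- function(nausea, constipation, tired_item, mmse) {
  check_range(nausea, 0, 100, "EORTC nausea-and-vomiting scale")
  check_range(constipation, 0, 100, "EORTC constipation scale")
  check_range(tired_item, 1, 4, "EORTC tiredness item", integer_valued = TRUE)
  check_range(mmse, 0, 30, "MMSE", integer_valued = TRUE)
  out <- (nausea >= 50) | (constipation >= 50) | (tired_item >= 3) |
    (mmse <= 23)
  # strict complete-case: any missing input gives a missing flag, even
  # when an observed criterion is already satisfied
  out[is.na(nausea) | is.na(constipation) | is.na(tired_item) |
        is.na(mmse)] <- NA
  out
}

#' Add the four response phenotype columns to a cohort
#'
#' Applies the four classifiers to the instrument columns of a cohort data
#' frame and appends logical columns `pain_control`,
#' `cognitive_dysfunction`, `sickness_response` and `opioid_ae_complaint`.
#' A flag is missing exactly when one of its required instrument fields is
#' missing (complete-case per outcome), so the per-outcome analysable n
#' can differ across outcomes.
#'
#' @param cohort Data frame with columns `bpi_average_pain`, `mmse`,
#'   `eortc_nausea_vomiting`, `eortc_constipation`, `eortc_tired_item`,
#'   `eortc_depressed_item`.
#' @return The cohort with the four phenotype columns appended.
#' @export
add_phenotypes <- function(cohort) {
  need <- c("bpi_average_pain", "mmse", "eortc_nausea_vomiting",
            "eortc_constipation", "eortc_tired_item", "eortc_depressed_item")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks instrument columns: ", paste(missing_cols, collapse = ", "))
  }
  cohort$pain_control <- classify_pain_control(cohort$bpi_average_pain)
  cohort$cognitive_dysfunction <- classify_cognitive_dysfunction(cohort$mmse)
  cohort$sickness_response <- classify_sickness_response(
    cohort$eortc_nausea_vomiting, cohort$eortc_tired_item,
    cohort$eortc_depressed_item)
  cohort$opioid_ae_complaint <- classify_opioid_ae_complaint(
    cohort$eortc_nausea_vomiting, cohort$eortc_constipation,
    cohort$eortc_tired_item, cohort$mmse)
  cohort
}

phenotype_names <- function() {
  c("pain_control", "cognitive_dysfunction", "sickness_response",
    "opioid_ae_complaint")
}
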