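#' Controlled vocabulary of treatment categories
#'
#' Treatments are captured at the class level: in-class switching and in-class
#' combinations are invisible downstream, so the category label is the finest
#' unit the era builder and pathway engine ever see. Two modalities exist:
#' `"drug"` events carry a days' supply, `"procedure"` events are dated visits
#' (behavioral therapy, therapeutic brain stimulation).
#'
#' @return A tibble with columns `label` and `modality`.
#' @export
#' @examples
#' treatment_categories()
treatment_categories <- function() {
  tibble::tibble(
    label = c(
      "behavioral_therapy", "brain_stimulation",
      "SSRI", "SNRI", "TCA", "MAOI", "other_antidepressant",
      "anxiolytic", "antipsychotic", "atypical_antipsychotic",
      "anticonvulsant", "centrally_acting_sympathomimetic",
      "hypnotic_sedative", "NMDA_antagonist", "imidazoline_agonist",
      "acetylcysteine", "pentoxifylline", "riluzole", "celecoxib",
      "simvastatin", "baclofen"
    ),
    modality = c(
      "procedure", "procedure",
      rep("drug", 19L)
    )
  )
}

#' Treatment category labels by modality
#'
#' @param modality `"drug"`, `"procedure"`, or `"all"` (default).
#' @return Character vector of category labels.
#' @export
treatment_category_labels <- function(modality = c("all", "drug", "procedure")) {
  modality <- match.arg(modality)
  cats <- treatment_categories()
  if (modality == "all") cats$label else cats$label[cats$modality == modality]
}

#' Controlled vocabulary of condition categories
#'
#' Diagnosis codes are assumed pre-mapped to these category labels; the
#' package performs no vocabulary translation. `"ASD"` anchors cohort entry,
#' the remainder are the comorbid neurological and psychological conditions
#' whose baseline prevalence is reported.
#'
#' @return Character vector of condition-category labels.
#' @export
condition_categories <- function() {
  c("ASD", "ADHD", "anxiety", "mood_disorder", "developmental_delay",
    "seizure_disorder", "malaise_and_fatigue")
}

#' Default diagnosis code set identifying autism spectrum disorder
#'
#' ICD-10-CM codes used for cohort entry.
#'
#' @return Character vector of code strings.
#' @export
asd_diagnosis_codes <- function() {
  c("F84.9", "F84.5", "F84.0", "F84.8")
}
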