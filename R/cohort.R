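#' Apply the cohort-selection rules
#'
#' Reproduces the study-entry filters on a patient/sample table: patients
#' must have metastatic or stage IV disease, a single unambiguous solid-tumor
#' primary diagnosis, and at least one sample with tumor purity at or above
#' the minimum (30% by default). Among a patient's eligible samples, the one
#' taken closest to but not before the metastatic/stage IV diagnosis date is
#' retained; patients whose eligible samples all precede that date are
#' excluded. When the diagnosis date is missing but the stage qualifies, the
#' earliest eligible sample is used.
#'
#' @param patients Tibble with `patient_id`, `cancer_type` (`NA` = missing
#'   diagnosis), `stage` (one of `"I"`,`"II"`,`"III"`,`"IV"`,
#'   `"metastatic"`,`"unknown"`), `metastatic_dx_date` (`Date`, may be `NA`)
#'   and optionally `conflicting_diagnosis` (logical).
#' @param samples Tibble with `patient_id`, `sample_id`, `biopsy_date`
#'   (`Date`), `tumor_purity` (percent).
#' @param thr A [fusion_thresholds()] object (uses `min_tumor_purity_pct`).
#' @param hematologic_types Cancer-type labels treated as hematologic
#'   malignancies and excluded.
#' @return A list with `eligible` (tibble `patient_id`, `sample_id`) and
#'   `audit` (tibble `reason`, `n`; sums to `nrow(patients)`).
#' @export
select_cohort <- function(patients, samples, thr = fusion_thresholds(),
                          hematologic_types = c("leukemia", "lymphoma",
                                                "multiple myeloma",
                                                "myeloma")) {
  patients <- tibble::as_tibble(patients)
  samples <- tibble::as_tibble(samples)
  if (!"conflicting_diagnosis" %in% names(patients)) {
    patients$conflicting_diagnosis <- FALSE
  }
  patients$conflicting_diagnosis[is.na(patients$conflicting_diagnosis)] <- FALSE

  reason <- rep(NA_character_, nrow(patients))
  missing_dx <- is.na(patients$cancer_type) | patients$conflicting_diagnosis
  reason[missing_dx] <- "missing_or_conflicting_diagnosis"
  hema <- is.na(reason) &
    tolower(patients$cancer_type) %in% tolower(hematologic_types)
  reason[hema] <- "hematologic_malignancy"
  not_met <- is.na(reason) & !patients$stage %in% c("IV", "metastatic")
  reason[not_met] <- "not_metastatic_or_stage_iv"

  candidates <- patients[is.na(reason), , drop = FALSE]
  chosen <- tibble::tibble(patient_id = character(0), sample_id = character(0))
  if (nrow(candidates) > 0) {
    smp <- dplyr::inner_join(
      samples,
      dplyr::select(candidates, "patient_id", "metastatic_dx_date"),
      by = "patient_id"
    )
    pure <- smp[smp$tumor_purity >= thr$min_tumor_purity_pct, , drop = FALSE]
    # days from diagnosis to biopsy; NA diagnosis date = stage-qualified
    # patient without a recorded date, for whom the earliest sample is used
    pure$lag_days <- ifelse(
      is.na(pure$metastatic_dx_date),
      as.numeric(pure$biopsy_date - as.Date("1900-01-01")),
      as.numeric(pure$biopsy_date - pure$metastatic_dx_date)
    )
    post <- pure[!is.na(pure$lag_days) & pure$lag_days >= 0, , drop = FALSE]
    if (nrow(post) > 0) {
      chosen <- post |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::arrange(.data$lag_days, .data$sample_id, .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup() |>
        dplyr::select("patient_id", "sample_id")
    }
    idx <- match(candidates$patient_id, chosen$patient_id)
    has_pure <- candidates$patient_id %in% pure$patient_id
    cand_reason <- ifelse(!is.na(idx), "retained",
                          ifelse(has_pure, "no_sample_after_diagnosis",
                                 "low_purity_or_no_sample"))
    reason[is.na(reason)] <- cand_reason
  }

  audit <- tibble::as_tibble(as.data.frame(table(reason),
                                           stringsAsFactors = FALSE))
  names(audit) <- c("reason", "n")
  list(eligible = chosen, audit = audit)
}

#' Tumor mutational burden
#'
#' TMB is the number of nonsynonymous somatic coding mutations (counted
#' upstream with coverage > 100x and allelic fraction > 5%) divided by the
#' megabase size of the panel. Samples with TMB at or above the cut
#' (10 mutations/Mb by default) are TMB-high.
#'
#' @param n_nonsyn Non-negative mutation count(s); `NA` allowed.
#' @param panel_mb Panel size in megabases; must be positive.
#' @return `compute_tmb()`: mutations/Mb. `classify_tmb()`: character vector
#'   in `{"TMB_low","TMB_high","TMB_unknown"}`.
#' @examples
#' compute_tmb(10, 1.0)         # 10 mut/Mb
#' classify_tmb(c(9, 10, NA))   # low, high, unknown
#' @export
compute_tmb <- function(n_nonsyn, panel_mb) {
  if (!is.numeric(panel_mb) || length(panel_mb) != 1 || is.na(panel_mb) ||
      panel_mb <= 0) {
    stop("`panel_mb` must be a single positive number.", call. = FALSE)
  }
  if (any(!is.na(n_nonsyn) & n_nonsyn < 0)) {
    stop("`n_nonsyn` must be non-negative.", call. = FALSE)
  }
  n_nonsyn / panel_mb
}

#' @rdname compute_tmb
#' @param tmb Values in mutations/Mb (e.g. from [compute_tmb()]).
#' @param thr A [fusion_thresholds()] object (uses `tmb_high_cut`).
#' @export
classify_tmb <- function(tmb, thr = fusion_thresholds()) {
  ifelse(is.na(tmb), "TMB_unknown",
         ifelse(tmb >= thr$tmb_high_cut, "TMB_high", "TMB_low"))
}
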