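#' Build an actionability matrix
#'
#' Maps (fusion driver, cancer type) to FDA-approval status of a matched
#' fusion-targeted therapy. Pan-cancer drivers (`RET`, `NTRK1/2/3`) are
#' approved in every indication; emerging drivers (`BRAF`, `EGFR`) have no
#' approval in any indication; for the remaining drivers the status is
#' looked up in the supplied table, and pairs absent from the table default
#' to `not_approved`.
#'
#' @param status A data frame with columns `driver`, `cancer_type`,
#'   `status` (`approved`/`not_approved`). `cancer_type = "*"` applies the
#'   status to every cancer type.
#' @param pan_cancer,actionable,emerging Driver sets; defaults are the
#'   assessed 4 / 9 / 2 genes.
#' @return An object of class `actionability_matrix`.
#' @export
actionability_matrix <- function(status,
                                 pan_cancer = pan_cancer_drivers(),
                                 actionable = actionable_drivers(),
                                 emerging = emerging_drivers()) {
  status <- tibble::as_tibble(status)
  need <- c("driver", "cancer_type", "status")
  miss <- setdiff(need, names(status))
  if (length(miss) > 0) {
    stop("Actionability table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  status$driver <- normalize_gene_symbols(status$driver)
  pan_cancer <- normalize_gene_symbols(pan_cancer)
  actionable <- normalize_gene_symbols(actionable)
  emerging <- normalize_gene_symbols(emerging)
  if (any(!status$status %in% c("approved", "not_approved"))) {
    stop("`status` must be 'approved' or 'not_approved'.", call. = FALSE)
  }
  if (length(intersect(actionable, emerging)) > 0) {
    stop("Actionable and emerging driver sets must be disjoint.",
         call. = FALSE)
  }
  bad_pan <- status$driver %in% pan_cancer & status$status == "not_approved"
  if (any(bad_pan)) {
    stop("Pan-cancer driver(s) listed as not_approved: ",
         paste(unique(status$driver[bad_pan]), collapse = ", "),
         call. = FALSE)
  }
  bad_emg <- status$driver %in% emerging & status$status == "approved"
  if (any(bad_emg)) {
    stop("Emerging driver(s) listed as approved: ",
         paste(unique(status$driver[bad_emg]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(status = status, pan_cancer_drivers = pan_cancer,
         actionable_drivers = actionable, emerging_drivers = emerging),
    class = "actionability_matrix"
  )
}

#' Read an actionability matrix from CSV
#'
#' @param path CSV with columns `driver,cancer_type,status`; if `NULL`, the
#'   bundled matrix (the study's approval grid) is used.
#' @inheritParams actionability_matrix
#' @return An `actionability_matrix`.
#' @export
read_actionability <- function(path = NULL,
                               pan_cancer = pan_cancer_drivers(),
                               actionable = actionable_drivers(),
                               emerging = emerging_drivers()) {
  if (is.null(path)) {
    path <- system.file("extdata", "actionability_matrix.csv",
                        package = "fusionattr")
  }
  status <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  actionability_matrix(status, pan_cancer = pan_cancer,
                       actionable = actionable, emerging = emerging)
}

#' Classify a (driver, cancer type) pair
#'
#' Vectorized over `driver` and `cancer_type`. Emerging drivers always
#' return `"emerging"`; pan-cancer drivers always `"approved"`; other
#' actionable drivers take the matrix status, defaulting to
#' `"not_approved"` when the pair is unlisted.
#'
#' @param driver,cancer_type Character vectors (recycled to common length).
#' @param matrix An `actionability_matrix`.
#' @return Character vector in `{"approved","not_approved","emerging"}`.
#' @export
classify_actionability <- function(driver, cancer_type, matrix) {
  stopifnot(inherits(matrix, "actionability_matrix"))
  driver <- normalize_gene_symbols(driver)
  n <- max(length(driver), length(cancer_type))
  driver <- rep_len(driver, n)
  cancer_type <- rep_len(as.character(cancer_type), n)
  known <- c(matrix$actionable_drivers, matrix$emerging_drivers)
  if (any(!driver %in% known)) {
    stop("Unknown driver(s): ",
         paste(unique(driver[!driver %in% known]), collapse = ", "),
         call. = FALSE)
  }
  out <- rep("not_approved", n)
  key <- paste(driver, cancer_type, sep = "\r")
  tab_exact <- matrix$status[matrix$status$cancer_type != "*", , drop = FALSE]
  tab_wild <- matrix$status[matrix$status$cancer_type == "*", , drop = FALSE]
  hit <- match(key, paste(tab_exact$driver, tab_exact$cancer_type, sep = "\r"))
  out[!is.na(hit)] <- tab_exact$status[hit[!is.na(hit)]]
  wild <- match(driver, tab_wild$driver)
  use_wild <- is.na(hit) & !is.na(wild)
  out[use_wild] <- tab_wild$status[wild[use_wild]]
  out[driver %in% matrix$pan_cancer_drivers] <- "approved"
  out[driver %in% matrix$emerging_drivers] <- "emerging"
  out
}

#' Stratify attributed fusions by approval status
#'
#' Counts attributed fusions by FDA-approval status of the (driver, cancer
#' type) pair, cross-tabulated with the detecting analyte. Emerging drivers
#' are reported in their own stratum so that `approved + not_approved`
#' equals the total number of actionable fusions.
#'
#' @param attributed Output of [attribute_cohort()].
#' @param patients Patient table with `patient_id` and `cancer_type`.
#' @param matrix An `actionability_matrix`.
#' @return A tibble of counts by `approval`, `category` and `driver`, plus a
#'   fusion-level `share_pct` within each approval stratum.
#' @export
stratify_actionability <- function(attributed, patients, matrix) {
  attributed <- tibble::as_tibble(attributed)
  patients <- tibble::as_tibble(patients)
  if (nrow(attributed) == 0) {
    return(tibble::tibble(approval = character(0), category = character(0),
                          driver = character(0), n = integer(0)))
  }
  unmatched <- setdiff(attributed$patient_id, patients$patient_id)
  if (length(unmatched) > 0) {
    stop("Attributed fusion(s) with no matching patient record: ",
         paste(head(unmatched, 5), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(
    attributed,
    dplyr::select(patients, "patient_id", "cancer_type"),
    by = "patient_id"
  )
  joined$approval <- classify_actionability(joined$driver,
                                            joined$cancer_type, matrix)
  dplyr::count(joined, .data$approval, .data$category, .data$driver,
               name = "n")
}
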