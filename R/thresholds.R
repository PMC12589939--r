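#' Assay and analysis thresholds
#'
#' Bundles every numeric cutoff used by the attribution pipeline. Defaults
#' reproduce the clinically validated operating point of the dual-analyte
#' assay: an RNA limit of blank (LOB) of 3 total supporting reads, so a
#' positive RNA fusion call requires at least `lob_reads + 1 = 4` reads; a
#' DNA structural-variant call requires at least 15 supporting reads when a
#' matching fusion partner was independently detected by RNA sequencing, or
#' at least 35 reads otherwise; cohort entry requires a minimum tumor purity
#' of 30%; and tumor mutational burden (TMB) of at least 10 mutations per
#' megabase is classified as TMB-high.
#'
#' @param lob_reads Limit of blank for RNA fusion calls, in total supporting
#'   reads (junction + spanning). Default 3.
#' @param rna_call_min_reads Minimum total supporting reads for a positive
#'   RNA call. Must equal `lob_reads + 1` (a call must exceed the LOB).
#' @param dna_min_with_rna_match Minimum DNA supporting reads when a matching
#'   fusion partner was detected by RNA. Default 15.
#' @param dna_min_without_match Minimum DNA supporting reads with no RNA
#'   corroboration. Default 35.
#' @param min_tumor_purity_pct Minimum tumor purity (percent) for cohort
#'   inclusion. Default 30.
#' @param tmb_high_cut TMB-high boundary in mutations/Mb; values `>=` the cut
#'   are TMB-high. Default 10.
#' @param tmb_min_coverage Minimum coverage (fold) for variants entering the
#'   TMB numerator; an upstream contract, carried for documentation. Default 100.
#' @param tmb_min_vaf_pct Minimum allelic fraction (percent) for TMB
#'   variants; upstream contract. Default 5.
#' @param panel_size_mb Megabase size of the DNA panel's TMB-eligible
#'   territory. No universal value exists; the default of 1.0 Mb is
#'   illustrative and should be set to the panel in use.
#' @param ci_confidence Confidence level for score intervals. Default 0.95.
#'
#' @return An object of class `fusion_thresholds` (a validated list).
#' @examples
#' thr <- fusion_thresholds()
#' thr$rna_call_min_reads # 4
#' @export
fusion_thresholds <- function(lob_reads = 3,
                              rna_call_min_reads = lob_reads + 1,
                              dna_min_with_rna_match = 15,
                              dna_min_without_match = 35,
                              min_tumor_purity_pct = 30,
                              tmb_high_cut = 10,
                              tmb_min_coverage = 100,
                              tmb_min_vaf_pct = 5,
                              panel_size_mb = 1.0,
                              ci_confidence = 0.95) {
  thr <- list(
    lob_reads = lob_reads,
    rna_call_min_reads = rna_call_min_reads,
    dna_min_with_rna_match = dna_min_with_rna_match,
    dna_min_without_match = dna_min_without_match,
    min_tumor_purity_pct = min_tumor_purity_pct,
    tmb_high_cut = tmb_high_cut,
    tmb_min_coverage = tmb_min_coverage,
    tmb_min_vaf_pct = tmb_min_vaf_pct,
    panel_size_mb = panel_size_mb,
    ci_confidence = ci_confidence
  )
  if (rna_call_min_reads != lob_reads + 1) {
    stop("`rna_call_min_reads` must equal `lob_reads + 1`: a positive RNA call ",
         "must strictly exceed the limit of blank.", call. = FALSE)
  }
  if (dna_min_with_rna_match > dna_min_without_match) {
    stop("`dna_min_with_rna_match` must not exceed `dna_min_without_match`.",
         call. = FALSE)
  }
  num <- vapply(thr, is.numeric, logical(1))
  if (!all(num)) stop("All thresholds must be numeric.", call. = FALSE)
  pos <- c("rna_call_min_reads", "dna_min_with_rna_match",
           "dna_min_without_match", "min_tumor_purity_pct", "tmb_high_cut",
           "tmb_min_coverage", "tmb_min_vaf_pct", "panel_size_mb")
  bad <- pos[vapply(pos, function(f) thr[[f]] <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("Thresholds must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (ci_confidence <= 0 || ci_confidence >= 1) {
    stop("`ci_confidence` must be in (0, 1).", call. = FALSE)
  }
  structure(thr, class = "fusion_thresholds")
}

#' @export
print.fusion_thresholds <- function(x, ...) {
  cat("Fusion attribution thresholds\n")
  cat(sprintf("  RNA: LOB %d reads; positive call >= %d total supporting reads\n",
              x$lob_reads, x$rna_call_min_reads))
  cat(sprintf("  DNA: >= %d reads with RNA partner match, >= %d without\n",
              x$dna_min_with_rna_match, x$dna_min_without_match))
  cat(sprintf("  Cohort: tumor purity >= %g%%\n", x$min_tumor_purity_pct))
  cat(sprintf("  TMB: high >= %g mut/Mb (panel %g Mb)\n",
              x$tmb_high_cut, x$panel_size_mb))
  cat(sprintf("  CI confidence: %g\n", x$ci_confidence))
  invisible(x)
}
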