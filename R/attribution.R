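#' RNA fusion call positivity
#'
#' A fusion is detected by RNA sequencing when its total supporting reads
#' (junction + spanning) strictly exceed the limit of blank, i.e. reach
#' `rna_call_min_reads` (4 by default, for a LOB of 3).
#'
#' @param ev RNA rows of a [fusion_evidence()] tibble.
#' @param thr A [fusion_thresholds()] object.
#' @return Logical vector, one element per call.
#' @export
rna_positive <- function(ev, thr = fusion_thresholds()) {
  ev <- validate_fusion_evidence(ev)
  if (nrow(ev) > 0 && any(ev$analyte != "RNA")) {
    stop("rna_positive() expects RNA evidence only.", call. = FALSE)
  }
  ev$read_support >= thr$rna_call_min_reads
}

# unordered, alias-normalized gene-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "::")
}

#' Cross-analyte partner match
#'
#' A DNA structural-variant call has a "matching fusion partner detected in
#' RNA" when some RNA call from the same patient passes the limit of blank
#' and involves the same unordered, alias-normalized gene pair. Sub-LOB RNA
#' evidence does not count as detected and therefore does not unlock the
#' lower DNA read-support threshold.
#'
#' @param dna_call DNA rows of a [fusion_evidence()] tibble.
#' @param rna_calls RNA rows for the same patient(s) (may be empty).
#' @param thr A [fusion_thresholds()] object.
#' @return Logical vector, one element per DNA call.
#' @export
partner_match <- function(dna_call, rna_calls, thr = fusion_thresholds()) {
  dna_call <- validate_fusion_evidence(dna_call)
  rna_calls <- validate_fusion_evidence(rna_calls)
  if (nrow(dna_call) == 0) return(logical(0))
  if (any(dna_call$analyte != "DNA")) {
    stop("partner_match() expects DNA calls in `dna_call`.", call. = FALSE)
  }
  if (nrow(rna_calls) == 0) return(rep(FALSE, nrow(dna_call)))
  if (any(rna_calls$analyte != "RNA")) {
    stop("partner_match() expects RNA calls in `rna_calls`.", call. = FALSE)
  }
  pos <- rna_calls[rna_positive(rna_calls, thr), , drop = FALSE]
  keys <- unique(paste(pos$patient_id,
                       pair_key(pos$gene_5p, pos$gene_3p)))
  paste(dna_call$patient_id,
        pair_key(dna_call$gene_5p, dna_call$gene_3p)) %in% keys
}

#' DNA structural-variant call positivity
#'
#' A fusion is detected by DNA sequencing when its supporting reads reach 15
#' and a matching fusion partner was detected by RNA, or reach 35 regardless
#' of RNA support.
#'
#' @inheritParams partner_match
#' @return Logical vector, one element per DNA call.
#' @export
dna_positive <- function(dna_call, rna_calls = empty_evidence(),
                         thr = fusion_thresholds()) {
  dna_call <- validate_fusion_evidence(dna_call)
  if (nrow(dna_call) == 0) return(logical(0))
  if (any(dna_call$analyte != "DNA")) {
    stop("dna_positive() expects DNA evidence only.", call. = FALSE)
  }
  matched <- partner_match(dna_call, rna_calls, thr)
  dna_call$read_support >= thr$dna_min_without_match |
    (dna_call$read_support >= thr$dna_min_with_rna_match & matched)
}

# strip "chr" prefixes so contig dialects compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Is the driver's relevant protein domain entirely within the retained
# fusion segment? Vectorized; drivers without a domain entry are
# unconstrained (TRUE). Breakpoint exactly at a domain boundary is intact.
domain_intact <- function(driver, driver_side, driver_chrom, driver_pos,
                          domains) {
  idx <- match(driver, domains$driver)
  out <- rep(TRUE, length(driver))
  has <- !is.na(idx)
  if (!any(has)) return(out)
  side_ok <- driver_side[has] == domains$retained_side[idx[has]]
  chrom_ok <- norm_chrom(driver_chrom[has]) ==
    norm_chrom(domains$chrom[idx[has]])
  pos_ok <- ifelse(
    domains$retained_side[idx[has]] == "5p",
    driver_pos[has] >= domains$domain_end[idx[has]],
    driver_pos[has] <= domains$domain_start[idx[has]]
  )
  out[has] <- side_ok & chrom_ok & pos_ok
  out
}

# expand evidence into one row per (call, driver gene it involves)
driver_centric <- function(ev, drivers) {
  take <- function(side) {
    g_drv <- if (side == "5p") ev$gene_5p else ev$gene_3p
    rows <- ev[g_drv %in% drivers, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    rows$driver <- if (side == "5p") rows$gene_5p else rows$gene_3p
    rows$partner <- if (side == "5p") rows$gene_3p else rows$gene_5p
    rows$driver_side <- side
    rows$driver_chrom <- if (side == "5p") rows$chrom_5p else rows$chrom_3p
    rows$driver_pos <- if (side == "5p") rows$pos_5p else rows$pos_3p
    rows
  }
  dplyr::bind_rows(take("5p"), take("3p"))
}

#' Select the reported RNA fusion partner for one driver
#'
#' When RNA sequencing supports multiple fusion partners for a driver, the
#' reported partner is the one whose breakpoint keeps the driver's relevant
#' protein domain intact and, among those, has the highest total supporting
#' reads; ties break to the lexicographically smallest partner symbol. If no
#' candidate keeps the domain intact, the highest-support candidate overall
#' is used (with a message).
#'
#' @param rna_calls RNA calls passing the LOB for one patient and driver.
#' @param driver The driver gene symbol.
#' @param domains A domain table from [read_domain_table()].
#' @return A list with `partner` and `support`.
#' @export
select_rna_partner <- function(rna_calls, driver,
                               domains = read_domain_table()) {
  rna_calls <- validate_fusion_evidence(rna_calls)
  if (nrow(rna_calls) == 0) {
    stop("select_rna_partner() requires at least one candidate call.",
         call. = FALSE)
  }
  driver <- normalize_gene_symbols(driver)
  dc <- driver_centric(rna_calls, driver)
  if (is.null(dc) || nrow(dc) == 0) {
    stop("No candidate call involves driver ", driver, ".", call. = FALSE)
  }
  dc$intact <- domain_intact(dc$driver, dc$driver_side, dc$driver_chrom,
                             dc$driver_pos, domains)
  if (!any(dc$intact)) {
    message("No ", driver, " candidate keeps the domain intact; ",
            "falling back to highest support.")
    dc$intact <- TRUE
  }
  dc <- dc[dc$intact, , drop = FALSE]
  ord <- order(-dc$read_support, dc$partner)
  list(partner = dc$partner[ord[1]], support = dc$read_support[ord[1]])
}

#' Select the reported DNA fusion partner for one driver
#'
#' Among multiple DNA-supported partners the one with the highest read
#' support is reported; ties break lexicographically.
#'
#' @param dna_calls DNA calls for one patient and driver.
#' @param driver The driver gene symbol.
#' @return A list with `partner` and `support`.
#' @export
select_dna_partner <- function(dna_calls, driver) {
  dna_calls <- validate_fusion_evidence(dna_calls)
  if (nrow(dna_calls) == 0) {
    stop("select_dna_partner() requires at least one candidate call.",
         call. = FALSE)
  }
  driver <- normalize_gene_symbols(driver)
  dc <- driver_centric(dna_calls, driver)
  if (is.null(dc) || nrow(dc) == 0) {
    stop("No candidate call involves driver ", driver, ".", call. = FALSE)
  }
  ord <- order(-dc$read_support, dc$partner)
  list(partner = dc$partner[ord[1]], support = dc$read_support[ord[1]])
}

empty_attributed <- function() {
  tibble::tibble(patient_id = character(0), driver = character(0),
                 category = character(0), rna_partner = character(0),
                 dna_partner = character(0), rna_support = integer(0),
                 dna_support = integer(0))
}

#' Attribute detected fusions to analytes across a cohort
#'
#' The pipeline's core computation. For every patient and driver gene, all
#' RNA and DNA evidence is reduced to a single verdict: detected by RNA
#' only, by DNA only, or by both analytes. Detection is per-patient and
#' per-driver: a driver with any positive RNA call and any positive DNA call
#' is classified `both` even when the detected partners or breakpoints
#' differ between analytes. Drivers with no positive call in either analyte
#' are absent from the output. Reported partners are reconciled with
#' [select_rna_partner()] / [select_dna_partner()].
#'
#' @param evidence A [fusion_evidence()] tibble mixing RNA and DNA calls,
#'   possibly for many patients.
#' @param drivers Driver genes to assess; defaults to the nine actionable
#'   plus two emerging drivers.
#' @param thr A [fusion_thresholds()] object.
#' @param domains A domain table from [read_domain_table()].
#' @return A tibble with columns `patient_id`, `driver`, `category`
#'   (`RNA_only`/`DNA_only`/`both`), `rna_partner`, `dna_partner`,
#'   `rna_support`, `dna_support`; at most one row per patient x driver.
#' @export
attribute_cohort <- function(evidence,
                             drivers = c(actionable_drivers(),
                                         emerging_drivers()),
                             thr = fusion_thresholds(),
                             domains = read_domain_table()) {
  ev <- validate_fusion_evidence(evidence)
  drivers <- normalize_gene_symbols(drivers)
  if (nrow(ev) == 0) return(empty_attributed())
  dc <- driver_centric(ev, drivers)
  if (is.null(dc) || nrow(dc) == 0) return(empty_attributed())
  dc$pkey <- paste(dc$patient_id, pair_key(dc$gene_5p, dc$gene_3p))

  rna <- dc[dc$analyte == "RNA", , drop = FALSE]
  dna <- dc[dc$analyte == "DNA", , drop = FALSE]
  rna$positive <- rna$read_support >= thr$rna_call_min_reads
  pos_keys <- unique(rna$pkey[rna$positive])
  dna$matched <- dna$pkey %in% pos_keys
  dna$positive <- dna$read_support >= thr$dna_min_without_match |
    (dna$read_support >= thr$dna_min_with_rna_match & dna$matched)

  rna_pos <- rna[rna$positive, , drop = FALSE]
  dna_pos <- dna[dna$positive, , drop = FALSE]
  if (nrow(rna_pos) == 0 && nrow(dna_pos) == 0) return(empty_attributed())

  rna_sel <- NULL
  if (nrow(rna_pos) > 0) {
    rna_pos$intact <- domain_intact(rna_pos$driver, rna_pos$driver_side,
                                    rna_pos$driver_chrom, rna_pos$driver_pos,
                                    domains)
    # domain-intact candidates first; fall back to all when none is intact
    rna_sel <- rna_pos |>
      dplyr::group_by(.data$patient_id, .data$driver) |>
      dplyr::arrange(dplyr::desc(.data$intact),
                     dplyr::desc(.data$read_support), .data$partner,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "driver", rna_partner = "partner",
                    rna_support = "read_support")
  }
  dna_sel <- NULL
  if (nrow(dna_pos) > 0) {
    dna_sel <- dna_pos |>
      dplyr::group_by(.data$patient_id, .data$driver) |>
      dplyr::arrange(dplyr::desc(.data$read_support), .data$partner,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "driver", dna_partner = "partner",
                    dna_support = "read_support")
  }
  if (is.null(rna_sel)) {
    out <- dna_sel
    out$rna_partner <- NA_character_
    out$rna_support <- NA_integer_
  } else if (is.null(dna_sel)) {
    out <- rna_sel
    out$dna_partner <- NA_character_
    out$dna_support <- NA_integer_
  } else {
    out <- dplyr::full_join(rna_sel, dna_sel,
                            by = c("patient_id", "driver"))
  }
  out$category <- ifelse(
    !is.na(out$rna_support) & !is.na(out$dna_support), "both",
    ifelse(!is.na(out$rna_support), "RNA_only", "DNA_only")
  )
  out |>
    dplyr::select("patient_id", "driver", "category", "rna_partner",
                  "dna_partner", "rna_support", "dna_support") |>
    dplyr::arrange(.data$patient_id, .data$driver)
}

#' @rdname attribute_cohort
#' @details `attribute_patient()` is the single-patient form; it errors if
#'   the evidence spans more than one patient.
#' @export
attribute_patient <- function(evidence,
                              drivers = c(actionable_drivers(),
                                          emerging_drivers()),
                              thr = fusion_thresholds(),
                              domains = read_domain_table()) {
  ev <- validate_fusion_evidence(evidence)
  if (length(unique(ev$patient_id)) > 1) {
    stop("attribute_patient() expects evidence for a single patient.",
         call. = FALSE)
  }
  attribute_cohort(ev, drivers, thr, domains)
}
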