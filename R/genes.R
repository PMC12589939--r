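#' Driver gene sets
#'
#' The fusion drivers assessed by the pipeline. Nine actionable drivers have
#' an FDA-approved matched therapy in at least one solid-tumor indication;
#' of those, `RET` and the three `NTRK` genes carry pan-indication
#' (tumor-agnostic) approvals. `BRAF` and `EGFR` are emerging fusion targets
#' with therapies in clinical development but no approval in any indication.
#'
#' @return Character vector of HGNC symbols.
#' @export
actionable_drivers <- function() {
  c("ALK", "RET", "ROS1", "NTRK1", "NTRK2", "NTRK3", "FGFR2", "FGFR3", "NRG1")
}

#' @rdname actionable_drivers
#' @export
emerging_drivers <- function() {
  c("BRAF", "EGFR")
}

#' @rdname actionable_drivers
#' @export
pan_cancer_drivers <- function() {
  c("NTRK1", "NTRK2", "NTRK3", "RET")
}

#' Gene symbol normalization
#'
#' Uppercases, trims and alias-normalizes gene symbols so that cross-analyte
#' matching never fails because one pipeline reports a deprecated symbol
#' (e.g. `ACPP` for `ACP3`, or `SEPT14` for `SEPTIN14`). The bundled alias
#' table is deliberately small; supply your own for a larger dictionary.
#'
#' @param x Character vector of gene symbols.
#' @param aliases A two-column data frame (`alias`, `symbol`); defaults to
#'   the bundled table.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_gene_symbols(c("acpp", " Alk", "SEPT14"))
#' @export
normalize_gene_symbols <- function(x, aliases = default_gene_aliases()) {
  if (length(x) == 0) return(character(0))
  out <- toupper(trimws(as.character(x)))
  if (any(!nzchar(out) | is.na(out))) {
    stop("Gene symbols must be non-empty.", call. = FALSE)
  }
  hit <- match(out, aliases$alias)
  out[!is.na(hit)] <- aliases$symbol[hit[!is.na(hit)]]
  out
}

#' @rdname normalize_gene_symbols
#' @export
default_gene_aliases <- function() {
  path <- system.file("extdata", "gene_aliases.csv", package = "fusionattr")
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Protein-domain retention table
#'
#' For partner selection the pipeline prefers RNA fusion candidates whose
#' breakpoint keeps the driver's functionally relevant protein domain
#' (typically the kinase domain) intact. Each driver has one entry giving
#' which fused side retains the domain (`5p` or `3p`) and the genomic
#' interval of the domain on a named contig. The bundled table
#' (`domains_synthetic.csv`) uses illustrative coordinates, as suitable for
#' simulation; override it with assay-specific coordinates for real data.
#'
#' @param path CSV with columns `driver,retained_side,chrom,domain_start,domain_end`.
#' @return Tibble with one row per driver.
#' @export
read_domain_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domains_synthetic.csv",
                        package = "fusionattr")
  }
  dom <- readr::read_csv(path, col_types = readr::cols(
    driver = "c", retained_side = "c", chrom = "c",
    domain_start = "d", domain_end = "d"
  ), progress = FALSE)
  need <- c("driver", "retained_side", "chrom", "domain_start", "domain_end")
  miss <- setdiff(need, names(dom))
  if (length(miss) > 0) {
    stop("Domain table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!dom$retained_side %in% c("5p", "3p"))) {
    stop("`retained_side` must be '5p' or '3p'.", call. = FALSE)
  }
  if (any(dom$domain_start > dom$domain_end)) {
    stop("`domain_start` must be <= `domain_end`.", call. = FALSE)
  }
  if (anyDuplicated(dom$driver)) {
    stop("Each driver must have exactly one domain entry.", call. = FALSE)
  }
  dom$driver <- normalize_gene_symbols(dom$driver)
  dom
}

#' Bundled per-driver fusion partner pool
#'
#' Recurrent partner genes per driver, used by the synthetic-cohort
#' generator so that partner-distribution analyses see realistic categories
#' (e.g. `TACC3` for `FGFR3`, `BICC1` and `ACP3` for `FGFR2`, `CD74` and
#' `ATP1B1` for `NRG1`).
#'
#' @return Tibble with columns `driver`, `partner`.
#' @export
default_partner_pool <- function() {
  path <- system.file("extdata", "fusion_partners.csv", package = "fusionattr")
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  out$driver <- normalize_gene_symbols(out$driver)
  out$partner <- normalize_gene_symbols(out$partner)
  out
}
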