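#' Construct a fusion evidence table
#'
#' One row per candidate fusion call in one analyte for one sample. This is
#' the common currency of the pipeline: RNA and DNA readers, the simulator
#' and the attribution engine all produce or consume it. For RNA calls,
#' `read_support` is the total supporting reads (junction + spanning); for
#' DNA calls it is the structural-variant supporting read count.
#'
#' @param patient_id,sample_id Opaque identifiers.
#' @param analyte `"RNA"` or `"DNA"`.
#' @param gene_5p,gene_3p HGNC-style symbols of the 5' and 3' fusion
#'   partners; uppercased and alias-normalized on construction.
#' @param chrom_5p,pos_5p,strand_5p,chrom_3p,pos_3p,strand_3p Breakpoints
#'   (1-based positions, strand `+`/`-`).
#' @param read_support Non-negative integer read support.
#' @return A `tbl_df` with one row per call, invariant-checked.
#' @export
fusion_evidence <- function(patient_id, sample_id, analyte,
                            gene_5p, gene_3p,
                            chrom_5p, pos_5p, strand_5p,
                            chrom_3p, pos_3p, strand_3p,
                            read_support) {
  ev <- tibble::tibble(
    patient_id = as.character(patient_id),
    sample_id = as.character(sample_id),
    analyte = as.character(analyte),
    gene_5p = normalize_gene_symbols(gene_5p),
    gene_3p = normalize_gene_symbols(gene_3p),
    chrom_5p = as.character(chrom_5p),
    pos_5p = as.integer(pos_5p),
    strand_5p = as.character(strand_5p),
    chrom_3p = as.character(chrom_3p),
    pos_3p = as.integer(pos_3p),
    strand_3p = as.character(strand_3p),
    read_support = as.integer(read_support)
  )
  validate_fusion_evidence(ev)
}

#' Validate a fusion evidence table
#'
#' Checks the structural invariants: known analyte, non-empty uppercase gene
#' symbols, positions `>= 1`, strands in `+`/`-`, and non-negative read
#' support.
#'
#' @param ev A data frame in the [fusion_evidence()] layout.
#' @return The validated tibble (invisibly the same data).
#' @export
validate_fusion_evidence <- function(ev) {
  need <- c("patient_id", "sample_id", "analyte", "gene_5p", "gene_3p",
            "chrom_5p", "pos_5p", "strand_5p", "chrom_3p", "pos_3p",
            "strand_3p", "read_support")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0) {
    stop("Fusion evidence missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ev) == 0) return(tibble::as_tibble(ev))
  if (any(!ev$analyte %in% c("RNA", "DNA"))) {
    stop("`analyte` must be 'RNA' or 'DNA'.", call. = FALSE)
  }
  bad_support <- which(is.na(ev$read_support) | ev$read_support < 0)
  if (length(bad_support) > 0) {
    stop("Negative or missing `read_support` at row ", bad_support[1], ".",
         call. = FALSE)
  }
  bad_pos <- which(ev$pos_5p < 1 | ev$pos_3p < 1)
  if (length(bad_pos) > 0) {
    stop("Breakpoint positions must be >= 1 (row ", bad_pos[1], ").",
         call. = FALSE)
  }
  if (any(!c(ev$strand_5p, ev$strand_3p) %in% c("+", "-"))) {
    stop("Strands must be '+' or '-'.", call. = FALSE)
  }
  if (any(!nzchar(ev$gene_5p)) || any(!nzchar(ev$gene_3p))) {
    stop("Gene symbols must be non-empty.", call. = FALSE)
  }
  tibble::as_tibble(ev)
}

# empty evidence table with the right column types
empty_evidence <- function() {
  fusion_evidence(
    patient_id = character(0), sample_id = character(0),
    analyte = character(0), gene_5p = character(0), gene_3p = character(0),
    chrom_5p = character(0), pos_5p = integer(0), strand_5p = character(0),
    chrom_3p = character(0), pos_3p = integer(0), strand_3p = character(0),
    read_support = integer(0)
  )
}
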