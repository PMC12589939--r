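#' Read RNA fusion calls from a TSV
#'
#' Reads a STAR-Fusion-like tab-separated table of RNA fusion candidates.
#' Total supporting reads are defined as `junction_reads + spanning_frags`,
#' the quantity the limit-of-blank threshold is expressed in. Row order is
#' preserved.
#'
#' @param path Path to a TSV with columns `patient_id, sample_id, gene_5p,
#'   gene_3p, chrom_5p, pos_5p, strand_5p, chrom_3p, pos_3p, strand_3p,
#'   junction_reads, spanning_frags`.
#' @return A [fusion_evidence()] tibble with `analyte = "RNA"`.
#' @export
read_rna_fusions <- function(path) {
  need <- c("patient_id", "sample_id", "gene_5p", "gene_3p",
            "chrom_5p", "pos_5p", "strand_5p",
            "chrom_3p", "pos_3p", "strand_3p",
            "junction_reads", "spanning_frags")
  header <- names(readr::read_tsv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE))
  miss <- setdiff(need, header)
  if (length(miss) > 0) {
    stop("RNA fusion TSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", sample_id = "c", gene_5p = "c", gene_3p = "c",
    chrom_5p = "c", pos_5p = "i", strand_5p = "c",
    chrom_3p = "c", pos_3p = "i", strand_3p = "c",
    junction_reads = "i", spanning_frags = "i"
  ), progress = FALSE)
  if (nrow(raw) == 0) return(empty_evidence())
  bad <- which(is.na(raw$junction_reads) | raw$junction_reads < 0 |
                 is.na(raw$spanning_frags) | raw$spanning_frags < 0)
  if (length(bad) > 0) {
    stop("Negative or missing read count at row ", bad[1],
         " of ", path, ".", call. = FALSE)
  }
  fusion_evidence(
    patient_id = raw$patient_id, sample_id = raw$sample_id, analyte = "RNA",
    gene_5p = raw$gene_5p, gene_3p = raw$gene_3p,
    chrom_5p = raw$chrom_5p, pos_5p = raw$pos_5p, strand_5p = raw$strand_5p,
    chrom_3p = raw$chrom_3p, pos_3p = raw$pos_3p, strand_3p = raw$strand_3p,
    read_support = raw$junction_reads + raw$spanning_frags
  )
}

#' Write RNA fusion calls to a TSV
#'
#' Inverse of [read_rna_fusions()]. Total support is decomposed as all
#' junction reads (`junction_reads = read_support`, `spanning_frags = 0`)
#' unless the evidence carries `junction_reads`/`spanning_frags` columns,
#' in which case those are written as-is.
#'
#' @param ev RNA rows of a [fusion_evidence()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fusions <- function(ev, path) {
  ev <- validate_fusion_evidence(ev)
  if (nrow(ev) > 0 && any(ev$analyte != "RNA")) {
    stop("write_rna_fusions() expects RNA evidence only.", call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = ev$patient_id, sample_id = ev$sample_id,
    gene_5p = ev$gene_5p, gene_3p = ev$gene_3p,
    chrom_5p = ev$chrom_5p, pos_5p = ev$pos_5p, strand_5p = ev$strand_5p,
    chrom_3p = ev$chrom_3p, pos_3p = ev$pos_3p, strand_3p = ev$strand_3p,
    junction_reads = if ("junction_reads" %in% names(ev))
      ev$junction_reads else ev$read_support,
    spanning_frags = if ("spanning_frags" %in% names(ev))
      ev$spanning_frags else 0L
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read DNA structural-variant calls
#'
#' Accepts either a VCF 4.2 file of breakend (`SVTYPE=BND`) records or a TSV
#' mirroring the RNA dialect with a single `read_support` column. In the VCF
#' path, mated BND pairs (linked by `MATEID`) are merged into a single
#' DNA fusion call; gene annotations are taken from the INFO keys
#' `GENEA`/`GENEB` and supporting reads from INFO `SR`. Unmated breakends and
#' breakends lacking gene annotation are dropped with a warning.
#'
#' @param path Path to a `.vcf` or `.tsv` file.
#' @return A [fusion_evidence()] tibble with `analyte = "DNA"`.
#' @export
read_dna_svs <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_dna_svs_vcf(path)
  } else {
    read_dna_svs_tsv(path)
  }
}

read_dna_svs_tsv <- function(path) {
  need <- c("patient_id", "sample_id", "gene_5p", "gene_3p",
            "chrom_5p", "pos_5p", "strand_5p",
            "chrom_3p", "pos_3p", "strand_3p", "read_support")
  header <- names(readr::read_tsv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE))
  miss <- setdiff(need, header)
  if (length(miss) > 0) {
    stop("DNA call TSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", sample_id = "c", gene_5p = "c", gene_3p = "c",
    chrom_5p = "c", pos_5p = "i", strand_5p = "c",
    chrom_3p = "c", pos_3p = "i", strand_3p = "c",
    read_support = "i"
  ), progress = FALSE)
  if (nrow(raw) == 0) return(empty_evidence())
  bad <- which(is.na(raw$read_support) | raw$read_support < 0)
  if (length(bad) > 0) {
    stop("Negative or missing read_support at row ", bad[1], " of ",
         path, ".", call. = FALSE)
  }
  fusion_evidence(
    patient_id = raw$patient_id, sample_id = raw$sample_id, analyte = "DNA",
    gene_5p = raw$gene_5p, gene_3p = raw$gene_3p,
    chrom_5p = raw$chrom_5p, pos_5p = raw$pos_5p, strand_5p = raw$strand_5p,
    chrom_3p = raw$chrom_3p, pos_3p = raw$pos_3p, strand_3p = raw$strand_3p,
    read_support = raw$read_support
  )
}

read_dna_svs_vcf <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("Unparseable VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_evidence())
  info_of <- function(key) unname(vcfR::extract.info(vcf, element = key))
  svtype <- info_of("SVTYPE")
  bnd <- !is.na(svtype) & svtype == "BND"
  if (!any(bnd)) return(empty_evidence())
  rec <- tibble::tibble(
    id = fix$ID[bnd],
    chrom = fix$CHROM[bnd],
    pos = as.integer(fix$POS[bnd]),
    mateid = info_of("MATEID")[bnd],
    genea = info_of("GENEA")[bnd],
    geneb = info_of("GENEB")[bnd],
    sr = suppressWarnings(as.integer(info_of("SR")[bnd])),
    patient = info_of("PATIENT")[bnd],
    sample = info_of("SAMPLE")[bnd],
    strands = info_of("STRANDS")[bnd]
  )
  no_gene <- is.na(rec$genea) | is.na(rec$geneb)
  if (any(no_gene)) {
    warning(sum(no_gene), " BND record(s) without gene annotation dropped.",
            call. = FALSE)
    rec <- rec[!no_gene, , drop = FALSE]
  }
  unmated <- is.na(rec$mateid) | !(rec$mateid %in% rec$id)
  if (any(unmated)) {
    warning(sum(unmated), " BND record(s) without a mate dropped.",
            call. = FALSE)
    rec <- rec[!unmated, , drop = FALSE]
  }
  if (nrow(rec) == 0) return(empty_evidence())
  # keep one record per mate pair: the lexicographically first ID anchors the
  # 5' breakend, its mate the 3' breakend
  first <- rec[rec$id < rec$mateid, , drop = FALSE]
  mate_idx <- match(first$mateid, rec$id)
  strands <- ifelse(is.na(first$strands), "++", first$strands)
  fusion_evidence(
    patient_id = ifelse(is.na(first$patient), "unknown", first$patient),
    sample_id = ifelse(is.na(first$sample), "unknown", first$sample),
    analyte = "DNA",
    gene_5p = first$genea, gene_3p = first$geneb,
    chrom_5p = first$chrom, pos_5p = first$pos,
    strand_5p = substr(strands, 1, 1),
    chrom_3p = rec$chrom[mate_idx], pos_3p = rec$pos[mate_idx],
    strand_3p = substr(strands, 2, 2),
    read_support = pmax(first$sr, rec$sr[mate_idx], na.rm = TRUE)
  )
}

#' Write DNA structural-variant calls as VCF 4.2 breakends
#'
#' Inverse of [read_dna_svs()]: each DNA fusion call becomes a mated pair of
#' `SVTYPE=BND` records with `MATEID`, gene annotations (`GENEA`/`GENEB`),
#' supporting reads (`SR`), strand orientation (`STRANDS`) and sample
#' provenance (`PATIENT`/`SAMPLE`) in INFO.
#'
#' @param ev DNA rows of a [fusion_evidence()] tibble.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_dna_svs <- function(ev, path) {
  ev <- validate_fusion_evidence(ev)
  if (nrow(ev) > 0 && any(ev$analyte != "DNA")) {
    stop("write_dna_svs() expects DNA evidence only.", call. = FALSE)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fusionattr",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend ID\">",
    "##INFO=<ID=GENEA,Number=1,Type=String,Description=\"5-prime gene\">",
    "##INFO=<ID=GENEB,Number=1,Type=String,Description=\"3-prime gene\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Breakend strands\">",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient ID\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample ID\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- header
  if (nrow(ev) > 0) {
    n <- nrow(ev)
    id_a <- sprintf("bnd_%06d_a", seq_len(n))
    id_b <- sprintf("bnd_%06d_b", seq_len(n))
    info_common <- sprintf(
      "GENEA=%s;GENEB=%s;SR=%d;STRANDS=%s%s;PATIENT=%s;SAMPLE=%s",
      ev$gene_5p, ev$gene_3p, ev$read_support, ev$strand_5p, ev$strand_3p,
      ev$patient_id, ev$sample_id
    )
    rec_a <- sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s;%s",
                     ev$chrom_5p, ev$pos_5p, id_a, ev$chrom_3p, ev$pos_3p,
                     id_b, info_common)
    rec_b <- sprintf("%s\t%d\t%s\tN\t]%s:%d]N\t.\tPASS\tSVTYPE=BND;MATEID=%s;%s",
                     ev$chrom_3p, ev$pos_3p, id_b, ev$chrom_5p, ev$pos_5p,
                     id_a, info_common)
    lines <- c(lines, as.vector(rbind(rec_a, rec_b)))
  }
  writeLines(lines, path)
  invisible(path)
}
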