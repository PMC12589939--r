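# Small evidence builders. Default coordinates put the ALK breakpoint on the
# 3' (retained) side upstream of the bundled synthetic kinase-domain
# interval, so calls are domain-intact unless a test says otherwise.

rna_call <- function(patient = "P1", g5 = "EML4", g3 = "ALK", support = 10,
                     p5 = 42396490, p3 = 29400000,
                     c5 = "2", c3 = "2", sample = "S1") {
  fusion_evidence(
    patient_id = patient, sample_id = sample, analyte = "RNA",
    gene_5p = g5, gene_3p = g3,
    chrom_5p = c5, pos_5p = p5, strand_5p = "+",
    chrom_3p = c3, pos_3p = p3, strand_3p = "+",
    read_support = support
  )
}

dna_call <- function(patient = "P1", g5 = "EML4", g3 = "ALK", support = 40,
                     p5 = 42396500, p3 = 29400100,
                     c5 = "2", c3 = "2", sample = "S1") {
  fusion_evidence(
    patient_id = patient, sample_id = sample, analyte = "DNA",
    gene_5p = g5, gene_3p = g3,
    chrom_5p = c5, pos_5p = p5, strand_5p = "+",
    chrom_3p = c3, pos_3p = p3, strand_3p = "+",
    read_support = support
  )
}

bind_ev <- function(...) dplyr::bind_rows(...)

# minimal patient table for attribution summaries
patient_table <- function(ids, cancer_type = "NSCLC") {
  tibble::tibble(patient_id = ids, cancer_type = cancer_type)
}
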