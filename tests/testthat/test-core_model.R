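test_that("thresholds enforce their invariants", {
  thr <- fusion_thresholds()
  expect_equal(thr$rna_call_min_reads, thr$lob_reads + 1)
  expect_error(fusion_thresholds(lob_reads = 3, rna_call_min_reads = 3),
               "limit of blank")
  expect_error(fusion_thresholds(dna_min_with_rna_match = 40,
                                 dna_min_without_match = 35),
               "must not exceed")
  expect_error(fusion_thresholds(tmb_high_cut = -1), "positive")
})

test_that("gene symbols are uppercased and alias-normalized", {
  expect_equal(normalize_gene_symbols(c("acpp", " Alk ", "SEPT14")),
               c("ACP3", "ALK", "SEPTIN14"))
  expect_error(normalize_gene_symbols(c("ALK", "")), "non-empty")
})

test_that("RNA TSV reader sums junction and spanning reads, preserves order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("patient_id", "sample_id", "gene_5p", "gene_3p", "chrom_5p",
          "pos_5p", "strand_5p", "chrom_3p", "pos_3p", "strand_3p",
          "junction_reads", "spanning_frags", sep = "\t"),
    paste("P1", "S1", "EML4", "ALK", "2", "42396490", "+", "2", "29400000",
          "+", "3", "1", sep = "\t"),
    paste("P2", "S2", "cd74", "ros1", "5", "149784243", "+", "6",
          "117600000", "-", "10", "5", sep = "\t")
  ), path)
  ev <- read_rna_fusions(path)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$read_support, c(4L, 15L))
  expect_equal(ev$gene_5p, c("EML4", "CD74"))
  expect_true(all(ev$analyte == "RNA"))
})

test_that("RNA TSV reader diagnoses format and validation errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("patient_id", "sample_id", "gene_5p", sep = "\t"), path)
  expect_error(read_rna_fusions(path), "junction_reads")

  header <- paste("patient_id", "sample_id", "gene_5p", "gene_3p",
                  "chrom_5p", "pos_5p", "strand_5p", "chrom_3p", "pos_3p",
                  "strand_3p", "junction_reads", "spanning_frags", sep = "\t")
  writeLines(header, path)
  expect_equal(nrow(read_rna_fusions(path)), 0)

  writeLines(c(header,
               paste("P1", "S1", "EML4", "ALK", "2", "42396490", "+", "2",
                     "29400000", "+", "-1", "1", sep = "\t")), path)
  expect_error(read_rna_fusions(path), "row 1")
})

test_that("RNA evidence round-trips through the TSV dialect", {
  ev <- bind_ev(rna_call(support = 7), rna_call("P2", "KIF5B", "RET",
                                                support = 22, c3 = "10",
                                                p3 = 43600000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rna_fusions(ev, path)
  back <- read_rna_fusions(path)
  expect_equal(back[names(ev)], ev)
})

test_that("DNA evidence round-trips through paired VCF breakends", {
  ev <- bind_ev(dna_call(support = 40),
                dna_call("P9", "CD74", "ROS1", support = 35,
                         c5 = "5", p5 = 149784243, c3 = "6",
                         p3 = 117600000, sample = "S9"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_dna_svs(ev, path)
  back <- read_dna_svs(path)
  expect_equal(back[names(ev)], ev)
})

test_that("VCF reader merges mates, skips unmated and unannotated BNDs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_dna_svs(dna_call(support = 40), path)
  lines <- readLines(path)
  # append one unmated BND and one mated pair without gene annotation
  lines <- c(lines,
             "3\t500\tlone_a\tN\tN[4:600[\t.\tPASS\tSVTYPE=BND;MATEID=lone_b;GENEA=AAA;GENEB=BBB;SR=50;PATIENT=PX;SAMPLE=SX",
             "5\t700\tnogene_a\tN\tN[6:800[\t.\tPASS\tSVTYPE=BND;MATEID=nogene_b;SR=60;PATIENT=PY;SAMPLE=SY",
             "6\t800\tnogene_b\tN\t]5:700]N\t.\tPASS\tSVTYPE=BND;MATEID=nogene_a;SR=60;PATIENT=PY;SAMPLE=SY")
  writeLines(lines, path)
  expect_warning(expect_warning(back <- read_dna_svs(path), "gene annotation"),
                 "without a mate")
  expect_equal(nrow(back), 1)
  expect_equal(back$read_support, 40L)

  # VCF with no BND records at all
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), path)
  expect_equal(nrow(read_dna_svs(path)), 0)
})

test_that("actionability matrix applies pan-cancer, default and error rules", {
  m <- read_actionability()
  expect_equal(classify_actionability("RET", "sarcoma", m), "approved")
  expect_equal(classify_actionability("NTRK2", "anything", m), "approved")
  expect_equal(classify_actionability("ALK", "NSCLC", m), "approved")
  expect_equal(classify_actionability("ALK", "unlisted type", m),
               "not_approved")
  expect_equal(classify_actionability("BRAF", "melanoma", m), "emerging")
  expect_error(classify_actionability("TP53", "NSCLC", m), "Unknown driver")
  expect_error(
    actionability_matrix(tibble::tibble(driver = "RET",
                                        cancer_type = "NSCLC",
                                        status = "not_approved")),
    "Pan-cancer"
  )
})
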