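mk_attributed <- function(ids, driver = "ALK", category = "both") {
  tibble::tibble(patient_id = ids, driver = driver, category = category,
                 rna_partner = "EML4", dna_partner = "EML4",
                 rna_support = 10L, dna_support = 40L)
}

test_that("summary strata agree with direct set-counting on random cohorts", {
  set.seed(101)
  drivers <- c("ALK", "RET", "NRG1")
  types <- c("t1", "t2")
  cats <- c("RNA_only", "DNA_only", "both")
  for (i in 1:300) {
    n_pat <- sample(5:25, 1)
    patients <- tibble::tibble(
      patient_id = sprintf("p%02d", seq_len(n_pat)),
      cancer_type = sample(types, n_pat, replace = TRUE)
    )
    n_fus <- sample(0:n_pat, 1)
    att <- tibble::tibble(
      patient_id = sample(patients$patient_id, n_fus),
      driver = sample(drivers, n_fus, replace = TRUE),
      category = sample(cats, n_fus, replace = TRUE)
    )
    summ <- summarize_cohort(att, patients)
    # overall margin vs direct counting
    expect_equal(prevalence(summ),
                 100 * dplyr::n_distinct(att$patient_id) / n_pat)
    if (n_fus > 0) {
      bd <- analyte_breakdown(summ)
      expect_equal(unname(bd["pct_rna_only"]),
                   100 * sum(att$category == "RNA_only") / n_fus)
      expect_equal(sum(bd), 100)
      # a random per-driver stratum
      d <- sample(unique(att$driver), 1)
      sub <- att[att$driver == d, ]
      expect_equal(prevalence(summ, d),
                   100 * dplyr::n_distinct(sub$patient_id) / n_pat)
    }
  }
})

test_that("detection increase is RNA-only gain over DNA-detected fusions", {
  att <- mk_attributed(sprintf("p%03d", 1:218))
  att$category <- rep(c("RNA_only", "DNA_only", "both"), c(122, 40, 56))
  summ <- summarize_cohort(att, patient_table(att$patient_id))
  expect_equal(round(detection_increase(summ)), 127)
  all_rna <- summarize_cohort(mk_attributed("p1", category = "RNA_only"),
                              patient_table("p1"))
  expect_true(is.na(detection_increase(all_rna)))
  no_rna <- summarize_cohort(mk_attributed("p1", category = "both"),
                             patient_table("p1"))
  expect_equal(detection_increase(no_rna), 0)
})

test_that("report rounding matches the publication style", {
  expect_equal(round_paper_pct(2.2251), 2.2)
  expect_equal(round_paper_pct(0.1457), 0.15)
  expect_equal(round_paper_pct(127.08, kind = "increase"), 127)
})

test_that("aggregating rare cancer types conserves totals", {
  patients <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:700),
    cancer_type = rep(c("big", "small1", "small2"), c(600, 60, 40))
  )
  agg <- aggregate_small_types(patients, min_patients = 500)
  expect_equal(nrow(agg), 700)
  expect_equal(sort(unique(agg$cancer_type)), c("big", "other"))
  expect_equal(sum(agg$cancer_type == "other"), 100)
})

test_that("stratification conserves counts across approval margins", {
  m <- read_actionability()
  att <- dplyr::bind_rows(
    mk_attributed(sprintf("a%02d", 1:10), driver = "RET"),
    mk_attributed(sprintf("b%02d", 1:6), driver = "ALK"),
    mk_attributed(sprintf("c%02d", 1:4), driver = "BRAF")
  )
  patients <- patient_table(att$patient_id,
                            cancer_type = rep(c("NSCLC", "sarcoma"), 10))
  st <- stratify_actionability(att, patients, m)
  expect_equal(sum(st$n), nrow(att))
  by_app <- tapply(st$n, st$approval, sum)
  expect_equal(unname(by_app[["emerging"]]), 4)
  expect_equal(sum(by_app[c("approved", "not_approved")]), 16)
  expect_error(stratify_actionability(att, patients[-1, ], m),
               "no matching patient")
  empty <- stratify_actionability(att[0, ], patients, m)
  expect_equal(nrow(empty), 0)
})

test_that("two-group comparisons use uncorrected chi-square and Mann-Whitney", {
  tab <- matrix(c(1369, 127, 56030, 9708), nrow = 2)
  res <- compare_groups(tab, kind = "chi2")
  expect_lt(res$p_value, 0.001)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))

  bal <- compare_groups(matrix(c(10, 10, 10, 10), 2), kind = "chi2")
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  expect_error(compare_groups(matrix(c(0, 0, 5, 5), 2), kind = "chi2"),
               "column 1")

  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  mw <- compare_groups(x, g, kind = "mannwhitney")
  expect_equal(mw$p_value, 1)
  expect_error(compare_groups(x, rep("a", 8), kind = "mannwhitney"),
               "two groups")
})

test_that("partner distribution collapses singletons and tests the rest", {
  partner <- c(rep("TACC3", 10), rep("BICC1", 10), "ONCEONLY")
  group <- c(rep("approved", 10), rep("not_approved", 11))
  res <- partner_distribution(partner, group)
  expect_true("other" %in% rownames(res$table))
  expect_false("ONCEONLY" %in% rownames(res$table))
  expect_lt(res$test$p_value, 0.01)

  # collapse_max = 2 keeps only partners in >= 3 patients
  res2 <- partner_distribution(c(rep("TACC3", 5), "A", "A", rep("B", 3)),
                               c(rep("approved", 7), rep("not_approved", 3)),
                               collapse_max = 2)
  expect_false("A" %in% rownames(res2$table))
  expect_true("B" %in% rownames(res2$table))

  expect_warning(res3 <- partner_distribution(rep("TACC3", 10),
                                              rep(c("approved",
                                                    "not_approved"), 5)),
                 "skipped")
  expect_null(res3$test)
})

test_that("expression contrast recovers a simulated shift and honours edge cases", {
  sim <- simulate_cohort(expression_sim_config(delta_log2 = 2,
                                               n_types = 3,
                                               n_per_type = 120,
                                               n_pos_per_type = 15),
                         seed = 5)
  ex <- sim$expression
  res <- expression_contrast(ex$tpm, ex$fusion_positive,
                             sim$patients$cancer_type)
  expect_gt(res$fixed_effect, 0)
  expect_lt(res$p_value, 0.001)
  expect_equal(nrow(res$per_type), 3)
  expect_true(all(res$per_type$p_value < 0.05))
  expect_true(res$satterthwaite_df > 0)

  # a type with one status only is dropped from per-type tests
  ct <- sim$patients$cancer_type
  drop_type <- ct == "type_01" & !ex$fusion_positive
  expect_warning(
    res2 <- expression_contrast(ex$tpm[!drop_type],
                                ex$fusion_positive[!drop_type],
                                ct[!drop_type]),
    "single fusion status"
  )
  expect_equal(nrow(res2$per_type), 2)

  expect_error(
    expression_contrast(ex$tpm[ct == "type_01"],
                        ex$fusion_positive[ct == "type_01"],
                        ct[ct == "type_01"]),
    "at least two cancer types"
  )
})
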