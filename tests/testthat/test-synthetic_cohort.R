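small_config <- function(noise_rate = 0.05) {
  cohort_config(
    mode = "calibrated",
    cancer_types = tibble::tibble(cancer_type = c("NSCLC", "other"),
                                  n_patients = c(300L, 200L)),
    cells = tibble::tibble(
      driver = c("ALK", "NRG1"),
      cancer_type = c("NSCLC", "other"),
      n_rna_only = c(5L, 3L), n_dna_only = c(4L, 2L), n_both = c(6L, 1L)
    ),
    noise_rate = noise_rate
  )
}

test_that("identical seed and config give identical cohorts", {
  a <- simulate_cohort(small_config(), seed = 9)
  b <- simulate_cohort(small_config(), seed = 9)
  expect_identical(a, b)
  c <- simulate_cohort(small_config(), seed = 10)
  expect_false(identical(a$rna_calls, c$rna_calls))
})

test_that("generated supports always satisfy the intended category rules", {
  sim <- simulate_cohort(small_config(noise_rate = 0.2), seed = 21)
  thr <- fusion_thresholds()
  truth <- sim$truth
  ev <- dplyr::bind_rows(sim$rna_calls, sim$dna_calls)
  att <- attribute_cohort(ev, drivers = c("ALK", "NRG1"), thr = thr)
  expect_equal(nrow(att), nrow(truth))
  merged <- dplyr::inner_join(att, truth, by = c("patient_id", "driver"))
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(merged$category.x, merged$category.y)
  # noise calls live in fusion-negative patients and never pass a rule
  noise <- ev[!ev$patient_id %in% truth$patient_id, ]
  expect_gt(nrow(noise), 0)
  expect_true(all(noise$read_support[noise$analyte == "RNA"] <=
                    thr$lob_reads))
  expect_true(all(noise$read_support[noise$analyte == "DNA"] <
                    thr$dna_min_with_rna_match))
})

test_that("infeasible calibrated counts fail before any output", {
  bad <- tibble::tibble(driver = "ALK", cancer_type = "NSCLC",
                        n_rna_only = 500L, n_dna_only = 0L, n_both = 0L)
  expect_error(
    cohort_config(mode = "calibrated",
                  cancer_types = tibble::tibble(cancer_type = "NSCLC",
                                                n_patients = 100L),
                  cells = bad),
    "exceed patients"
  )
  expect_error(
    cohort_config(mode = "calibrated",
                  cancer_types = tibble::tibble(cancer_type = "NSCLC",
                                                n_patients = 100L),
                  cells = tibble::tibble(driver = "ALK",
                                         cancer_type = "missing",
                                         n_rna_only = 1L, n_dna_only = 0L,
                                         n_both = 0L)),
    "unknown cancer type"
  )
})

test_that("zero prevalence yields an empty attribution", {
  cfg <- cohort_config(
    mode = "calibrated",
    cancer_types = tibble::tibble(cancer_type = "NSCLC", n_patients = 50L),
    cells = tibble::tibble(driver = "ALK", cancer_type = "NSCLC",
                           n_rna_only = 0L, n_dna_only = 0L, n_both = 0L),
    noise_rate = 0
  )
  sim <- simulate_cohort(cfg, seed = 2)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(attribute_cohort(
    dplyr::bind_rows(sim$rna_calls, sim$dna_calls))), 0)
})

test_that("stochastic prevalence tracks the configured rate", {
  cfg <- cohort_config(
    mode = "stochastic",
    cancer_types = tibble::tibble(cancer_type = "NSCLC",
                                  n_patients = 10000L),
    cells = tibble::tibble(driver = "ALK", cancer_type = "NSCLC",
                           prevalence = 0.02),
    noise_rate = 0
  )
  sim <- simulate_cohort(cfg, seed = 33)
  obs <- nrow(sim$truth) / 10000
  se <- sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(obs - 0.02), 3 * se)
  expect_true(all(sim$truth$category %in% c("RNA_only", "DNA_only", "both")))
})

test_that("blank simulation reproduces the LOB experiment design", {
  blanks <- simulate_blank_runs(seed = 1)
  expect_equal(nrow(blanks), 96)
  expect_equal(dplyr::n_distinct(blanks$sample_id), 24)
  expect_equal(dplyr::n_distinct(blanks$reagent_lot), 2)
  expect_equal(estimate_lob(blanks), list(lob = 3L, call_threshold = 4L))
  expect_equal(estimate_lob(simulate_blank_runs(n_outliers = 0, seed = 1)),
               list(lob = 0L, call_threshold = 1L))
  expect_equal(estimate_lob(simulate_blank_runs(outlier_value = 5,
                                                seed = 1)),
               list(lob = 5L, call_threshold = 6L))
})

test_that("truth-set simulation reproduces configurable confusion counts", {
  ts <- simulate_truth_set(seed = 4)
  res <- concordance(ts$calls, ts$truth, ts$universe_size)
  expect_equal(c(res$tp, res$fp, res$fn, res$tn), c(168, 1, 3, 14285))

  clean <- simulate_truth_set(tp = 20, fp = 0, fn = 0, tn = 100, seed = 4)
  res2 <- concordance(clean$calls, clean$truth, clean$universe_size)
  expect_equal(res2$ppa, 1)
  expect_equal(res2$npa, 1)

  blind <- simulate_truth_set(tp = 0, fp = 0, fn = 5, tn = 100, seed = 4)
  res3 <- concordance(blind$calls, blind$truth, blind$universe_size)
  expect_equal(res3$ppa, 0)
})
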