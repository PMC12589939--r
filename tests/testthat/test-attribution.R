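thr <- fusion_thresholds()

test_that("RNA positivity is strictly above the limit of blank", {
  expect_false(rna_positive(rna_call(support = 3), thr))
  expect_true(rna_positive(rna_call(support = 4), thr))
  expect_false(rna_positive(rna_call(support = 0), thr))
  expect_error(rna_positive(dna_call(), thr), "RNA evidence")
})

test_that("partner matching requires RNA positivity on the unordered pair", {
  # same unordered pair, reversed order -> match
  expect_true(partner_match(dna_call(g5 = "EML4", g3 = "ALK"),
                            rna_call(g5 = "ALK", g3 = "EML4",
                                     support = 10), thr))
  # different partner -> no match
  expect_false(partner_match(dna_call(g5 = "EML4", g3 = "ALK"),
                             rna_call(g5 = "KIF5B", g3 = "ALK",
                                      support = 10), thr))
  # same pair but sub-LOB RNA support -> not "detected", no match
  expect_false(partner_match(dna_call(g5 = "EML4", g3 = "ALK"),
                             rna_call(support = 2), thr))
  # aliases normalize before matching
  expect_true(partner_match(dna_call(g5 = "ACPP", g3 = "FGFR2"),
                            rna_call(g5 = "ACP3", g3 = "FGFR2",
                                     support = 8), thr))
})

test_that("DNA positivity uses the conditional 15/35 read thresholds", {
  matched_rna <- rna_call(support = 10)
  expect_true(dna_positive(dna_call(support = 15), matched_rna, thr))
  expect_false(dna_positive(dna_call(support = 14), matched_rna, thr))
  unmatched_rna <- rna_call(g5 = "KIF5B", g3 = "ALK", support = 10)
  expect_false(dna_positive(dna_call(support = 34), unmatched_rna, thr))
  expect_true(dna_positive(dna_call(support = 35), unmatched_rna, thr))
  expect_true(dna_positive(dna_call(support = 35), thr = thr))
  expect_error(dna_positive(rna_call(), thr = thr), "DNA evidence")
})

test_that("RNA partner selection prefers intact domains, then support, then name", {
  # ALK domain retained on the 3' side: pos_3p <= domain_start is intact
  intact10 <- rna_call(g5 = "XAAA", support = 10)
  intact20 <- rna_call(g5 = "XBBB", support = 20)
  broken50 <- rna_call(g5 = "XCCC", support = 50, p3 = 29460000)
  sel <- select_rna_partner(bind_ev(intact10, intact20), "ALK")
  expect_equal(sel$partner, "XBBB")
  expect_equal(sel$support, 20L)
  sel <- select_rna_partner(bind_ev(intact10, broken50), "ALK")
  expect_equal(sel$partner, "XAAA")
  tie <- bind_ev(rna_call(g5 = "XB", support = 10),
                 rna_call(g5 = "XA", support = 10))
  expect_equal(select_rna_partner(tie, "ALK")$partner, "XA")
  # nothing intact -> fall back to highest support, with a message
  expect_message(
    sel <- select_rna_partner(bind_ev(broken50), "ALK"),
    "falling back"
  )
  expect_equal(sel$partner, "XCCC")
  expect_error(select_rna_partner(rna_call()[0, ], "ALK"), "at least one")
})

test_that("DNA partner selection takes highest support with lexical ties", {
  calls <- bind_ev(dna_call(g5 = "AAA", support = 40),
                   dna_call(g5 = "BBB", support = 60))
  expect_equal(select_dna_partner(calls, "ALK")$partner, "BBB")
  expect_equal(select_dna_partner(dna_call(g5 = "ZZZ"), "ALK")$partner,
               "ZZZ")
  tie <- bind_ev(dna_call(g5 = "BBB", support = 40),
                 dna_call(g5 = "AAA", support = 40))
  expect_equal(select_dna_partner(tie, "ALK")$partner, "AAA")
  expect_error(select_dna_partner(dna_call()[0, ], "ALK"), "at least one")
})

test_that("per-patient attribution merges analytes regardless of partner", {
  ev <- bind_ev(rna_call(g5 = "EML4", support = 30),
                dna_call(g5 = "KIF5B", support = 50))
  att <- attribute_patient(ev)
  expect_equal(nrow(att), 1)
  expect_equal(att$category, "both")
  expect_equal(att$rna_partner, "EML4")
  expect_equal(att$dna_partner, "KIF5B")

  att <- attribute_patient(rna_call(g5 = "CD74", g3 = "NRG1", support = 12,
                                    c3 = "8", p3 = 32400000))
  expect_equal(att$driver, "NRG1")
  expect_equal(att$category, "RNA_only")

  # everything below threshold -> empty
  ev <- bind_ev(rna_call(support = 3), dna_call(support = 14))
  expect_equal(nrow(attribute_patient(ev)), 0)
  expect_error(attribute_patient(bind_ev(rna_call("P1"), rna_call("P2"))),
               "single patient")
})

test_that("attribution matches a brute-force oracle over the full rule grid", {
  grid <- expand.grid(r = 0:40, d = 0:40, m = c(TRUE, FALSE))
  grid$patient <- sprintf("TT%04d", seq_len(nrow(grid)))
  ev <- bind_ev(
    rna_call(patient = grid$patient, support = grid$r),
    dna_call(patient = grid$patient,
             g5 = ifelse(grid$m, "EML4", "KIF5B"), support = grid$d)
  )
  att <- attribute_cohort(ev, drivers = "ALK", thr = thr)
  got <- setNames(att$category, att$patient_id)

  # independent restatement of the stated rules
  rna_det <- grid$r >= 4
  dna_det <- grid$d >= 35 | (grid$d >= 15 & grid$m & rna_det)
  want <- ifelse(rna_det & dna_det, "both",
                 ifelse(rna_det, "RNA_only",
                        ifelse(dna_det, "DNA_only", NA)))
  expect_equal(unname(got[grid$patient[!is.na(want)]]),
               want[!is.na(want)])
  expect_false(any(grid$patient[is.na(want)] %in% att$patient_id))

  # monotonicity: detection never lost as either support grows, and the
  # category never flips RNA_only <-> DNA_only without passing "both"
  for (m in c(TRUE, FALSE)) {
    sl <- want[grid$m == m]
    cat_m <- matrix(sl, nrow = 41) # rows r = 0..40, cols d = 0..40
    det_m <- !is.na(cat_m)
    expect_true(all(apply(det_m, 2, function(col) all(diff(col) >= 0))))
    expect_true(all(apply(det_m, 1, function(row) all(diff(row) >= 0))))
    for (j in 1:41) {
      runs <- rle(cat_m[, j][!is.na(cat_m[, j])])$values
      expect_false(any(runs == "DNA_only" &
                         dplyr::lag(runs, default = "") == "RNA_only"))
    }
  }
})

test_that("increasing read support never drops a driver from attribution", {
  base <- bind_ev(rna_call(support = 4), dna_call(support = 15))
  for (extra in c(1, 10, 100)) {
    up_rna <- bind_ev(rna_call(support = 4 + extra), dna_call(support = 15))
    up_dna <- bind_ev(rna_call(support = 4), dna_call(support = 15 + extra))
    expect_equal(attribute_patient(up_rna)$category, "both")
    expect_equal(attribute_patient(up_dna)$category, "both")
  }
})
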