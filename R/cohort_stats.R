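#' Cohort summary of attributed fusions
#'
#' Builds the stratified count table behind all prevalence and
#' analyte-breakdown figures: one row per (driver, cancer type) stratum plus
#' `"combined"` / `"pan-cancer"` margins. Patient-level counts
#' (`n_patients_positive`, against `n_patients_total`) drive prevalence;
#' fusion-level counts (`n_fusions` split into `n_rna_only`, `n_dna_only`,
#' `n_both`) drive the analyte breakdown. The two differ only through the
#' rare patients carrying fusions in more than one driver.
#'
#' @param attributed Output of [attribute_cohort()].
#' @param patients Patient table with `patient_id` and `cancer_type`
#'   covering the whole tested cohort (fusion-negative patients included).
#' @return A tibble with columns `driver`, `cancer_type`,
#'   `n_patients_total`, `n_patients_positive`, `n_fusions`, `n_rna_only`,
#'   `n_dna_only`, `n_both`.
#' @export
summarize_cohort <- function(attributed, patients) {
  attributed <- tibble::as_tibble(attributed)
  patients <- tibble::as_tibble(patients)
  stopifnot(all(c("patient_id", "cancer_type") %in% names(patients)))
  joined <- dplyr::left_join(
    attributed,
    dplyr::select(patients, "patient_id", "cancer_type"),
    by = "patient_id"
  )
  if (nrow(joined) > 0 && any(is.na(joined$cancer_type))) {
    stop("Attributed fusion(s) reference patients absent from `patients`.",
         call. = FALSE)
  }
  type_totals <- dplyr::count(patients, .data$cancer_type,
                              name = "n_patients_total")
  all_total <- nrow(patients)
  if (nrow(joined) == 0) {
    return(tibble::tibble(
      driver = "combined", cancer_type = "pan-cancer",
      n_patients_total = all_total, n_patients_positive = 0L,
      n_fusions = 0L, n_rna_only = 0L, n_dna_only = 0L, n_both = 0L
    ))
  }

  cell_counts <- function(df) {
    tibble::tibble(
      n_patients_positive = dplyr::n_distinct(df$patient_id),
      n_fusions = nrow(df),
      n_rna_only = sum(df$category == "RNA_only"),
      n_dna_only = sum(df$category == "DNA_only"),
      n_both = sum(df$category == "both")
    )
  }
  by_cell <- joined |>
    dplyr::group_by(.data$driver, .data$cancer_type) |>
    dplyr::group_modify(~ cell_counts(.x)) |>
    dplyr::ungroup() |>
    dplyr::left_join(type_totals, by = "cancer_type")
  by_driver <- joined |>
    dplyr::group_by(.data$driver) |>
    dplyr::group_modify(~ cell_counts(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(cancer_type = "pan-cancer", n_patients_total = all_total)
  by_type <- joined |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::group_modify(~ cell_counts(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(driver = "combined") |>
    dplyr::left_join(type_totals, by = "cancer_type")
  overall <- cell_counts(joined) |>
    dplyr::mutate(driver = "combined", cancer_type = "pan-cancer",
                  n_patients_total = all_total)
  dplyr::bind_rows(by_cell, by_driver, by_type, overall) |>
    dplyr::select("driver", "cancer_type", "n_patients_total",
                  "n_patients_positive", "n_fusions", "n_rna_only",
                  "n_dna_only", "n_both")
}

get_stratum <- function(summary, driver, cancer_type) {
  row <- summary[which(summary$driver == driver &
                         summary$cancer_type == cancer_type), , drop = FALSE]
  if (nrow(row) == 0) {
    stop("No stratum (", driver, ", ", cancer_type, ") in summary.",
         call. = FALSE)
  }
  row[1, ]
}

#' Fusion prevalence in a stratum
#'
#' `100 * n_patients_positive / n_patients_total`, unrounded. Use
#' [round_paper_pct()] for report-style rounding (one decimal place, two
#' below 0.2%).
#'
#' @param summary A [summarize_cohort()] table.
#' @param driver,cancer_type Stratum selectors (`"combined"`,
#'   `"pan-cancer"` for margins).
#' @return Percent (numeric scalar), or `NA` when the stratum is empty.
#' @export
prevalence <- function(summary, driver = "combined",
                       cancer_type = "pan-cancer") {
  row <- get_stratum(summary, driver, cancer_type)
  if (is.na(row$n_patients_total) || row$n_patients_total == 0) {
    return(NA_real_)
  }
  100 * row$n_patients_positive / row$n_patients_total
}

#' Analyte breakdown of detected fusions in a stratum
#'
#' Shares of fusions detected by RNA only, DNA only, or both analytes, as
#' percentages of all fusions in the stratum (summing to 100).
#'
#' @inheritParams prevalence
#' @return Named numeric `c(pct_rna_only, pct_dna_only, pct_both)`; `NA`s
#'   when the stratum has no detected fusion.
#' @export
analyte_breakdown <- function(summary, driver = "combined",
                              cancer_type = "pan-cancer") {
  row <- get_stratum(summary, driver, cancer_type)
  if (row$n_fusions == 0) {
    return(c(pct_rna_only = NA_real_, pct_dna_only = NA_real_,
             pct_both = NA_real_))
  }
  c(pct_rna_only = 100 * row$n_rna_only / row$n_fusions,
    pct_dna_only = 100 * row$n_dna_only / row$n_fusions,
    pct_both = 100 * row$n_both / row$n_fusions)
}

#' Detection increase from adding RNA sequencing
#'
#' The relative gain in detected fusions from running RNA sequencing
#' concurrently with DNA sequencing:
#' `100 * n_rna_only / (n_dna_only + n_both)`, i.e. fusions found only by
#' RNA relative to everything DNA would have found alone.
#'
#' @inheritParams prevalence
#' @return Percent, or `NA` when nothing was DNA-detected.
#' @export
detection_increase <- function(summary, driver = "combined",
                               cancer_type = "pan-cancer") {
  row <- get_stratum(summary, driver, cancer_type)
  dna_detected <- row$n_dna_only + row$n_both
  if (dna_detected == 0) return(NA_real_)
  100 * row$n_rna_only / dna_detected
}

#' Report-style percentage rounding
#'
#' Percentages are rounded to one decimal place, except prevalences below
#' 0.2% (two decimals) and detection increases (`kind = "increase"`, whole
#' percent).
#'
#' @param pct Percent value(s).
#' @param kind `"share"` (default) or `"increase"`.
#' @return Rounded percent(s).
#' @export
round_paper_pct <- function(pct, kind = c("share", "increase")) {
  kind <- match.arg(kind)
  if (kind == "increase") return(round(pct))
  ifelse(pct < 0.2, round(pct, 2), round(pct, 1))
}

#' Aggregate rare cancer types
#'
#' Relabels cancer types with fewer than `min_patients` tested patients as
#' `"other"`, the aggregation used for per-cancer-type displays. Totals are
#' conserved.
#'
#' @param patients Patient table with `cancer_type`.
#' @param min_patients Aggregation threshold (default 500).
#' @param label Replacement label.
#' @return `patients` with `cancer_type` relabelled.
#' @export
aggregate_small_types <- function(patients, min_patients = 500,
                                  label = "other") {
  patients <- tibble::as_tibble(patients)
  counts <- table(patients$cancer_type)
  small <- names(counts)[counts < min_patients]
  patients$cancer_type[patients$cancer_type %in% small] <- label
  patients
}

#' Fusion rate stratified by tumor mutational burden
#'
#' Computes the proportion of fusion-positive patients within each TMB
#' class, the comparison used to show that driver fusions concentrate in
#' TMB-low tumors.
#'
#' @param patients Patient table with `patient_id` and `n_nonsynonymous_mutations`
#'   (`NA` = TMB not evaluable).
#' @param attributed Output of [attribute_cohort()]; patients appearing here
#'   are fusion-positive.
#' @param thr A [fusion_thresholds()] object (panel size, TMB cut).
#' @return Tibble with `tmb_class`, `n_positive`, `n_total`, `rate_pct`.
#' @export
fusion_rate_by_tmb <- function(patients, attributed,
                               thr = fusion_thresholds()) {
  patients <- tibble::as_tibble(patients)
  tmb <- compute_tmb(patients$n_nonsynonymous_mutations, thr$panel_size_mb)
  cls <- classify_tmb(tmb, thr)
  pos <- patients$patient_id %in% unique(attributed$patient_id)
  tibble::tibble(tmb_class = cls, positive = pos) |>
    dplyr::group_by(.data$tmb_class) |>
    dplyr::summarise(n_positive = sum(.data$positive),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rate_pct = 100 * .data$n_positive / .data$n_total)
}

#' Two-group comparison
#'
#' The study's two workhorse tests: Pearson's chi-square (no continuity
#' correction) for categorical contrasts and the two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test for quantitative contrasts.
#'
#' @param x For `kind = "chi2"`, a contingency matrix/table of non-negative
#'   counts; for `kind = "mannwhitney"`, a numeric vector of values.
#' @param g Group labels (two groups), only for `kind = "mannwhitney"`.
#' @param kind `"chi2"` or `"mannwhitney"`.
#' @param correct Apply Yates continuity correction to the chi-square test
#'   (off by default).
#' @return List with `statistic` and `p_value`.
#' @export
compare_groups <- function(x, g = NULL, kind = c("chi2", "mannwhitney"),
                           correct = FALSE) {
  kind <- match.arg(kind)
  if (kind == "chi2") {
    x <- as.matrix(x)
    if (any(x < 0)) stop("Contingency cells must be non-negative.",
                         call. = FALSE)
    rs <- rowSums(x)
    cs <- colSums(x)
    if (any(rs == 0) || any(cs == 0)) {
      margin <- if (any(rs == 0)) {
        paste("row", which(rs == 0)[1])
      } else {
        paste("column", which(cs == 0)[1])
      }
      stop("Degenerate contingency table: ", margin, " sums to zero.",
           call. = FALSE)
    }
    res <- suppressWarnings(chisq.test(x, correct = correct))
  } else {
    if (is.null(g)) stop("`g` is required for the Mann-Whitney test.",
                         call. = FALSE)
    g <- as.factor(g)
    if (nlevels(droplevels(g)) != 2) {
      stop("Mann-Whitney comparison requires exactly two groups.",
           call. = FALSE)
    }
    res <- suppressWarnings(
      wilcox.test(x ~ droplevels(g), alternative = "two.sided", exact = FALSE)
    )
  }
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Expression contrast between fusion-positive and fusion-negative patients
#'
#' Per cancer type, a two-sided Mann-Whitney U test of expression TPM
#' between fusion-positive and fusion-negative patients; across cancer
#' types, a random-intercept linear mixed model `tpm ~ fusion_status +
#' (1 | cancer_type)` fitted with \pkg{lmerTest}, with the significance of
#' the fusion-status fixed effect evaluated via Satterthwaite degrees of
#' freedom. TPM is modelled on the natural scale by default; set
#' `log_transform = TRUE` for `log1p(TPM)`.
#'
#' @param tpm Numeric vector of expression values (TPM) for the driver gene.
#' @param fusion_status Logical (or two-level) vector: fusion-positive?
#' @param cancer_type Cancer-type labels.
#' @param log_transform Model `log1p(TPM)` instead of TPM.
#' @return A list with `fixed_effect` (TPM-scale coefficient for fusion
#'   positivity), `satterthwaite_df`, `p_value`, and `per_type` (tibble of
#'   per-cancer-type Mann-Whitney p-values).
#' @export
expression_contrast <- function(tpm, fusion_status, cancer_type,
                                log_transform = FALSE) {
  stopifnot(length(tpm) == length(fusion_status),
            length(tpm) == length(cancer_type))
  pos <- as.logical(fusion_status)
  if (any(is.na(pos))) stop("`fusion_status` must be TRUE/FALSE.",
                            call. = FALSE)
  y <- if (log_transform) log1p(tpm) else tpm
  dat <- tibble::tibble(y = y, pos = pos,
                        cancer_type = as.character(cancer_type))

  both_status <- dat |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$pos) == 2,
                     .groups = "drop")
  dropped <- both_status$cancer_type[!both_status$ok]
  if (length(dropped) > 0) {
    warning("Cancer type(s) with a single fusion status dropped from ",
            "per-type tests: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  per_type <- dat |>
    dplyr::filter(.data$cancer_type %in%
                    both_status$cancer_type[both_status$ok]) |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      p_value = suppressWarnings(
        wilcox.test(.data$y[.data$pos], .data$y[!.data$pos],
                    alternative = "two.sided", exact = FALSE)$p.value
      ),
      .groups = "drop"
    )

  if (dplyr::n_distinct(dat$cancer_type) < 2) {
    stop("The mixed model requires at least two cancer types; ",
         "use the per-type Mann-Whitney test instead.", call. = FALSE)
  }
  fit <- lmerTest::lmer(y ~ pos + (1 | cancer_type), data = dat)
  coefs <- stats::coef(summary(fit))
  row <- coefs["posTRUE", ]
  list(
    fixed_effect = unname(row["Estimate"]),
    satterthwaite_df = unname(row["df"]),
    p_value = unname(row["Pr(>|t|)"]),
    per_type = per_type
  )
}

#' Fusion partner distribution between approval strata
#'
#' Cross-tabulates reconciled fusion partners against a two-level grouping
#' (FDA-approved vs non-approved indication) and tests for a difference
#' with Pearson's chi-square. Partners observed in at most
#' `collapse_max` patients are collapsed into an `"other"` category before
#' testing, matching how rare partners are displayed.
#'
#' @param partner Character vector of partner gene symbols (one per
#'   patient/fusion).
#' @param group Two-level grouping vector (e.g. `approved`/`not_approved`).
#' @param collapse_max Partners seen in `<=` this many patients are
#'   collapsed (1 by default; 2 is used for drivers with many singleton
#'   partners).
#' @param correct Yates correction flag, passed to [compare_groups()].
#' @return List with `table` (partner x group contingency) and `test`
#'   (`statistic`, `p_value`, or `NULL` with a warning when fewer than two
#'   partner categories remain).
#' @export
partner_distribution <- function(partner, group, collapse_max = 1,
                                 correct = FALSE) {
  stopifnot(length(partner) == length(group))
  partner <- normalize_gene_symbols(partner)
  counts <- table(partner)
  rare <- names(counts)[counts <= collapse_max]
  partner[partner %in% rare] <- "other"
  tab <- table(partner, group)
  if (nrow(tab) < 2) {
    warning("Fewer than two partner categories after collapsing; ",
            "test skipped.", call. = FALSE)
    return(list(table = tab, test = NULL))
  }
  list(table = tab, test = compare_groups(tab, kind = "chi2",
                                          correct = correct))
}
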