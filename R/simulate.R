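#' Simulation configuration for synthetic fusion cohorts
#'
#' Describes a synthetic cohort with the statistical structure the
#' attribution pipeline assumes, in two modes. In `calibrated` mode every
#' (driver, cancer type) cell fixes exact counts of fusions per attribution
#' category, so running the full pipeline on the generated cohort is an
#' arithmetic identity against the configuration. In `stochastic` mode each
#' cell gives a prevalence and categories are drawn from `category_probs`,
#' for distribution-level property checks.
#'
#' @param mode `"calibrated"` or `"stochastic"`.
#' @param cancer_types Tibble `cancer_type`, `n_patients`.
#' @param cells Calibrated: tibble `driver`, `cancer_type`, `n_rna_only`,
#'   `n_dna_only`, `n_both`. Stochastic: tibble `driver`, `cancer_type`,
#'   `prevalence` (fraction).
#' @param multi_fusion Optional tibble `driver_a`, `driver_b`,
#'   `cancer_type`: patients carrying two driver fusions (calibrated mode).
#' @param tmb Optional tibble `fusion_positive` (logical), `tmb_class`
#'   (`TMB_low`/`TMB_high`/`TMB_unknown`), `n`, giving exact patient counts
#'   per stratum; `NULL` draws mutation counts from a common distribution.
#' @param category_probs Named probabilities for `RNA_only`, `DNA_only`,
#'   `both` (stochastic mode).
#' @param noise_rate Fraction of fusion-negative patients receiving a
#'   sub-threshold noise call in each analyte (RNA support below the LOB;
#'   DNA support below the matched-call minimum), emulating technical
#'   background that must never pass the attribution rules.
#' @param support Read-support distribution parameters: negative binomial
#'   means/dispersions per analyte (`rna_mu`, `rna_size`, `dna_mu`,
#'   `dna_size`), truncated at generation time to each category's feasible
#'   region.
#' @param expression Optional list (`gene`, `meanlog`, `sdlog`, `type_sd`,
#'   `delta_log2`): log-normal baseline TPM with per-cancer-type location
#'   offsets, and a log2-fold upward shift in patients fusion-positive for
#'   `gene`.
#' @param thr A [fusion_thresholds()] object the generated read supports
#'   must respect.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(mode = c("calibrated", "stochastic"),
                          cancer_types, cells,
                          multi_fusion = NULL, tmb = NULL,
                          category_probs = c(RNA_only = 0.17,
                                             DNA_only = 0.20, both = 0.63),
                          noise_rate = 0.01,
                          support = list(rna_mu = 30, rna_size = 5,
                                         dna_mu = 45, dna_size = 5),
                          expression = NULL,
                          thr = fusion_thresholds()) {
  mode <- match.arg(mode)
  cancer_types <- tibble::as_tibble(cancer_types)
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("cancer_type", "n_patients") %in% names(cancer_types)),
            all(cancer_types$n_patients >= 0))
  if (mode == "calibrated") {
    need <- c("driver", "cancer_type", "n_rna_only", "n_dna_only", "n_both")
    miss <- setdiff(need, names(cells))
    if (length(miss) > 0) {
      stop("Calibrated cells missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (any(cells$n_rna_only < 0 | cells$n_dna_only < 0 | cells$n_both < 0)) {
      stop("Calibrated cell counts must be non-negative.", call. = FALSE)
    }
    per_type <- tapply(cells$n_rna_only + cells$n_dna_only + cells$n_both,
                       cells$cancer_type, sum)
    avail <- setNames(cancer_types$n_patients, cancer_types$cancer_type)
    unknown <- setdiff(names(per_type), names(avail))
    if (length(unknown) > 0) {
      stop("Cells reference unknown cancer type(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    over <- per_type > avail[names(per_type)]
    if (any(over)) {
      stop("Configured fusion counts exceed patients for cancer type(s): ",
           paste(names(per_type)[over], collapse = ", "), call. = FALSE)
    }
  } else {
    need <- c("driver", "cancer_type", "prevalence")
    miss <- setdiff(need, names(cells))
    if (length(miss) > 0) {
      stop("Stochastic cells missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (any(cells$prevalence < 0 | cells$prevalence > 1)) {
      stop("Prevalences must be in [0, 1].", call. = FALSE)
    }
    if (abs(sum(category_probs) - 1) > 1e-8 || any(category_probs < 0)) {
      stop("`category_probs` must be non-negative and sum to 1.",
           call. = FALSE)
    }
  }
  if (!is.null(tmb)) {
    tmb <- tibble::as_tibble(tmb)
    stopifnot(all(c("fusion_positive", "tmb_class", "n") %in% names(tmb)),
              all(tmb$n >= 0),
              all(tmb$tmb_class %in% c("TMB_low", "TMB_high", "TMB_unknown")))
  }
  if (noise_rate < 0 || noise_rate > 1) {
    stop("`noise_rate` must be in [0, 1].", call. = FALSE)
  }
  structure(
    list(mode = mode, cancer_types = cancer_types, cells = cells,
         multi_fusion = multi_fusion, tmb = tmb,
         category_probs = category_probs, noise_rate = noise_rate,
         support = support, expression = expression, thr = thr),
    class = "cohort_config"
  )
}

# negative binomial truncated to [lower, upper] by inverse-CDF sampling
rtrunc_nbinom <- function(n, mu, size, lower = 0, upper = Inf) {
  if (n == 0) return(integer(0))
  plo <- if (lower <= 0) 0 else pnbinom(lower - 1, mu = mu, size = size)
  phi <- if (is.infinite(upper)) 1 else pnbinom(upper, mu = mu, size = size)
  u <- runif(n, plo, phi)
  out <- qnbinom(u, mu = mu, size = size)
  pmin(pmax(out, lower), if (is.infinite(upper)) out else upper)
}

#' Generate a synthetic dual-analyte fusion cohort
#'
#' Produces a patient table, RNA fusion calls, DNA structural-variant calls
#' and the ground-truth labels implied by the configuration. Read supports
#' are drawn so that each intended category satisfies the attribution rules
#' exactly: `both` fusions have RNA support at or above the call threshold
#' and a matching DNA call at or above the matched-call minimum; `RNA_only`
#' fusions have no DNA call; `DNA_only` fusions have DNA support at or above
#' the unmatched minimum with all RNA evidence at or below the LOB. Noise
#' calls in fusion-negative patients never pass any rule. Identical seed and
#' configuration give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed controlling all randomness.
#' @param domains Domain table used to place domain-intact breakpoints.
#' @param partner_pool Per-driver partner gene pool.
#' @return List with `patients`, `rna_calls`, `dna_calls`, `truth`
#'   (tibble `patient_id`, `driver`, `cancer_type`, `category`), and
#'   `expression` (tibble or `NULL`).
#' @export
simulate_cohort <- function(config, seed = 1,
                            domains = read_domain_table(),
                            partner_pool = default_partner_pool()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  thr <- config$thr

  ct <- config$cancer_types
  n_tot <- sum(ct$n_patients)
  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n_tot)),
    sample_id = sprintf("S%06d", seq_len(n_tot)),
    cancer_type = rep(ct$cancer_type, ct$n_patients),
    stage = "IV",
    age_at_biopsy = round(pmin(pmax(rnorm(n_tot, 65, 10), 18), 95), 1),
    gender = sample(c("male", "female"), n_tot, replace = TRUE),
    race = sample(c("White", "Black or African American", "Asian", "Other",
                    "Unknown"), n_tot, replace = TRUE,
                  prob = c(0.50, 0.08, 0.025, 0.045, 0.35)),
    smoking_status = sample(c("current_or_former", "nonsmoker", "unknown"),
                            n_tot, replace = TRUE,
                            prob = c(0.46, 0.345, 0.195)),
    tumor_purity = round(runif(n_tot, thr$min_tumor_purity_pct, 95)),
    metastatic_dx_date = as.Date("2019-01-01") +
      sample(0:1500, n_tot, replace = TRUE)
  )
  patients$biopsy_date <- patients$metastatic_dx_date +
    sample(0:120, n_tot, replace = TRUE)

  # expand configured cells into one truth row per fusion
  if (config$mode == "calibrated") {
    cells <- config$cells
    truth <- tibble::tibble(
      driver = rep(cells$driver,
                   times = cells$n_rna_only + cells$n_dna_only + cells$n_both),
      cancer_type = rep(cells$cancer_type,
                        times = cells$n_rna_only + cells$n_dna_only +
                          cells$n_both),
      category = unlist(lapply(seq_len(nrow(cells)), function(i) {
        rep(c("RNA_only", "DNA_only", "both"),
            times = c(cells$n_rna_only[i], cells$n_dna_only[i],
                      cells$n_both[i]))
      }), use.names = FALSE)
    )
  } else {
    cells <- config$cells
    n_type <- setNames(ct$n_patients, ct$cancer_type)
    n_pos <- rbinom(nrow(cells), n_type[cells$cancer_type],
                    cells$prevalence)
    cat_levels <- c("RNA_only", "DNA_only", "both")
    truth <- tibble::tibble(
      driver = rep(cells$driver, times = n_pos),
      cancer_type = rep(cells$cancer_type, times = n_pos)
    )
    truth$category <- cat_levels[
      sample.int(3, nrow(truth), replace = TRUE,
                 prob = config$category_probs[cat_levels])
    ]
  }
  truth$driver <- normalize_gene_symbols(truth$driver)

  # one distinct patient per fusion within each cancer type
  truth$patient_id <- NA_character_
  for (tp in unique(truth$cancer_type)) {
    rows <- which(truth$cancer_type == tp)
    pool <- patients$patient_id[patients$cancer_type == tp]
    if (length(rows) > length(pool)) {
      stop("Sampled fusion count exceeds patients for cancer type ", tp,
           ".", call. = FALSE)
    }
    truth$patient_id[rows] <- sample(pool, length(rows))
  }

  # merge configured multi-fusion pairs onto single patients
  if (!is.null(config$multi_fusion) && nrow(config$multi_fusion) > 0) {
    used <- character(0)
    for (i in seq_len(nrow(config$multi_fusion))) {
      mf <- config$multi_fusion[i, ]
      ia <- which(truth$driver == mf$driver_a &
                    truth$cancer_type == mf$cancer_type &
                    !truth$patient_id %in% used)
      ib <- which(truth$driver == mf$driver_b &
                    truth$cancer_type == mf$cancer_type &
                    !truth$patient_id %in% used)
      ib <- setdiff(ib, ia)
      if (length(ia) == 0 || length(ib) == 0) {
        stop("Cannot place multi-fusion pair ", mf$driver_a, "/",
             mf$driver_b, " in ", mf$cancer_type,
             ": no available fusions.", call. = FALSE)
      }
      host <- truth$patient_id[ia[1]]
      truth$patient_id[ib[1]] <- host
      used <- c(used, host)
    }
  }

  # TMB strata
  patients$n_nonsynonymous_mutations <- NA_integer_
  pos_ids <- unique(truth$patient_id)
  if (!is.null(config$tmb)) {
    assign_tmb <- function(ids, strata) {
      if (sum(strata$n) != length(ids)) {
        stop("TMB stratum counts (", sum(strata$n),
             ") do not match patient count (", length(ids), ").",
             call. = FALSE)
      }
      ids <- sample(ids)
      cls <- rep(strata$tmb_class, times = strata$n)
      split(ids, factor(cls, levels = c("TMB_low", "TMB_high",
                                        "TMB_unknown")))
    }
    pos_split <- assign_tmb(pos_ids,
                            config$tmb[config$tmb$fusion_positive, ])
    neg_split <- assign_tmb(setdiff(patients$patient_id, pos_ids),
                            config$tmb[!config$tmb$fusion_positive, ])
    per_mb <- thr$panel_size_mb
    for (s in list(pos_split, neg_split)) {
      idx <- match(s$TMB_low, patients$patient_id)
      patients$n_nonsynonymous_mutations[idx] <-
        sample.int(ceiling(thr$tmb_high_cut * per_mb), length(idx),
                   replace = TRUE) - 1L
      idx <- match(s$TMB_high, patients$patient_id)
      patients$n_nonsynonymous_mutations[idx] <-
        ceiling(thr$tmb_high_cut * per_mb) - 1L +
        sample.int(30, length(idx), replace = TRUE)
    }
  } else {
    patients$n_nonsynonymous_mutations <-
      rnbinom(n_tot, mu = 5 * thr$panel_size_mb, size = 2)
  }

  # evidence for true fusions
  n_f <- nrow(truth)
  ev <- NULL
  if (n_f > 0) {
    pool_by_driver <- split(partner_pool$partner, partner_pool$driver)
    truth$partner <- vapply(truth$driver, function(d) {
      p <- pool_by_driver[[d]]
      if (is.null(p)) "UNKNOWNPARTNER" else sample(p, 1)
    }, character(1))
    didx <- match(truth$driver, domains$driver)
    retained <- ifelse(is.na(didx), "5p", domains$retained_side[didx])
    dchrom <- ifelse(is.na(didx), "1", domains$chrom[didx])
    dstart <- ifelse(is.na(didx), 1e6, domains$domain_start[didx])
    dend <- ifelse(is.na(didx), 2e6, domains$domain_end[didx])
    # breakpoint on the driver side placed so the domain stays intact
    drv_pos <- as.integer(ifelse(retained == "5p",
                                 dend + sample(500:5000, n_f, replace = TRUE),
                                 pmax(1, dstart -
                                        sample(500:5000, n_f,
                                               replace = TRUE))))
    par_chrom <- as.character(sample(1:22, n_f, replace = TRUE))
    par_pos <- sample.int(2e8, n_f, replace = TRUE)

    mk_side <- function(side) {
      drv_on_side <- retained == side
      list(
        gene = ifelse(drv_on_side, truth$driver, truth$partner),
        chrom = ifelse(drv_on_side, dchrom, par_chrom),
        pos = ifelse(drv_on_side, drv_pos, par_pos),
        strand = rep("+", n_f)
      )
    }
    s5 <- mk_side("5p")
    s3 <- mk_side("3p")
    sidx <- match(truth$patient_id, patients$patient_id)
    base <- tibble::tibble(
      patient_id = truth$patient_id,
      sample_id = patients$sample_id[sidx],
      gene_5p = s5$gene, gene_3p = s3$gene,
      chrom_5p = s5$chrom, pos_5p = as.integer(s5$pos), strand_5p = "+",
      chrom_3p = s3$chrom, pos_3p = as.integer(s3$pos), strand_3p = "+"
    )
    sup <- config$support
    has_rna <- truth$category %in% c("RNA_only", "both")
    has_dna <- truth$category %in% c("DNA_only", "both")
    rna_ev <- base[has_rna, , drop = FALSE]
    rna_ev$analyte <- "RNA"
    rna_ev$read_support <- rtrunc_nbinom(sum(has_rna), sup$rna_mu,
                                         sup$rna_size,
                                         lower = thr$rna_call_min_reads)
    dna_ev <- base[has_dna, , drop = FALSE]
    dna_ev$analyte <- "DNA"
    dna_lower <- ifelse(truth$category[has_dna] == "both",
                        thr$dna_min_with_rna_match,
                        thr$dna_min_without_match)
    dna_ev$read_support <- as.integer(mapply(
      function(lo) rtrunc_nbinom(1, sup$dna_mu, sup$dna_size, lower = lo),
      dna_lower))
    # DNA-only fusions also leave sub-LOB RNA evidence for the same pair
    sub <- base[truth$category == "DNA_only", , drop = FALSE]
    sub$analyte <- "RNA"
    sub$read_support <- sample(0:thr$lob_reads, nrow(sub), replace = TRUE)
    ev <- dplyr::bind_rows(rna_ev, dna_ev, sub)
  }

  # sub-threshold noise calls in fusion-negative patients
  neg <- patients[!patients$patient_id %in% truth$patient_id, , drop = FALSE]
  if (config$noise_rate > 0 && nrow(neg) > 0) {
    drv_set <- unique(c(config$cells$driver, actionable_drivers()))
    mk_noise <- function(ids, analyte, max_support) {
      n <- length(ids)
      if (n == 0) return(NULL)
      d <- sample(drv_set, n, replace = TRUE)
      p <- paste0("NOISEP", sample.int(50, n, replace = TRUE))
      tibble::tibble(
        patient_id = ids,
        sample_id = patients$sample_id[match(ids, patients$patient_id)],
        gene_5p = p, gene_3p = d,
        chrom_5p = as.character(sample(1:22, n, replace = TRUE)),
        pos_5p = sample.int(2e8, n, replace = TRUE),
        strand_5p = "+",
        chrom_3p = as.character(sample(1:22, n, replace = TRUE)),
        pos_3p = sample.int(2e8, n, replace = TRUE),
        strand_3p = "+",
        analyte = analyte,
        read_support = sample.int(max_support + 1, n, replace = TRUE) - 1L
      )
    }
    rna_noise_ids <- neg$patient_id[runif(nrow(neg)) < config$noise_rate]
    dna_noise_ids <- neg$patient_id[runif(nrow(neg)) < config$noise_rate / 2]
    ev <- dplyr::bind_rows(
      ev,
      mk_noise(rna_noise_ids, "RNA", thr$lob_reads),
      mk_noise(dna_noise_ids, "DNA", thr$dna_min_with_rna_match - 1L)
    )
  }

  if (is.null(ev) || nrow(ev) == 0) {
    rna_calls <- empty_evidence()
    dna_calls <- empty_evidence()
  } else {
    ev <- fusion_evidence(
      patient_id = ev$patient_id, sample_id = ev$sample_id,
      analyte = ev$analyte, gene_5p = ev$gene_5p, gene_3p = ev$gene_3p,
      chrom_5p = ev$chrom_5p, pos_5p = ev$pos_5p, strand_5p = ev$strand_5p,
      chrom_3p = ev$chrom_3p, pos_3p = ev$pos_3p, strand_3p = ev$strand_3p,
      read_support = ev$read_support
    )
    rna_calls <- ev[ev$analyte == "RNA", , drop = FALSE]
    dna_calls <- ev[ev$analyte == "DNA", , drop = FALSE]
  }

  expression <- NULL
  if (!is.null(config$expression)) {
    ex <- config$expression
    types <- unique(patients$cancer_type)
    offs <- setNames(rnorm(length(types), 0, ex$type_sd %||% 0.5), types)
    tpm <- rlnorm(n_tot, meanlog = ex$meanlog +
                    offs[patients$cancer_type], sdlog = ex$sdlog)
    pos_gene <- patients$patient_id %in%
      truth$patient_id[truth$driver == normalize_gene_symbols(ex$gene)]
    tpm[pos_gene] <- tpm[pos_gene] * 2^ex$delta_log2
    expression <- tibble::tibble(
      patient_id = patients$patient_id,
      gene = normalize_gene_symbols(ex$gene),
      tpm = tpm,
      fusion_positive = pos_gene
    )
  }

  list(
    patients = patients,
    rna_calls = rna_calls,
    dna_calls = dna_calls,
    truth = truth[, c("patient_id", "driver", "cancer_type", "category")],
    expression = expression
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate blank replicate runs for LOB estimation
#'
#' Emulates the limit-of-blank experiment: fusion wild-type samples run in
#' duplicate with two reagent lots (default 24 samples x 2 lots x 2
#' replicates = 96 measurements). By default a single measurement carries
#' `outlier_value = 3` total supporting reads — the highest blank signal the
#' experiment is calibrated to — and all others are zero.
#'
#' @param n_samples,n_lots,n_replicates Blank design dimensions.
#' @param outlier_value Read support of injected outlier measurement(s).
#' @param n_outliers Number of outlier measurements (0 disables).
#' @param seed Integer seed (placement of outliers).
#' @return Tibble `sample_id`, `reagent_lot`, `replicate`, `read_support`.
#' @export
simulate_blank_runs <- function(n_samples = 24, n_lots = 2,
                                n_replicates = 2, outlier_value = 3,
                                n_outliers = 1, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(
    sample_id = sprintf("blank_%02d", seq_len(n_samples)),
    reagent_lot = sprintf("lot_%d", seq_len(n_lots)),
    replicate = seq_len(n_replicates),
    stringsAsFactors = FALSE
  )
  out <- tibble::as_tibble(grid)
  out$read_support <- 0L
  if (n_outliers > 0) {
    idx <- sample.int(nrow(out), n_outliers)
    out$read_support[idx] <- as.integer(outlier_value)
  }
  out
}

#' Simulate an orthogonal-panel truth set
#'
#' Builds positive call and truth identifier sets over a finite variant
#' universe with configurable confusion counts. The defaults reproduce the
#' assay-validation operating point: 168 true positives, 1 false positive,
#' 3 false negatives and 14,285 true negatives, giving a positive percent
#' agreement of 98.2% and negative percent agreement of 99.993%.
#'
#' @param tp,fp,fn,tn Confusion-matrix counts.
#' @param seed Integer seed (identifier shuffling only).
#' @return List with `calls`, `truth` (character vectors) and
#'   `universe_size`.
#' @export
simulate_truth_set <- function(tp = 168, fp = 1, fn = 3, tn = 14285,
                               seed = 1) {
  set.seed(seed)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  ids <- sample(sprintf("s%03d:v%05d",
                        sample.int(290, tp + fp + fn, replace = TRUE),
                        seq_len(tp + fp + fn)))
  truth <- ids[seq_len(tp + fn)]
  calls <- c(truth[seq_len(tp)],
             if (fp > 0) ids[tp + fn + seq_len(fp)] else character(0))
  list(calls = calls, truth = truth, universe_size = tp + fp + fn + tn)
}
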