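---
title: "Dual-analyte fusion attribution: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-analyte fusion attribution: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionattr)
library(dplyr)
```

## The problem

Oncogenic gene fusions (ALK, RET, ROS1, NTRK1/2/3, FGFR2, FGFR3, NRG1, and
the emerging targets BRAF and EGFR) are individually rare but collectively
common enough that missing one denies a patient a matched targeted therapy.
Clinical laboratories increasingly profile tumors with *both* a targeted
DNA panel and whole-transcriptome RNA sequencing. The two analytes disagree
often — DNA panels miss breakpoints in large introns, RNA only sees
expressed fusions — so a principled way to decide, per patient and per
driver gene, *which assay detected the fusion* is needed before any cohort
statistic (prevalence, detection gain from adding RNA, actionability
breakdown) can be computed.

`fusionattr` implements that attribution rule set and everything around it:
assay-validation statistics (limit of blank, concordance with an orthogonal
panel), cohort-selection filters, actionability stratification, the cohort
summary statistics, and a synthetic-cohort generator used to validate the
whole pipeline against known ground truth.

## The attribution model

For one patient and one driver gene:

* an RNA call is **detected** when its total supporting reads
  (junction + spanning) strictly exceed the limit of blank:
  `read_support >= 4` for the default LOB of 3;
* a DNA structural-variant call is **detected** when
  `read_support >= 35`, or `read_support >= 15` *and* an RNA call for the
  same unordered, alias-normalized gene pair is itself detected;
* the driver's category is `both` if any RNA call and any DNA call are
  detected — partners and breakpoints need not agree between analytes —
  otherwise `RNA_only` or `DNA_only`; drivers with no detected call in
  either analyte are absent from the output.

Two interpretation choices deserve a note, because the rules as usually
stated leave them open:

* **"Matching partner detected in RNA" requires RNA positivity.** A sub-LOB
  RNA call for the same gene pair does not unlock the 15-read DNA
  threshold. "Detected" means the same thing everywhere in the pipeline:
  above the LOB.
* **Pair matching is unordered.** DNA breakend orientation does not fix the
  transcript's 5′/3′ order, so (EML4, ALK) in DNA matches (ALK, EML4) in
  RNA. Symbols are uppercased and run through a small alias table first
  (e.g. `ACPP` → `ACP3`), so cross-analyte matching cannot fail on
  nomenclature.

When several RNA partners pass the LOB for one driver, the reported partner
is the one whose breakpoint keeps the driver's functionally relevant
protein domain intact and, among those, has the highest support; ties break
to the lexicographically smallest symbol (a deterministic, if arbitrary,
rule — any fixed tie-break would do). If *no* candidate keeps the domain
intact the pipeline falls back to the highest-support candidate and says
so; refusing to report a partner seemed worse than reporting the best
available one. DNA partner selection is by highest read support alone.

Domain intactness is evaluated against a per-driver table giving the
retained fusion side (`5p`/`3p`) and the domain's genomic interval; a
breakpoint exactly at a domain boundary counts as intact. The bundled
table (`domains_synthetic.csv`) carries *illustrative* coordinates chosen
for simulation work — real analyses should supply assay-specific
coordinates via `read_domain_table()`.

## Thresholds

All cutoffs live in one object:

```{r}
fusion_thresholds()
```

* `lob_reads = 3` — the highest blank observation in the LOB experiment
  (24 wild-type samples × 2 lots × 2 replicates; 95 measurements of zero
  and one of 3). `estimate_lob()` takes the maximum by construction, so the
  default call threshold is 4 total reads.
* `dna_min_with_rna_match = 15`, `dna_min_without_match = 35` — the
  conditional DNA read-support thresholds.
* `min_tumor_purity_pct = 30` — cohort entry; the boundary is inclusive
  ("a minimum of 30%" admits exactly 30%).
* `tmb_high_cut = 10` mutations/Mb, boundary inclusive (≥ 10 is high).
  `panel_size_mb` has no universal value; the default of 1.0 Mb is
  illustrative and used as-is in tests — set it to your panel.
* `ci_confidence = 0.95` for Wilson score intervals. The score interval was
  chosen over Clopper–Pearson because it reproduces the published
  validation bounds (94.97–99.40% at 168/171) and behaves well at
  proportions near 1.

## Cohort selection

`select_cohort()` retains patients with metastatic or stage IV disease, a
single unambiguous solid-tumor diagnosis, and at least one sample with
purity ≥ 30%, choosing the sample closest to but not before the
metastatic/stage IV diagnosis. Two cases the rules leave open are resolved
as follows and counted in the audit tally: patients whose eligible samples
all *precede* the diagnosis date are excluded (no fallback is defensible
when the rule says "closest to but after"), and a missing diagnosis date
with a qualifying stage uses the earliest eligible sample ("metastatic or
stage IV" reads as an OR). The audit tally always sums to the input patient
count, and the filter is idempotent.

TMB strata carry an explicit `TMB_unknown` category rather than silently
dropping patients whose mutation count is missing; cohort-level TMB tables
therefore partition the cohort exactly.

## Statistics

* Categorical contrasts use Pearson's chi-square **without** continuity
  correction (the common default at cohort sample sizes; a `correct` flag
  exists). Quantitative contrasts use the two-sided Mann–Whitney U test.
* The expression contrast fits, per cancer type, a Mann–Whitney test of
  TPM between fusion-positive and fusion-negative patients, and across
  types a random-intercept model `tpm ~ fusion_status + (1 | cancer_type)`
  via `lmerTest`, with the fixed effect's significance from Satterthwaite
  degrees of freedom. TPM is modelled on the natural scale by default
  (`log_transform = TRUE` gives `log1p`); the natural scale keeps the fixed
  effect interpretable in TPM units and matches how the contrast is usually
  reported.
* Partner-distribution tests collapse partners observed in ≤ 1 patient
  (configurable to ≤ 2 for drivers with many singletons) into `"other"`
  before the chi-square test, and refuse to test a single-category table.
* Report-style rounding (`round_paper_pct()`): one decimal place for
  shares and prevalences, two decimals below 0.2%, whole percent for
  detection increases. All functions return unrounded values; rounding is
  presentation only.

## The synthetic-cohort generator

No public data exist for this kind of dual-analyte cohort (clinical
multimodal databases are controlled-access), so the generator *is* the
test bed. It has two modes.

**Calibrated mode** fixes exact counts per (driver, cancer type,
category) cell and draws only nuisance quantities (which patients are
positive, read supports within each category's feasible region, partner
genes, demographics). Read supports are truncated negative binomials
(over-dispersed, like real support distributions), truncated so that every
intended category satisfies the attribution rules *exactly*: `both` →
RNA ≥ 4 with a matching DNA call ≥ 15; `RNA_only` → RNA ≥ 4, no DNA call;
`DNA_only` → DNA ≥ 35 with all RNA evidence at or below the LOB.
Noise calls in fusion-negative patients (1% rate by default) are capped
below every threshold. Attribution on a calibrated cohort is therefore an
arithmetic identity: the pipeline must recover every configured count, and
the tests assert that it does, at 100%.

`calibrated_pancancer_config()` encodes the default study conditions:
67,278 patients in nine cancer-type strata, 1,497 fusion-positive patients
carrying 1,501 fusions (four patients carry two driver fusions each), ALK
497, NRG1 98, 1,059 fusions in FDA-approved indications, 134 positives
among 1,102 cholangiocarcinoma patients, pancreatic and thyroid RNA-only
counts 23/63 and 2/55, and TMB strata 1,369/57,399 (low), 127/9,835
(high), 44 unknown. Where a count has no published value (the remaining
per-driver totals and most of their cancer-type spread), it was fixed once
at a value consistent with every published margin — e.g. RET + NTRK
totals of 406 pan-approved fusions so the approved margin closes at 1,059,
and 427/497 ALK fusions in NSCLC (85.9%). These are the generator's study
conditions, not tunable knobs. `calibrated_emerging_config()` does the
same for the BRAF/EGFR scenario (218 positives, 122 RNA-only, giving the
56% RNA-only share and 127% detection increase).

**Stochastic mode** draws positive counts binomially from configured
prevalences and categories from a multinomial, for distribution-level
property tests (observed prevalence within 3 binomial standard errors,
and so on).

What the generator does *not* emulate: assay failure, purity-dependent
sensitivity, correlated noise between analytes, breakpoint sequence
content, or partner-by-indication structure beyond a per-driver partner
pool. Passing tests therefore demonstrate the *pipeline arithmetic and
rule logic* on cohorts with realistic marginal structure — not assay
performance on real tissue.

## Numerical and degenerate-input choices

* Truncated negative binomial sampling is by inverse CDF, so it is exact
  and deterministic under a seed (no rejection loops).
* `wilson_ci()` is the closed-form score interval, vectorized; tests sweep
  all `k ≤ n ≤ 500` against an independently coded form (1e-12) and
  against `prop.test(correct = FALSE)`.
* PPA is reported as absent (`NA`), not 0, when `tp + fn = 0`; likewise NPA
  and the per-stratum shares on empty strata.
* Degenerate contingency tables (a zero margin) error with the offending
  margin named; single-cancer-type input to the mixed model errors with a
  pointer to the per-type test.
* Problem sizes in the test suite were chosen to keep the full run around
  a minute on one core: the calibrated pan-cancer cohort runs at full size
  (67,278 patients; generation ≈ 1 s), the null-calibration of the mixed
  model uses 200 replicates of 5 × 80 patients.

## Interface

The package is function-first: readers (`read_rna_fusions()`,
`read_dna_svs()`, `read_actionability()`, `read_domain_table()`), the
attribution engine (`attribute_cohort()` and the rule primitives),
validation (`estimate_lob()`, `wilson_ci()`, `concordance()`), cohort
statistics (`summarize_cohort()` and friends) and the generator
(`simulate_cohort()` et al.) compose in a few lines of R, as in the README
worked example; `scripts/acceptance.R` is a thin script over these same
functions that regenerates the headline numbers. No shell entry point is
shipped — an analysis of this kind is driven from R.

## Known limitations

* The bundled domain table is synthetic; partner selection on real data
  needs real domain coordinates.
* The alias table is minimal by design; heavy-duty symbol normalization
  should pre-process inputs with a full HGNC dictionary.
* VCF ingestion expects breakend pairs annotated with `GENEA`/`GENEB` and
  `SR`; other annotation dialects need a thin adapter (or the TSV mirror).
* Patient-level and fusion-level denominators differ when patients carry
  multiple driver fusions; `summarize_cohort()` reports both, and users
  should be explicit about which a percentage uses — published figures
  mix the two.
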