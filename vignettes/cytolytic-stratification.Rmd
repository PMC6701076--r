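---
title: "Cytolytic stratification of colorectal tumor cohorts: methods and design"
author: "immunoCYT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytolytic stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoCYT)
```

# The model

Cytotoxic T and NK cells kill tumor cells through granzyme A (*GZMA*) and
perforin (*PRF1*); their joint transcription is a widely used proxy for
local immune cytolytic activity. immunoCYT computes, for each sample of a
bulk RNA-seq cohort:

1. **TPM.** Each gene's raw counts are divided by its maximum transcript
   length (bp) to give a coverage estimate, columns are scaled to sum to
   $10^6$, and a small offset (default 0.01) is added to every entry.
2. **Cytolytic index.** The raw cytolytic activity is the geometric mean
   of the *GZMA* and *PRF1* TPM,
   $\mathrm{CYT} = (\mathrm{TPM}_{GZMA}\cdot\mathrm{TPM}_{PRF1})^{1/2}$,
   reported alongside as $\log_2(\mathrm{CYT}+1)$.
3. **Strata.** Tumors in the top quartile of the index are *CYT-high*,
   the bottom quartile *CYT-low*, the rest *middle*.

The strata are then associated with: nonsynonymous mutation burden and
MSI status called from the MAF (a tumor is MSI when it carries at least
one *missense* mutation in MLH1, MLH3, MSH2, MSH3, MSH4, MSH5, MSH6,
PMS1 or PMS2 — deliberately the literal missense-only rule), substitution
spectra, intratumor heterogeneity (MATH), copy-number event burden,
neoepitope loads, immune-checkpoint expression, and overall survival.
Validation-cohort scoring rules (TIL/aggregate ordinal bins, 0–2+ stain
scale, MMR IHC positivity, the Bethesda 5-marker panel, TIL/TAN median
splits, and Pfaffl RT-qPCR quantification) are provided as vectorized
scorers.

# Key statistics

* **MATH** = $100 \times 1.4826\,\mathrm{MAD}(v) / \mathrm{median}(v)$
  over a tumor's variant allele fractions $v$ — the ratio of the width to
  the center of the VAF distribution. The 1.4826 constant (normal-
  consistent MAD scaling) is the established convention; we require at
  least 5 usable VAFs, below which the score is reported unavailable.
* **Copy-number events**: segments with mean $\ge 0.6$ (amplification)
  or $\le -0.4$ (deletion), boundaries inclusive, counted per sample; the
  literal sums of qualifying segment means are emitted as an auxiliary
  column. Segment means are used as provided (no re-centering, no length
  weighting).
* **Neoepitopes**: a peptide is a CDN when its mutant IC50 $< 50$ nM, an
  ADN when its differential agretopicity index
  $\mathrm{DAI} = \mathrm{IC50}_{wt}/\mathrm{IC50}_{mut}$ strictly
  exceeds 10 (MHC-I) or 4 (MHC-II), and a priority neoepitope when it is
  both, or a CDN from a frameshift. All inequalities strict, matching
  the printed cutoffs; a log2 DAI column is emitted for inspection but
  never used for calls.
* **Group tests**: Mann–Whitney (two groups) or Kruskal–Wallis (more),
  with Benjamini–Hochberg adjustment within each analysis family (DE
  genes, checkpoint panel, gene–stratum associations, Fisher pairs) —
  never pooled across families. Fisher's exact test (two-sided) drives
  co-occurrence and gene–stratum association. Kaplan–Meier curves and
  Mantel–Cox log-rank tests use the survival package.

# Tunable parameters

All thresholds live in a `CytConfig` (YAML-serializable via
`loadConfig()`/`saveConfig()`); defaults are the analysis values:

| parameter | default | unit / meaning |
|---|---|---|
| `cytGenes` | GZMA, PRF1 | genes in the geometric mean |
| `tpmOffset` | 0.01 | TPM units, added to remove zeros |
| `quartileFraction` | 0.25 | fraction per extreme stratum |
| `mmrGenes` | the nine MMR genes | MSI calling panel |
| `cdnIc50Cutoff` | 50 | nM, strict `<` |
| `daiCutoffMhc1` / `daiCutoffMhc2` | 10 / 4 | unitless, strict `>` |
| `scnaAmpCutoff` / `scnaDelCutoff` | 0.6 / −0.4 | log2-ratio, inclusive |
| `cpmFilter` / `cpmSampleFraction` | 1 / 0.5 | keep gene if CPM ≥ 1 in ≥ 50% |
| `deFdr` | 0.1 | BH FDR for DE calls |
| `survivalAlpha` | 0.05 | log-rank threshold |
| `tilMedian` / `tanMedian` | 5 / 2 | %, median dichotomization |
| `mmrPositivePct` | 10 | %, IHC positivity (≥) |

# Numerical choices and tie-breaks

* **Offset order.** The offset is added *after* scaling to $10^6$, so
  pre-offset columns sum to exactly $10^6$ and every post-offset entry is
  at least 0.01; the offset exists to keep logarithms and geometric means
  finite, which only requires it on the final scale.
* **Index definition.** The reported index is $\log_2(\mathrm{CYT}+1)$.
  Stratification ranks the raw geometric mean, so this choice cannot
  change strata membership.
* **Quartile ties.** Samples are ranked by raw activity with ties broken
  lexicographically by sample ID — the stratification is deterministic
  and invariant to input order.
* **Boundary conventions.** TIL count exactly 215 scores 2; exactly 5
  aggregates score 1; 0% staining scores 0; IHC positivity uses ≥ 10%;
  values equal to a dichotomization median go to the *low* group. Each is
  the conservative (lower) bin where the published bins leave the point
  open, and each is configurable.
* **Degenerate inputs.** All-zero sample columns, constant genes in
  median splits, groups below minimum size, zero-variance correlations,
  zero median VAFs and zero-depth records are rejected or reported
  unavailable with explicit diagnostics — never silently dropped.
* **Dialect drift.** MAF variant classifications outside the controlled
  vocabulary are retained and flagged, and excluded from nonsynonymous
  counts, so novel dialects do not abort runs.

# Documented simplifications

* **Differential expression** replaces limma-voom (precision weights,
  empirical-Bayes moderation, quantile normalization) with Welch's t on
  log2 CPM (0.5-count stabilizer). The package's claims about DE are
  therefore calibrated by planted-effect recovery and null false-positive
  control, not by reproducing any particular gene list.
* **Gene–stratum association** uses a per-gene Fisher exact test of
  mutated-vs-not against CYT-high/CYT-low rather than the regression
  framework referenced upstream, which is not specified in enough detail
  to reproduce.
* **Two-gene synergy** dichotomizes each gene at its cohort median
  (ties low). Server-side cutpoint optimization used by public synergy
  services is deliberately not emulated: median splits are deterministic
  and standard. Both `both_low` vs rest and `both_high` vs rest log-rank
  tests are emitted, plus the three-group curves.
* **VAF clustering** for clonality is reduced to the MATH statistic; no
  mutation clusters are inferred.
* **Stratification scope.** `stratifyCyt()` accepts a `by` factor so
  quartiles can be formed within each dataset (e.g. colon and rectum
  cohorts separately); the synthetic cohort is single-dataset so the
  pipeline stratifies it as one.

# The synthetic cohort generator

`simulateCohort()` emulates a TCGA-like colorectal cohort so that every
stage is testable without downloads. Per tumor it draws a latent
standard-normal cytolytic activity $a$; the planted tier is the top and
bottom quartile of $a$. Components:

* **Expression**: negative-binomial, per-gene log-normal baselines and
  dispersions; *GZMA*/*PRF1* means scale as $2^{2.5a}$ with tight
  dispersion (markers of this expression level are measured precisely,
  and the planted tier must be recoverable from the computed index);
  checkpoint genes scale as $2^{0.8a}$ and gain $2^{1.5}$ in MSI tumors;
  library sizes vary at least two-fold; one all-zero gene exercises the
  CPM filter.
* **Mutations**: Poisson nonsynonymous burden, mean 300 (MSI) / 60 (MSS),
  doubled in the high tier; every MSI tumor carries a planted missense
  MMR mutation and MSS tumors none; Beta(5, 5) VAFs thinned binomially at
  depth 80; C>T-dominated substitution spectrum; ~30% additional silent
  records.
* **Copy number**: Poisson beyond-cutoff events, mean 40 in the low tier
  vs 20 otherwise, amplification/deletion split evenly, background
  segments strictly inside the cutoffs.
* **Affinities**: ~2 candidate peptides per missense mutation; mutant
  IC50 log-normal (median 500 nM, log-sd 1.8), putting about 10% under
  the 50 nM CDN cutoff; DAI log-normal (median 1, log-sd 1.2).
* **Survival**: exponential event times, administrative censoring
  Uniform(0, 240) months, hazard ratio 1.8 on the below-median-activity
  half. The baseline hazard (0.025/month) and follow-up window were set
  by a design-power calculation: the planted both-low effect should be
  detectable by the log-rank test with ~95% power at the default 200
  tumors, which requires on the order of 165 observed events. The ground
  truth records the hazard group separately from the quartile tier.

`nullEffects()` removes every planted effect at once for calibration
runs. All randomness flows from the configuration seed; identical
configurations give identical cohorts.

**What the generator does not emulate** — and hence what green tests do
not show about real data: gene–gene correlation beyond the planted
latent factor, GC/length biases, subclonal copy-number structure and
per-locus recurrence, linkage between specific mutations and expression,
non-exponential hazards, and informative censoring. Passing tests
demonstrate that the operations implement their definitions and recover
effects of the stated sizes under the stated noise — not that the
biological conclusions transfer to any particular cohort.

# Problem sizes used by the test-suite

Unit tests run on cohorts of 8–80 tumors with 60–200 genes. The
recovery checks use the generator defaults (200 tumors, 2,000 genes,
100 replicates per effect family; the differential-expression power
check uses 50 samples per stratum at the planted 1.5 log2 fold-change),
and the null-calibration checks use 200 replicates of a 60-tumor,
100-gene cohort per family, testing each family's p-values against
uniformity by Kolmogorov–Smirnov at $\alpha = 0.01$. These sizes were
chosen so a full run stays comfortably interactive while keeping the
binomial noise of replicate proportions well inside the asserted
margins.

# Worked example

```{r example}
cohort <- simulateCohort(simConfig(nTumor = 60, nGenes = 300, seed = 1))
res <- runPipeline(cohort)
head(res$samples[, c("sample_id", "cyt_index", "stratum", "msi_status",
                     "nonsyn_count", "total_count")])
subset(res$tests, comparison %in%
       c("nonsyn_burden_msi_vs_mss", "scna_total_high_vs_low",
         "both_low_vs_rest"))
```

# Known limitations

* MSI calling from mutations is a coarse proxy (the literal
  missense-in-MMR rule); the Bethesda marker-panel and IHC dMMR callers
  are provided for cohorts with those data.
* The DE test is unmoderated; for small strata a limma-style analysis
  on the exported matrix is preferable.
* Affinities are numeric inputs: no peptide enumeration or binding
  prediction is performed.
* Segment means are thresholded as provided; cohorts needing
  re-centering must do so upstream.
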