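---
title: "Methods: ETS fold-change filtering, cohort testing and panel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ETS fold-change filtering, cohort testing and panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pea3targets)
```

## The study design being modelled

Two prostate cancer cell lines (MDA-PCa-2b and PC3) co-overexpress the
PEA3-family ETS transcription factors ETV1 and ETV4, which makes their
individual transcriptional programmes inseparable by observation alone.
The design this package computes over therefore combines five perturbation
models, each with one control and two independently manipulated
populations:

| model | cell line | manipulation | ETS |
|---|---|---|---|
| shETV1-LNCaP | LNCaP | shRNA silencing | ETV1 |
| shETV1-MDA-PCa-2b | MDA-PCa-2b | shRNA silencing | ETV1 |
| shETV4-MDA-PCa-2b | MDA-PCa-2b | shRNA silencing | ETV4 |
| shETV4-PC3 | PC3 | shRNA silencing | ETV4 |
| PNT2-ETV1 | PNT2 (benign) | de novo overexpression | ETV1 |

Expression is handled throughout in log2 space and fold-changes are
computed from log2 differences. The data the design produces are
single-array-per-population normalized intensities; the log2 convention
gives a symmetric noise model and exact signed-FC algebra. This is a
package-level choice — the platform convention for normalized exon-array
intensities — and everything downstream is stated in terms of it.

## Fold-change algebra

`signed_fold_change()` maps a log2 difference `d` to `+2^d` (d ≥ 0) or
`-2^-d` (d < 0): a 2-fold decrease is written −2.0, so |FC| ≥ 1 always and
the up/down thresholds ±1.5 and ±1.2 act symmetrically.

**Clone consensus** (`consensus_model_fc()`): a gene is considered
differentially expressed in a model only when both manipulated populations
change in the same direction; the consensus is the arithmetic mean of their
signed FCs (a geometric option — mean of the log2 differences — is
available, since "average fold-change" does not dictate the scale of
averaging). A population FC of exactly +1.0 carries no direction and is
treated as agreeing only with another +1.0; any mixed-direction pair is
*undefined* (`NA`), and undefined entries are never coerced to a neutral
value.

**Association orientation** (`association_fc()`): to compare silencing and
overexpression models the consensus FC is re-expressed relative to ETS
level — silencing flips the sign (a gene that falls upon knockdown is
positively associated with the ETS), overexpression is unchanged. All set
filters below operate on this association axis; it is the only orientation
under which the three include-models of the invasion-and/or-AIG rule
(two silencing, one overexpression) can agree on a direction.

## Target and phenotype set rules

Comparators follow the wording of the thresholds: the target rules use
"no less than", i.e. `|FC| >= 1.5`; the phenotype rules use "higher than",
i.e. strict `>`. Both comparators are arguments, not constants.

* **ETS-specific targets**: qualifying direction in *both* silencing models
  of that ETS (LNCaP + MDA for ETV1; PC3 + MDA for ETV4). The PNT2-ETV1
  overexpression model is excluded from target filtering (benign,
  non-tumorigenic background), and the ETS genes themselves are excluded
  from their own candidate lists.
* **ETS-shared targets**: qualifying direction in at least 3 of the 4
  silencing models.
* **Report bookkeeping**: the specific and shared rules are computed
  independently, so a strongly shared gene also passes both specific rules.
  The report exposes the raw rule outputs, but its headline sets use Venn
  semantics — a gene meeting the shared rule is classed as shared and
  removed from the specific lists — because that is the only reading under
  which the inclusion–exclusion identity
  `union = |ETV1| + |ETV4| + |shared| − |inverse|` is exact. Genes in both
  specific lists with *opposite* directions (up with ETV1, down with ETV4)
  are flagged `inverse` and kept in both; same-direction double members are
  also reported and flagged, a case the filtering rules themselves do not
  address.
* **Phenotype rules** (`invasion_or_aig_genes()`, `aig_genes()`,
  `invasion_genes()`): include/exclude cascades as in the README. On the
  include side an undefined entry disqualifies the gene (it cannot show a
  consistent profile there); on the exclude side an undefined entry does
  *not* fire the exclusion, for the same reason. Exclusion requires the
  same direction as the include signal; an opposite-direction change in an
  exclude model is no ground for exclusion. Where a rule lists two exclude
  models, *both* must fire. The three rules are computed independently and
  their overlaps reported, not enforced.

Monotonicity properties (raising an include cut shrinks a set; raising an
exclude cut enlarges it; specific/shared sets shrink as the threshold
rises) are asserted by property tests, and all rules are checked against
brute-force predicate enumeration on random profiles.

## Statistical components

* **Comparative Ct**: `2^-(Ct_target − mean(Ct_refs))`; multiple reference
  genes (18S, GUSB) are combined by the arithmetic mean of Cts, equivalent
  to a geometric mean of linear quantities. Median-centering against a
  tumour series divides by the series median (even count: mean of the two
  central values), so the centered series has median exactly 1. The outlier
  flag threshold is configurable and carries no claim of a canonical value,
  because outlier calling on the centered scale is inherently a judgement
  call.
* **Student's t** (`two_sample_t()`): classical pooled-variance t on the
  relative-to-control ratios of independent experiments (not on replicate
  wells), unpaired, two-sided; Welch behind a flag. Zero pooled variance is
  resolved by convention: p = 1 for equal means, p = 0 otherwise.
* **Mann–Whitney** (`mann_whitney()`): exact distribution when
  `min(nA, nB) <= 8` and the data are tie-free, otherwise the normal
  approximation with tie and continuity correction. Exact p-values are
  verified against full enumeration of rank assignments for all
  configurations with `nA + nB <= 10`.
* **Covariate independence**: "independent of age and PSA" is
  operationalized as a non-significant Mann–Whitney difference (p ≥ 0.05)
  of each covariate between the compared groups. This is an interpretation
  — stratification or regression adjustment would be alternatives — and the
  report accompanies the gene associations without ever gating them.
  A covariate missing for (nearly) all samples is marked not assessable.
* **No multiple-testing correction** is applied by default: raw p-values
  are compared against 0.05, matching the analysis being reproduced; a
  Benjamini–Hochberg column is available behind `adjust = TRUE`.

## Panel evaluation

The panel rule calls a tumour positive (predicted pT3) when at least `k` of
the panel genes lie strictly below their per-gene `q`-th percentile.
Percentiles use linear interpolation at position `(n−1)·q/100` (the type-7
quantile; a nearest-rank variant is available — at n = 50 the two can
differ). Thresholds are computed on the evaluable tumours themselves
(staged carcinomas), as a retrospective analysis implies; a frozen
external threshold would be the prospective variant. Strict `<` flagging
guarantees that under ties the "bottom q%" never exceeds q% of samples.

Evaluation against pT2/pT3 stage uses the Pearson chi-square without
continuity correction (1 df, two-sided); degenerate tables (an empty
margin) yield `NA` rather than a fabricated p, and metrics with zero
denominators are `NA`. The cut-off grid defaults to (10, 1), (25, 2),
(50, 4) and the scan ranks rules by ascending p — note that the minimum p
over a scanned grid is subject to selection, which the null-calibration
test quantifies (≤ 15% of label-permuted cohorts reach p < 0.05 on any of
the three rules).

## The synthetic generators

`gen_cellline_experiment()` emits the five models above (two manipulated
populations each, one array per population, each model with its own
control) with per-gene baselines ~ N(8, 1) log2 units and i.i.d. Gaussian
noise per cell, sd 0.1 by default. Planted roles shift the manipulated
populations in the association direction of the role (sign inverted in
silencing models on the observed axis):

* target roles (`ETV1_target_*`, `ETV4_target_*`, `shared_*`, `inverse`)
  at |log2FC| 1.0 (2-fold) by default;
* phenotype roles: `aig_assoc` and `invasion_assoc` at 2-fold in their
  include models; `invasion_or_aig_assoc` at log2(1.35) — the broad rule's
  scientific point is catching weak but concordant changes, so its planted
  effect sits inside the (1.2, 1.5] band: above the 1.2 inclusion cut and
  below the 1.5 cut of the stricter rules. With the default 2-fold effect
  those genes would simply *be* single-phenotype genes and the three
  planted classes would not be distinguishable.

`gen_tumor_cohort()` emits 9 NPT + 50 PCa with subtype counts 14/22/14
(12 of the 14 PEA3 tumours ETV1-rearranged), stage 24 pT3 / 26 pT2 and
Gleason 25 high / 25 low among carcinomas, age ~ N(63, 7) years and PSA
~ logNormal(log 8, 0.4) ng/ml independent of stage by construction
(optional shifts exist for the covariate-dependence tests). The pT2/pT3
split of the real 50-tumour series is not published; 24/26 is the
prevalence most consistent with the printed panel metrics and is a
configurable default, not a fact. Cohort roles shift group means by the
planted log2FC (`stage_low_in_pT3` down in pT3, `gleason_assoc` down in
high-Gleason, `pea3_up` up in PEA3 tumours).

What the generators deliberately do **not** model: probe-level effects,
batch and array-quality artefacts, correlated gene modules,
mean–variance dependence, and tumour purity. Passing tests on this data
demonstrate that the *procedures* are implemented correctly and have the
expected operating characteristics under their own assumptions — not that
the original biological gene lists would be recovered from real arrays.
No attempt is made to reproduce the identity of the study's actual gene
sets (the raw arrays are not deposited); published per-gene lists enter
only as documentation.

## Problem sizes and determinism

The simulation studies use ~1000 null genes per cell-line experiment,
100-gene cohorts for panel power (the panel needs only its seven genes plus
background), 500 random instances for oracle-equivalence checks, 500 label
permutations for calibration and 100 seeds for the power and null regimes —
sizes at which every Monte-Carlo bound tested has comfortable margin while
the whole suite runs in well under a minute per study. All generators
require an explicit seed and are byte-reproducible given it; the pipeline
manifest records the configuration and an md5 checksum per output so reruns
can be verified file by file.

## Known limitations

* The exact/approximate switch in `mann_whitney()` follows sample size and
  ties only; for moderate samples with heavy ties the normal approximation
  is the only route offered.
* `covariate_independence()` accepts the null (p ≥ 0.05 declared
  "independent"), inheriting the usual caveat that non-significance is not
  evidence of no effect.
* The panel evaluation offers no ROC/AUC machinery; it reproduces fixed
  (q, k) rules and their 2×2 metrics only.
* Fold-change filtering is threshold-based by design; no moderated
  variance or shrinkage statistics are involved anywhere.
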