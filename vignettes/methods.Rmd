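---
title: "Methods: acute phosphoproteomic perturbation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acute phosphoproteomic perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoresponse)
```

This vignette documents the models and procedures the package
implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-cohort generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The measurement model and normalization

The input is a multiplexed bead assay: for each (sample, condition,
replicate) well, a median fluorescence intensity (MFI) per
phosphosite-resolved analyte, plus a GAPDH loading control per well.
Each sample is exposed to each drug once, at a clinically anchored
concentration, for one hour, alongside three DMSO vehicle wells.

`normalize_plate()` turns wells into signed perturbation profiles in
three steps:

1. **Loading-control normalization.** Each analyte MFI is divided by
   the same well's GAPDH MFI and log2-transformed. This removes
   per-well scale (lysate amount, bead count), which we verify as an
   exact invariance: multiplying all intensities of a well by any
   constant leaves every downstream change untouched.
2. **Median-centering on vehicle wells.** Per analyte, the median log2
   ratio across all DMSO wells of the plate is subtracted everywhere.
   This anchors intermediate values on the plate's vehicle state.
3. **DMSO referencing.** The change for (sample, drug, analyte) is the
   centered value of the drugged well minus the mean centered value of
   that sample's DMSO replicates.

Step 2 cancels algebraically in step 3; it is retained because the
centered intermediate values are interpretable on a plate-anchored
scale and the decomposition makes each step testable. With a single
noiseless DMSO well the output reduces exactly to
`log2(drug/DMSO)` per analyte, which the tests assert on random toy
plates.

Zero or negative MFIs (possible after background subtraction upstream)
are clamped to half the smallest positive intensity on the plate, with
a warning; a non-positive GAPDH is unrecoverable and is an error. The
floor factor is configurable.

**Regulation counting** (`count_regulated()`) uses a threshold `tau` on
the log2 scale, default 0.1. The threshold is a free parameter of the
analysis, not an estimated quantity: any count of "regulated"
phosphoproteins is conditional on it.

**Assay concentrations** are set from the clinical maximum plasma
concentration via the equal-free-concentration rule
`cmax × fu_plasma / fu_medium` (`adjust_cmax_for_binding()`), where
`fu` is the unbound fraction in plasma and in 20%-FBS medium. This
assumes binding equilibrium and that only unbound drug is active.

## Sensitivity quartiles and predictors

Per drug, samples are sorted by GI50 (the 72-hour growth-inhibition
IC50) ascending and cut into four contiguous near-equal groups;
remainders go to the earlier groups, ties break by sample id, so
labelling is deterministic and invariant under any strictly monotone
transform of GI50. **Q1 is the most sensitive quartile** by this
package's convention; a `direction` flag reverses it.

`cross_validate_predictor()` implements Monte-Carlo cross-validation:
`n_folds` (default 100) independent random stratified splits holding
out 15%. We read "100-fold cross validation with a rotating leave-out"
as repeated random splits rather than a 100-way partition, which a
35-sample panel cannot support. Feature selection — random-forest
recursive elimination dropping the lowest-importance 20% per round —
runs strictly inside each training split; the fold worker
(`.fit_predict_fold`) is written so that tests can assert directly that
garbling the held-out rows and labels leaves the selected features
unchanged (no leakage).

AUCs are one-vs-rest per quartile from a single multiclass model. The
headline number pools all out-of-fold prediction scores before
computing the AUC; per-fold mean ± SD are reported alongside. Folds
whose holdout lacks a class skip that quartile's per-fold AUC and are
counted. `cohort_cv()` additionally pools predictions across drugs for
a cohort-level AUC — at 35 samples per drug, a per-drug pooled AUC
still carries a standard error near 0.1, so only the cohort-level
number is stable enough to headline.

Hyperparameters the source design leaves open, fixed here and exposed
as arguments: 500 trees per forest, impurity-decrease importance,
elastic-net mixing α = 0.5 with the penalty chosen by internal
class-stratified cross-validation (falling back to a mid-path penalty
when a class is too small to cross-validate). Elastic-net weights are
reported on standardized features (zero mean, unit variance), which is
what makes the ±0.1 significance rule scale-meaningful.

The genomic baseline runs the identical protocol on three binary
mutation flags (EGFR, KRAS, PIK3CA). `mutation_quartile_enrichment()`
collapses quartiles to sensitive (Q1∪Q2) vs resistant (Q3∪Q4) halves
and applies the Yates-corrected chi-square (correction clipped at zero,
margin-zero tables return p = 1 with a warning).

## The environmental perturbation score

For a network node $v$ with direct neighbors $N(v)$ and analytes $a$
mapping to nodes:

$$\mathrm{EPS}(v) = \sum_{u \in N(v)} \sum_{a \mapsto u} |\Delta_a|$$

Choices embedded here, and why:

- **Neighborhood = distance-1, self excluded.** The score is meant to
  flag signalling junctions whose *environment* is perturbed; excluding
  the node's own change makes it literally true that a node can rank
  first while itself unperturbed. An `include-self` weight
  (`self_weight`, default 0) is available.
- **Plain unweighted sum.** Degree normalization and edge weights are
  deliberate non-defaults: the score is meant to reward highly
  connected, highly perturbed environments. The data model keeps a
  hook for weights.
- **Site-level entities.** Proteins carrying two or more measured
  phosphosites are ranked once per site. With `self_weight = 0` both
  sites inherit the protein's neighborhood sum and tie; the per-site
  self-term is the mechanism by which their ranks can separate. How
  site ranks separated in the motivating analyses is not
  reconstructible from the published text; the default keeps the pure
  neighborhood score.
- **Ranking** covers tractable (druggable) entities only, descending
  EPS, ties assigned the minimum rank of the tied block with output
  order fixed by entity id.

`eps_score()` is validated against an independent brute-force triple
loop over (node, neighbor, analyte) on random graphs, and satisfies two
structural properties asserted in tests: linearity in |changes| (with
rank invariance) and monotone non-increase under edge removal.

Combination logic: `nominate_combinations()` orders candidate partners
by the best rank among their targets in the anchor's ranking;
`topk_concordance()` counts, over screen records whose Bliss summary
exceeds 0.1, those whose partner target ranks within the top k.

## Bliss synergy

Single-agent fractional effects (effect = 1 − viability) combine under
Bliss independence as `fa + fb − fa·fb`; the excess of the observed
combined effect over this expectation measures synergy, and the grid
summary is the mean excess (max and top-quartile-mean are available —
the published analyses report single Bliss scores per combination
without defining the reduction, so the reduction is configurable with
mean as default). Observed effects are clamped to [0, 1] with a logged
warning; missing cells are excluded from the summary, more than 25%
missing is an error. The ordered-pair screen design (anchor at a fixed
concentration, partner over a dose range) reconciles a 252-record
ordered screen with its 21-combination unordered heatmap view; the
pipeline emits both.

## Rank-bias and permutation statistics

The validation statistic compares the EPS ranks attained by partner
targets in the top versus bottom Bliss-quartile records by a two-sided
Mann–Whitney U. One rank per record (the partner's best target) is the
default; an "all target sites" mode exists because the published
description is ambiguous about the sampling unit. Exact p-values are
used when both groups have ≤ 8 observations (closed-form null
distribution when untied; full enumeration for small tied samples),
otherwise the tie-corrected, continuity-corrected normal approximation;
tests pin the exact path to closed-form examples and bound the
exact-approximate gap at moderate sizes.

`permutation_robustness()` locates the observed p in a null built by
shuffling rank assignments across entities *within each (sample,
anchor) ranking universe* — this preserves each universe's rank support
exactly, which a global shuffle (also available) does not. The
empirical quantile counts ties as half; with discrete rank data exact
p-value ties between the observed and permuted statistics are common,
and the mid-tie definition is the one that is uniform under the null,
which the calibration test (KS over 200 seeds) verifies.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions under which the pipeline is validated. Defaults: 35 cell
lines and 16 patient-derived samples, 7 drugs, a 52-analyte panel over
51 proteins (one protein carries two phosphosites, exercising
site-level ranking), a 60-node interaction network, and a combination
screen of all ordered drug pairs in 6 cell lines (252 records). One
seed drives everything, with fixed per-stage offsets so stages can be
regenerated independently.

- **Network.** Barabási–Albert scale-free (3 edges per added node):
  curated interactomes are hub-dominated, and the EPS neighborhood sum
  is intrinsically degree-sensitive, so degree structure is the one
  network property the generator must get right. Drug targets are
  drawn with probability proportional to degree — targeted kinase
  inhibitors hit central signalling proteins — and are always
  tractable; half of all nodes are tractable by default.
- **Perturbations.** Inhibition propagates locally from each drug's
  target: mean change −`effect_size` × 0.5^distance, truncated beyond
  distance 2; two feedback analytes per drug (beyond the propagation
  radius) get mean +`effect_size`/2; Gaussian noise SD `noise_sd`
  (default 1, inflated 1.5× for patient samples to mimic the noisier
  *ex vivo* material). Defaults `effect_size = 2`, `noise_sd = 1` give
  a signal-to-noise regime in which the planted structure is
  recoverable but not trivial.
- **Sensitivity.** log10 GI50 = baseline + `signature_coef` × (sum of
  the sample's observed changes at the drug's 5 signature analytes) +
  Gaussian noise (SD 0.3 log10 units). Setting `signature_coef = 0`
  yields the exact global null (GI50 pure noise) used for calibration;
  note that `effect_size = 0` does *not*, since GI50 tracks the
  observed noisy changes. The true quartile is recorded from the
  noiseless score.
- **Genotypes.** Independent Bernoulli(0.2) flags — a decoy
  uninformative by construction.
- **Screen.** Single-agent effects follow Hill curves through the
  simulated GI50s (anchor fixed at half its GI50, partner over a
  100-fold range); the combined effect is the Bliss expectation plus a
  planted excess plus noise (SD 0.02), clamped to [0, 1]. The planted
  excess decays linearly with the partner target's EPS rank in the
  anchor's ranking (maximum 0.45 at rank 1, zero beyond rank ~21), so
  that concordance between EPS and synergy is recoverable by
  construction and — with the default geometry — roughly half of all
  252 records clear the 0.1 synergy threshold, the synergy prevalence
  regime the validation statistics are meant for. An explicit
  `synergy_pairs` table overrides the rank-aligned planting.

What the generator deliberately does **not** emulate: batch and plate
effects, analyte cross-reactivity, heavy-tailed measurement noise,
realistic mutation spectra or mutation-response coupling, growth-rate
confounding of GI50, and dose-design irregularities. Passing tests
therefore demonstrate that the pipeline recovers the structure it
assumes when that structure is present, and stays calibrated when it is
absent — not that real screens satisfy those assumptions.

## Problem sizes and numerical choices in the validation suite

- The predictor-recovery check runs the full study geometry (35 × 7 ×
  52, 100 splits, in-fold RFE to 10 features); the null-calibration
  check uses a 60-cell-line null cohort because the pooled null AUC at
  n = 35 has standard error ≈ 0.05, too coarse for a meaningful
  [0.4, 0.6] calibration band, while n = 60 brings it to ≈ 0.03.
- The permutation-uniformity check runs 200 outer seeds of a reduced
  cohort (8 lines, 5 drugs, 16 analytes, 199 inner permutations) —
  uniformity of the empirical quantile is size-free, so the small
  geometry tests the same property at a fraction of the cost.
- The rank-bias recovery check uses the full 10,000-permutation null.
- Exact floating-point assertions are used where the arithmetic is
  exact (noiseless planted excess, EPS oracle equivalence at 1e-12);
  boundary comparisons on the Bliss lattice allow 1e-12 slack for
  round-off at the fb = 1 edge.

## Known limitations

- EPS rankings on noisy profiles are dominated by node degree; the
  score has no built-in correction for it (by design), so rankings
  should be read against the network's degree structure.
- The Mann–Whitney normal approximation is used inside the permutation
  loop regardless of group size for speed; at the default quartile
  sizes (≥ 60 per group) the exact path is never applicable anyway.
- `run_pipeline()` resumes only the simulate stage from checksummed
  outputs; downstream stages are cheap relative to simulation and are
  recomputed.
- The pipeline assumes one plate per cohort; multi-plate harmonization
  beyond the per-plate normalization is out of scope.
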