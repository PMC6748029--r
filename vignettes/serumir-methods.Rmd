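---
title: "serumir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{serumir: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumir)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the published
procedure left the design open.

## 1. Subgroup classification

Monocytes secrete IL-1β (pro-inflammatory) and IL-10 (counter-regulatory)
after overnight stimulation; their ratio is a compact readout of
innate-immune set-point. For each subject and each culture condition
(medium, LPS, zymosan, CL097) the ratio is compared with the control
cohort's per-condition mean μ_c and sample SD σ_c (n − 1 denominator; the
estimator was not published, and the sample SD is the conventional
choice):

* **high** fires when the ratio exceeds μ_c + 2σ_c in at least
  `high_2sd_min_conditions` (default 1) conditions, or exceeds μ_c + σ_c
  in at least `high_1sd_min_conditions` (default 3) conditions;
* **low** fires when the ratio falls below μ_c − σ_c in at least
  `low_1sd_min_conditions` (default 1) condition;
* **normal** covers all ratios inside (μ_c − σ_c, μ_c + σ_c), or exactly
  one condition in (μ_c + σ_c, μ_c + 2σ_c].

Design choices where the published wording is open:

* *"more than two culture conditions"* is read literally as ≥ 3 of the four
  conditions; `high_1sd_min_conditions = 2` is a plausible alternative and
  is configurable.
* The unstimulated **medium** condition counts as a culture condition
  (the published correlation tables report medium-condition ratios);
  `conditions_used` can restrict the set.
* **Rule gap**: a subject with exactly two conditions in the +1SD..+2SD
  band and none beyond matches neither the high rule (needs 3) nor the
  printed normal rule (allows 1). The package assigns *normal* — the
  nearest printed rule — and sets a `rule_gap` flag rather than invent a
  fourth class.
* **Conflict**: the high and low rules can fire simultaneously. All
  source-cohort subjects were classified, so conflicts there were absent
  or silently resolved; the default `strict` policy returns `ambiguous`,
  and an opt-in `max_abs_z` policy lets the larger |z| tail win.
* Cells with a zero or assay-floor-censored IL-10 denominator are invalid
  and excluded from the condition counts — never imputed, never allowed to
  produce infinities.
* Boundary convention: the printed inequalities are strict; a ratio equal
  to μ_c + σ_c (a measure-zero event) is counted in the lower region.
* Multi-timepoint subjects: identical labels keep the label; normal + low
  resolves to low (the handling reported for the one such subject in the
  source cohort), symmetrically normal + high to high; any high + low mix
  or ambiguous component yields `ambiguous`.

## 2. Bioenergetic parameters

The 4-phase extracellular-flux protocol (baseline, oligomycin, FCCP,
antimycin A + rotenone; three repeated OCR measurements per phase over an
18-minute window, in pMol/min) is summarized per phase by the **mean** of
its measurements — the published text states three repeats but not the
summary statistic; `median` and `last` are available. Parameters:

| parameter | definition |
|---|---|
| non-mito | OCR after antimycin A + rotenone |
| ALR | baseline − oligomycin |
| PLR | oligomycin − non-mito |
| basal | ALR + PLR (≡ baseline − non-mito) |
| MRC | FCCP − non-mito |
| RC | MRC − basal |

`basal` and `RC` are computed *from* ALR/PLR/MRC so that the identities
basal = ALR + PLR and RC = MRC − basal hold to the last bit, not merely to
rounding. Negative derived values are reported with QC flags, never clipped
— clipping would bias the downstream correlation screens. Efficiency
ratios ALR/PLR and MRC/PLR are undefined (NA, flagged) when PLR ≤ 0.

## 3. Count normalization and differential expression

The DE engine is authored in this package (not delegated to a library) so
that every step is inspectable and testable against oracles:

* **CPM filter**: the threshold corresponds to a minimum raw count of 5 in
  the *smallest* library (`5 / min(lib) × 1e6` CPM); a miRNA is kept when
  it reaches the threshold in at least `ceiling(min_samples_frac ×
  n_smaller_group)` samples (default: the whole smaller group — the
  required sample count was not published and is configurable).
* **TMM**: reference = sample whose 75th-percentile CPM is closest to the
  mean 75th percentile; M and A values over miRNAs positive in both sample
  and reference; symmetric trimming of 30% tails of M and 5% tails of A
  (the published defaults of the cited normalization method); factor =
  2^(weighted mean of surviving M) with inverse asymptotic binomial
  variances as weights; factors rescaled to geometric mean 1. Ties in the
  trim ranks use average ranks so a tied block stays together.
* **Common dispersion** φ (NB variance = μ + φμ²): maximizes the summed
  per-miRNA conditional log-likelihood of counts given their group totals
  at equalized library sizes; log-grid on [1e-4, 4] plus golden-section
  refinement; φ = 0 returned at the boundary (Poisson limit). A single
  common dispersion is used because the cited method's default exact-test
  path is the one the published analysis invokes; tagwise/trended options
  are out of scope.
* **Library equalization**: proportional scaling with rounding when
  effective sizes are within 20% of each other; otherwise a mid-p NB
  quantile map per cell using a provisional φ of 0.1, refined once. The
  route taken is recorded in the estimate metadata.
* **Exact test**: condition on each miRNA's total t; the two group sums
  are NB with sizes n_i/φ and means proportional to group size; the
  two-sided p sums the conditional probabilities of all splits at most as
  probable as the observed one (small-p rule). φ = 0 reduces to the
  conditional binomial test. Numerically, totals ≤ 4096 are enumerated at
  unit steps (exact); larger totals are evaluated on a 20,001-point
  strided grid — the conditional distribution is smooth at that scale and
  the relative quadrature error is below 1e-3, far inside the resolution
  that matters for FDR ranking.
* **Calls**: fold changes from TMM-normalized group-mean CPM with a
  0.5-count prior; *up/down* requires fold change > `fc_threshold`
  (default 2) **and** BH FDR < `fdr_threshold` (default 0.05). The
  published ">2-fold variations" table does not print its significance
  criterion; fold change + FDR matches the volcano-plot presentation and
  both thresholds are configurable.

## 4. Statistical battery

Spearman's rho is the Pearson correlation of mid-ranks (tie-corrected by
construction); p-values use the t approximation with n − 2 df, or exact
permutation enumeration for n ≤ 9. Mann–Whitney uses exact enumeration of
rank allocations for combined n ≤ 10 and otherwise the tie-corrected
normal approximation *without* continuity correction, so that the squared
z statistic equals the two-group Kruskal–Wallis chi-square. Fisher's exact
test enumerates the hypergeometric support and sums probabilities ≤ the
observed table's; the chi-square test is Pearson's without continuity
correction. The correlation screen reports *nominal* p-values with the
tier ladder (<0.0001 … <0.05), matching the reporting style of the tables
it reproduces — no multiplicity adjustment is applied inside the screen,
but a BH column over the full screen is emitted alongside for modern use.

The covariate screen operationalizes "covariance analysis rejected the
effects of these variables": for each miRNA it fits
`log2(level + 1) ~ covariate + group` and tests the group effect with the
partial F test against the covariate-only model. A group effect that stays
significant (p < 0.05) after adjustment means the covariate does not
explain the group difference (`group_effect_retained`). A constant
covariate reduces exactly to the one-way model; a covariate perfectly
collinear with the grouping is a confounded design and errors with a
diagnostic.

## 5. The synthetic cohort: what it emulates, and what it does not

Defaults state the cohort the pipeline targets: 35 controls, subgroups of
48 (high), 43 (normal) and 25 (low); four culture conditions; an
eight-cytokine panel; 500 miRNAs; and the planted DE pattern high 8 up +
9 down, normal 0 up + 10 down, low 0 up + 18 down with |log2FC| = 2 (the
low set shares 9 down-regulated miRNAs with the high set, as real subgroup
signatures overlap).

* **Cytokines** are lognormal per condition × cytokine (log-SD 0.3) —
  positive, right-skewed, typical of ELISA readouts, with stimulated
  conditions roughly ten-fold above medium and a within-subject shared
  component across conditions (`condition_corr = 0.6`): a subject that
  responds strongly to one agonist tends to respond strongly to all.
  Subgroup membership is planted by multiplying IL-1β by `ratio_shift`
  (high 6, low 0.15) so the ratio scales by the shift and both cytokine
  margins stay lognormal. Detection-limit censoring is off by default
  (the source assay's floor handling was not published); when enabled,
  censored values are substituted by the limit and flagged.
* **Why planted-normal subjects shrink their ratio SD** (`normal_sd_shrink
  = 0.5`): for *any* continuous distribution, about a third of i.i.d.
  draws fall outside mean ± 1 SD per condition, so a "normal" subject
  drawn from the control distribution itself cannot satisfy the
  all-conditions band rule with high probability — the band rule
  implicitly describes subjects *more stable* than the control spread.
  Shrinking the planted-normal IL-1β/IL-10 latent SD encodes exactly
  that. Together with rejection sampling of each ASD subject's
  IL-1β/IL-10 latents against the closed-form theoretical reference (at
  most `max_tries = 200` redraws), planted labels meet the configured
  `target_purity` (0.9) against the realized empirical reference. These
  values were fixed from closed-form lognormal calculations before any
  acceptance run.
* **OCR traces** use phase means (100, 40, 160, 10) pMol/min, per-
  measurement Gaussian noise (SD 5) and a per-subject lognormal
  respiration scale (log-SD 0.25) so bioenergetic parameters vary across
  subjects while efficiency ratios stay stable. The antimycin phase's
  within-phase CV legitimately exceeds the 25% QC threshold at these
  settings — a realistic property of near-zero OCR phases, surfaced as a
  QC flag rather than hidden.
* **miRNA counts** are NB with a heavy-tailed abundance profile (log-SD
  1.5 across miRNAs), uniform library sizes on [5e5, 1e6] (depths were not
  published; these are conventional serum small-RNA scales), dispersion
  0.2, and per-sample renormalization of the mean vector — fold changes
  therefore perturb the composition exactly as in real sequencing, and
  TMM has real work to do.
* **Planted correlations** use a Gaussian copula: the count is drawn by NB
  quantile transform of a latent correlated with the target's normal
  score. Rank correlations are copula-invariant, which is why the plan is
  stated in Spearman terms. For respiration targets the coupling uses the
  normal scores of the *measured* parameter (not the latent subject
  scale): planting against the latent would silently attenuate the
  realized correlation by the measurement-noise factor, and the plan's
  contract is a rank correlation with the observable variable. The default
  plan plants ρ = 0.6 between a low-subgroup-down miRNA and LPS-stimulated
  TNF-α in the low stratum, and ρ = −0.6 between a normal-subgroup miRNA
  and PLR in controls (the control stratum of the published respiration
  screen is dominated by negative correlations).

What the generator does **not** emulate — and hence what a green test does
not establish: sequencing-level artifacts (adapter content, mapping
ambiguity), batch and plate effects, tagwise dispersion heterogeneity,
age/sex-structured miRNA biology, correlated comorbidity structure, and
real assay floors. Tests green on this world establish the *algorithms*
(rule logic, normalization, exact tests, screens) — not clinical validity
of the biomarkers.

## 6. Numerical choices

* All randomness flows from one root seed; each stage derives an
  independent substream (`derive_seed`), so cohorts are reproducible
  byte-for-byte and stages can be re-run in isolation.
* The dispersion search treats the lower grid edge as the Poisson boundary
  and returns φ = 0 there rather than a spuriously small positive value.
* The exact test's zero-total features return p = 1 with a flag.
* `bh_adjust` is the standard step-up map with monotonicity enforcement.
  Note the step-up map is *not* idempotent (p = (0.04, 0.5) → (0.08, 0.5)
  → (0.16, 0.5)); the suite asserts monotonicity and agreement with the
  reference implementation instead.
* TMM trim boundaries use average ranks so tied M/A blocks are kept or
  dropped together, matching the canonical implementation to ~1e-6 on
  tie-free data.

## 7. Known limitations

* The common-dispersion exact test is the cited method's default path;
  tagwise or GLM-based DE is out of scope by design.
* The correlation screen's nominal tiers reproduce the published reporting
  style; users wanting family-wise control should use the emitted BH
  column.
* Classification purity on noisy worlds depends on the empirical control
  reference (n = 35 by default); with very small control groups the
  realized subgroup sizes drift from planted sizes even though each
  planted subject satisfied its rule against the theoretical reference.
* The pipeline starts from a count matrix; read-level processing is out of
  scope.
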