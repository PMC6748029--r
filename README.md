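# serumir

Serum miRNA profiling linked to innate-immune subgroups and mitochondrial
respiration.

## The problem

A subset of children with autism spectrum disorder (ASD) shows evidence of
innate-immune dysregulation. One practical way to detect it is functional:
purify peripheral blood monocytes, stimulate them overnight with a panel of
TLR agonists — medium (unstimulated), LPS (TLR4), zymosan (TLR2/6), CL097
(TLR7/8) — and compare the ratio of secreted pro-inflammatory IL-1β to
counter-regulatory IL-10 against typically-developing controls. Subjects
whose ratios sit above, inside, or below control reference bands form
**high**, **normal** and **low** innate-immune subgroups, which also differ
in PBMC mitochondrial respiration. Because the cell assay needs fresh blood
and is slow, circulating serum miRNAs are attractive surrogate biomarkers:
they are stable, need little blood, and are secreted largely by
monocyte/macrophage-lineage cells.

`serumir` implements the complete analysis chain needed to evaluate that
idea, end to end and reproducibly:

1. **Subgroup classification** — per-subject IL-1β/IL-10 ratios per culture
   condition, compared against the control mean μ_c and SD σ_c per
   condition c:
   * *high*: ratio > μ_c + 2σ_c in ≥ 1 condition, or > μ_c + σ_c in ≥ 3
     conditions;
   * *low*: ratio < μ_c − σ_c in ≥ 1 condition;
   * *normal*: all ratios inside (μ_c − σ_c, μ_c + σ_c), or exactly one in
     (μ_c + σ_c, μ_c + 2σ_c); with explicit gap/conflict policies and
     multi-timepoint reconciliation.
2. **Bioenergetics** — Seahorse-style 4-phase OCR traces (baseline →
   oligomycin → FCCP → antimycin A + rotenone; 3 measurements per phase)
   reduced to non-mitochondrial respiration, basal, ATP-linked respiration
   (ALR = baseline − oligomycin), proton-leak respiration (PLR = oligomycin
   − non-mito), maximal respiratory capacity (MRC = FCCP − non-mito),
   reserve capacity (RC = MRC − basal), and the ALR/PLR, MRC/PLR efficiency
   ratios.
3. **Differential expression** — CPM filtering anchored to a minimum raw
   count of 5 in the smallest library, TMM normalization (doubly trimmed,
   precision-weighted M-values), a common negative-binomial dispersion φ
   (variance = μ + φμ²) estimated by conditional maximum likelihood, a
   conditioned NB exact test (two-sided, small-p rule) per subgroup vs
   control, and Benjamini–Hochberg FDR control. All re-implemented in this
   package and cross-checked against enumeration oracles and the reference
   implementation in the test suite.
4. **Association screens** — stratified Spearman correlations of miRNA
   levels against IL-1β/IL-10 ratios, cytokine production (IL-10, TNF-α,
   CCL2) per condition and respiration parameters per subject, with tiered
   nominal p-values; plus Mann–Whitney / Kruskal–Wallis / Fisher /
   chi-square group tests and a GLM covariate (confounding) screen.
5. **Synthetic cohorts** — a seeded generator producing subject metadata,
   lognormal cytokine panels with planted subgroup ratio shifts, OCR
   traces, and NB miRNA counts with a planted differential-expression
   pattern (high: 8 up + 9 down; normal: 0 up + 10 down; low: 0 up +
   18 down) and Gaussian-copula planted correlations — so every stage is
   testable without patient data.

## Worked example

```r
library(serumir)
cfg <- sim_config(n_control = 12,
                  n_per_subgroup = c(high = 10, normal = 10, low = 10),
                  n_mirna = 80, nb_dispersion = 0.1,
                  library_size_range = c(1e5, 1.5e5), seed = 42)
res <- run_pipeline(config = cfg)
print(res)
```

```
== serumir run report ==
subjects: 42 (12 controls)
subgroups: high=11, low=10, normal=9
differential expression (vs control):
  high     up   8  down   9  (of 80 tested)
  normal   up   0  down  10  (of 80 tested)
  low      up   0  down  18  (of 80 tested)
  ASD      up   6  down   1  (of 80 tested)
top correlations per stratum:
  [control]
    mir-004 ~ IL-10 (CL097): rho 0.874, <0.0005
    mir-016 ~ ALR (-): rho 0.797, <0.005
    mir-020 ~ TNF-a (CL097): rho -0.783, <0.005
  ...
```

Reading the output: the classifier recovered the planted subgroup sizes up
to boundary noise (one planted-normal subject drifted into each tail
group); the subgroup-vs-control exact tests recovered the planted 8/9,
0/10, 0/18 up/down pattern exactly at these settings; the screen reports
rank correlations with the tier labels used in clinical reporting. The
combined all-ASD comparison dilutes subgroup-specific signals — the point
the subgrouping is designed to make.

Single stages work standalone:

```r
derive_parameters(c(baseline = 100, oligomycin = 40, FCCP = 160,
                    antimycin_rotenone = 10))
#> respiration (pMol/min): basal 90.0, ALR 60.0, PLR 30.0, MRC 150.0,
#> RC 60.0, non-mito 10.0
```

## Command line

```sh
serumir simulate --outdir cohort --seed 7        # write a synthetic cohort
serumir run --indir cohort --outdir results      # full pipeline
serumir classify --indir cohort --outdir results # single stages: classify,
                                                 # respire, de, associate
```

(the `serumir` script is installed under `exec/` in the package directory;
equivalently call `serumir::serumir_main(c("run", ...))`.)

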