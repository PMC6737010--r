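---
title: "Methods: resting-state network segregation and graph metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state network segregation and graph metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netseg)
```

## The analysis model

`netseg` implements a resting-state functional-connectivity pipeline for
aging cohorts. The unit of input is one subject's ROI time-series matrix:
T fMRI volumes by N regions of interest, where the ROIs come from the
264-region functional parcellation and carry one of ten network labels
(Hand, Vis, Mouth, Aud, DMN, Sal, CO, FP, DAN, VAN; 214 labelled ROIs in
total) or `"unassigned"`.

Per subject the pipeline computes:

1. **Connectivity.** Pearson correlations among all ROI pairs, Fisher
   z-transformed (`z = atanh(r)`), with two kinds of cells flagged as
   excluded rather than overwritten: the diagonal, and every ROI pair whose
   centres lie within 20 mm of each other (shared-signal contamination
   between overlapping spheres). One stored object serves both downstream
   conventions — `conn_na_view()` for averaging (excluded = NA) and
   `conn_zero_view()` for graph construction (excluded = 0).
2. **Network correlation summaries.** For each network: the mean positive z
   over within-network pairs, the mean positive z over pairs joining the
   network to all other selected networks, and the mean negative z over
   between-network pairs. Positive and negative means drop opposite-signed
   cells from numerator and denominator alike. Each cross-network cell
   contributes to the between means of both networks it joins (the row-wise
   averaging scheme). Within-network negative means are computed but
   flagged not-for-analysis: they are rare and hard to interpret.
3. **System segregation.**
   `SS = (z̄_within − z̄_between) / z̄_within`, computed on positive
   correlations only, with negatives set to zero. Higher SS = networks
   operating more independently. SS ≤ 1 whenever z̄_within > 0 and
   z̄_between ≥ 0; SS is undefined (error) when z̄_within ≤ 0.
4. **Graph metrics.** The z matrix is proportionally thresholded at
   densities 2–10% in 1% steps (keep the top `round(d·K)` positive edges of
   the K valid pairs), then: participation coefficient
   `PC_i = 1 − Σ_s (k_is/k_i)²` against the *fixed atlas partition*;
   local efficiency (global efficiency of each node's neighbor-induced
   subgraph); global efficiency (mean inverse shortest-path length,
   disconnected pairs contributing 0); and Louvain-maximized Newman
   modularity Q. Nodal metrics are averaged per network.
5. **Group statistics.** Age groups YA 20–34, yMA 35–49, oMA 50–64,
   OA 65–80; repeated-measures ANCOVA-style F tests with scrubbing
   percentage as covariate and subject as error stratum for within-subject
   factors (network, direction, threshold); Bonferroni-corrected pairwise
   group post hocs (×6 for four groups); Pearson correlations of metrics
   with continuous age and with cognition domain z-scores (VOCAB, SPEED,
   FLUID, MEM), the latter deliberately uncorrected (exploratory).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| proximity threshold | 20 (strict `<`) | mm | exclusion of overlapping-sphere pairs |
| density grid | 0.02–0.10 step 0.01 | proportion | threshold-robustness grid |
| graph mode | weighted (binary by flag) | — | toolbox convention; unstated in the source analysis, both shipped |
| edge length | 1/weight | — | stronger correlation = shorter path |
| Louvain restarts | 10, seeds `seed..seed+9` | — | deterministic best-Q over randomized node orders |
| scrub cutoff | 30 | % volumes | subject inclusion rule |
| SS variant | zeroed-in-denominator | — | zeroed negatives stay in the cell count, per the metric's construction; `positives-only` flag mirrors the per-network averaging rule |

Design choices where the design was genuinely open:

- **"Within 20 mm"** is read as strict `d < 20`; boundary pairs are
  retained (`strict = FALSE` gives `≤`).
- **Whole-brain z̄_within/z̄_between pool cells** across networks
  (cell-weighted), not a mean of network means; a `network-weighted`
  pooling flag provides the alternative.
- **ROIs outside the ten selected networks** are dropped everywhere,
  including graph construction, so the graph's node set equals the
  averaging set.
- **Tie handling at the retention boundary**: stable sort by (weight
  descending, node-pair lexicographic), and `round(d·K)` uses
  round-half-away-from-zero, so thresholded edge sets are bit-reproducible.
- **The group tests are univariate GLM F tests** with subject error strata,
  not SPSS-style multivariate statistics (Wilks/Pillai). What is testable
  on synthetic data — which effects exist and their direction — does not
  depend on one package's multivariate machinery; exact F values from the
  original study are out of scope regardless, because its raw data are not
  public.

## The synthetic cohort: what it emulates, what it does not

`simulation_config()` states a world:

- ten networks at the canonical sizes (214 ROIs);
- within-network Pearson r of 0.22–0.30 at age 20, declining linearly at
  −0.0015/year (so ≈ −0.09 over the 60-year span), between-network r 0.08,
  age-stable — magnitudes chosen so measured mean positive z (≈ 0.18–0.25)
  and its age decline sit in the range the study reports;
- T = 285 volumes at TR 2 s (9.5-min protocol; 150 = 5-min), multivariate
  normal draws from the block covariance (unit variances; PSD by
  construction when r_within ≥ r_between ≥ 0, eigenvalue-clipping repair
  otherwise, rejected if the repair shifts any eigenvalue by > 0.05);
- scrubbing fraction 0.03 at age 20 rising 0.0009/year with sd 0.02
  (matching the reported ≈3% young vs ≈7% old scrubbing), applied as
  seeded random volume deletion; subjects whose realized fraction reaches
  30% are excluded, emulating the inclusion rule;
- cognition domain scores `β·trueSS + N(0,1)`, z-scored within the cohort,
  with β = 4.5 (SPEED), 3.5 (FLUID, MEM), 0 (VOCAB). Given the true-SS
  spread of ≈ 0.035 across 20–80 years this implies SS–domain correlations
  of ≈ 0.15–0.2, the magnitude of the significant SS–cognition
  relationships the study reports; VOCAB is the domain the study found
  age-increasing and connectivity-silent, so it is left uncoupled.

Not modelled, by design: temporal autocorrelation of BOLD (draws are white
in time), hemodynamics, physiological noise, motion-spike structure,
registration error, and the dense tail of weak true correlations that real
parcellations produce. Consequently the synthetic age–SS correlation is
much stronger (r ≈ −0.9) than the r = −0.119 reported in a real cohort,
where between-subject biological variance dominates. A green recovery test
therefore establishes that the *pipeline's estimators track the generative
parameters* — not that effect sizes of real data are reproduced.

## Numerical conventions

- Fisher transform errors on off-diagonal |r| = 1 (degenerate input); the
  diagonal is masked before it matters.
- Correlations are clamped to [−1, 1] against floating-point drift, and PC
  to [0, 1].
- Shortest paths use Floyd–Warshall in compiled code; Louvain's move phase
  is compiled as well, with the node order drawn per restart from the seed,
  labels canonicalized by smallest community member. `evaluate_q()` scores
  any fixed partition, so detected communities never leak into PC.
- All randomness flows through explicit seeds; cohort generation, the CLI
  (`netseg_cli()`), and both views of every matrix are byte-reproducible.

## Known limitations

- Louvain is a greedy heuristic; optimality is only asserted (and tested)
  on small graphs where exhaustive search is feasible.
- The ANCOVA uses sequential sums of squares with the covariate entered
  first and no sphericity correction (the source analysis is silent on
  both); a Greenhouse–Geisser option is not implemented.
- The bundled atlas's coordinates are synthetic (24-mm grid, so the default
  proximity set is empty); only its label counts mirror the real
  parcellation. Analyses needing true geometry must supply a real atlas
  table.
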