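---
title: "Methods: dilution-replicate analysis of qPCR assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilution-replicate analysis of qPCR assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilrepqpcr)
```

## The model

In the dilution-replicate design each biological replicate is assayed as a
short serial-dilution series (the canonical layout is fivefold: dilution
factors 1, 5, 25) instead of identical technical replicates. The wells of
one amplicon are modelled jointly:

$$
\mathrm{Cq}_{r,d} = a_r + b \,\log_{10} D_d + \varepsilon_{r,d},
$$

one ordinary least-squares fit per amplicon with a **single shared slope**
$b$ (cycles per log10 dilution factor) and a **per-replicate intercept**
$a_r$ (the Cq the undiluted template of replicate $r$ would produce). The
slope carries the amplification efficiency, $E = 10^{1/b}$, and intercept
differences carry the relative template quantities,
$\log_{10} Q_r = (a_{\mathrm{ref}} - a_r)/b$. The key assumptions are those
of any standard-curve analysis: a common fluorescence threshold across all
compared genes, efficiency constant across the (narrow) dilution range, and
independent, homoscedastic Cq noise. `fit_collinear()` implements the model
through `lm()` on an indicator-coded design; a unit test verifies
coefficient-level agreement (to 1e-10) with an explicit normal-equations
solve of the same design matrix.

The classical single-standard-curve formula $E = 10^{-1/\text{slope}}$
regresses Cq on log10(concentration) instead. With concentration taken as
the reciprocal of the dilution factor the two slopes differ only in sign, so
both conventions return the same efficiency; `classical_efficiency()` is
provided as a cross-check utility and tested for exact agreement.

Normalized expression divides a replicate's gene-of-interest quantity by the
**geometric mean** of its reference-gene quantities (arithmetic averaging of
reference genes biases ratios and is deliberately not offered). Values are
then rescaled so the geometric mean of the scaling-reference group equals 1.
The choice of scaling group moves all values by one global factor and leaves
every group contrast invariant — a property test asserts this — so the
default (the first group in file order) is statistically inert.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `dilution_factors` | 1, 5, 25 | fold | canonical fivefold three-point series |
| `outlier_threshold` | 3.0 | studentized residuals | conventional cutoff; flags are advisory only |
| efficiency warning band | [1.6, 2.1] | E | practical assay-quality range; warning, never an error |
| `k_donors` (imputation) | 5 | donors | standard predictive-mean-matching pool size |
| imputation refusal / warning | 50 % / 30 % | missing fraction | imputing many values distorts curves; hard stop past half |
| `alpha` | 0.05 | — | freely selectable significance level |
| `scaling_group` | first group | — | contrast-invariant, see above |

## Statistical tests

The test plan is frozen as this package's documented contract (printed in
every result and plot caption): parametric — Welch or paired t for two
groups, Dunnett many-to-one, Tukey HSD, or Welch+Holm for selected pairs;
nonparametric — Mann-Whitney or Wilcoxon signed-rank for two groups,
Kruskal-Wallis followed by Dunn z-tests with Holm adjustment otherwise.
Every test consumes log2-transformed expression: qPCR expression values are
approximately log-normal, so parametric tests are only defensible after the
transform, and rank tests are unaffected by it. Multiplicity is handled
within each gene (the family that is annotated on one plot), not across
genes. Dunnett and Tukey adjusted p-values come from `multcomp`; Dunn's
test is computed directly from joint ranks with tie correction, as no
installed package provides it.

A type-I-error calibration test simulates 200 null datasets (two groups of
six replicates, Cq noise 0.2 cycles) through the *entire* pipeline and
checks that both families reject at 0.05 within two binomial standard
errors. Two hundred replicates keeps the full-pipeline calibration fast
while still bounding the rate usefully; the Mann-Whitney rate is
conservative at n = 6 because the exact null distribution is discrete.

## The synthetic-data generator

`simulate_dilrep()` draws Cq values from the exponential-amplification
model $\mathrm{Cq} = \mathrm{baseline} - \log_{10}(Q)/\log_{10}(E) +
\log_{10}(D)/\log_{10}(E) + \mathcal{N}(0, \sigma)$. It emulates exactly
the features the pipeline estimates: per-amplicon efficiencies, true
relative quantities per group, the dilution grid, i.i.d. Gaussian Cq noise
(σ defaults to 0.2 cycles, a typical between-well repeatability), and
completely-at-random missingness restricted to reference-gene wells. The
default noise model is the standard qPCR assumption; nothing forces real
data to obey it. The generator does **not** emulate plateau-phase
amplification kinetics, pipetting bias in the dilution steps (which the
design cannot distinguish from an efficiency shift), inter-run effects, or
structured missingness — so passing recovery tests demonstrates correctness
of the estimator under the stated model, not robustness to miscalibrated
pipettes or plate effects.

## Numerical choices and degenerate inputs

* **Noiseless data.** Externally studentized residuals of numerically-zero
  residuals are meaningless (0/0 after case deletion); a well is flagged
  only if its raw residual also exceeds `1e-8 × max(1, sd(Cq))`. When case
  deletion leaves a perfect fit, the 0/0 studentized residual is resolved to
  0 or ±∞ by the raw residual's magnitude.
* **Perfect separation.** Exactly constant groups with distinct means
  (the noiseless-simulation limit) would crash a t-test; the p-value is
  reported as 0 with a warning, and as 1 when the groups are also identical.
* **Reproducible adjusted p-values.** The single-step Dunnett/Tukey
  adjustment integrates a multivariate t numerically with quasi-random
  points; the integration seed is fixed so repeated runs give bitwise-equal
  result tables.
* **Name parsing.** Replicate names split at the *last* underscore, so
  group names may themselves contain underscores; the suffix must be
  alphanumeric.
* **Imputation.** Single imputation (one completed table feeds one
  regression), predictors = log10 dilution plus the other amplicons' Cq in
  the same reaction row, donor draw weighted by inverse prediction distance
  (with a 1e-8 floor to keep exact matches finite), ties broken by row
  order. The weighted-PMM variant implemented here is this package's own
  concretization; imputed values are always observed values, so imputation
  never extrapolates beyond the observed Cq range.
* **Output format.** All tables are written point-decimal/comma-field at
  full double precision regardless of the input dialect, so downstream
  parsing and byte-level reproducibility checks are deterministic.

## Design choices where the design was open

* **Cq-Cq lines** are derived from the two collinear fits (slope ratio and
  intercept combination) rather than by regressing GOI Cq on RG Cq
  directly; the derived line is exact under the model and keeps the
  diagnostic consistent with the fitted curves.
* **Outliers are flagged, never auto-removed**; refitting without flagged
  wells is an explicit, once-only operation. Automated removal of
  dilution-series points silently changes efficiencies.
* **Validation problem sizes** (100 random oracle instances, 200 null
  datasets, 50 imputation seeds, 20 noisy-recovery seeds) were chosen to
  make the full suite run in well under a minute per module while leaving
  Monte-Carlo error far below the tested tolerances.

## Known limitations

Inter-run/multi-plate normalization, two-way and multi-factor designs
(export the intermediate expression table and use external statistical
software), vendor thermocycler export formats, and per-well efficiency
estimation from raw fluorescence curves are all out of scope. The
dilution-replicate design itself is unsuitable for templates near the
detection limit, where the most dilute well may fail to amplify.
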