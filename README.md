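# dilrepqpcr

Efficiency-corrected relative quantification for qPCR experiments run in the
**dilution-replicate design**, with automated statistics and
publication-style plots.

## The problem and the method

Accurate relative quantification by qPCR requires knowing each amplicon's
amplification efficiency E (the per-cycle template multiplication factor;
E = 2 is perfect doubling). The textbook approach estimates E from a
separate standard curve — a dilution series of one standard sample — and
hopes that all experimental Cq values fall inside its linear range.

The dilution-replicate design removes the separate standard curve: every
biological replicate is itself run as a short serial-dilution series
(typically fivefold: dilution factors 1, 5, 25). All replicates of an
amplicon then jointly define its standard curve through a **collinear fit**
— one ordinary least-squares model with a single shared slope b (cycles per
log10 dilution) and one intercept a_r per replicate:

```
Cq_{r,d} = a_r + b * log10(D_d) + error
E = 10^(1 / b)
log10(Q_r) = (a_ref - a_r) / b
```

Every sample contributes to the efficiency estimate, precision grows with
the number of replicates, and all Cq values are guaranteed to lie inside the
curve's range. Relative quantities Q_r follow from intercept differences;
normalized expression divides each replicate's gene-of-interest quantity by
the **geometric mean** of its reference-gene quantities. All group
comparisons are tested on log2-transformed expression (qPCR data are
approximately log-normal), with the test chosen automatically from the
user's family/comparison settings (Welch/paired t, Dunnett, Tukey HSD,
Mann-Whitney, Wilcoxon signed-rank, Kruskal-Wallis + Dunn, Holm adjustment).

The package also provides weighted predictive-mean-matching imputation of
missing reference-gene Cq values, outlier flagging by externally studentized
residuals, Cq-Cq diagnostic lines, a pass-through mode for precalculated
relative expression tables, and a synthetic-data generator with known ground
truth used by the test suite.

## Worked example

```r
library(dilrepqpcr)

# simulate a two-group experiment in which group "half" received exactly
# half the template of group "full" (one reference gene, perfect doubling)
sim <- simulate_dilrep(ground_truth(
  groups = c("full", "half"), n_replicates = 3,
  reference_genes = "RG1", target_genes = "GOI1",
  efficiencies = 2, quantities = c(half = 0.5), noise_sd = 0, seed = 1
))

res <- run_analysis(sim$dataset, stats = stats_config("parametric"))
res$fits$GOI1
#> <amplicon_fit: GOI1>
#>   slope 3.3219 cycles/log10(D) (SE 0.0000), E = 2.0000, R^2 = 1.00000
#>   6 replicates, 18 wells, 0 flagged outlier(s)

res$expression
#> # A tibble: 6 x 7
#>   sample group replicate_id pair_id gene  norm_expr log2_norm_expr
#> 1 full_1 full  1            <NA>    GOI1      1               0
#> 2 full_2 full  2            <NA>    GOI1      1               0
#> 3 full_3 full  3            <NA>    GOI1      1               0
#> 4 half_1 half  1            <NA>    GOI1      0.500          -1.00
#> 5 half_2 half  2            <NA>    GOI1      0.5            -1
#> 6 half_3 half  3            <NA>    GOI1      0.500          -1.00
```

The fitted slope 3.3219 = 1/log10(2) corresponds to efficiency exactly 2,
and the halved template is recovered as a −1.00 log2 expression difference.
With `outdir =` set, `run_analysis()` also writes the expression, relative
quantity, standard-curve and statistics CSVs, per-gene expression plots
(multi-page PDF plus one PNG per gene, `log`-tagged file names on the log2
scale) and standard-curve / Cq-Cq diagnostic pages.

A thin command-line wrapper with `run` and `simulate` subcommands is
installed at `inst/cli/dilrepqpcr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dilrepqpcr.R", package="dilrepqpcr"))')" \
  run --input data.csv --reference-genes RG1,RG2 --outdir results
```

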