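# epgtools

Quantify DNA degradation from capillary-electrophoresis electropherograms.

Genome-wide sequencing needs high-molecular-weight (HMW) DNA (fragments
above ~20 kbp), but tissue sampled in the field often sits in a
preservation solution — typically DESS (20% DMSO, 0.25 M EDTA, saturated
NaCl) or absolute ethanol — for days to months before extraction. Fragment
Analyzer class instruments report each extract as an electropherogram:
relative fluorescence (RFU) versus fragment size (bp). epgtools takes a set
of such traces from a designed preservation experiment
(solution x heat treatment x storage temperature x storage time, with
several individuals as replicates) and quantifies how fast the HMW fraction
is lost under each condition.

## What it computes

* **Cross-run merging.** Runs disagree in size calibration at large sizes,
  so traces are harmonized before comparison: sizes ≤ 1 kbp unchanged,
  sizes in (1, 10] kbp rounded up to the next 10 bp, sizes > 10 kbp rounded
  to the nearest 100 bp; RFUs averaged within bins, negatives clipped to 0;
  traces aligned on the union grid with flagged linear interpolation.
* **Group summaries.** Per-treatment mean traces with pointwise 95%
  Student-t confidence bands.
* **HMW quantification.** Windowed trapezoidal AUC with signal below
  250 bp excluded (RNA guard): raw HMW% = 100·AUC(≥20 kbp)/AUC(≥250 bp),
  standardized HMW% (sHMW%) = 100·AUC(≥20 kbp)/max over all groups x times,
  and the per-time DESS/ETOH scale factor sHMW%_DESS / sHMW%_ETOH.
* **Fragmentation score.** A Genomic Quality Number style per-sample score,
  10·AUC(≥ threshold)/AUC(≥250 bp) ∈ [0, 10], threshold 10 kbp by default.
* **Factorial ANOVA.** Sequential (type-I) sums of squares for
  solution, heat, temperature, time and all interactions, fitted by least
  squares on effect-coded design matrices, plus the partial F test of the
  full model against a solution-only model.
* **Synthetic experiments.** A generator for the full 200-sample design —
  lognormal size-component mixtures with treatment-dependent exponential
  HMW decay, per-fish amplitude effects, per-run size-axis jitter and
  additive detector noise — so the entire chain runs and is testable
  without instrument data (`simulate_experiment()`).

## Worked example

```r
library(epgtools)

cfg <- pipeline_config(simulation = simulation_config(seed = 1),
                       outdir = "epg_results")
res <- run_pipeline(cfg)

format_scale_factors(res$scale_factors)
#>   time_days raw_pct_DESS raw_pct_ETOH std_pct_DESS std_pct_ETOH scale_factor
#> 1         1         20.5          4.3        100           21.9          4.6
#> 2         7         19.5          3.5         96.2         18.2          5.3
#> 3        14         17.2          3.7         84.6         19.2          4.4
#> 4        30         14.2          3.6         69.9         18.6          3.8
#> 5        90          7.9          3.7         39.9         19.3          2.1
```

DESS at 1 day holds the most HMW DNA of any group, so it is the
standardization reference (sHMW% = 100 exactly); ethanol-stored samples
have already lost most HMW DNA on day one (21.9% of the reference), and the
DESS/ETOH ratio shrinks over time as the DESS samples slowly degrade too.

```r
res$anova_full
#> Factorial ANOVA (sequential SS), response: gqn
#>      term df      sumsq         F         p
#>  solution  1 1.2205e+02 9.596e+03 9.79e-145 ***
#>      heat  1 3.7087e-01 2.916e+01  2.37e-07 ***
#>  ...
#> Residuals: df = 160 , SS = 2.0351

res$model_comparison
#>   statistic df_num df_den  p_value
#> 1      61.3     38    160 2.88e-77
```

The preservation solution dominates the fragmentation score by orders of
magnitude — exactly the structure the simulator was configured with (a
250x decay-rate multiplier for ethanol). All stage outputs (group
summaries, HMW reports, scale factors, scores, ANOVA table, plot data and a
JSON manifest, each tagged with the configuration hash) land in `outdir`.

With real instrument exports, replace the simulation with files:

```r
cfg <- pipeline_config(traces_paths = c("run1.csv", "run2.csv", "run3.csv"),
                       design_path = "design.csv", outdir = "results")
```

A thin command-line wrapper with `simulate` / `merge` / `quantify` /
`anova` / `report` subcommands is installed at
`system.file("cli/epgtools.R", package = "epgtools")`.

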