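---
title: "Quantifying DNA degradation from electropherograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA degradation from electropherograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgtools)
```

## The problem

Genome-wide sequencing applications need high-molecular-weight (HMW) DNA —
fragments above roughly 20 kbp — while field sampling often forces tissue to
sit for days or months in a preservation solution before extraction. Capillary
electrophoresis instruments (Fragment Analyzer class) summarize the fragment
size distribution of an extract as an *electropherogram*: relative
fluorescence units (RFU) against fragment size in bp. Degraded DNA shows up as
a smear around 1 kbp; intact DNA keeps a hump above 20 kbp. epgtools
turns a collection of such traces, organized as a designed preservation
experiment (solution x heat treatment x storage temperature x storage time,
with several fish as biological replicates), into:

* per-treatment mean traces with 95% confidence bands,
* an HMW quantification: windowed AUC, HMW percentage, max-referenced
  standardized HMW percentage (sHMW%), and per-time DESS/ETOH scale factors,
* a per-sample fragmentation score in [0, 10] (a Genomic Quality Number
  style summary), and
* the full-factorial ANOVA over the design, with a partial F test of the
  full model against a solution-only model.

Here DESS is the DMSO/EDTA/saturated-NaCl preservation buffer and ETOH is
absolute ethanol, the two standard low-cost field preservatives.

## Cross-run merging

Different instrument runs disagree slightly in size calibration at large
fragment sizes, so traces from different runs rarely share size points.
`bin_size()` harmonizes the size axis:

* sizes up to 1 kbp are kept unchanged (calibration is tight there),
* sizes in (1 kbp, 10 kbp] are rounded **up** to the next multiple of 10 bp,
* sizes above 10 kbp are rounded **half-up to the nearest** multiple of 100 bp.

The two regions deliberately use different rounding verbs (ceiling versus
nearest); both rules are confined to `bin_size()` so the convention lives in
one function. `merge_traces()` averages RFU values whose sizes fall in the
same bin and then clips negative averages to zero. Baseline-subtracted
instrument exports genuinely contain small negative RFUs; whether clipping
should precede or follow the within-bin averaging is a convention, so it is
exposed as `clip = "after"` (default) or `"before"`. `align_runs()` then
puts every trace on the union grid of all binned sizes, filling a trace's
own gaps by linear interpolation (flagged, never silent) and refusing to
extrapolate beyond its observed range.

`summarize_group()` computes pointwise means and confidence bands per
treatment group and time. With five biological replicates per cell a normal
approximation is hard to defend, so the default band is the Student-t
interval `mean ± t(0.975, n-1) * SD/sqrt(n)`; `ci = "normal"` is available
for comparison. A group of one gets a degenerate band equal to its mean.

## HMW quantification

`trace_auc()` integrates RFU over size by the trapezoidal rule on the
observed (unevenly spaced) grid, linearly interpolating the signal at window
boundaries that fall between grid points — this makes the integral exactly
additive across adjacent windows and is verified in the tests against a
100x-refined Riemann sum. Signal below 250 bp is excluded from all
quantification because residual RNA co-migrates there; the HMW window starts
at 20 kbp. Both cutoffs are arguments.

`hmw_report()` computes, per group and time, the total AUC (>= 250 bp), the
HMW AUC (>= 20 kbp), the raw HMW percentage `100 * hmw/total`, and the
standardized percentage `100 * hmw/max(hmw)`, where the reference is the
single group x time entry with the globally largest HMW AUC across the whole
analysis (not per-time maxima). In a typical preservation experiment that
reference is the DESS 1-day group; it scores exactly 100 by construction.
Ties for the maximum are broken by table order and reported. Raw percentages
are invariant to uniform rescaling of a trace, standardized percentages are
not — which is why a group's raw and standardized values can legitimately
order differently.

`scale_factors()` tabulates `std_pct_DESS / std_pct_ETOH` per time point at
full precision; `format_scale_factors()` rounds percentages and ratios to
one decimal for reporting, the conventional table format.

AUC-based summaries are computed on the per-group *mean* traces (the "plot"
being standardized); per-sample AUC percentages are available by computing
`trace_auc()` on raw traces, as the pipeline does when `response =
"raw_pct"` is requested for the ANOVA.

## Fragmentation score and ANOVA

`gqn_surrogate()` scores each sample as `10 * AUC(size >= threshold) /
AUC(size >= 250)`. Vendor GQN implementations are proprietary but share this
structure: a 0-10 score for the fraction of DNA mass above a user-set
threshold. The threshold default is 10 kbp — vendor software leaves it to
the user, and 10 kbp sits between the degraded smear and the HMW hump, so
the score moves over the whole degradation trajectory; it is recorded in
every output and exposed as an argument.

`factorial_anova()` fits the per-sample score on the storage factors by
least squares on effect-coded (sum-to-zero) design matrices and reports
sequential (type-I) sums of squares in the canonical order: solution, heat,
temperature, time, then 2-, 3- and 4-way interactions. Storage time enters
as a categorical factor (five levels), not a slope. On the complete balanced
200-sample design the sequential decomposition coincides with type-II/III;
rather than assuming this the fit re-derives the SS under the reversed term
order and stops if they differ (`verify_order_invariance`, default on —
simulation loops that fit thousands of models may switch it off since the
property is also asserted in the test suite). Each term's block of
effect-coded columns is built directly from the factors' sum-to-zero
contrasts, so a term's column space does not depend on its position in the
term list. Fish identity is deliberately not in the model: the design uses
fish as replicates within cells, and the reported term list matches the
factorial treatment structure. p-values are unadjusted. Missing cells with
the full interaction list make the model unidentifiable; the fit refuses
with advice to reduce the term list rather than silently dropping columns.

`compare_models()` is the partial F test
`F = [(RSS_r - RSS_f)/(df_r - df_f)] / MS_residual_f` for a reduced model
nested in the full one — used by the pipeline to ask whether anything beyond
the preservation solution explains fragmentation.

## The synthetic experiment

`simulate_experiment()` generates the full crossing: 5 fish x 2 solutions x
2 heat treatments x 2 temperatures x 5 time points (1, 7, 14, 30, 90 days)
= 200 traces, each fish contributing one sample per cell. A trace is a
three-component lognormal mixture on the size axis:

| component | location | log-SD | initial weight | emulates |
|---|---|---|---|---|
| LMW | 150 bp | 0.30 | 0.22 | residual RNA / very short fragments |
| degraded | 1 kbp | 0.55 | 0.60 | the degradation smear |
| HMW | 40 kbp | 0.30 | 0.18 | intact genomic DNA |

Unimodal humps on a log-size axis are what real smears look like; the
initial weights put the raw HMW fraction near the 15-20% range typical of
fin-clip extractions. Degradation moves mass: the HMW weight decays as
`w_H(t) = w_H(0) exp(-r t)` and the lost mass accrues to the 1 kbp smear
(real degradation shows exactly this pairing — the >20 kbp hump shrinks
while the ~1 kbp smear grows). The per-day rate is multiplicative over
treatments, `r = r0 x 250^[ETOH] x 2^[room] x 1.5^[untreated]` with
`r0 = 0.0075`, so the reference cell (DESS, cold, heat-treated) decays at
exactly `r0`. These defaults reproduce the qualitative phenomenology of
published preservation experiments: DESS kept cold retains more than half
its HMW DNA after three months, while ethanol-stored samples lose most HMW
DNA within the first day. The multiplicative structure is the simplest one
that makes every factorial term meaningful and lets tests dial main effects
and interactions independently.

On top of the mixture: a per-fish lognormal amplitude effect (log-SD 0.2 —
extraction yield varies by individual), a per-run multiplicative size-axis
jitter (SD 1%, emulating the calibration drift that motivates merging;
by default one simulated run per extraction time point, configurable via
`runs` since real run/sample assignments vary), and additive i.i.d.
Gaussian detector noise (SD 0.1 RFU against low-hundreds peak signal),
which can push RFUs below zero exactly as baseline-subtracted instrument
output does.

Ground truth is recorded per sample: the decay rate, the component weights,
and the analytic HMW *signal* fraction — the lognormal-CDF ratio of mass in
[20 kbp, grid max] to mass in [250 bp, grid max] within the sample's own
(jittered) window. The signal fraction, not the bare component weight, is
what a windowed AUC on a finite grid measures, so recovery tests compare
against it; the two differ mainly by the HMW tail beyond the 60 kbp grid
end.

What the simulator does *not* model: the long-time plateau of ethanol
degradation (a single exponential keeps decaying, real ethanol samples
collapse fast and then stabilize), enzyme kinetics, ladder chemistry,
baseline drift, or biological variation in degradation state between
replicates beyond the amplitude effect. Passing tests therefore demonstrate
that the analysis chain recovers known mixture structure and treatment
effects under realistic noise — not that any particular biological dataset
will show those effects.

## Numerical choices and degenerate inputs

* Trapezoidal AUC with exact cut-point interpolation; additivity holds to
  1e-9 relative.
* Zero total signal yields a missing percentage or score, never 0; an
  integration window disjoint from the observed range yields area 0 with a
  classed warning.
* A constant ANOVA response gives all-zero SS and missing F and p.
* Standardization ties are broken by table order and messaged.
* Traces with fewer than two points are excluded from alignment with a
  message; exclusions are never silent.
* Written trace CSVs use 17 significant digits and are parsed back with the
  base reader, so write/read round-trips are bit-exact.

## Problem sizes in the test suite

The suite exercises the full 200-sample design throughout. Simulation-heavy
checks use a 120-point size grid (the default is 500) — grid resolution
affects only quadrature detail, not the design — with 500 replicates for
the null-calibration check of the solution term and 200 replicates for the
power/ranking check. Recovery checks against simulator truth run one
200-sample experiment each at zero and at default noise on the default
grid.

## Limitations

* The GQN-style score is a documented surrogate with the same inputs and
  range as vendor scores, not a reimplementation of any proprietary
  algorithm; absolute values are not comparable across software.
* AUC percentages are relative measures; no absolute mass (ng) calibration
  is attempted.
* The ANOVA treats fish as replication, not as a random effect; with five
  fish a mixed model would be fragile, but strong fish effects will inflate
  residual variance.
* Confidence bands are pointwise, not simultaneous.
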