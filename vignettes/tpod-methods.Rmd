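---
title: "Methods: from dose-series counts to transcriptomic points of departure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dose-series counts to transcriptomic points of departure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tpodr derives transcriptomic points of departure (tPODs) from a dose-series
RNA-seq experiment: a vehicle control plus a geometric dilution series
anchored at a sub-phenotypic top concentration (typically the compound's
EC20), with a small number of replicates per concentration. The pipeline
is: per-gene differential expression for the top-dose contrast, a Williams
trend prefilter over the whole series, per-gene benchmark-dose (BMD)
modeling, a postfilter on the resulting BMDs, and two tPOD summaries of
the retained BMD distribution. This vignette records the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Study design

`make_design(anchor_uM, n_dilutions, dilution_factor, n_replicates)`
describes the exposure layout. Defaults follow the anchored-dilution
design: a 10-fold dilution series ending at the anchor, three biological
replicates per concentration. The number of dilution steps below the
anchor is not fixed by the design idea itself; the default of 3 (five
concentrations including the control) matches a plate-friendly layout and
keeps every concentration within three decades of the anchor. All
concentrations are carried in µM end to end; log10 transforms happen only
at use sites (density estimation, plotting) and are never stored.

## Differential expression

`nb_test()` fits, per gene, a negative-binomial generalized linear model
with replicate and condition terms (`~ replicate + condition`) on raw
counts with log size-factor offsets, and tests the condition coefficient
with a two-sided Wald test; `p.adjust(..., "BH")` controls the FDR across
tested genes. A gene is a DEG when `q < 0.05` and `|log2FC| >= 0.585`
(1.5-fold). Size factors are median-of-ratios over genes expressed in all
samples, rescaled to geometric mean 1.

Dispersion is estimated by method of moments per gene (solving
`var = mu + phi mu^2` from pooled within-condition moments on normalized
counts), then stabilized against a fitted mean-dispersion trend
`phi(mu) = a0 + a1 / mu`. The stabilization is deliberately strong at
three replicates per arm: the per-gene estimate enters with weight 0.3 on
the log scale and the result is floored at 0.9 times the trend, so
below-trend moment estimates (the main source of anti-conservative Wald
tests at this sample size) are pulled back up while above-trend genes keep
part of their excess dispersion. With this scheme the null rejection rate
at nominal 0.05 sits at 0.04–0.05 in simulation, and the empirical FDR
among called DEGs stays near the nominal level. This stage is a compact
NB-GLM test in the spirit of the established count-based DE tools, not a
reimplementation of any of them; exact concordance with those tools is
not a goal.

## Williams trend prefilter

`williams_trend()` screens genes for monotone dose response before any
curve fitting. The statistic is Williams' many-to-one form: the top-dose
mean is replaced by its monotone amalgamation over the dose groups
(weighted pool-adjacent-violators, `pava()`), and compared with the
control mean using the pooled within-group variance:

$$\bar t = \frac{\tilde m_k - m_0}{\sqrt{s^2 (1/n_k + 1/n_0)}}.$$

Rather than interpolating Williams' published critical-value tables, the
null is generated by permuting sample labels across concentration groups
(default 10,000 permutations, one shared permutation set for all genes,
seeded). Both response directions are evaluated; the better-fitting
direction is kept and the one-sided permutation p-value is doubled. The
prefilter pass requires `p < 0.05` (a conventional screening level; the
method's originators state only the fold-change gate) and a maximum
linear-scale fold change of any concentration versus control of at least
1.5, computed on back-transformed group means of the log2 normalized
matrix. Permutation p-values are exact in distribution at any sample
size, which matters at n = 3, and the shared permutation set keeps the
per-gene cost at one matrix multiplication.

## Benchmark-dose modeling

`fit_dose_response()` fits eight continuous models to each prefiltered
gene's log2 normalized expression under homoscedastic Gaussian error:
linear, quadratic, power, Hill, and the nested exponential family
exp2–exp5 (background `a`, rate `b`, asymptote ratio `cc`, shape `d`).
Power and Hill exponents are bounded to [0.5, 18]; the exponential shape
`d` to [1, 18] so curvature at zero stays sublinear. All fits run on the
scaled concentration `t = c / c_top` with parameter boxes defined in
scaled units, which makes BMD, BMDL and BMDU exactly equivariant under
rescaling of the concentration axis.

Numerically, every model is profiled down to its nonlinear parameters:
linear and quadratic are ordinary least squares; power and Hill solve the
background/scale pair by linear least squares for fixed exponents; exp2
and exp3 solve the scale by projection; exp4 and exp5 are rewritten as
`A + B exp(-(b t)^d)`, linear in (A, B). Exponential rates are searched on
the log scale — the dilution series spans three decades, and so must the
rate. Multi-start optimization uses a deterministic Latin-hypercube-style
grid (at least 5 starts) plus data-driven warm starts (a half-max guess
for Hill; each nested exponential is seeded from its simpler parent, so
the nested model can never lose likelihood), followed by a bounded
quasi-Newton polish and a derivative-free polish that rescues the flat
ridges of weakly identified fits.

Model selection is by the small-sample corrected AICc (ties: fewer
parameters, then fixed suite order). With ~15 observations and up to five
free parameters the plain-AIC penalty is too weak; in recovery
simulations AICc reduces the median relative BMD error by roughly five
percentage points. Plain AIC remains available (`criterion = "aic"`).

The benchmark response (BMR) defaults to 1.0 times the control SD of log2
expression, the common continuous-data convention; 1.349 or any other
multiple can be set via `bmr_factor`. The control SD itself defaults to a
*moderated* residual SD: the selected model's residual variance shrunk
toward the cohort median with 8 prior degrees of freedom. At three
replicates the raw residual SD carries ~20% relative noise which
propagates one-for-one into the BMR and then the BMD; moderation removes
most of that without biasing the scale. The unshrunk residual SD and the
control-replicate sample SD remain options.

The BMD solves `|f(c) - f(0)| = BMR` by a bracketed root search on
(0, 10 × c_top]. Confidence bounds are a two-sided 90% profile-likelihood
interval (a 95% one-sided BMDL): the model is constrained to pass through
the benchmark response at a candidate BMD — for every model the scale
parameter is eliminated analytically by that constraint — the remaining
parameters are re-optimized, and the bound lies where the concentrated
deviance `n log(RSS_c / RSS_hat)` crosses the 90% chi-square(1) quantile.
The reference RSS is the better of the unconstrained optimum and the
constrained optimum at the BMD itself, so optimizer slack at near-zero
residual noise cannot push the deviance negative. A side that never
crosses inside the search box `[bmd/10^4, 100 c_top]` is reported at the
box edge and flagged `boundary`; if profiling fails outright, a
2,000-draw parametric-bootstrap percentile interval is used and flagged.

## Postfilter and tPODs

`postfilter_bmds()` applies three exclusion rules: `BMDU/BMDL > 40`
(uninformative fits), `BMD` above the highest tested concentration, and
`BMD` more than 10-fold below the lowest nonzero concentration. The
filter is idempotent and the cap is configurable.

`derive_tpods()` then computes two summaries. The percentile tPOD is the
10th percentile of retained BMDs under the linear-interpolation (type 7)
quantile convention. The mode tPOD is the first (lowest-concentration)
mode of a Gaussian kernel density of `log10(BMD)` on a 512-point grid
spanning the data range plus three bandwidths; the bandwidth default is
Silverman's rule on the log10 values, with a scalar override. Mode
significance uses two rules: maxima below 5% of the global density
maximum are discarded as grid noise, and a mode must be separated from
its neighbour by an antimode dipping below 90% of the smaller mode's
density (10% prominence). The prominence level was calibrated on
simulated cohorts with planted bimodal BMD mixtures: genuine
between-cluster valleys show dip ratios of 0.63–0.83 while shoulder
artifacts from estimation noise sit at 0.99+, so 0.1 separates the
regimes with a wide margin. The first-mode gene set is every retained
gene with `log10(BMD)` below the first antimode; a unimodal density
returns all retained genes, flagged.

## Synthetic data

`make_truth()` and `simulate_counts()` generate fully specified
ground-truth experiments. Baseline means are lognormal
(`meanlog = log 60`, `sdlog = 1.3`), NB dispersions lognormal around 0.05
(`sdlog = 0.4`) — a typical bulk RNA-seq regime. A configurable minority
of genes (default 10%, mirroring a sparse-response compound; denser
regimes are a parameter away) carries a dose-dependent log2 shift, split
evenly across Hill (sigmoidal), saturating-exponential and linear shapes,
half up- and half down-regulated. Each responsive gene is assigned its
true BMD first — log-uniform across the nonzero design range, or drawn
from an explicit mixture on the log10 axis — and the curve parameters are
solved so the log2 shift crosses the benchmark response exactly there.
The generator's default benchmark response equals the dispersion-implied
per-sample noise SD (`sqrt(0.05)/log 2 ≈ 0.32` log2 units), so recorded
true BMDs mean the same thing as the 1-SD BMR the analysis applies; an
explicit `bmr` overrides this. Linear-shape targets are kept in the top
decade because a linear curve crossing the BMR at a low concentration
would imply an implausibly steep top-dose shift.

Counts are negative-binomial draws around
`baseline * 2^curve(conc)`, column-scaled so expected library sizes hit a
lognormally jittered target (`sdlog = 0.1`, emulating depth variation).
Each gene draws from its own seeded stream, so enlarging a truth table
never reshuffles existing genes.

What the generator does *not* emulate: read-level error, mapping
ambiguity, batch structure beyond replicate labels, gene-gene
correlation, non-monotone (e.g. U-shaped) dose responses, and
heteroscedastic log-scale noise. Passing recovery tests therefore show
that the estimators work under idealized NB sampling with monotone truth,
not that they are robust to all failure modes of real libraries.

## Behavior module

Larval locomotion tables (per-larva, per-minute bins with distance and
well-centred mean position) are summarized by `phase_metrics()`: baseline
distance over the last five light minutes, the startle delta (first
5-minute dark-phase distance minus the preceding 5 light minutes), and
the cumulative-duration percentage of the first dark phase spent in a
centred inner zone. Zone occupancy is decided per bin from the radial
distance of the bin's mean position; the default geometry (6 mm inner
circle in a 10 mm well) makes the inner zone 36% of the arena, which is
also the expected occupancy of a larva with uniform positional density —
the calibration used in the tests. Group comparisons use one-way ANOVA
followed by Dunnett-style many-to-one contrasts whose familywise max-|t|
null is approximated by Monte-Carlo draws (group means from independent
normals, pooled variance from a scaled chi-square; default 100,000 draws,
seeded). The Monte-Carlo route avoids critical-value tables and is
cross-checked against an independent multivariate-t implementation in the
test suite. A group with zero variance triggers a rank-based fallback
(Kruskal–Wallis plus pairwise Wilcoxon, Bonferroni) with a warning.

## Enrichment

`ora()` performs one-sided hypergeometric over-representation of a query
list against GMT gene-set collections, intersected with a user-supplied
universe (the recommended universe is all genes tested for DE, the
standard background correction), BH-adjusted, with terms larger than
1,000 members excluded by default — very broad terms are rarely
interpretable and are conventionally not reported.

## Degenerate inputs and edge rules

Constant genes get a Williams statistic of 0 and p = 1; zero pooled
variance with unequal means yields an infinite statistic. All-zero genes
are excluded from DE testing and reported with missing statistics. Ties
in p-values are broken by gene id so reports are deterministic. Fewer
than five retained BMDs skip mode detection with a warning (the
percentile tPOD is still computed from one value or more). A fold-change
ratio is always reported on the >= 1 scale. The `exp2`/`exp3` sign, the
response direction at the BMD, and the first-crossing convention for
non-monotone fitted curves (smallest crossing, flagged) are fixed as
described above.

## Problem sizes in the shipped tests

The package's own validation uses simulation sizes chosen to make the
statistical assertions sharp while staying comfortable on a laptop:
2,000-gene null cohorts for prefilter and DE calibration, a 200-gene
known-truth cohort for BMD recovery, a 5,000-gene end-to-end run with a
planted bimodal BMD mixture for tPOD recovery, 20 replicate DE cohorts
for FDR estimation, and 500 null simulations for the Dunnett familywise
error rate. `scripts/acceptance.R` re-runs the same computations from
scratch under a caller-supplied seed.

## Known limitations

BMD estimation from three replicates over a 10-fold-spaced series is
intrinsically noisy: in recovery simulations at realistic dispersion the
median relative BMD error is ~30–37% for the full model suite, and even
an oracle handed the true model family and true BMR achieves ~26%
(Hill-shaped genes alone: ~66%) — the spacing, not the estimator, is the
binding constraint. Fold-change-based prefiltering biases the retained
set toward larger-amplitude genes. The homoscedastic Gaussian error model
on log2 expression understates uncertainty for very low counts. The
Williams permutation null is shared across genes, which is valid
marginally but induces slight dependence between per-gene p-values. The
DE stage's strong dispersion moderation trades a little power at the
extremes for calibration at n = 3.
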