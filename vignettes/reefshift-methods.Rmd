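---
title: "Methods: thermal stress, community change, and recovery feasibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal stress, community change, and recovery feasibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefshift)
```

reefshift quantifies a coral-to-algae phase shift on Eastern Tropical
Pacific reefs from three kinds of monitoring data: a multi-decadal daily
sea-surface-temperature (SST) record, benthic-cover transects, and coral
belt transects. This vignette documents the models, the tunable parameters
that matter, the numerical choices, and what the synthetic-data generator
does and does not establish.

## Thermal-stress climatology

The climatology is two-stage: daily SST is averaged within each
year-month, and those year-month means are averaged, unweighted, across
the baseline years (default 1985–1990 plus 1993; 1991–1992 are excluded
because volcanic aerosols depressed the satellite record). The unweighted
second stage insulates the Maximum of Monthly Means (MMM) from unequal
month lengths. The bleaching threshold is MMM + 0.5 °C — the more
sensitive local variant rather than the MMM + 1 °C satellite-product
default — and the cooling threshold is the climatological monthly mean
− 0.5 °C, one value per calendar month.

Degree heating weeks (DHW) accumulate the *hotspot magnitude* SST − MMM
on days strictly exceeding the bleaching threshold, summed over a trailing
84-day (12-week) window and divided by 7 to give °C-weeks. Accumulating
magnitudes (not a day count) is the only reading consistent with the
°C-weeks unit, and matches the NOAA convention the threshold scheme
adapts; a `count_days` flag exposes the day-count alternative for
sensitivity analysis. A constant hotspot of *h* °C held for the full
window gives DHW = 12 *h* exactly, which the tests use as a closed-form
anchor. Missing days contribute zero to the window, with a warning once
more than 10 % of the covered range is absent; DHW is `NA` until the
first complete window. Exceedance counting is strict (`>` warm, `<`
cool); with non-zero offsets, ties have measure zero in real data.

Trend fitting is ordinary least squares (`stats::lm`) on decimal years
(days / 365.25), which removes leap-year drift from per-decade slope
conversions. The same wrapper serves the SST trend (optionally with an
ENSO-index covariate) and the annual warm-/cool-day frequency trends.

## SIMPER with permutation inference

Between two labelled periods, the Bray–Curtis dissimilarity between
samples *a* and *b* decomposes exactly as
$d(a,b) = \sum_j |a_j - b_j| / \sum_k (a_k + b_k)$,
and SIMPER averages the per-variable terms over every between-period pair
of transects. The per-variable sum of averages therefore equals the mean
between-group dissimilarity to machine precision (asserted at 1e-12), and
the consistency ratio is the mean/SD of the pairwise terms. Proportions
enter as-is: the inputs are already on a common scale, so no
standardization or square-root transform is applied.

Inference permutes the period labels across samples (within a site for
site-level runs) and recomputes each variable's average between-group
contribution. With the add-one estimator
$p = (1 + \#\{\text{perm} \ge \text{obs}\}) / (1 + n_\text{perm})$
and the conventional 100 permutations, the attainable floor is
1/101 ≈ 0.0099 — the value that appears wherever a contribution is more
extreme than every permutation. The source analysis describes comparing
within- and between-group dissimilarities without fixing a statistic; the
contribution-based statistic above was adopted because it is the quantity
SIMPER reports and it reproduces the observed p-value floor. An explicit
seed is required for every permutation run; there is no default.

Missing cells are imputed before analysis with the site-period mean of
the variable, falling back to the variable's global mean when a variable
is absent from an entire site-period; a count of imputed cells is
attached to the result. Ranking ties are broken by variable name for
deterministic reports. Percentage change is 100 × (after − before) /
before and is flagged `NA` (not an error) when the before mean is zero.
The before/after windows are required configuration, not defaults,
because the study's own period definitions varied between analyses.

## Diversity, prevalence, and proportion utilities

Shannon diversity uses the natural log (the reported site means, ≈0.1–1.3
for ≤13 taxa, are only consistent with nats). Bleaching prevalence is the
fraction of colonies in a configurable set of non-healthy states; the
inclusive default (pale through fully bleached) is a choice, not a claim
about the source data — the narrower set excluding `pale` is first-class
configuration and the chosen set is recorded on the output. Proportions
destined for logit-link modelling are clipped to [0.0001, 0.9999].

## The recovery-feasibility index (ERFI)

Six site-level indicators — live coral, CCA, turf, cyanobacteria cover,
bleaching prevalence, Shannon diversity — are aggregated over a date
window (unweighted mean over transects and dates, the simplest defensible
reading; alternatives are selectable), z-scored across sites, and
decomposed by PCA (`stats::prcomp`, i.e. SVD of the standardized matrix,
numerically stable at 9 × 6). Each variable's weight is the sum of its
absolute loadings on the first three components,
$L_j = |l_{j1}| + |l_{j2}| + |l_{j3}|$, which is invariant to eigenvector
sign flips. Expert direction weights (defaults coral +4, CCA +2,
diversity +2, cyanobacteria −2, bleaching −2, turf −3) give composite
weights $C_j = L_j D_j$; the raw site score is $\sum_j C_j z_{ij}$ and a
min–max normalization maps scores to [0, 1]. Because z columns sum to
zero, raw scores always sum to zero. Both raw and normalized scores are
reported: the source presentation mixes the two, so the choice is left to
the user.

Numerical choices: sample SD (n − 1) for the z-scores, exposed as a flag
since the convention is not stated anywhere authoritative;
zero-variance columns dropped with a message; fewer than three
retrievable components (e.g. three sites give rank 2 after centering) are
summed as available and flagged; degenerate all-equal raw scores
normalize to 0.5 with a warning. Bleaching prevalence entering ERFI comes
from belt transects by default; the benthic `bleached` cover category is
a documented alternative.

## The synthetic-data generator

The generator's defaults state the study world; they were fixed from the
reported conditions and are not tuned per test.

* **SST**: 1985-01-01 to 2025-03-31; annual mean 28.0 °C; seasonal
  amplitude 1.0 °C peaking near day 105 (boreal-spring maximum typical of
  the eastern Pacific warm pool); trend 0.23 °C/decade; AR(1) noise with
  lag-1 correlation 0.75 and stationary SD 0.25 °C (typical of daily
  satellite SST residuals), initialized at the stationary distribution so
  short series have no burn-in artifact; half-sine warm pulses for the
  1997–98, 2009–10, 2015–16, 2019–20 events and a triple-pulse 2023–24
  event. These choices land the baseline climatology near MMM = 29.08 °C
  and the record maximum near 31.2 °C by construction of the stated
  components, not by per-seed calibration.
* **Benthic cover**: per-transect Dirichlet draws (simplex constraint
  holds exactly) with total concentration 60 — transect-level SD of a
  20 % cover category ≈ 5 points, matching replicate-transect scatter in
  reef point-intercept data. The concentration profile switches from a
  coral-dominated to a turf-dominated mix at the configured breakpoint;
  category means follow the reported before/after composition. A per-site
  quality tilt multiplies favourable categories by exp(1.5 q) and
  unfavourable ones by exp(−1.2 q), q ∈ [−1, 1], so that site contrasts
  span the observed range (≈ 45 % coral at the best site down to ≈ 3 % at
  the worst).
* **Belt transects**: Poisson colony counts (mean 80, dense *Pocillopora*
  stands), multinomial taxon allocation from a geometric abundance
  profile whose evenness is solved so the *expected plug-in Shannon
  estimate* matches the site's target (`site_diversity` = exp(H)); the
  plug-in estimator is biased low by ≈ (S − 1)/2n (Miller–Madow), and the
  reported site values are themselves plug-in statistics, so the
  generator targets the statistic rather than the population entropy.
  Health states are drawn per colony with a site-level logit-normal
  bleached fraction (grand mean logit −1.17 ≈ 23 %, site spread scaled by
  the reported 0.48 between-site SD) split across the four non-healthy
  states.

What a green test on synthetic data establishes: the pipeline's algebra,
its permutation machinery, and its ability to recover generating
parameters and strong site gradients at realistic noise levels. What it
does not establish: agreement with the deposited field tables (not
redistributable here), spatial or temporal autocorrelation between
transects, observer effects, or the landslide/sedimentation dynamics that
shaped the real after-period. Site rankings among closely spaced
mid-gradient sites are genuinely stochastic at 3–6 transects per survey,
which is why the acceptance checks assert rank concordance averaged over
replicate worlds rather than one exact nine-site order.

## Known limitations

* The SIMPER permutation statistic is one defensible reading of an
  under-specified procedure; PERMANOVA/ANOSIM-style alternatives are out
  of scope.
* ERFI carries no uncertainty quantification, matching its source
  definition; treat small score differences as ties.
* The pipeline configuration format is JSON only (no YAML parser in the
  supported dependency set).
* Logger aggregation assumes UTC-consistent timestamps; no clock-drift
  correction is attempted.
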