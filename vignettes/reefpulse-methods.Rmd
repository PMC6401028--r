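---
title: "Methods: bleaching response, thermal history, and community change on equatorial reefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bleaching response, thermal history, and community change on equatorial reefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefpulse)
```

`reefpulse` packages the full statistical chain of a coral-bleaching
field study on an equatorial atoll chain: scoring bleaching from
photo-quadrat point counts, deriving heat-stress and climate-history
metrics from weekly satellite SST, quantifying local human disturbance,
and asking (i) which environmental factors predict the bleaching
response and (ii) which factors structure the coral community. This
vignette documents the models, the parameter choices, and the places
where the design was genuinely open.

## Survey data model

A survey is a set of point records: site, atoll, depth band (3–5 m or
10–12 m), year, transect, image, point index, a benthic label from a
controlled vocabulary, a genus-level taxon for coral-derived points, and
a bleaching severity for scoreable coral points. The standard design is
50 points in each of 25 images per transect (1,250 points). Cover is
computed on the pooled transect, not the five 10-m replicates — the
replicate-level computation exists (`by_transect = TRUE`) but is not the
default. Coral mortality is carried as three distinct dead states
(recently dead, turf-covered, CCA-covered); these enter live-fraction
denominators but are not scoreable on the bleaching-severity scale,
which covers live (normal through 80–100 % bleached) and recently dead
colonies only.

The community matrix holds each taxon's share of live coral per
site/depth/year row. The rare-taxon filter removes taxa whose share of
the *pooled* live-coral observations across all rows does not exceed
0.5 % (a per-row filter would let a taxon flicker in and out between
rows); rows are then renormalized. Applying the filter twice changes
nothing, and `min_share = 0` is the identity. `RA_POR` — the relative
abundance of stress-tolerant *Porites* (massive morphotypes plus
*Porites rus*) — is computed within live coral, consistent with the
community matrix.

## Bleaching Response Index

Bleaching severity is tallied over seven ordered categories
(normal, pale, 0–20 %, 20–50 %, 50–80 %, 80–100 % bleached, recently
dead). The BRI is the weighted mean of the category proportions with
weights 0–6 and divisor 6, giving an index in [0, 1]. Published variants
of this formula differ in whether an implicit zero-weight category
precedes the seven scored ones; the alternative reading (weights 1–7,
same divisor) is available as `convention = "printed"`, and a 0–100
percentage scale as `percent = TRUE`. Proportions, not percentages, are
the expected input. The index is linear in the tally, which yields two
properties the tests exercise: pooling tallies pools BRIs by point
count, and moving probability mass to a more severe category can never
decrease the index. The year-to-year difference `delta_bri()` is defined
as earlier-event minus later-event BRI, so a weakened later response is
a positive change.

## Thermal metrics

Weekly SST series are validated to a strict 7-day grid; gaps up to two
weeks are linearly interpolated and larger gaps rejected. The
climatology is computed over a configurable baseline (default
1985–2009, the pre-event period): weekly values are binned by calendar
month, averaged over the whole baseline, and the warmest month is the
maximum monthly mean (MMM). Degree heating weeks follow the heritage
Coral Reef Watch rule: HotSpot(t) = max(0, SST(t) − MMM), and DHW(t) is
the sum over the trailing 12 weeks (inclusive) of HotSpots ≥ 1 °C, with
a partial window for the first 11 weeks. Window length and HotSpot
threshold are arguments. DHW is computed by direct window summation
rather than a cumulative-sum difference; the latter accumulates rounding
drift over multi-decade series.

Event metrics over a stated window: maximum SST, maximum DHW, and week
counts above 4 and 8 °C-week. Exceedance counts (`WkDHW4`, `WkDHW8`,
`fDHW4`, `fDHW8`) use strict inequality; the Alert Level I duration
(`weeks_alert1`) uses DHW ≥ 4. Historical metrics over the baseline:
coefficient of variation of weekly SST; standard deviations across years
of the annual maximum weekly and monthly-mean SST; means of annual
maximum weekly SST and annual maximum DHW; mean annual exceedance-week
counts; and the fractions of years whose maximum DHW exceeds 4 and 8.
All standard deviations are sample (n − 1) statistics, and years are
calendar years of week-start dates.

## Human-disturbance metric and site table

The population metric divides each closest village's population by its
along-coast distance to the site, sums over the designated villages, and
standardizes by the across-site mean, so standardized values average
exactly 1. Exposure is a user-supplied ordinal (1–4); PAR, chlorophyll-a
and significant wave height are consumed as pre-extracted site values.
The site-table join keeps sites missing from a source with explicit
`NA`s and a join report; `strict = TRUE` upgrades that to an error.

## Inference chain

**Two-sample tests.** Each sample is screened with Shapiro-Wilk at
α = 0.05; two normal-looking samples get Welch's t, otherwise a
permutation test on the difference in group means — exhaustive over all
assignments when there are at most 10⁵, else Monte Carlo with
p = (1 + #{|d*| ≥ |d|}) / (1 + B), B = 9,999 by default. A constant
sample cannot support a normality claim and is routed to the
permutation path.

**Univariate screen.** Ordinary least-squares regressions of the
response on each predictor separately, reporting R with the slope's
sign, the root-mean-square residual, and Bonferroni flags at α/m for
α ∈ {0.01, 0.05, 0.10}. The family size m defaults to the number of
predictors screened and is recorded on the output, since different
choices of family change only the flags, not the statistics.

**GAM / GLM fitting.** Smooth terms are penalized cubic regression
splines with shrinkage (`bs = "cs"`, basis dimension k = 3, so a term
can be shrunk entirely out of the model); thin-plate shrinkage splines
are available for sensitivity checks, linear terms and one pairwise
interaction for GLM-style models. Smoothness is selected by REML, the
stable choice at small sample sizes — under GCV a genuinely present
smooth is occasionally shrunk to zero when a correlated competitor
carries overlapping information; the GCV score is still reported, as is
AICc = −2ℓ + 2k + 2k(k + 1)/(n − k − 1) with k the effective parameter
count of the penalized fit. A smooth whose covariate has at most k
unique values (e.g. an exceedance frequency over 25 baseline years has
0.04 granularity) is demoted to a linear term rather than failing.
Model comparison ranks by AICc and runs analysis-of-deviance F-tests on
declared nested pairs; a non-positive deviance drop reports F = 0 rather
than an error. Each fitted term also reports an effect direction — the
sign of the association between its partial effect and its covariate,
with 0 for a numerically null term — used by the sign-recovery checks.

**Community analysis.** Bray-Curtis dissimilarity, NMDS and PERMANOVA
are implemented from first principles (the vegan package serves only as
an independent cross-check in the test suite). NMDS minimizes Kruskal's
stress-1 by alternating isotonic regression of configuration distances
on the dissimilarity ranks with a Guttman majorization update; the best
of 20 restarts (the first from classical metric scaling, the rest
random) is returned, centered, rotated to principal axes, and
axis-flipped to non-negative coordinate sums so a fixed seed gives a
unique answer. Because only ranks enter, any strictly monotone transform
of the input dissimilarities leaves the stress unchanged. PERMANOVA
Gower-centers the squared dissimilarities into an inner-product matrix
and takes sequential (Type I) sums of squares as increments of
trace(H G) over the cumulatively built hat matrices; continuous
covariates enter with 1 df, categorical factors with levels − 1.
P-values come from unrestricted permutation of observation rows —
exhaustive enumeration when all n! arrangements fit within the requested
permutation count, Monte Carlo with the add-one rule otherwise. On
Euclidean distances with one factor the pseudo-F reproduces classical
ANOVA exactly. Term order matters under sequential SS; the default
pipeline order places the disturbance metric first, then thermal
history, climate variability, and chlorophyll, and the order is
user-configurable and reported.

**Sampling sufficiency.** For each subsample size n, n images are drawn
without replacement 1,000 times; the percent cover of live coral and of
the four most common taxa (ranked on the full image set) is recomputed
from the pooled points of each draw, and the coefficient of variation
(sample sd / mean) summarizes the spread; categories with zero mean
report `NA` rather than an infinite CV. Without replacement, the CV at
n = all images is exactly zero. `minimal_images()` returns the smallest
n with every tracked category below the threshold (default CV < 0.25).

## The synthetic study system

The generator emulates the statistical structure the analysis assumes,
not ocean physics. Its defaults describe a 14-site, three-atoll
equatorial chain and were fixed once, from the study system's described
regime, before any acceptance checks:

* **SST** (weekly, 1985–2012): mean 29 °C; seasonal sinusoid of
  amplitude 1 °C (~2 °C annual range) peaking in boreal spring; an AR(1)
  interannual component with 1-year lag correlation 0.5 whose stationary
  sd at the equator is 1.4 °C — twice the seasonal component's sd,
  matching the regime where year-to-year variation dominates
  seasonality — decaying with an e-folding of 2° latitude; 0.25 °C white
  noise; and planted events (2004, 2009) adding 2 °C for 24 weeks from
  1 December, spanning the warm season. The interannual path is a single
  basin-scale realization shared by all sites and scaled by each site's
  latitude-dependent amplitude: ENSO is one ocean state, and
  site-independent paths would inject physically spurious cross-site
  heat-stress noise.
* **Environment:** winter PAR rises weakly with |latitude|
  (1 mol photons m⁻² d⁻¹ per degree around a 40 mol photons m⁻² d⁻¹
  level) with substantial site-level variation (sd 2.5) representing
  patchy cloudiness; chlorophyll falls away from the equatorial
  upwelling; one atoll is the urbanized center (villages of 4,000–12,000
  people) while the others are rural (100–900).
* **Bleaching:** each coral point's taxon comes from the site's true
  community; its severity from an ordered-categorical model. The
  site-level stress dose is β_stress·MaxDHW + β_par·(PAR − 30) −
  β_history·fDHW4 (defaults 0.05 per °C-week, 0.6 per PAR unit, 8 per
  unit frequency), multiplied by taxon susceptibility (1.0 for
  *Acropora* down to 0.15 for *Porites rus*) and by a lognormal colony
  frailty (sd 0.6 on the log scale), then cut at equally spaced
  thresholds (2, 3, …, 7) into the seven categories. The frailty is
  multiplicative so that a zero dose produces exactly no bleaching; the
  PAR reference (30) sits below the realistic winter range so the light
  term keeps the dose positive and the thermal-history buffer acts as
  damping rather than pushing sites into an uninformative floor. The
  coefficient scale was chosen so the cross-site univariate correlation
  structure reproduces the qualitative pattern of the study system —
  light the strongest positive correlate of bleaching, past variability
  and heat-stress frequency strongly negative — with site BRIs spanning
  roughly 0–0.55.
* **Communities:** Dirichlet draws (concentration 300) around a base
  mixture; the *Porites rus* weight is tilted by
  exp(pop_effect · (pop_metric − 1)) with pop_effect = 2, a strong
  default reflecting the near-dominance of the weedy species at heavily
  disturbed sites.

What the generator does *not* emulate — and what passing tests therefore
cannot show about field data: spatial autocorrelation between adjacent
quadrats and nearby sites, observer misclassification, depth-band
differences (scenarios emit the shallow band only), genuine ENSO
dynamics or event timing, tissue-level acclimatization, and recruitment
dynamics between survey years.

## Numerical and reproducibility choices

* All scenario randomness flows from one seed; per-site substreams are
  derived arithmetically (seed · 10007 + site · 97 + stage, kept below
  2³¹), so site j's data do not depend on how many sites precede it.
* NMDS convergence uses a stress-change tolerance of 1e-8 with at most
  500 majorization iterations per start; a collapsed (all-coincident)
  configuration aborts the start rather than dividing by zero.
* Permutation p-values use the add-one rule in Monte Carlo mode and the
  plain proportion in exhaustive mode; comparisons use a 1e-12 slack so
  ties of the observed statistic with its own permutation count as
  exceedances.
* Degenerate inputs fail loudly and early: empty tally scopes, all-zero
  community rows, aliased PERMANOVA terms, SST gaps over two weeks, and
  non-positive coastline distances are errors naming the offender.
* The test suite sizes follow the design: 1,000-replicate oracle and
  property loops for DHW and BRI, 2,000 null pairs for two-sample
  calibration, 500 null PERMANOVA scenarios at 199 permutations, and 200
  full-scenario replicates for the power and sign-recovery checks.

## Known limitations

* The BRI weight convention cannot be fully pinned down from published
  formula variants; both conventions are implemented and the default is
  the one consistent with indices in [0, 1].
* PERMANOVA uses unrestricted permutation (no strata), appropriate for
  the unblocked design but not for repeated-measures extensions.
* Gaussian-identity GAMs can in principle predict outside [0, 1] for a
  bounded index; the family is an argument for users who prefer a
  quasi-binomial variant.
* The sufficiency analysis treats images as exchangeable; spatial
  structure along the transect would make its CVs optimistic.
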