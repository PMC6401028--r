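# reefpulse

Analysis pipeline for coral-bleaching surveys on equatorial atoll reefs.

Reefs near the equator experience a peculiar climate: weak seasonality but
large year-to-year sea-surface-temperature (SST) swings driven by ENSO.
`reefpulse` implements the statistical chain used to ask whether that
history of frequent heat stress — together with light, water quality, and
local human disturbance — shapes how strongly corals bleach when a new
heat-stress event arrives, and how it restructures the coral community.

The pipeline covers:

* **Photo-quadrat surveys** — validated ingestion of point-count tables
  (50 points x 25 images per transect), benthic cover, taxon community
  matrices with a rare-taxon filter (taxa ≤ 0.5 % of live-coral
  observations are dropped), and live-fraction / *Porites* relative
  abundance summaries.
* **Bleaching Response Index (BRI)** — severity proportions over the seven
  ordered categories *c₁* (normal) … *c₇* (recently dead) are combined as

  BRI = (0·c₁ + 1·c₂ + 2·c₃ + 3·c₄ + 4·c₅ + 5·c₆ + 6·c₇) / 6

  so BRI runs from 0 (no response) to 1 (all colonies recently dead).
* **Thermal metrics from weekly SST** — maximum monthly mean (MMM)
  climatology; HotSpot = max(0, SST − MMM); Degree Heating Weeks, the
  trailing 12-week sum of HotSpots ≥ 1 °C; event metrics (MaxSST, MaxDHW,
  weeks with DHW > 4 / > 8 °C-week); and 25-year climate-history metrics
  (CV of weekly SST, σ of annual maxima, mean annual maximum DHW, and the
  frequencies fDHW4 / fDHW8 of years whose maximum DHW exceeds 4 / 8).
* **Human disturbance** — the population metric: village population over
  along-coast distance, standardized to an across-site mean of 1.
* **Inference** — Shapiro-Wilk-gated Welch / permutation two-sample tests
  (exhaustive enumeration on small samples); Bonferroni-screened
  univariate regressions; GAMs with cubic shrinkage splines (basis
  dimension 3) compared by second-order AICc and analysis-of-deviance
  F-tests; GLMs with pairwise interactions; Bray-Curtis dissimilarity,
  non-metric multidimensional scaling (Kruskal stress-1, isotonic
  regression + Guttman majorization, written from first principles), and
  sequential-sums-of-squares PERMANOVA with permutation p-values, also
  from first principles.
* **Sampling sufficiency** — Monte Carlo resampling of n images to find
  the smallest image count whose cover estimates have a coefficient of
  variation below 0.25.
* **Synthetic scenarios** — a seeded generator emulating the study
  system end-to-end (shared basin-scale ENSO state, latitude-graded
  interannual variance, planted event years, ordered-severity bleaching
  driven by heat stress, winter light and thermal history, and
  Dirichlet communities whose weedy *Porites rus* share rises with the
  population metric), so every stage is testable without field data.

## Worked example

```r
library(reefpulse)

world <- simulate_site_set(scenario_config(n_sites = 14, seed = 1))
bri   <- bri_table(world$surveys)
tab   <- merge(bri, world$site_table, by = c("site_id", "depth_band"))

## univariate screen of the bleaching response against site predictors
screen <- univariate_screen(tab$bri, tab[c("PAR", "fDHW4", "CV_SST")])
screen[, c("predictor", "R", "RMSE", "p_raw")]
#>   predictor          R       RMSE        p_raw
#> 1       PAR  0.6343805 0.12840939 1.481898e-02
#> 2     fDHW4 -0.8311727 0.09236161 2.299409e-04
#> 3    CV_SST -0.8620458 0.08419147 7.343889e-05
```

Bleaching is stronger at bright (high-PAR) sites and much weaker at sites
with high historical SST variability and heat-stress frequency — the
thermal-history buffer. A two-smooth GAM quantifies the same structure:

```r
fit <- fit_response_model(tab, "bri", smooth = c("PAR", "fDHW4"))
fit
#> <rp_model_fit> bri ~ s(PAR, bs = "cs", k = 3) + s(fDHW4, bs = "cs", k = 3)
#>   n = 14 | adj r2 = 0.761 | deviance explained = 80.3% | AICc = -16.46
```

Community structure against the disturbance gradient:

```r
cover <- compute_cover(world$surveys, detail = "label_taxon")
comm  <- build_community_matrix(cover)          # sites x taxa shares
bc    <- bray_curtis(comm)
ord   <- nmds(bc, seed = 1)                     # stress ~ 0.02
pd    <- world$site_table
pt    <- permanova(bc, pd, c("pop_metric", "fDHW4", "CV_SST", "chl_a"),
                   n_perm = 999, seed = 1)
pt[pt$term == "pop_metric", c("term", "Df", "F.model", "R2", "p")]
#>         term Df F.model        R2     p
#> 1 pop_metric  1 86.4429 0.8497993 0.001
```

The population term dominates (R² ≈ 0.85, p = 0.001): heavily disturbed
sites converge on *Porites rus*-dominated communities. The full chain —
ingestion through PERMANOVA and the image-sufficiency analysis — runs as
one call:

```r
man <- run_pipeline(list(simulate = list(n_sites = 14)),
                    out_dir = "run1", seed = 1)
```

A thin command-line wrapper is installed at `inst/cli/reefpulse.R`
(`Rscript reefpulse.R run-all --out run1 --seed 1`).

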