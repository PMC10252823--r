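# isofoodweb

Stable-isotope food-web and trophic-niche analysis for restored coastal
wetlands.

Restoration ecologists judge whether a rehabilitated mangrove has recovered
its *function* — not just its trees — by asking whether the aquatic food web
works like that of an unmodified reference site. Stable isotopes carry that
evidence: a consumer's δ¹³C traces which basal carbon source (mangrove C₃
plants, phytoplankton, seston, epiphytes, seagrass) built its tissue, and
δ¹⁵N traces its trophic level. `isofoodweb` implements the full statistical
workflow for such studies, for ecologists comparing restored and reference
communities sampled across areas and seasons:

* **Preprocessing** — δ notation, lipid normalization
  (δ¹³C − 3.32 + 0.99 · C:N when C:N > 3.5), trophic-discrimination
  correction δ_corr = δ − (TL − 1)·Δ with Δ = (0.4, 3.4) ‰ per trophic
  level, Pearson screening of redundant sources, and Monte-Carlo
  mixing-polygon feasibility checks.
* **Bayesian mixing models** — per consumer group, δ_jX ~
  N(Σₖ pₖ(μ_kX + λ_X), Σₖ pₖ²(σ_kX² + τ_X²) + ε_X²) with a flat
  Dirichlet prior on the diet p, zero-mean discrimination (τ = 1.3, 1.0 ‰),
  adaptive random-walk Metropolis on log-ratio coordinates, and
  Gelman–Rubin / Geweke diagnostics.
* **Community isotopic-niche metrics** — the six Layman metrics (NR, CR,
  TA, CD, MNND, SDNND), standard ellipse areas SEA = π√det(S),
  SEA_C = SEA·(n−1)/(n−2), and a Bayesian SEA posterior.
* **Dietary-niche hypervolumes** — Gaussian-KDE hypervolumes over
  posterior diet proportions (z-standardized jointly across areas) and
  Sørensen overlap 2·V∩/(V₁+V₂) with bootstrap CIs.
* **Environmental statistics** — correlation-matrix PCA of log10(x+1)
  variables, tie-corrected Kruskal–Wallis tests, Dunn–Bonferroni
  post-hocs.
* **A seeded synthetic-data generator** that emulates the 4-area × 3-season
  study design with known true diets, so every stage is testable without
  field data.

See `vignettes/methods.Rmd` for the models, parameter choices and known
limitations.

## Worked example

Simulate the default study, correct the consumers, and estimate the diet of
the reference-mangrove fish community in the "nortes" season:

```r
library(isofoodweb)

scenario  <- default_scenario(seed = 1)
consumers <- generate_consumers(scenario)
sources   <- generate_sources(scenario)

srcsum    <- summarize_sources(sources[sources$source != "seston", ])
corrected <- trophic_correct(consumers, scenario$guilds, scenario$tdf_per_level)

grp <- subset(corrected, area == "RefM" & season == "nortes" & taxon_group == "fish")
fit <- fit_mixing_model(grp, subset(srcsum, season == "nortes"),
                        settings = mcmc_desk_profile(), seed = 7,
                        group = list(area = "RefM", season = "nortes",
                                     taxon_group = "fish"))
fit
#> Group: RefM / nortes / fish
#>         source    median       lower     upper pct pct_lower pct_upper  rhat
#>      C3_plants 0.2735966 0.056462439 0.4705728  27         6        47 1.002
#>      epiphytes 0.1390772 0.008764376 0.3481420  14         1        35 1.002
#>  phytoplankton 0.4094179 0.011581060 0.8604821  41         1        86 1.003
#>       seagrass 0.1647693 0.017839175 0.3596803  16         2        36 1.002
```

Each row is a basal source: `median` is the posterior median proportion of
that source in the group's assimilated diet, `lower`/`upper` the central 95%
credible interval (`pct_*` the same in percent), and `rhat` the split-chain
convergence diagnostic (values near 1 mean the 3 chains agree). The
generator's true diet for this cell is (C₃ 0.34, phytoplankton 0.28,
seagrass 0.30, epiphytes 0.09): every truth is covered by its interval, and
the wide phytoplankton interval is the honest signature of a 4-source /
2-tracer problem.

Community-level niche metrics for the reference area (one point per taxon):

```r
layman_metrics(community_points(subset(corrected, area == "RefM")))
#>     nr   cr   ta   cd mnnd sdnnd n_points
#> 1 1.67 6.65 7.85 1.25 0.32  0.24       30
```

`nr`/`cr` are the δ¹⁵N and δ¹³C ranges (trophic length and basal-resource
diversity, ‰), `ta` the convex-hull niche area (‰²), `cd`, `mnnd`, `sdnnd`
the spread and packing of the 30 taxa in isotope space.

`run_pipeline()` chains all stages (screening, polygon check, Layman/SEA,
one mixing model per area × season × taxon group, hypervolume overlaps
against the reference area, environmental PCA and rank tests) and writes
per-stage CSVs, a JSON summary, and a seeded run log.

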