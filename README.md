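# finchtrack

Movement-ecology toolkit for VHF radio-telemetry of small territorial
birds — built around the tracking workflow used for Darwin's finches on an
arid island coast, where tagged birds are located by taking compass
bearings from road-side stations, ranges are small (hectares), and the
questions are where a bird lives, which habitats it prefers, and how far
it commutes to a communal roost at night.

The package implements, in a planar (UTM-like) metre frame:

* **Azimuthal telemetry model (ATM).** Each observed bearing is modelled
  as von Mises around the true azimuth from observer to bird,
  `a_i ~ vM(θ(o_i, p_j), κ)`, with the concentration κ shared across all
  bearings of an individual, a uniform position prior over the
  intersection of detection-range discs (600 m default), and κ ~ U(0, 200].
  Fitting is Metropolis-within-Gibbs with burn-in adaptation
  (`atm_fit()`), plus geometric biangulation (`ray_intersection()`),
  fix filtering (off-land estimates, shallow inter-bearing angles), and
  blind-test relocation error.
* **Home ranges.** Bivariate-normal kernel utilization distributions with
  the reference bandwidth `h = sqrt((s²_x + s²_y)/2) n^(-1/6)`, 95%
  range / 50% core isopleths clipped to land, minimum convex polygons with
  rarefaction curves, and directional range overlap.
* **Habitat selection.** Availability vs usage per habitat, the Neu
  chi-square goodness-of-fit test, Bonferroni-corrected usage confidence
  intervals with the classical positive/neutral/negative direction rule,
  and Jacobs' preference index `D = (r − p)/(r + p − 2rp)`.
* **Commuting metrics.** Day/night classification, distances to the nest,
  night/day commute ratios, and communal-roost entry tallies.
* **Synthetic tracking study.** A deterministic banded coastal landscape
  (beach, Manzanillo forest, road, pond, dry forest), ground-truth tracks
  (diurnal activity around the nest, nocturnal commuting to a coastal
  roost), and noisy bearings from road/path stations — so the whole
  pipeline is testable end-to-end without any field data.

See `vignettes/finchtrack-methods.Rmd` for the models, defaults, and
design choices.

## Worked example

Simulate the default study, triangulate one bird, estimate its ranges,
and test habitat selection:

```r
library(finchtrack)

scen <- synthetic_scenario(seed = 2)     # 5 birds, kappa = 60, 600 m range
brg  <- subset(scen$bearings, individual_id == "bird1")

post  <- atm_fit(brg, atm_config(n_iter = 20000, n_burn = 4000, seed = 1))
fixes <- filter_fixes(point_estimates(post), scen$landscape$land)$retained
relocation_error(fixes, scen$truths$bird1$positions)$mean_m

h    <- href_bandwidth(cbind(fixes$x, fixes$y))
ud   <- kernel_ud(cbind(fixes$x, fixes$y), h)
hr95 <- isopleth(ud, 95, land = scen$landscape$land, individual_id = "bird1")
selection_table(hr95, scen$landscape, fixes)
```

which prints (abridged):

```
kappa: median 59.3, 95% CI [33.1, 95.7], ESS 225
relocation error: 27.9 m over 36 retained fixes
href = 61.4 m; home range (95%) 21.29 ha; core (50%) 5.34 ha; MCP 8.60 ha
selection_table (bird1): chi2 = 6.41, df = 4, p = 0.171
 individual_id           habitat availability used usage_prop expected chi2_part  ci_low ci_high direction   jacobs
         bird1             beach       0.0265    0      0.000    0.953   0.95322 0.00000   0.000  negative -1.00000
         bird1 manzanillo-forest       0.3297   12      0.333   11.868   0.00146 0.13096   0.536   neutral  0.00826
         bird1        paved-road       0.0234    0      0.000    0.842   0.84229 0.00000   0.000  negative -1.00000
         bird1      inland-water       0.0721    6      0.167    2.597   4.45876 0.00667   0.327   neutral  0.44014
         bird1        dry-forest       0.5483   18      0.500   19.739   0.15323 0.28535   0.715   neutral -0.09662
```

Read the table row-wise: the bird never used the beach or the road
although they make up ~5% of its range (Jacobs' D = −1, negative
selection), used the dry forest in proportion to its dominance
(D ≈ −0.1, neutral), and the posterior for the bearing-error
concentration recovers the generating value (κ = 60). The 27.9 m
relocation error is what the calibrated bearing noise is designed to
produce — a few tens of metres, as hand-held VHF equipment achieves.

Published per-bird selection tables can be fed in directly from their
printed availability proportions and relocation counts:

```r
p  <- c("beach" = 0.032, "inland-water" = 0.025, "manzanillo-forest" = 0.158,
        "dry-forest" = 0.700, "paved-road" = 0.084)
selection_from_counts(p, c(1, 0, 1, 28, 0), individual_id = "JP4645")
```

The full synthetic-to-report pipeline is `run_pipeline(pipeline_config())`
(or `Rscript inst/scripts/run_pipeline.R --seed 1 --out out/`), which
writes bearings (CSV), habitats and home ranges (GeoJSON), and a JSON
report with per-bird κ summaries, areas, selection tables, commute
metrics, and a reproducibility manifest.

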