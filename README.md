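# patchlink

Graph-theoretic landscape connectivity and community-diversity analysis for
small semi-natural habitat patches in fragmented agricultural landscapes.

Many industrial micro-sites — fenced water-abstraction plots, pipeline
stations, extensively mown verges — hold remnant grassland inside intensive
cropland. Whether such sites sustain diverse plant and insect communities
depends on local conditions (soil, vegetation structure, floral resources),
on how well each site is connected to the surrounding habitat network, and
on the agrochemical pressure of the fields around it. `patchlink`
implements the full analysis chain for that question, plus a seeded
synthetic-data generator so the whole chain is testable with known ground
truth.

## What it computes

**Connectivity.** From a categorical land-use raster (2-m cells, ESRI
ASCII grid or in-memory matrix) and a class→resistance table (tiers 1 /
10 / 100 / 1000 for habitat / favourable / unfavourable / barrier),
`patchlink` extracts habitat patches (8-connected components), computes
least-cost distances (accumulated resistance × length; free movement
within patches), builds the planar non-thresholded patch graph
(cost-weighted Voronoi adjacency), and evaluates the probability of
connectivity

    PC = Σ_i Σ_j a_i a_j exp(-k d_ij) / A²

together with each patch's importance `dPC_i = 100 (PC − PC'_i)/PC`, where
`PC'` is recomputed after removing patch i. The decay `k = −ln(p*)/d*` is
calibrated per taxon (dispersal distances 100/300 m for butterflies and
orthopterans, 150/500 m for flora; `p* = 0.05`). Each study site inherits
the dPC of its patch.

**Community metrics.** Per-site species richness (with a congeneric
collapse rule for genus-level records), total abundance (quadrat counts
for plants, individuals for insects), Pielou evenness `J = H/ln S`,
community-weighted mean traits (dispersal, specialization, pollination
dependence) with renormalization over trait-known taxa, the co-occurrence
specialization index `θ = γ/μ(α)`, and genus-level trait propagation under
unanimity.

**Covariates.** Area-weighted mean herbicide treatment-frequency index
(TFI) of field polygons within 100-m and 300-m buffers, missing when less
than half of the buffer is documented; floral availability; herbaceous
height-class covers.

**Inference.** The fixed three-predictor Gaussian linear model
`response ~ herbicide + connectivity + local` (z-scored continuous
predictors, clay as soil reference) for every taxon × response, preceded
by a collinearity screen that never co-selects variables with `|r| > 0.3`;
pairwise-complete Pearson correlation matrices across taxa (0.01 flags);
Cook's distance, spread-vs-fitted and permutation Moran's I diagnostics.

**Synthetic studies.** `generate_study()` draws a full study — landscape,
sites, fields with TFI, covariates, three taxon communities and trait
tables — with configurable true effect vectors, deterministic per seed.

## Worked example

```r
library(patchlink)

study <- generate_study(synthetic_config(seed = 1))
res   <- run_pipeline(study)

# which variables survived the collinearity screen?
res$screen$rhopalocera$selected
#>         herbicide      connectivity             local
#>         "tfi_100" "dpc_insects_300"          "floral"

# focal model: butterfly abundance
subset(res$models, taxon == "rhopalocera" & response == "abundance")
#>          taxon  response  n            term   beta   se      t        p
#> 29 rhopalocera abundance 30     (Intercept) 26.167 3.51  7.447 6.60e-08
#> 30 rhopalocera abundance 30         tfi_100 -1.118 3.66 -0.306 7.62e-01
#> 31 rhopalocera abundance 30 dpc_insects_300  5.089 3.83  1.330 1.95e-01
#> 32 rhopalocera abundance 30          floral  0.441 3.75  0.118 9.07e-01
```

The coefficient table reads like the usual mixed field-study report: at
this seed, butterfly abundance rises by about 5 individuals per standard
deviation of site connectivity (true embedded effect +9.27, well inside
the fitted interval), herbicide pressure pulls it down, and five of 35
sites are dropped because less than half of their 100-m surroundings have
documented herbicide use. The per-patch connectivity report is in
`res$connectivity`, per-site metrics in `res$metrics`, the run log —
screen exclusions, dropped sites, truncation events — in `res$log`.

The numbered scripts under `analysis/` run the same chain stage by stage
(`01_simulate_study.R` → `05_models.R`, each taking an optional seed) and
write their tables under `results/`.

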