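# sealspacing

Fine-scale spatial analysis of pinniped haul-out colonies from
georeferenced polygon annotations: per-animal nearest-neighbour
distances, fixed-radius neighbourhood densities, species comparisons,
and a spatial-perturbation null model that tests whether seals actively
avoid very small separations ("social distancing").

## The problem

Grey seals (*Halichoerus grypus*) and harbour seals (*Phoca vitulina*)
rest ashore in dense aggregations. Aerial imagery lets each animal be
outlined as a polygon in a projected metric CRS, which turns questions
about colony structure into point-pattern statistics:

- **Nearest-neighbour distance (NND).** For animal $i$ in a site,
  $\mathrm{NND}_i = \min_{j \ne i} d(\partial P_i, \partial P_j)$, the
  minimum edge-to-edge distance between polygon boundaries (0 for
  touching animals). Each animal contributes one value.
- **Density.** The number of other animals whose centroids fall within
  $r \in \{1, 3, 5, 10\}$ m of the focal centroid.
- **Species contrasts.** Median and 25%-quantile NND differences via
  quantile regression on a species factor; per-radius count differences
  via a negative-binomial GLM (log link).
- **Social distancing.** Each polygon is displaced by an isotropic
  Gaussian jitter whose SD is a cross-validated kernel bandwidth
  (species-averaged across sites), keeping its orientation; overlapping
  placements are repaired by 1° rotations, then 10 cm translation steps
  in a random direction. The proportion of NNDs below 25 cm is compared
  between observed and shuffled records with a binomial GLM. A deficit
  in the observed data is evidence of avoidance at small distances.

A synthetic-colony generator (clustered body-ellipse patterns with a
controllable hard-core minimum gap) provides ground-truthed input for
every stage, so the whole pipeline is testable without survey data.

## Worked example

```r
library(sealspacing)

sites  <- generate_paired_study(seed = 7)   # 2 grey-like + 5 harbour-like sites
bundle <- run_pipeline(sites,
                       pipeline_config(shuffle = shuffle_config(seed = 11),
                                       quiet = TRUE))
bundle$nnd_summary_species
#>   species   n      mean    median       q25       q75
#> 1    grey 400 0.4290229 0.3504620 0.3016652 0.4771603
#> 2 harbour 600 0.8579781 0.6506352 0.5090366 0.9403371
```

The grey-like colonies are generated denser with a smaller hard-core
gap, so their median NND (0.35 m) sits well below the harbour-like one
(0.65 m); the quantile regression in `bundle$tests` estimates that
difference (~0.30 m) with a large *t* value. The proximity rows of
`bundle$tests` show the planted avoidance signal: the observed
proportion of NNDs under 25 cm is exactly 0 (the generator enforces a
minimum gap above the threshold), while the shuffled configurations put
0.64 (grey-like) and 0.40 (harbour-like) of animals within 25 cm of a
neighbour — an overwhelming deficit on the likelihood-ratio test.
`bundle$shuffles[[1]]$resolution_log` records, per polygon, whether it
initially overlapped and how much rotation/translation freed it, and
`bundle$bandwidths` lists the per-site cross-validated bandwidths along
with the species averages actually used.

With `out_dir` set, the same objects are written as CSV/GeoJSON/JSON
together with a provenance copy of the configuration; re-running from
the same seed reproduces every file byte for byte. A thin command-line
wrapper lives at `inst/cli/sealspacing-pipeline.R`
(`simulate` and `run` subcommands).

Real annotations are read with
`read_annotations("colonies.geojson", species_field = "species",
site_field = "site")`; coordinates must already be in a projected metric
CRS (e.g. EPSG:28992) — geographic coordinates are rejected, and
mixed-species or pupping-season sites are excluded by `filter_sites()`
before comparison.

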