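---
title: "Fine-scale spacing in seal haul-out colonies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale spacing in seal haul-out colonies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sealspacing` analyses the fine-scale spatial arrangement of pinnipeds
resting on land. The raw material is a set of georeferenced polygons, one
per animal, traced on high-resolution aerial imagery and grouped into
haul-out sites, each site labelled grey seal (*Halichoerus grypus*) or
harbour seal (*Phoca vitulina*). Three questions drive the analysis: how
far is each animal from its nearest neighbour, how many conspecifics
surround it at fixed radii, and — the subtle one — do animals actively
avoid very small separations ("social distancing"), or is the observed
scarcity of near-contact simply what their clustering pattern would
produce by chance?

# The observed statistics

**Nearest-neighbour distance (NND).** All distances are edge-to-edge:
the minimum planar Euclidean distance between two polygon boundaries,
zero when animals touch or overlap. For a site with $n \ge 2$ animals
the $n \times n$ distance matrix is computed and each animal's NND is
the minimum of its row, the diagonal excluded. Every animal contributes
one value — a mutual nearest pair is deliberately counted twice, since
each animal's position is treated as an independent placement decision.
Distances are never pooled across sites before the per-animal step;
species summaries pool the per-animal records. Coordinates must be in a
projected metric CRS (the intended source data use Amersfoort / RD New,
EPSG:28992); geographic coordinates are rejected outright rather than
reprojected.

**Neighbourhood density.** For each focal animal, the number of other
animals whose centre point (area centroid) lies within 1, 3, 5 and 10 m
of the focal centre. A centre exactly on the circle counts as inside; no
edge correction is applied, so counts near colony margins are biased
low — a deliberate simplification, flagged here rather than corrected.

**Species comparisons.** Median (and 25%-quantile) NND differences are
estimated by quantile regression of NND on a species factor
(`quantreg::rq`), reporting the asymptotic sparsity ("nid") *t*
statistic. The quantile-regression point estimate, not the *t* value, is
the scientifically meaningful surface; the inference method is recorded
in the result's metadata because quantile-regression standard errors are
method-dependent. Neighbour counts are compared per radius with a
negative-binomial GLM (log link, `MASS::glm.nb`), accommodating the
strong overdispersion that clustered colonies produce.

# The shuffle null model

The social-distancing test compares the observed NND distribution with
that of a *spatial perturbation* of the same colony:

1. **Bandwidth.** A Gaussian kernel bandwidth $\sigma$ is chosen per
   site by cross-validation (below), then averaged across sites of the
   same species; the species average is applied to each site. A
   per-site option and a manual override exist.
2. **Displacement.** Each polygon's centre is jittered by an isotropic
   Gaussian displacement with standard deviation $\sigma$ per axis,
   rejection-resampled until the proposal lies inside the site's
   analysis window. Orientation is preserved. (An alternative mode
   draws new centres from the fitted kernel intensity surface; the
   jitter mode is the default because it follows the reading "a new
   location sampled from the kernel around the centre of each polygon"
   and conserves local density structure most directly.)
3. **Overlap resolution.** Seals do not lie on top of one another, so
   overlapping placements must be repaired. Polygons are finalized one
   at a time in a seeded random order, each tested against all
   already-finalized polygons. An overlapping polygon is rotated about
   its centroid in 1° increments through 359°; if no rotation frees it,
   rotation is reset and the polygon is stepped 10 cm at a time along a
   random direction until free. Overlap means interiors intersecting
   with positive area (
   $> 10^{-9}\,\mathrm{m}^2$, so grazing floating-point contacts do not
   trigger the resolver); boundary contact is allowed.
4. **Comparison.** The proportion of NNDs below 25 cm (a threshold set
   by the annotation imprecision of 7.5–10 cm imagery) is compared
   between observed and shuffled records with a binomial GLM on the
   observed/shuffled factor. A deficit of small NNDs in the observed
   data relative to the shuffle is the social-distancing signal.

**Cross-validated bandwidth.** The default selector minimises the
least-squares (mean-square-error) cross-validation score of the
edge-uncorrected Gaussian intensity estimate
$\hat\lambda_\sigma(u) = \sum_j \phi_\sigma(u - x_j)$:
$$M(\sigma) = \int \hat\lambda_\sigma^2\,du
  - 2\sum_i \hat\lambda_{\sigma,-i}(x_i),$$
with the integral taken over the plane and evaluated in closed form via
the Gaussian convolution identity, minimised by golden-section search
over $[0.1\,\mathrm{m}, \mathrm{diam}(W)/2]$. It is deterministic for
fixed input and errors on degenerate patterns (all centres identical, or
fewer than 10 points — supply `bandwidth_override` instead). The
K-function-based selector of Berman & Diggle is available as
`method = "diggle"` (delegating to `spatstat.explore::bw.diggle`) for
users who want the classical spatstat behaviour; the two agree in order
of magnitude and in the clustered-vs-homogeneous ordering, not to the
digit.

## Design choices in the resolver

The resolution procedure is underdetermined in several places; the
package pins the following, all recorded per polygon in a resolution
log so that any run can be audited:

- *Processing order* is a seeded random permutation; obstacles are
  already-finalized polygons only. This makes termination behaviour
  order-explicit and every run reproducible from `(seed, site_id)` —
  each site draws from its own RNG substream, so adding a site never
  perturbs another site's shuffle.
- *Rotation* is searched in one direction (+1° steps); after a failed
  rotation sweep the orientation is reset before translating, so a
  translated polygon retains its original heading.
- *Translation* steps along one random unit direction. If the path
  would carry the centroid outside the analysis window, that direction
  is abandoned and a fresh one drawn (at most 25). This keeps every
  final placement inside the window — a property the rest of the
  pipeline relies on — at the cost of occasionally consulting more than
  one direction.
- `initial_overlap_fraction` records the fraction of polygons that
  overlapped *any* other at their proposed pose, before resolution —
  the quantity comparable to published overlap rates.

## The analysis window

Nothing in the data defines "the space the seals were distributed in".
The default window is the convex hull of all annotation vertices of the
site, buffered outward by 10 m: it contains all animals, is bounded, and
is reproducible from the data alone. A user-supplied window polygon
overrides it. The window bounds displacement proposals and the
translation paths of the resolver.

# Synthetic colonies

The generator exists so that every pipeline stage can be exercised, with
known ground truth, without survey data. A colony is built by dart
throwing: cluster parents uniform in the window; each animal's centre
Gaussian around a random parent (uniform over the window when
`cluster_sd = Inf`); the body a 24-vertex ellipse with a heading drawn
from the profile's orientation model; and a candidate rejected if its
edge-to-edge distance to any accepted animal falls below the profile's
hard-core gap (overlap and contact are rejected even at gap 0). The
hard-core gap plants an *exact* avoidance signal: a gap of 0.5 m makes
the observed proportion of NNDs below 0.25 m identically zero, which the
shuffle must then detectably exceed.

The default profiles are honest placeholders, not measurements: a
grey-like profile (2.0 m × 0.6 m body, 0.25 m gap, four clusters of
spread 2.5 m, 200 animals per site) and a harbour-like profile
(1.5 m × 0.5 m, 0.40 m gap, three clusters of spread 3.5 m, 120 animals
per site), both with near-common headings (SD 15°) as real haul-outs
show. They were chosen once so that the generated spacing magnitudes are
plausible for dense moulting aggregations versus looser feeding-season
groups — pooled median edge-to-edge NNDs of roughly 0.4 m versus
0.7 m — and so that every species contrast the pipeline estimates has a
known sign (grey-like denser, smaller gap, smaller median NND). Any
numeric claim in the test suite derives from this configured truth,
never from assumed seal biology.

What the generator does *not* emulate: tides and topography,
mother–pup pairing, body-size mixtures, soft (probabilistic) avoidance,
and the lateral side-by-side packing of real herds. The last point
matters when interpreting small radii: with uniform-ish placement and a
hard minimum gap, centre pairs closer than 1 m are geometrically rare,
so synthetic radius-1 counts are much lower than in real colonies.
Passing tests therefore certify the pipeline's mechanics and its
statistical recovery of planted signals, not biological realism of any
particular parameter value.

# Numerical choices

- Quantile interpolation is pinned to linear interpolation between
  order statistics (type 7) for all summary quantiles, so summaries are
  bit-for-bit reproducible across runs.
- A distance exactly equal to a density radius counts as inside; an NND
  exactly equal to the proximity threshold counts as a failure
  (≥ 0.25 m). Both ties are measure-zero on real data and pinned for
  determinism.
- The binomial comparison reports the Wald *z* as its statistic but
  takes its p-value from the likelihood-ratio test: when one condition
  has zero successes (exactly what a planted hard core produces) the
  Wald statistic degenerates while the deviance difference remains
  finite and well behaved.
- The confidence interval in the density summary is the normal
  approximation on the mean (±1.96 SE), with a percentile bootstrap as
  an alternative; both are provided because the appropriate interval
  for published tables of this kind is ambiguous.
- Degenerate inputs fail loudly: single-animal sites are excluded from
  NND analysis (with a logged reason), all-zero count groups refuse a
  log-link rate model, and unresolvable overlaps name the polygon and
  seed.

# Problem sizes

The test suite and the acceptance script are sized to run comfortably
on one CPU: geometry oracles on ~1000 random fixtures; shuffle
invariants on twenty 200-animal shuffles; hard-core recovery on twenty
150-animal colonies; null calibration on 1000 simulations of 40-animal
colonies; statistical recovery at 5000 records per group; and the
acceptance script's study at the default 2 × 200 + 5 × 120 design.
These sizes are the package's reference conditions; all of them scale
linearly or quadratically in ways the functions document.

# Known limitations

- **The proximity test is anticonservative under the null.** The
  binomial GLM treats per-animal NND indicators as independent
  Bernoullis, but roughly 60% of animals in a Poisson-like pattern
  belong to mutual nearest-neighbour pairs whose two indicators share
  one distance. The effective sample is therefore ~30% smaller than the
  nominal one and the binomial variance understates the truth by a
  factor around 1.5, so a nominal 5% test rejects more often than 5%
  under a true null. The acceptance suite measures this directly by
  shuffling patterns generated with no inhibition. Interpreting
  *marginal* p-values from this test on real data is correspondingly
  risky; the very small p-values produced by a genuine hard-core
  deficit are not.
- Sites are pooled in all species comparisons; no site-level random
  effects are fitted.
- No edge correction in the density counts; margins bias counts low.
- The shuffle is a one-pass perturbation, not an equilibrium sampler of
  a point-process model: it answers "what if the same animals were
  placed slightly differently", not "what does a fitted process
  predict".
- Only GeoJSON is read and written. Shapefile inputs should be
  converted (e.g. `ogr2ogr -f GeoJSON`) before use; reprojection is
  likewise the user's job — the package validates, but never
  transforms, coordinates.

# A worked example

```{r, eval = FALSE}
library(sealspacing)

sites <- generate_paired_study(seed = 7)
bundle <- run_pipeline(
  sites,
  pipeline_config(shuffle = shuffle_config(seed = 11), quiet = TRUE))

bundle$nnd_summary_species
bundle$tests
plot_nnd_histogram(bundle$histograms, "grey")
```

The bundle contains per-animal records, per-species and per-site
summaries, the per-site bandwidths (and the species averages actually
used), the shuffled configurations with their resolution logs, the test
table and the binned observed-vs-shuffled histograms; with an `out_dir`
the same objects are written as CSV/GeoJSON/JSON, together with a
verbatim provenance copy of the configuration, so a run can be
reproduced byte for byte from its own output directory.
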