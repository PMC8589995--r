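---
title: "Flow generation with gravity and deep models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow generation with gravity and deep models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
flow-generation problem, the model family, the training and evaluation
procedure, the synthetic data the tests run on, and the design decisions
taken where the design was genuinely open. Code chunks are illustrative and
not evaluated at build time; every empirical statement below is one the test
suite or `scripts/acceptance.R` computes.

## The flow-generation problem

A study region is tessellated into *locations* — census-unit-like polygons
with a centroid, an area (km²) and a resident population — grouped into
square *regions of interest* (ROIs) of a configurable side (25 km by
default). `build_square_grid()` constructs the ROI grid in a local
equirectangular projection of the boundary's bounding box, so cells measure
the requested number of kilometres on a side; only cells overlapping the
boundary with positive area are retained. `assign_locations()` attaches
each location to the unique cell containing its centroid, using half-open
`[min, max)` intervals on both axes (the global maximum edge is closed) so
a centroid on a shared edge belongs to exactly one cell deterministically.
Locations whose centroid falls in no retained cell — coastline slivers in
real data — are excluded and reported, since there is no principled cell to
receive them.

Flows `y(l_i, l_j)` count people moving between locations per unit time;
the *total outflow* `O_i = Σ_j y(l_i, l_j)` is input data, not a model
output. All models here are *singly constrained*: they distribute a known
`O_i` over candidate destinations, so generated per-origin totals equal
`O_i` by construction. Following the within-ROI modelling convention, flows
whose endpoints lie in different ROIs are dropped by
`restrict_flows_within_rois()`, and a model's candidate set for an origin is
its ROI's location set. Self-flows (`i = j`) are valid candidates by default
(`include_self = FALSE` disables them): within-location commuting exists in
census data.

Distances are haversine great-circle distances between centroids with the
IUGG mean Earth radius 6371.0088 km. For self-pairs the distance is floored
at a within-location characteristic length, `0.5 · sqrt(area/π)` (half the
radius of the circle with the location's area): a power-law deterrence is
undefined at `r = 0`, and a person moving within a location still travels a
distance of about that scale. The same floor is applied to the distance
input of the network models, so the deep models and the gravity model see
the same geometry — an inconsistency here (raw zeros for the networks,
floored distances in the generative truth) measurably degrades
transferability across ROIs.

## Model family

All four models score each candidate destination `l_j` of an origin `l_i`
and convert scores to probabilities with a softmax; they differ only in the
score function:

* **G** — `s_ij = β1 ln m_j + β2 g(r_ij)` with `g = ln` (power-law
  deterrence `r^{β2}`) or identity (exponential `e^{β2 r}`). This is the
  singly constrained gravity model written as a multinomial logit, and the
  parameters are fitted by exact maximum likelihood: BFGS with analytic
  gradient on the per-trip-normalized negative loglikelihood, followed by
  Newton polishing to a gradient max-norm below 1e-8 (the 2×2 Hessian is
  closed-form). The fit errors out rather than returning an unconverged
  estimate.
* **NG** — the same deep network as DG but on population and distance only.
  Its input is 3-dimensional by default (origin population, destination
  population, distance); a 2-input form (destination population, distance)
  is available, matching the gravity model's informational content exactly.
* **MFG** — a single linear layer (no hidden layers) on the full
  39-dimensional input.
* **DG** — a feed-forward network with 15 hidden layers (six of width 256,
  nine of width 128 in the reference architecture), leaky-rectifier
  activations with negative slope 0.01, and a scalar linear output, applied
  to `x(l_i, l_j) = [x_i, x_j, r_ij]` where `x_i` is the 19-value location
  feature vector (population + 18 geographic features). A *light* variant
  uses 5 inputs: the two populations, the distance, and each side's total
  POI/building count.

The 18 geographic features come in 7 categories: land-use areas in km² for
the residential, commercial, industrial, retail and natural classes; road
lengths in km for the residential, main (motorway/trunk/primary/secondary)
and other classes; and POI and building counts for transport, food, health,
education and retail facilities. `aggregate_osm_features()` builds them
from tagged points, lines and polygons, resolving tags through an editable
CSV mapping shipped as data (`default_tag_mapping()`), clipping lines and
polygons exactly at location boundaries so that pieces sum to wholes.
Clipping supports convex location polygons (half-plane clipping for
segments, Sutherland–Hodgman for polygons, in the metric projection); a POI
that appears both as a node and as a building footprint is counted once in
each of the separate "POIs" and "buildings" features. All feature values
except distance are divided by the location's area
(`normalize_by_area()`); the population can be exempted, which the bundled
experiments use (see below).

## Training

The network models minimize the cross-entropy
`H = −Σ_i Σ_j (y_ij / O_i) ln p_ij` — equivalently, the multinomial
negative loglikelihood per trip — with RMSprop (squared-gradient smoothing
0.99, momentum 0.9) over mini-batches of 64 origins. When an origin's ROI
has more candidates than `max_sampled_destinations` (512 by default),
negative sampling keeps every observed (positive-flow) destination and pads
with uniformly drawn zero-flow candidates; the softmax is renormalized over
the sampled set during training and runs over the full ROI at evaluation.
Dropping an observed destination would make its loss term undefined, which
is why sampling always retains them. All randomness — initialization
(fan-in-scaled uniform), epoch shuffling, candidate sampling — derives from
one seeded generator, making training bit-reproducible.

`training_config()` defaults mirror the reference recipe (20 epochs,
learning rate 5e-6, momentum 0.9, batch 64, 512 sampled destinations),
which is tuned for country-scale data with thousands of optimizer steps per
epoch. The bundled synthetic studies are three orders of magnitude smaller
(~200 training origins), so `study_training_config()` adapts the recipe —
600 epochs at learning rate 5e-4 — and adds two small-data safeguards,
exposed as ordinary configuration:

* **Input conditioning** (`standardize = "log1p_zscore"`): features are
  nonnegative and heavy-tailed (populations and counts span orders of
  magnitude), so inputs are log1p-compressed and z-scored with training-set
  statistics; the distance column uses a floored plain `log`, because
  spatial interaction is log-linear in distance. The conditioning is stored
  in the model and applied identically at evaluation.
* **Decoupled weight decay** (`weight_decay = 15`): an L2 pull applied
  directly to the weights (`W ← (1 − lr·λ)W`), not added to the gradient
  before RMSprop's normalization. The coupled form divides the decay
  gradient by the running RMS, which for weights with small data gradients
  turns the decay into a constant-rate march to zero and can collapse the
  whole network onto the dead all-zero point — a failure mode we reproduce
  rather than speculate about. With ~200 origins the networks otherwise
  interpolate multinomial noise (training CPC above the generative
  process's own CPC) at the expense of held-out ROIs.

An optional Polyak tail-averaging of the weights exists
(`average_tail`) but defaults to off: averaged iterates from distant,
permutation-equivalent basins score worse than the final iterate in our
experiments.

`study_mlp_spec()` keeps the 15-hidden-layer shape but narrows it to six
layers of 32 and nine of 16 — at synthetic problem sizes the narrow network
reaches the generative process's cross-entropy floor, and training stays
inside a desktop-CPU minute budget.

The bundled experiments keep the population feature raw
(`normalize_population = FALSE`) while area-normalizing everything else.
The reason is identifiability, not convenience: the gravity mass `m_j` is
the raw resident count, and location area is not itself an input feature,
so a model seeing only the density `m_j / A_j` cannot reconstruct
`ln m_j` — with a fully normalized population the deep model is
structurally unable to express the gravity score, and the
gravity-recoverability check would compare function classes that do not
nest. The package supports either convention.

## Evaluation

`cpc()` is the Common Part of Commuters (Sørensen–Dice index on flows),
`2 Σ min(ŷ, y) / (Σ ŷ + Σ y)`: 1 for identical tables, 0 for disjoint
supports, invariant to a common rescaling. When generated and real
per-origin totals agree — true for every singly constrained model — CPC
equals the fraction of trips assigned to the correct destination, and
`cpc_accuracy_equivalence_check()` verifies that identity against an
explicit trip-level assignment count. `nrmse()` (RMSE over the pair
universe divided by the real flows' range; mean- and sd-normalizers are
options), `pearson()` (zeros included over a fixed within-ROI pair
universe, so the metric is well defined) and `jsd()` (natural-log
Jensen–Shannon divergence, bounded by ln 2) complete the suite. JSD
defaults to comparing the two pair-level flow distributions; a
flow-magnitude histogram mode exists because both conventions appear in the
literature. `decile_report()` ranks ROIs by population (ties broken by ROI
id, remainders spread from the lowest decile up), cuts them into ten
equal-sized groups and reports per-decile mean/std CPC across runs with the
relative improvement `100 (CPC_model − CPC_base) / CPC_base` against a
baseline.

The experiment protocol (`run_experiment()`) repeats, for each of `n_runs`
runs: a population-stratified 50/50 ROI split (each decile contributes
equally many ROIs to each side, deterministic given `seed + run`), training
of each requested model strictly on train-ROI data, flow generation on test
ROIs from real outflows, and metric computation both pooled over all test
pairs and per ROI. `run_leave_one_city_out()` implements the
transferability protocol: each labelled city's ROIs are held out in turn,
the model trains on all other cities, and the held-out city's CPC is
compared with the stratified-protocol CPC on the same ROIs.

## Shapley explanations

`exact_shapley()` enumerates all `2^k` coalitions of up to 12 feature
groups; a coalition's value is the mean model score over hybrid inputs
taking coalition features from the explained instance and the rest from
each row of a background set (interventional substitution). Local accuracy
— baseline plus the sum of attributions equals the prediction — then holds
to numerical precision, and a feature the score ignores receives exactly
zero. `sampled_shapley()` is the permutation-sampling estimator for larger
inputs (one background row and one feature permutation per sample),
deterministic given its seed, with per-feature Monte-Carlo standard errors;
its baseline is the mean score of the sampled background rows, so local
accuracy is exact by construction there too. Attributions target the
pre-softmax score by default: the score is well defined for a single
origin–destination pair, whereas a probability depends on the whole
candidate set. Attributing the probability for a fixed candidate set is a
documented alternative (wrap `predict_probabilities()` as the score
function).

## Synthetic data: what it emulates and what it does not

`gen_geography()` draws, per ROI, a uniform number of locations (8–15 by
default) with uniformly scattered centroids, gamma-distributed areas
rescaled to cover 60% of the cell, log-normal populations (median 300,
σ_log 0.8 — the scale of small census output areas; minimum one resident),
land-use areas as random fractions of the location area, gamma road
lengths, and negative-binomial POI/building counts whose means scale with
population^0.7 — denser places have more facilities, with over-dispersion.
`gen_flows()` draws per-origin outflows Poisson with mean
`trips_rate · population` (`trips_rate = 0.4` by default, a commuting-scale
budget) and assigns each origin's trips multinomially to within-ROI
destinations from a known process:

* the **gravity process** — the closed-form model with `β1 = 1`,
  `β2 = −2`, power-law deterrence; or
* the **nonlinear process** — a ground-truth score combining a
  distance-damped POI attraction
  (`3 · ln(1 + POIs_j) / (1 + r/5 km)`), a non-monotone population term
  (`22.8 z − 2 z²` with `z = ln(1 + m_j)`, peaking at the median
  log-population, so destination attractiveness *falls* for the largest
  populations), and a mild linear distance decay. By construction a logit
  linear in `[ln m, ln r]` is misspecified for this process while a
  flexible function of the full feature vector is not, which is what makes
  the gravity-vs-deep ordering a meaningful check.

Location "polygons" are not generated — models consume centroids and areas
only, and the geometry-clipping code paths are exercised by their own
convex-rectangle fixtures. The generator emulates heterogeneity and
over-dispersion but not spatial autocorrelation between neighbouring
locations, street-network structure, or reporting artefacts of real
censuses; a model ranking observed on this synthetic data therefore shows
that the pipeline can recover and distinguish the generative mechanisms it
defines, not that the same margins will appear on any real census.

## Study conditions and problem sizes

The bundled studies, used by the test suite and the acceptance script, run
at sizes a desktop CPU handles in minutes: 40 ROIs, five repeated runs,
the narrow 15-layer network. Two generative settings are used: the
nonlinear process at the default commuting-scale trip budget (the
model-ordering and transferability studies, with four synthetic city
labels), and the gravity process at a larger trip budget
(`trips_rate = 15`, so outflows of a few thousand trips, the same scale as
the gravity-recovery simulation's 5000 trips per origin) for the
recoverability study — at the commuting-scale budget the CPC ceiling is set
by multinomial sampling noise, and the comparison would measure smoothing
rather than whether the deep model's function class recovers gravity.

## Numerical choices and degenerate inputs

Softmaxes and log-likelihoods are computed with max-shift stabilization;
probabilities at evaluation are exact to normalization within 1e-9. An
all-zero pair of flow tables makes CPC undefined and raises an error, as do
a constant real table for NRMSE/Pearson and an all-zero table for JSD. A
zero model probability on an observed destination yields an infinite
cross-entropy, reported as `Inf` rather than clipped. Gravity fitting
requires positive masses and at least two candidates per origin; ROIs with
fewer than ten members degrade the stratified split to a plain random split
with a warning. Ties in population ranking are broken by id so decile cuts
are deterministic. Model archives serialize weights as JSON at 17
significant digits, which restores doubles exactly.

## Known limitations

* Geometry clipping requires convex location polygons; non-convex census
  polygons would need a decomposition step that is out of scope.
* The equirectangular projection is adequate for study regions up to a few
  hundred km; continental-scale boundaries would distort cell sizes at the
  latitude extremes.
* Training is single-threaded plain R; it is sized for the synthetic
  studies, not for country-scale censuses.
* The leave-one-city-out comparison is as noisy as its per-city CPC
  estimates; with few ROIs per city the ±2-std band is wide.
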