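---
title: "Ensemble species distribution modelling from line-transect surveys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble species distribution modelling from line-transect surveys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the models it
fits, the assumptions behind them, the parameters that matter, what the
synthetic study system does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The problem

Coastal dolphins and other inshore megafauna are surveyed by driving
systematic transects and recording schools. The analytical question is
two-fold: *where* does the species concentrate (as a probability-of-
occurrence surface over a management grid), and *is that concentration
covered by no-take sanctuary zones*? Presence data from transects carry a
strong observation filter — a cell without sightings may simply be a cell
without search effort — so the response must be built jointly from
sightings and effort.

## From surveys to a response grid

All analysis lives on a square lattice (default 500 m; the scale at which
the locational error of boat-based sightings, the ~100 m spatial spread of
a school, and the 250 m observation half-width all blur into one cell).
Cells are half-open intervals, so a sighting on a shared edge belongs to
exactly one cell — an arbitrary but deterministic convention.

*Effort* is the exact clipped track length per cell (metres). Length is
conserved: the per-cell efforts of a clipped track sum to its in-grid
length to within 1e-6 relative, and this is asserted in the tests.

*Presences* are cells with at least one on-effort sighting. *Absences* are
chosen by effort ranking: among surveyed cells with no sightings, take the
most-searched cells, exactly as many as there are presences. The rationale
is that a heavily searched cell with no encounters is the closest thing a
visual survey has to a true absence. Ties at the selection threshold are
broken by cell index — deterministic and logged. The effort value of the
weakest selected cell is reported as the absence threshold, which makes the
selection auditable.

The survey corridor uses flat (butt) end caps on each buffered segment.
Caps are not specified by common GIS practice in any single way; flat caps
make the area of a single buffered segment exactly `length x 2 x buffer`,
which in turn makes the corridor-area contract exactly testable. Corridor
area is computed by deterministic fine-grid integration (10 m cells aligned
to absolute multiples of the resolution) because the package represents the
corridor analytically (segments + buffer) rather than as an explicit
polygon; membership tests are exact, and the union of overlapping buffers
is counted once by construction.

## Predictor layers

* **Euclidean distance to coast** is a point-to-segment minimum over the
  coastline polyline, zero for cells the coastline crosses.
* **Cost distances** (reef crest, passages, boat ramps, sanctuary zones)
  are shortest paths over marine cells only, on the 8-connected lattice
  with orthogonal steps of one cell and diagonal steps of `sqrt(2)` cells.
  This is the standard raster cost-distance model; it never crosses land,
  and in open water it can overestimate the straight-line distance by at
  most `1/cos(22.5 degrees) - 1`, about 8.25% (the octile-metric bound),
  plus up to one cell of discretization. Cells with no marine path to the
  target are flagged unreachable and excluded from the model table with a
  warning rather than silently imputed.
* **Slope** is the maximum gradient magnitude to any marine 3x3 neighbour,
  in degrees; **seabed complexity** is the standard deviation of depth over
  the cell and its marine neighbours, in metres. The field uses several
  variants of these terrain derivatives; these definitions are the simplest
  neighbourhood statistics that are exactly recomputable per cell, and the
  tests recompute them cell by cell.
* **Ordinary kriging** (for station measurements such as SST) uses a
  spherical semivariogram and the nearest 12 samples per cell — the
  "12-point variable search radius" convention read as nearest-12. Weights
  solve the ordinary-kriging system with the unbiasedness constraint, so
  they sum to one for every predicted cell (asserted in the tests); with
  zero nugget the predictor interpolates the samples exactly. Duplicate
  sample locations are averaged first, which removes the only source of
  exact singularity; any residual ill-conditioning falls back to a tiny
  ridge jitter.
* **Benthic habitat** is the majority class over a 10x10 sub-lattice of
  each cell (50 m sampling for 500 m cells). Polygons are tested in list
  order, so a mosaic needs no between-polygon tie rule; class ties within a
  cell break lexicographically. Cells covered by no polygon are labelled
  `unclassified` and excluded from the model table with a warning.

The kriged SST layer is computed on demand but not part of the default
candidate set: the default eight-variable design (habitat, depth, slope,
complexity, and the four distances) mirrors the standard overall-model
design for this kind of study.

## Collinearity screening

Screening runs `vifcor` then `vifstep` on the continuous predictors:
`vifcor` repeatedly finds the pair with the largest absolute Pearson
correlation and, while it exceeds 0.7, removes the member with the larger
VIF (computed on the current set); `vifstep` then removes the largest VIF
while it exceeds 3. `VIF_j = 1/(1 - R^2_j)` from the least-squares
regression of predictor `j` on the others; exact dependence is reported as
an infinite VIF and handled by the loop, not by an exception. VIF ties drop
the variable later in input order (logged). The categorical habitat layer
is excluded from screening — Pearson correlation is undefined for unordered
categories — and passed through to the model. A single surviving variable
has VIF 1 by definition, so the procedures cannot empty the table; the
"all removed" error is defensive.

The two procedures are applied sequentially (vifcor, then vifstep on the
survivors), and both reports are kept. Applying them in parallel and
intersecting would be an equally defensible reading; the sequential order
was chosen because it reproduces the common usage of the corresponding
R procedures, and both reports are logged so the choice is transparent.

## The ensemble model

`esdm()` is the package's central fitting function. For each of `n_runs`
(default 10) stratified 75/25 calibration/test splits and each of six
algorithms, it fits a probability-emitting classifier:

* **GAM** — binomial/logit with thin-plate smooths (basis dimension 4 per
  term; linear terms for near-discrete variables),
* **GBM** — gradient-boosted trees (100 rounds, depth 3, learning rate 0.1,
  logistic objective, single-threaded for determinism),
* **CTA** — a classification tree (cp 0.01, minimum bucket 5),
* **FDA** — linear discriminant analysis over a natural-spline basis
  expansion (3 df per continuous variable), the classic realization of a
  flexible discriminant,
* **RF** — a 500-tree probability forest,
* **MAXENT** — an L1-regularized logistic regression over a
  linear + quadratic + forward-hinge feature expansion (hinge knots at the
  calibration quartiles), with the penalty chosen by seeded 5-fold
  cross-validation. Under a presence/absence design, maximum entropy
  estimation reduces to exactly this regularized logistic form, which is
  why the package implements it this way rather than shipping a
  presence-background engine.

Hyperparameters are fixed, documented defaults appropriate to a few hundred
response cells; none of the package's contracts depend on their exact
values. A non-converging fit falls back to a plain binomial GLM and the
fallback is recorded on the fitted object. Factor levels are frozen at
training time; a level seen only at prediction time (possible when
predicting over the whole grid) is collapsed to the modal training level —
a documented fallback that keeps grid-wide prediction total.

Each run records its held-out **AUC**, computed as the rank-sum
(concordance) statistic with ties counted one half — the probability that a
random presence cell outranks a random absence cell. The test suite checks
this implementation against exhaustive pair enumeration on all small
tables.

**Variable importance** is the permutation statistic: for each predictor,
`1 - mean Pearson r` between the model's predictions and its predictions
after permuting that predictor, over 10 seeded permutations, clipped to
[0, 1]. Clipping at zero follows the convention that the statistic ranks
variables from zero to one; negative raw values (anticorrelation after
permutation) carry no extra information about importance. A variable the
model ignores scores exactly 0. If the standard predictions are constant
the correlation is undefined and every importance is 0 (logged). The
alternative reading — rescaling mean correlations across variables instead
of `1 - r` per variable — is noted; `1 - mean(r)` is used because it keeps
each variable's score interpretable in isolation. Permuted predictions are
batched (all permutations of one variable stacked into a single predict
call), which is statistically identical to looping and considerably
faster. Importance is evaluated on the calibration rows, whose predictions
are the model's fitted values.

The per-algorithm mean importances over runs, plus the unweighted mean of
means across algorithms, form the importance table — the headline ranking
of predictors.

**Ensemble prediction** includes every run with test AUC strictly above
0.5 and weights it by `w_i = AUC_i / sum AUC_j`. The per-cell ensemble
probability is the weighted mean — a convex combination, so it is bounded
by the included models' per-cell minimum and maximum (asserted in the
tests). Raw-AUC-proportional weights are the simplest faithful reading of
"weighted by predictive accuracy"; decay-transformed weights would sharpen
the ensemble but add a tuning constant with no basis in the design.

**Ensemble evaluation** is out-of-fold: each response row is scored by the
AUC-weighted mean of the included models in whose *test* split it fell, and
the ensemble AUC is computed over the rows that were held out at least
once. This never lets a model score rows it was calibrated on. With few
runs a minority of rows may never be held out; they are simply dropped from
the evaluation (with 3 runs about 42% of rows, with 10 runs under 6%).

## Zone assessment

The surface is banded Low = [0, 0.3], Medium = (0.3, 0.6],
High = (0.6, 1]. Printed band definitions of the form "< 0.3 / 0.31–0.6 /
> 0.6" leave the hundredths gap and the endpoints ambiguous; half-open
intervals close the gap, keep "High" strictly above 0.6, and make the
partition total — every probability gets exactly one band (asserted).

The randomization test counts High cells inside sanctuary zones, then
relocates the same number of High cells uniformly at random (without
replacement) over all marine cells 5,000 times. The one-sided p is the
proportion of permuted counts greater than or equal to the observed one.
This null is exactly a hypergeometric draw, and the tests verify the
Monte-Carlo p against the exact hypergeometric tail. Keeping the number of
High cells fixed per permutation is the only reading consistent with
relocating the cells themselves; resampling band labels cell-wise would
change the High-cell count and test a different hypothesis. The null
ignores spatial autocorrelation of the surface — a contiguity-preserving
null would be stricter and is left as an extension.

Because the overlap index is a discrete count, the upper-tail p is
*super-uniform* under the null (conservative, never anti-conservative):
its null mean exceeds 0.5 by half the probability mass of the atom at the
observed value. The calibration test therefore asserts two things — that
empirical rejection rates never exceed their nominal levels, and that the
*mid-p* (which splits the atom) is uniform. A raw uniformity test on the
discrete p would reject for any correctly implemented test of this kind.

## The synthetic study system

The generator builds a ~150 km² coastal strip (50 km alongshore, up to
5 km offshore) against a sinusoidal coastline, with:

* **Fringing-reef bathymetry.** A shallow lagoon (1 m at the shore) runs
  out to a reef crest whose offshore distance `L(x)` varies alongshore
  (two superimposed sine components, mean 1.2 km); the crest shoulder sits
  near 6 m, then the bottom drops along a smoothstep of ~1.8 km width
  (itself modulated alongshore) to a deep plain whose depth varies
  alongshore between ~29 and 45 m. Lagoon cells carry patchy "bommie"
  roughness and parts of the plain carry rubble-field roughness (noise
  standard deviation inflated up to 3.5x the 1.2 m base). Morphology phases
  are drawn per seed, so every seed is a distinct landscape. This structure
  is not decorative: it is what keeps water depth from being linearly
  reconstructible from the distance layers, so that the predictor
  correlation matrix looks like real fringing-reef data (all pairwise
  |r| at or below ~0.7 except between the two terrain derivatives) and the
  two true drivers survive screening. The mapped reef-crest line is
  deliberately jittered (500 m alongshore wiggle) relative to the
  bathymetric crest, emulating a habitat map digitized from decades-old
  imagery.
* **Zones.** Six sanctuary blocks interleaved with recreation and
  general-use blocks along shore, sized greedily to 26/60/14% of marine
  area (realized fractions within a column's width of the targets).
* **Transects.** Two opposing, evenly spaced zig-zag sets (2.5 km vertex
  spacing, about 70 km each) plus a 13 km single line mid-lagoon; at a
  250 m buffer the corridor touches ~82% of marine cells.
* **Sightings.** School count is Poisson with mean 169; locations are drawn
  by rejection from the corridor with intensity proportional to the true
  occurrence model `logit p = 1 - ((depth - 10)/4.5)^2 - d_coast_km/0.5`,
  evaluated on the realized (noisy) cell bathymetry — the habitat the
  animals actually occupy — not on the smooth deterministic profile. The
  depth preference (10 +- 4.5 m) and the 0.5 km coast e-folding reproduce a
  species concentrated at 5-15 m within 2 km of shore; under the defaults,
  roughly two-thirds of presence cells fall in the 5-15 m band.

What the generator does **not** emulate: detection probability varying with
sea state, school size or distance from the trackline (every school in the
corridor is equally detectable — there is no distance-sampling detection
function); availability or perception bias; repeated passes over the same
transect (effort variation comes from the survey geometry, not revisits);
temporal structure of any kind (no seasons, no residency); and spatial
autocorrelation of sightings beyond what the smooth intensity induces
(schools are conditionally independent points). Consequently, green tests
show that the *pipeline* recovers a known generating process through the
full response-construction -> screening -> ensemble chain; they do not show
that any particular field dataset satisfies these assumptions.

## Reproducibility machinery

A pipeline run is a pure function of its configuration. The master seed
derives one sub-seed per stochastic stage (`seed + 1000 x stage counter`:
study area, sightings, model fitting, randomization test), so stages can be
re-run in isolation; every generator, split, permutation and stochastic
learner is seeded from this chain (boosting is run single-threaded to keep
it bit-reproducible). Two runs with one configuration produce byte-identical
CSV/JSON outputs, which the test suite checks file by file. The manifest
records the configuration fingerprint (a rolling hash of its canonical JSON
form), the stage seeds, package and R versions, accumulated warnings, and
the output file list.

## Problem sizes used by the test suite

The packaged experiments run at the study's native scale — the ~614-cell
default grid with ~170 schools per seed — with 3 calibration/test splits
per algorithm for the 50-seed recovery and null-calibration experiments,
and 10 splits (60 model runs) for single-run demonstrations and the
acceptance script. Oracle-equivalence checks run on deliberately tiny
inputs (tables of up to 12 rows for exhaustive AUC enumeration, 20 x 20
lattices for the Dijkstra comparison, 100 random tables for the screening
loops) where brute force is exact.

## Known limitations

* No distance-sampling correction: occurrence probabilities are relative to
  surveyed, equally-detectable conditions.
* Cost distances inherit octile-metric discretization error (bounded ~8.25%
  in open water).
* The slope/complexity operators are stand-ins for whichever derivatives a
  given GIS toolchain defines; on the synthetic bathymetry the two are
  nearly collinear, so screening typically removes one.
* The sanctuary-overlap null ignores spatial autocorrelation; p-values test
  random relocation, not relocation of spatially coherent patches.
* Ensemble out-of-fold evaluation drops never-held-out rows at small
  `n_runs`.
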