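---
title: "Ontogenetic allometry and convergence of salamander foot morphology: methods"
author: "footmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontogenetic allometry and convergence of salamander foot morphology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footmorph)
```

## The biological problem

European cave salamanders (*Hydromantes*, often placed in *Speleomantes*)
climb cave walls and rock faces, and adults of all eight European species
carry extensive interdigital foot webbing — long interpreted as a climbing
adaptation. Whether that adult morphology is *built* during growth
(allometry: webbing increases with size) or simply *retained* from the
juvenile state (isometry) is a developmental question that changes the
evolutionary interpretation entirely. footmorph implements the full
analysis chain needed to ask it from museum-style ontogenetic series:
landmark-based shape analysis, webbing sinuosity, species-specific
allometry models, a permutation test of whether species converge on a
common adult morphology, ancestral-state reconstruction of growth regime
on a phylogeny, and a biomechanical power-law model of foot growth.

Because the original museum measurements are not deposited anywhere
machine-readable, the package ships a calibrated synthetic-data generator
that reproduces the statistical structure of such ontogenetic series; all
tests and the acceptance run operate on it end to end.

## Measurements and shape variables

**Sinuosity** is the distal foot-outline perimeter divided by foot width,
`p/d`. A perfectly webbed foot whose outline runs straight across the digit
tips has sinuosity 1 (the geometric floor); deep interdigital notches raise
it. It is dimensionless and falls as webbing increases.

**Foot shape** is captured by nine fixed anatomical landmarks (five digit
tips and four interdigital notch points) in two dimensions. `gpa()`
performs generalized Procrustes superimposition:

1. centre each configuration and scale it to unit centroid size;
2. rotate each onto the running consensus — rotations only, never
   reflections, since feet are handed anatomical objects;
3. update the consensus (centred, unit size) and repeat until its
   root-mean-square change falls below `tol` (default `1e-8`, with
   `max_iter = 100`; exhaustion is flagged, not thrown).

The consensus is initialised from the first configuration; for landmark
data of this kind the fixed point does not depend on the initialisation,
and the final solution is rotated into a canonical frame (consensus
principal axes with a deterministic sign rule), which makes the output
invariant — to numerical precision — under arbitrary rotation, translation
and rescaling of the inputs. Shape variables are Kendall tangent-space
coordinates: each aligned configuration is orthogonally projected onto the
tangent space at the consensus pole. Within the shape ranges seen here
(Procrustes distances well below 0.1) tangent distances track Procrustes
distances to better than 1%. Centroid size — the square root of summed
squared landmark distances from the centroid — is retained as the size
variable for the shape analyses.

Thin-plate spline deformation grids (`tps_grid()`, kernel
`U(r) = r^2 log r^2`, affine plus bending decomposition) visualise shape
change; the warp interpolates the landmarks exactly, bending energy is
non-negative and vanishes exactly for affine deformations, and target
displacements can be exaggerated (conventionally doubled) for legibility.
Collinear reference landmarks make the spline system singular and are
rejected with an informative error.

## Allometry models

* `fit_species_regressions()` — per-species OLS of sinuosity on size, with
  the two-sided t test on the slope. `code_trajectories()` codes a species
  **allometric** when `p < alpha` (default 0.05, strict inequality: a p
  value exactly at the threshold, or undefined under zero residual
  variance, codes isometric).
* `ancova_webbing()` — `sinuosity ~ species + size + species:size` with
  sequential (Type I) sums of squares in entry order, F against the
  residual mean square. The interaction term is the formal test of
  species-specific trajectories.
* `mancova_shape()` — the same model for the multivariate tangent
  coordinates, using Pillai's trace with the standard approximate-F
  transform. Superimposition leaves four tangent dimensions without
  variance, so the response is first projected onto its non-degenerate
  principal subspace (Pillai's trace is invariant under this full-rank
  reduction); if the response dimension ever reaches the residual degrees
  of freedom it is truncated further with a warning. A one-column response
  reduces exactly to the univariate ANCOVA. Raw centroid size is the
  default covariate; log size is a switch.
* `regression_scores()` — projection of each specimen's tangent
  coordinates onto the normalised pooled regression vector of shape on log
  centroid size: a one-dimensional allometry axis for ontogenetic
  scatterplots. Fully isometric data have no such axis and raise an error.
* `fit_power_law()` — the biomechanical foot-growth model `A = b W^alpha`
  fitted by OLS on the log-log scale; `compare_growth_parameters()` ranks
  reference species by Euclidean distance in `(alpha, log b)` space. The
  shipped `growth_reference_table()` contains *illustrative synthetic*
  reference entries (a climbing-adapted cave-dweller-like pair at
  `alpha = 0.75, b = 0.14` and two tropical-arboreal-like pairs), not
  published measurements.

The size covariate for the webbing analyses is selectable
(`foot_length`, the default, or `foot_width`): ontogenetic series of this
kind have been analysed under both conventions and the two are nearly
collinear; the default follows the way such regressions are usually
tabulated.

## The ontogenetic convergence test

For each species a linear trajectory of morphology on size is fitted and
evaluated at the species' smallest and largest observed specimen, giving a
juvenile and an adult predicted morphology per species. The statistic is

\[ \sum D_{juv} - \sum D_{adult}, \]

the summed pairwise Euclidean distance among juvenile predictions minus
that among adult predictions: positive when adults are more alike than
juveniles. Shape distances are computed on the tangent coordinates — the
space the trajectories were fitted in.

Significance comes from permutation (`n_permutations = 9999` by default):
specimen morphologies are randomised against the fixed (species, size)
design across the pooled sample, trajectories are refitted, and the
statistic recomputed; the p value is the proportion of permuted statistics
at least as large as the observed one, ties counting towards the
numerator. Two conventions are exposed: the raw proportion `b/m`
(default, which can legitimately be zero when the observed statistic
exceeds every permuted one) and the `(b+1)/(m+1)` variant that is strictly
positive.

**What is shuffled.** Two schemes are offered. The default permutes the
*raw* specimen morphologies: under the null of a single shared trajectory
with i.i.d. errors these are exchangeable, and the test is exact — its
rejection rate at nominal 5% sits inside the binomial band in the
package's calibration tests. The alternative (`shuffle = "fitted"`)
permutes the specimen-level *fitted* morphologies, a literal reading of
randomising "predicted morphologies with respect to size". It yields the
identical observed statistic, but fitted values carry only about `2/n` of
the residual variance, so the permutation distribution is compressed and
the scheme rejects far too often under a true null; it is retained as a
documented switch, not the default. Note also that the permutation null
assumes exchangeable responses: with a shared but *sloped* trajectory,
permuting morphologies against size destroys the size dependence itself
and the nominal level is no longer guaranteed — the calibration fixture
therefore uses a flat shared trajectory.

## Ancestral reconstruction of growth regime

Growth regime (allometric/isometric) is a binary character evolved on the
phylogeny under the two-state equal-rates Mk model: the probability of
change along a branch of length `t` is `(1 - exp(-2 q t))/2`. The rate `q`
is the only free parameter; with eight tips a richer model is not
identifiable. The root prior is flat — which for the symmetric model is
also the stationary distribution, so the choice is forced up to
documentation. `mk_log_likelihood()` implements Felsenstein pruning with
per-node rescaling; `reconstruct_ancestral_states()` maximises it over
`q` (a 40-point log-scale grid scan to bracket the optimum, then
golden-section refinement to `1e-8` — the grid guard matters because the
likelihood saturates at high rates whenever the tip pattern is maximally
homoplastic) and computes marginal state probabilities at every node by
the inside-outside decomposition (subtree-below times rest-of-tree).
Tips are observed: their marginals put probability one on the coded
state. The ML state of a node is the argmax of its marginals; exact ties
are reported as `"ambiguous"`, never broken silently, and transitions are
counted only on branches whose two ends are unambiguous and differ. When
all tips share one state the likelihood is monotone decreasing in the
rate; the rate is pinned to the lower bound with a warning and the
reconstruction is the shared state everywhere.

The packaged newick tree (`hydromantes_tree()`) is a *synthetic* fixture:
its topology mirrors the accepted relationships of the eight European
species (a Sardinian clade nesting the three allometric species together
with the isometric *H. imperialis*; a mainland clade as outgroup), but its
branch lengths are made up. Inferences drawn on it are qualitative
demonstrations, not estimates about the real genus.

## The synthetic-data generator

`generate_dataset()` draws, per species: foot length uniform over the
species' size range (uniform maximises regression leverage over an
ontogenetic series and is the simplest documented choice); sinuosity from
the linear trajectory plus additive Gaussian noise on the ratio scale,
redrawn while below the geometric floor of 1 (redraw counts are reported);
foot width as a fixed fraction (0.55) of foot length, perimeter as
`sinuosity * width`; body weight log-uniform on 0.5–10 g, with 5% of
weights subsequently set missing (museum specimens are not always
weighable); foot area from `A = b W^alpha` with multiplicative log-normal
noise; and landmarks equal to the species' mean shape displaced along its
allometric shape vector by log centroid size, plus isotropic landmark
noise, scaled to the specimen's size in mm. Each configuration is then
pushed through nuisance transforms — rotation uniform on the circle,
translation uniform on ±10 mm, digitiser scale log-uniform on 0.5–2 —
so that superimposition has demonstrable work to do; the digitiser scale
is carried in the TPS `SCALE=` record and undone by `landmark_mm()`, which
is how real digitised landmark files work.

The reference fixture `hydromantes_params()` encodes the study design the
package emulates: 330 specimens across eight species (24–54 per species),
five isometric and three allometric. The allometric species use sinuosity
slopes near −0.035 to −0.053 per mm, as reported for these species, and
the within-species noise sd is set so the slope standard error implied by
each species' design equals the reported one — so the fixture reproduces
the strength of evidence of a real ontogenetic series, not an idealised
version of it. Trajectory intercepts place every species' adult mean
sinuosity inside 2.3–2.8, bracketing the reported adult range
(2.38–2.73); the three allometric species share one allometric shape
vector (magnitude 0.05 per unit log centroid size) and reach a common
webbed adult shape at maximum size, while the isometric species hold that
webbed shape throughout growth — the configuration that generates
ontogenetic convergence.

A consequence worth stating plainly: with regime coding performed at
`alpha = 0.05` per species, a truly isometric species codes correctly with
probability exactly 0.95, so the chance that *all* regimes of an
eight-species fixture are recovered simultaneously is bounded by
`0.95^5 ≈ 0.77` before allometric power (about 0.68–0.97 at the
calibrated effect sizes) is even considered; joint recovery occurs in
roughly 40% of seeds. That is a property of the published design's
evidence strength, not of the implementation, and single-seed end-to-end
runs can therefore miss one of the weaker allometric species. When that
happens the remaining allometric tips may be maximally homoplastic on the
tree, in which case the equal-rates model correctly saturates and the
reconstruction declines to infer transitions.

What the generator does **not** emulate: correlation between the scalar
measurements and the landmark configuration of the same foot (they are
generated through parallel channels), non-uniform size sampling,
structured digitisation error, or within-locality variation. Passing tests
therefore validate the statistical machinery, not those aspects of real
data.

Auxiliary fixtures: `shared_trajectory_params()` (a flat shared trajectory
— the exchangeable null used for type-I calibration) and
`convergent_ontogeny_params()` (a common adult optimum with juvenile
values dispersed over 0.7 sinuosity units — the alternative used for power
checks).

## Numerical choices and problem sizes

* GPA: `tol = 1e-8` on consensus RMS change, `max_iter = 100`; canonical
  orientation via consensus principal axes, sign fixed by the largest
  |coordinate| landmark.
* Mk rate search: bounds `1e-6`–`100`, log-scale grid of 40 then
  `optimize()` at `1e-8`.
* MANCOVA principal-subspace cut-off: eigenvalues above `1e-10` of the
  largest.
* Test-suite problem sizes are chosen to make the checks sharp but quick:
  type-I calibration uses 200 simulated datasets at 999 permutations,
  power checks 100 datasets, regime-recovery 100 seeds of the full
  330-specimen fixture, power-law bias 500 seeds at n = 40, and the
  enumeration oracles cover all trees of 3–6 tips over a 20-point rate
  grid.

## Limitations

* Trajectories are linear in size; curvilinear ontogenies are out of
  scope, as are sliding semilandmarks and outline methods.
* The convergence statistic compares endpoint predictions only; it is not
  a general phenotypic-trajectory-analysis toolkit (no angle or
  path-length comparisons).
* No phylogenetic correction is applied to the species-level regressions
  — species are modelled separately, matching the analysis the package
  reproduces.
* The shipped tree and growth references are synthetic stand-ins; only
  qualitative statements about the real taxa can be supported by runs on
  them.
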