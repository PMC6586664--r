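---
title: "Seasonal gradient analysis of carabid assemblages at field-woodlot ecotones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal gradient analysis of carabid assemblages at field-woodlot ecotones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The study system and the data model

The package analyses pitfall-trap transects that cross the boundary between
an arable field and a woodlot. Each transect has seven trap sites on a signed
axis — woodlot interior at −20, −10 and −3 m, the boundary at 0 m, and the
field at +3, +10 and +20 m — with four traps per site, four replicate
transects, and repeated sampling periods across the season (early spring,
late spring, summer, late summer, autumn). Pitfall catches confound local
density with movement activity ("activity-density"), and trapping-period
length and temperature differ between seasons, so all within-season spatial
analysis works on *relative* quantities rather than raw counts.

The data-preparation rules are:

* the damaged late-summer period is excluded (`exclude_period()`);
* the four traps of a site are pooled into one sample (`pool_traps()`),
  giving 28 pooled samples per period;
* species with fewer than 4 specimens over the retained dataset are dropped
  before ordination (`filter_rare_species()`);
* relative abundance at a distance is the pooled count there divided by the
  transect-period total; relative richness uses species counts instead, so
  its seven values can sum to more than 1 (at most 7). A transect-period in
  which a habitat group is entirely absent yields an *undefined* profile
  (0/0), which is carried explicitly as `NA` and excluded from curve fitting
  — absence of evidence at one site (an observed zero) and absence of the
  whole denominator are different things and are never conflated.

Species are assigned to open-habitat, forest, or generalist groups by a
trait table, matched by exact name after whitespace/case normalisation; a
mapping table can translate abbreviated names.

## Response curves: the HOF family

Spatial responses along the boundary gradient are modelled with the
Huisman–Olff–Fresco family of bounded logistic curves. With the gradient
scaled affinely from metres to $x \in [0,1]$ and
$z(x) = 1/(1+e^{a+bx})$, $w(x) = 1/(1+e^{c-dx})$:

| type | shape | formula | free parameters |
|------|-------|---------|-----------------|
| I | flat | $M/(1+e^a)$ | 1 |
| II | monotone | $M\,z(x)$ | 2 |
| III | plateau | $M\,z(x)/(1+e^c)$ | 3 |
| IV | symmetric unimodal | $M\,z(x)\,w(x)$, $d \equiv b$ | 3 |
| V | skewed unimodal | $M\,z(x)\,w(x)$ | 4 |

$M$ is fixed at 1 for relative data. Type IV's mode sits at
$x^\ast = (c-a)/(2b)$ and the curve is symmetric about it; $c = a+b$ gives
symmetry about the gradient midpoint (the boundary).

**Error family.** The default fit minimises the binomial deviance with the
profile's integer denominator as the trial count — relative abundance is a
count ratio with a known total, so the binomial likelihood is the natural
loss and automatically weights transect-periods with more individuals more
strongly. A gaussian (least-squares) fallback is available for responses
without meaningful denominators.

**Optimisation.** Each type is fitted by bounded quasi-Newton (`nlminb`)
with analytic gradients from a deterministic grid of starting values, under
the box $|a|,|b|,|c|,|d| \le 50$ on the scaled gradient (a slope of 50
already saturates within ~2% of the gradient, so the box only prevents
overflow, not shapes). Starting values always include the *exact embedding
of the nested sub-model optimum*: type I has a closed form; II starts from
(I, $b=0$); III and IV from (II, $c=-50$, where the extra logistic factor
equals 1 in double precision); V from (IV, $d=b$) and (III, $d=0$). Descent
from an exact embedding can only improve, so the deviance hierarchy
$D_V \le D_{IV} \le D_{II} \le D_I$ (and $D_V \le D_{III} \le D_{II}$) holds
by construction, not merely in expectation — a property the test suite
verifies on a thousand random profiles. Bootstrap refits use a reduced
start grid (the warm-start chain plus a few generic starts), since they fit
thousands of small perturbations of the same profile.

**Model selection.** The analysis tradition selects "the type with minimal
deviance", but over a nested family literal deviance minimisation
degenerately returns the most complex type. Both criteria are exposed:
`criterion = "deviance"` reproduces the literal rule (with ties within
$10^{-6}$ broken towards fewer parameters, so exact boundary ties collapse
to the simpler type), and the default `criterion = "aicc"` uses
small-sample-corrected AIC, which is what makes the *type* labels
meaningful. For a truth on the boundary between two types (IV inside V), an
information criterion still picks the larger type at a fixed positive rate
(roughly $P(\chi^2_1 > 2k_{\mathrm{corr}})$), which is why type-recovery
checks count a type V fit whose curve matches a type IV truth as a recovery
of the curve.

## Season contrasts: stratified bootstrap envelopes

To ask whether a focal period's spatial distribution differs from the rest
of the season, the package builds bootstrap confidence envelopes:

1. a bootstrap replicate redraws, at each distance independently and with
   replacement, as many profile values as were observed there across
   transects (per-distance sample sizes are conserved; values travel with
   their denominators so binomial refits stay valid);
2. each replicate is refitted (`select_hof`) and evaluated on a gradient
   grid;
3. the pointwise median and equal-tail 95% quantiles (type-7) over
   replicates form the median curve and envelope;
4. the focal period's median curve is compared pointwise with the pooled
   envelope of the other periods: any excursion outside the band flags the
   contrast.

**The pooled band is the pooled set of per-period curve distributions.**
Two readings of "the envelope for the pooled other periods" are
implemented. `pooled_mode = "resample_pooled"` refits curves to resamples
of the merged data (12 values per distance for 3 periods × 4 transects).
`pooled_mode = "pool_period_curves"` (the default) bootstraps each
non-focal period separately — conserving the design's four observations per
distance — and pools the three curve sets before taking the median and
quantiles. The default was chosen by a calibration experiment shipped in
the acceptance suite: on a seasonally constant simulation the merged-data
band is systematically narrower than the sampling spread of a single
period's median curve (three times the information), so the comparison
flags spurious "seasonal differences" in over half of the runs, which would
make the contrast useless; the pooled-curve-set band reflects the same
per-distance information as the focal curve plus the between-period spread,
and the same experiment flags well under a quarter of the constant-scenario
runs while detecting the built-in early-spring boundary peak essentially
always.

**Significance is pointwise.** The non-overlap flag applies no multiplicity
correction across grid points, mirroring how such figures are read; the
exported tables carry the full per-point mask so users can judge extent and
contiguity rather than a single star.

## Constrained ordination

Ordination is implemented from first principles (and cross-checked against
the vegan implementations in the tests, which are never used as the
computational path):

* **CCA** chi-square standardises the community matrix
  ($\bar Q = (P - rc')/\sqrt{rc'}$ with row/column masses $r, c$), removes
  covariates by row-weighted least squares, projects the remainder on the
  weighted, residualised constraints, and eigen-decomposes the fitted part.
  The inertia decomposition (total = covariate + constrained + residual) is
  exact to $10^{-8}$ by construction and asserted in tests.
* **pseudo-F** $ = (I_{constr}/q)/(I_{resid}/df_{res})$ with
  $df_{res} = n - 1 - q - p_{cov}$.
* **Permutation tests** permute the rows of the *raw constraint matrix*
  within blocks under the reduced model (covariates fixed; the permuted
  constraints are re-centred and re-residualised each time, and row masses
  stay attached to rows). Permutations are generated on the full design, so
  blocks stay balanced even when zero-total samples were dropped from the
  response. $p = (1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$ with ties counted
  as exceeding (conservative); 499 permutations give the attainable floor
  $p = 0.002$.
* **Three analyses** mirror the design: the *spatial* partial CCA (signed
  distance in metres as one numeric constraint — a factor coding is
  available — permuted within the 16 transect × period cells); the
  *interaction* CCA (distance × period contrasts constrained, main effects
  plus transect partialled out, period labels exchanged between whole cells
  within transects); and the *db-RDA* (Bray-Curtis dissimilarities of the
  log-transformed counts, classical PCoA, redundancy analysis of the
  retained positive-eigenvalue scores on the interaction with factor-coded
  main effects as covariates, transects as free-permutation blocks).
* **Covariate convention.** For the spatial analysis the default partials
  out transect *and* period (`covariate_mode = "caption"`), because the
  reported "net" spatial variance is corrected for both; a methods-literal
  transect-only mode is available. "Net variance explained" is
  constrained / (total − covariate) inertia; the raw fraction of total is
  also reported.
* **Numerical edge cases.** Samples with zero totals are dropped with a
  warning (the chi-square metric is undefined for them); aliased
  interaction columns that this creates are tolerated in the wrappers (the
  projection uses the attained rank) but are an error in the user-facing
  `cca()`; negative PCoA eigenvalues are reported and their axes dropped —
  no Lingoes/Cailliez correction is applied.

## The community simulator

`generate_catch_table()` emulates the design so every stage is testable
without the field data: for each transect × period × habitat group the
expected site totals follow the group's true HOF-shaped relative profile,
scaled by the period's expected per-transect total and a lognormal
transect-by-period activity multiplier; species counts are negative
binomial (size 2 by default — strong overdispersion of pitfall catches)
around the species' weight share, and each site's catch is split uniformly
(multinomial) over its four traps, with zero rows emitted.

`study_scenario()` encodes the study system's qualitative structure:
open-habitat species dominate the pool (~85% of expected catch); their
response rises towards the field with a sharp increase at the ecotone in
late spring and autumn (type V), peaks at the boundary in early spring
(type IV), and flattens into the woodlot in summer (type II); forest
species mirror this with an early-spring boundary peak; generalists are
edge-centred throughout. Expected per-period totals over four transects run
from the hundreds (autumn) to thousands (summer), matching the scale of the
field data. `no_difference_scenario()` keeps one shape per group across all
periods and is the null case for calibrating the season contrast.

Deliberate simplifications: the transect multiplier is shared by all
species and distances (it cancels from relative profiles, so it stresses
only the count-level analyses); species within a group share the group
curve (no per-species shape variation); there is no spatially explicit
movement, weather modulation, or temporal autocorrelation. Passing tests
on this generator demonstrates the statistical machinery under the stated
noise model — not that real carabid data satisfy that model.

## Problem sizes and reproducibility

Defaults follow the analysis tradition: 499 bootstrap replicates, 499
permutations, 95% envelopes on a 101-point grid. The test-suite studies use
deliberately smaller sizes chosen as a compromise between Monte-Carlo error
and runtime on a single CPU: envelope calibration and power runs use 59
replicates on a 51-point grid over 100 seeds per scenario; coverage checks
use 99 replicates over 100 outer replicates; the acceptance script uses 199
replicates on the full grid. Every stochastic step accepts a seed:
generator output is byte-reproducible, envelope comparisons derive one
seed per comparison, and permutation tests record their null F
distributions.

## Known limitations

* Pointwise envelope comparison has no family-wise error control; the
  extent of non-overlap should be read from the exported masks.
* The pseudo-F degrees of freedom assume fixed covariate and constraint
  ranks; aliased interaction cells reduce the rank and are handled, but
  heavily unbalanced data change what the interaction test can see.
* Bray-Curtis PCoA drops negative-eigenvalue axes; with strongly
  non-Euclidean dissimilarity structure some variation is excluded from
  the db-RDA response space.
* The binomial deviance treats pooled-sample counts as independent trials;
  overdispersion relative to that model widens envelopes only through the
  across-transect resampling, which is exactly why the bootstrap is
  stratified by distance.
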