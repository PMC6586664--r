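# carabidedge

Seasonal change in the spatial distribution of carabid beetles across arable
field–woodlot boundaries, analysed from pitfall-trap transects.

Ground beetles (Carabidae) supply pest- and weed-seed predation in arable
landscapes, and where they sit relative to non-crop habitat changes with the
season: open-habitat species overwinter near habitat edges, colonise field
interiors in spring, and can spill into woodlots in summer. This package
implements, as tested reusable code, the full analysis chain for a transect
design that crosses field–woodlot boundaries at signed distances
(−20, −10, −3, 0, +3, +10, +20 m; woodlot negative, four traps per site,
four transects, repeated sampling periods):

* **Data rules** — trap pooling into site samples, exclusion of a damaged
  sampling period, a fewer-than-4-specimens rarity filter, and relative
  abundance/richness profiles per transect × period (group-specific, with
  0/0 profiles kept explicit rather than imputed).
* **Response curves** — the Huisman–Olff–Fresco (HOF) family of bounded
  logistic shapes on the scaled gradient $x \in [0,1]$, with
  $z(x)=1/(1+e^{a+bx})$, $w(x)=1/(1+e^{c-dx})$: flat $M/(1+e^a)$ (I),
  monotone $Mz$ (II), plateau $Mz/(1+e^c)$ (III), symmetric unimodal $Mzw$
  with $d{=}b$ (IV), skewed unimodal $Mzw$ (V); fitted by binomial-deviance
  minimisation with nested warm starts, selected by AICc (or literal
  minimal deviance).
* **Season contrasts** — stratified bootstrap (resampling profile values
  across transects within each distance) yielding a median curve and 95%
  envelope; a focal period is flagged when its median curve leaves the
  pooled envelope of the other periods anywhere on the grid (pointwise, as
  such figures are read).
* **Ordination** — from first principles: partial canonical correspondence
  analysis (chi-square standardisation, row-weighted projections), with
  pseudo-F $=(I_{constr}/q)/(I_{resid}/df_{res})$ tested by restricted
  permutations (within transect × period blocks; period-label exchange for
  the distance × period interaction); Bray–Curtis principal coordinates and
  db-RDA of the interaction with transects as permutation blocks
  (499 permutations; attainable floor $p = 0.002$).
* **Simulator** — a negative-binomial community generator reproducing the
  design (group- and period-specific true HOF curves, lognormal transect
  effects, multinomial trap splits) so calibration, power and parameter
  recovery are measurable without the field data.

The vegan package is used only as an independent cross-check in the test
suite; all analysis paths are implemented in this package.

## Worked example

The repository is organised as an analysis workflow: numbered drivers under
`analysis/` run the package's functions and write their tables under
`results/`.

```sh
Rscript analysis/01_simulate.R 1    # study-like synthetic trap catches
Rscript analysis/02_profiles.R 1    # HOF envelopes: 32 season contrasts
Rscript analysis/03_ordination.R 1  # spatial CCA, interaction CCA, db-RDA
```

With seed 1 the first step prints:

```
Simulated 10092 individuals of 16 species over 4 transects x 4 periods
        period individuals species
1 early_spring        1287      16
2  late_spring        2289      16
3       summer        6017      16
4       autumn         499      16
```

— per-period totals in the hundreds to thousands, as in the field system.
Step 2 prints one row per group × response × focal period; `significant`
marks contrasts whose focal median curve leaves the pooled-period 95%
envelope (seed 1, abridged; 23 of 32 contrasts are flagged):

```
        group  response focal_period significant n_nonoverlap
 open_habitat abundance early_spring        TRUE           94
 open_habitat abundance       summer        TRUE           37
 open_habitat abundance       autumn       FALSE            0
   generalist abundance early_spring       FALSE            0
```

The built-in scenario plants an early-spring boundary peak and a flatter
woodlot-penetrating summer shape for the open-habitat group; both are
recovered (94 and 37 of 101 grid points outside the pooled band), while
the seasonally constant generalist group is not flagged in spring. Step 3
prints the three ordination results (seed 1):

```
    analysis  pseudo_f p_value net_variance_pct
     spatial 23.560749   0.002         19.54264
 interaction  1.311009   0.002         22.90863
       dbrda  3.078323   0.002         39.74599
```

`pseudo_f` is the per-degree-of-freedom ratio of constrained to residual
inertia, `p_value` its restricted-permutation probability (0.002 is the
floor with 499 permutations), and `net_variance_pct` the constrained share
of the covariate-adjusted inertia. The strong planted gradient makes the
spatial signal large; the seasonal shape changes make the interaction and
db-RDA tests significant too. Exact values depend on the seed — regenerate
them with the commands shown.

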