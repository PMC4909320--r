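---
title: "Models and methods behind rootchamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rootchamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootchamber)
```

rootchamber analyses paper-based plant growth chambers in which a seedling's
root system develops on a horizontal filter-paper "growth sheet" wicking
nutrient solution from a cup below, while a supersaturated salt solution
fixes the relative humidity (RH) of the shoot compartment. The package has
three scientific layers — a mass-balance model of the chamber, an image
phenotyping pipeline for thresholded 2D root masks, and the group statistics
that compare phenotypes across growth conditions — plus a synthetic-data
generator that manufactures inputs with known ground truth so that every
stage can be validated end to end without photographic data. This vignette
explains the models, their assumptions, the tunable parameters, and the
numerical and design choices that were genuinely open.

## Nutrient mass balance

Water leaves the nutrient cup by evaporation from the sheet and by
transpiration through the plant, at a combined areal rate $J_w$
(ml cm$^{-2}$ day$^{-1}$). That water carries dissolved nutrients up to the
sheet; the water departs as vapour, the nutrients do not. The advective
nutrient mass flux follows from unit bookkeeping alone:

$$J_n \;=\; J_w \, C \, M \quad \left[\frac{\text{mg}}{\text{cm}^2\,\text{day}}\right],$$

with $C$ the molarity (mol L$^{-1}$) of the nutrient in the cup and $M$ its
formula weight (g mol$^{-1}$); 1 ml $\times$ 1 mol L$^{-1}$ $\times$
1 g mol$^{-1}$ is exactly 1 mg, so no additional conversion factor is
needed. `nutrient_flux_to_sheet()` implements exactly this product, and its
tests verify it against an independent conversion walked through SI base
units.

Accumulation at the sheet builds a concentration excess $\Delta C$ over the
cup, which drives a diffusive return flux through the saturated paper
column of height $h$ (Fickian, $J_{\mathrm{diff}} = D\,\Delta C / h$). At
steady state the two fluxes balance:

$$\Delta C = \frac{J_n\,h}{D}.$$

`steady_state_enrichment()` solves this algebraically and reports
$\Delta C$ both in mg L$^{-1}$ and as a percentage of the cup
concentration. Two deliberate biases make the result an upper bound: plant
uptake is neglected (all delivered nutrient is assumed to accumulate), and
$h$ defaults to 0.2 cm, twice the typical operating distance. The default
nutrient is elemental phosphorus in half-strength MS medium
(1.25 mM KH$_2$PO$_4$ at full strength, so $C = 6.25\times10^{-4}$ mol/L
and $M = 31$ g/mol); tracking the element rather than the phosphate ion is
the package's convention for "phosphorus concentration", and both $C$ and
$M$ are configurable for any other species. With the default water flux of
0.05 ml cm$^{-2}$ day$^{-1}$ and $D = 0.89\times10^{-5}$ cm$^2$ s$^{-1}$
the enrichment evaluates to about 1.3% — the quantitative basis for
treating the sheet concentration as equal to the cup concentration.

```{r}
steady_state_enrichment(flux_params())
```

The analytic solution is cross-checked in the test suite against an
explicit finite-volume simulation of the 1-D diffusion column (200 nodes,
constant top-face influx, reservoir-pinned bottom, run for twelve diffusive
relaxation times), which agrees to well under 1%. The model is
deliberately 1-D and vertical; lateral transport in the sheet is handled
statistically (below), not mechanistically.

`simulate_cup_depletion()` covers the companion bookkeeping in the cup:
the liquid level is re-established with deionized water, so volume is
constant, no nutrients enter, and plant uptake is the only sink,
$\mathrm{d}C/\mathrm{d}t = -u(t)/V$. Uptake may be a constant or an
arbitrary schedule $u(t)$ (integrated by trapezoidal quadrature on a grid
100$\times$ finer than the output step). Zero uptake gives the flat null
expectation against which "no accumulation" claims are judged.

## Humidity homeostasis

The shoot compartment receives water vapour at a rate $\phi_{in}$ (ml/day
of liquid-water equivalent; default 5, matching a measured 4 + 1 ml/day of
evaporation plus transpiration), exchanges vapour with the laboratory
through leaks, and loses vapour to the salt. The package uses the minimal
kinetic model that exhibits every qualitative regime of interest: both
exchange terms are linear conductances,

$$\phi_{in} + k_{leak}\,( \mathrm{RH}_{lab} - \mathrm{RH}) \;=\; k_{salt}\,\max(\mathrm{RH} - \mathrm{RH}_{eq}, 0),$$

where $\mathrm{RH}_{eq}$ is the salt's equilibrium value and $k_{salt}$
(ml day$^{-1}$ per %RH) is proportional, to first order, to the exposed
area of the supersaturated solution. The salt term is one-sided: the sink
absorbs above equilibrium and does nothing below it. Consequences the
model reproduces:

* **Kinetic limitation.** A finite $k_{salt}$ leaves the steady state
  *above* $\mathrm{RH}_{eq}$ by $(\phi_{in} + k_{leak}(\mathrm{RH}_{lab} -
  \mathrm{RH}))/k_{salt}$: a strong vapour source with a small exposed salt
  area cannot be pulled down to thermodynamic equilibrium.
* **Leak bias.** With the laboratory near 50% RH, leaks pull high-RH
  chambers slightly down and low-RH chambers slightly up.
* **Depletion.** The salt stops buffering once it has absorbed
  `salt_capacity` ml of water (complete dissolution); afterwards RH relaxes
  up to the leak-determined level.

`humidity_steady_state()` solves the balance algebraically;
`simulate_humidity()` integrates it forward with the chamber's vapour
inventory as state, converting between RH and millilitres through the
saturation vapour density at 20 °C (17.3 g m$^{-3}$). The vapour time
constant of a ~20 L chamber is minutes, far shorter than any output step of
interest, so the integrator automatically sub-steps each output interval to
keep the explicit update stable; in the substep where capacity runs out
the salt absorbs only what remains, which keeps the water ledger exact.
The output carries cumulative input, net leak, and absorbed columns so
conservation can be audited directly; the suite checks the residual to
$10^{-6}$ of cumulative input. Temperature is a lookup key only (chambers
track ambient to within about a degree); there are no temperature
dynamics. Bundled equilibrium RH values (LiCl 11.3% through K$_2$SO$_4$
97.6% at 20 °C) are standard literature values for saturated salt
solutions.

## Root phenotyping on binary masks

A `root_mask` is a binary raster plus a physical pixel size; coordinates
are pixel centres, row-major from the top-left, and physical position is
index $\times$ pixel size. Three scalar phenotypes are computed:

* **Projected area**: root-pixel count $\times$ pixel area, in cm$^2$.
  This is the projected (2D) area; no attempt is made to reconstruct a
  cylindrical surface from widths, which would require a skeletonization
  step the pipeline deliberately avoids.
* **Span**: half the maximum Feret (caliper) diameter over root pixel
  centres, in cm. "Maximum width" is read as the orientation-free caliper
  diameter rather than a bounding-box width, which would depend on how the
  photograph happened to be rotated. A single pixel has zero span.
* **Symmetry**: let $d_1$ be the maximum Feret diameter and $\theta$ its
  direction; $d_2$ is the extent of the root pixels perpendicular to
  $\theta$. The ratio $d_2/d_1 \in (0, 1]$ is 1 for an isotropic system.
  Both extents are floored at one pixel — any nonempty pixel set is
  physically at least one pixel wide — which keeps the statistic defined
  and in $(0,1]$ for degenerate (e.g. collinear) masks while leaving
  ordinary masks untouched. On a pixel grid the maximizing pair need not
  be unique; the implementation takes the first maximal pair on the convex
  hull in scan order, and the tests accept any tied pair's ratio.

Span and symmetry run on the convex hull (the diameter of a point set is
the diameter of its hull), but are validated against $O(n^2)$ all-pairs
and 3600-angle brute-force scans on every test mask. Biomass is never
computed from images: it joins `phenotype_batch()` output as measured
data, and the span–biomass relationship is assessed by `pearson_r()`.

Grayscale images are binarized either at a fixed threshold or by Otsu's
method (exhaustive 256-level search maximizing between-class variance);
the test oracle is the equivalent intra-class-variance minimizer. There is
no defensible automatic rule for colour images, so unequal channels raise
an error rather than guessing a luminance conversion.

## Enclosed-void topology

The topology phenotype is the set of background regions *fully enclosed*
by roots. Connected components of background pixels are computed with
4-connectivity while root pixels act as 8-connected barriers — the
standard digital-topology duality; without it, a diagonal root "wall"
would paradoxically leak. Any component touching the image border is not
enclosed and is discarded; that is the only defensible reading for regions
clipped by the photograph edge. No minimum-size filter is applied by
default (a `min_area_cm2` argument exists). The labelling kernel is
compiled (a breadth-first search in C++); the tests pit it against a pure-R
border flood-fill oracle on hundreds of random masks, and check that
enclosure is invariant to padding and that voids, border background and
root components exactly partition the image.

Void sizes are summarized as log-binned histograms (bins span whole
decades, left-closed, counts conserved; the density column divides by
linear bin width and sample count so a power law $p(x)\propto x^{-\alpha}$
plots as a line of slope $-\alpha$). Both raw counts and densities are
reported, since either normalization is a legitimate reading of a
frequency plot.

`fit_powerlaw()` estimates the tail exponent by the continuous
maximum-likelihood (Hill) estimator
$\hat\alpha = 1 + n / \sum_i \ln(x_i/x_{min})$ with standard error
$(\hat\alpha - 1)/\sqrt{n}$, plus a log-binned OLS slope as the visual
alternative. When $x_{min}$ is not fixed it is selected by minimizing the
Kolmogorov–Smirnov distance of the fit over candidate data values (thinned
to 200 candidates on large samples). Fits are refused below 10 tail points
or on degenerate samples. Because large enclosed areas have long
perimeters and are the first casualties of imperfect thresholding,
`truncation_sensitivity()` reports how far the exponent moves when the top
fraction of areas is dropped — truncating the upper tail biases a Hill fit
upward, and the size of that shift is the right robustness statement for
an exponent estimated from thresholded photographs.

Cross-condition robustness of the whole distribution is tested
nonparametrically: `compare_area_distributions()` reports pairwise
two-sample KS statistics with seeded label-permutation p-values (add-one
convention, $p = (1 + \#\{D^\ast \ge D\})/(B+1)$) alongside per-condition
exponent fits and their differences with propagated standard errors. The
headline robustness question is settled by the KS comparison, not by
exponent equality: the exponent machinery is provided, but a distribution
can agree or differ in ways a single exponent does not capture. One
numerical subtlety: with a few hundred observations per side the
two-sample KS statistic lives on a coarse grid, so permuted statistics
often tie with the observed one; ties are counted as "at least as
extreme", which makes the permutation test slightly conservative (observed
type-I rates around 3–4% at a nominal 5% in the calibration runs). This
is the standard validity-preserving convention and is left as is.

## Group statistics

Group summaries are means with Student-t 95% confidence intervals (the
convention matching error bars on phenotype-versus-condition plots).
Two-group comparisons default to Welch's unequal-variance t-test, with a
seeded mean-difference permutation test always available; no test is ever
silently chosen based on the data. Spot-concentration heterogeneity is the
percent coefficient of variation per nutrient. The near/far analysis
subtracts the per-sheet, per-nutrient grand mean from each spot and
compares mean deviations of spots nearer than 5 mm to the root against the
rest, reporting Welch and permutation p-values with Holm-adjusted columns
when several nutrients are tested (raw p-values remain the primary
report). Monte-Carlo checks in the suite hold both tests to their nominal
type-I error within ±2% at 1000 replicates and verify detection power
above 0.9 for a 50% near-root depletion at 24 spots per side.

## The synthetic-data generator

The generator is the package's substitute for raw photographs and meters,
and its defaults are fixed at the reference chamber's operating
conditions: spot tables default to 48 spots per nutrient split evenly
about the 5 mm cutoff with an 11% point-to-point CV; humidity series
default to the NaCl chamber with 5 ml/day vapour input and a 50% RH
laboratory; the mass-balance defaults are listed above.

**Root masks.** Each primary axis is a discrete-step random walk from a
single central insertion point (the seedling plug): per 1 mm step the
heading gains Normal(0, 12°) noise, laterals initiate as a Poisson process
at 0.08 per mm and branch at ±55°, and growth stops when a shared
1500 mm length budget is spent or an axis reaches the frame. These values
were chosen once as a realistic two-week-old *Brassica rapa* system on a
64 mm sheet (256×256 px at 0.25 mm/px): entangled, loop-rich, spanning a
few centimetres, with hundreds of enclosed voids. An `anisotropy` dial
scales vertical step displacement by $(1 - a)$, providing symmetry ground
truth from near-isotropic ($a = 0$, symmetry near 1) to collinear
($a = 1$). Axes are rasterized by dense sampling (a quarter-pixel step)
and a square brush of the requested stroke width; re-rasterizing the
stored polylines reproduces the mask bit for bit. Ground truth is stored
with each mask: the true span and symmetry from the continuous axis
points, and the true void areas from the rasterized mask itself — voids
are a property of the image, not of the plant's topology, because loops
arise from axis crossings that only exist after rasterization. Void ground
truth therefore shares the extraction code path by construction;
independence of the extractor is established separately by the brute-force
flood-fill oracle.

**Spot tables.** Concentrations are lognormal, parameterized so the
arithmetic mean and CV match the request exactly; lognormal guarantees
positivity and is indistinguishable from a normal at CV ≈ 0.11. A
`near_effect` fraction shifts the near-spot mean, giving a truth-known
depletion signal for power studies.

**What the generator does not emulate.** Real thresholded photographs
carry correlated segmentation noise (broken strokes, specks, halo
pixels), roots have variable diameters and curvature correlations, and
spot measurements share sheet-level spatial structure. Passing tests
therefore demonstrate that the *algorithms* are correct on their stated
domain — binary masks and i.i.d. spot noise — not that any particular
photograph pipeline is artifact-free. The truncation-sensitivity and
KS-comparison tools exist precisely because real inputs violate these
idealizations at the large-area tail.

Every generator draws from a local RNG seeded per call; the global RNG
state is never touched, and identical spec + seed gives byte-identical
output.

## Validation problem sizes

The test suite and the acceptance script validate at these sizes, chosen
to bound Monte-Carlo error well inside each tolerance: 200 random masks
(up to 64×64) for the enclosure oracle; 40+ masks for the span/symmetry
oracles; Pareto samples of $10^4$ (100 replicates) for Hill recovery;
1000 replicates for type-I calibration of the KS permutation, Welch and
near/far tests (99–199 permutations each, a level-exact choice at
$\alpha = 0.05$); 200 replicates for power; a 200-node finite-volume
column for the diffusion cross-check; and $10^4$ spots for CV recovery.

## Known limitations

* The mass balance is steady-state and 1-D; transients after refills and
  horizontal gradients are out of scope.
* Humidity kinetics are first-order by construction; a salt bed whose
  exposed area shrinks as it dissolves would need $k_{salt}$ to vary.
* The salt sink is absorb-only; a supersaturated solution releasing water
  below its equilibrium RH is not modelled.
* Phenotypes are 2D: no skeletonization, lateral counts, or diameter
  classes, and projected area underestimates true surface area.
* The Hill fit assumes an i.i.d. tail; void areas of one plant are weakly
  dependent, so pooled-fit standard errors are approximate.
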