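---
title: "Quantifying damselfly mesostigmal sensilla: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying damselfly mesostigmal sensilla: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensimorph)
```

## The biological question and the measurement model

Female coenagrionid damselflies carry fields of cuticular mechanoreceptors
(sensilla) on their paired mesostigmal plates — the thoracic plates a male
grasps with his terminal appendages to form the premating tandem. Each
sensillum is innervated by a single neuron, so the field acts as a spatial
matrix of touch sensors: with $n$ binary sensilla a female can in principle
discriminate $2^n$ contact patterns (`tactile_pattern_capacity()`), which is
why even one extra sensillum is a meaningful gain in sensory resolution.
Where two species hybridize at a cost, reproductive character displacement
(RCD) predicts that such mate-assessment traits diverge more in sympatry
than in allopatry.

`sensimorph` implements the full analysis chain for testing those
predictions from digitized images: each female contributes a traced plate
outline (an ordered polygon, hundreds of vertices) and a set of sensilla
coordinates, digitized twice (technical replicates), with broken sensilla
recorded at their socket and counted. The pipeline starts at coordinates;
imaging and digitization are upstream of the package.

## Scalar traits

Per plate (`compute_traits()`):

* **sensilla count** — points digitized, broken sockets included;
* **plate area** — shoelace area of the outline polygon (µm²);
* **sensilla-region area** — area of the polygon connecting the outermost
  sensilla. We read "outermost polygon" as the *convex hull*: it is the
  unique parameter-free construction, whereas any concave alternative
  (alpha shapes, etc.) needs a tuning constant the measurement protocol does
  not supply;
* **coverage proportion** — hull area / plate area;
* **density** — count per hull area, reported per 1000 µm²;
* **nearest-neighbor distances** — per-sensillum distance to its closest
  neighbor; the mean is the arrangement summary used downstream (the median
  is computed too, and the two are strongly correlated in practice).

Replicates are averaged field-wise after per-replicate computation
(`average_replicates()`); averaged counts may be non-integral and are kept
real. Plates with fewer than three non-collinear sensilla get *missing*
hull-based traits rather than zeros — missing values drop out of population
means, zeros would bias them. Plates imaged at angles that permit counting
but distort geometry can be flagged `counts_only`; they contribute counts
and nothing else.

Left plates are mirrored about the vertical midline of their bounding box
(`standardize_plate_orientation()`) so everything downstream sees
right-plate orientation. Any vertical mirror axis is equivalent: the
translation it leaves behind is removed by centroid standardization. The
vertical axis orientation of the source images is preserved as stored; the
package never flips y.

## Spatial comparison of sensilla distributions

Raw coordinates are not comparable across females of different sizes, so
each plate is standardized (`standardize_cloud()`): outline and sensilla are
scaled jointly by $1/\sqrt{\text{area}}$ (unit plate area) and translated so
the outline's *area* centroid — not the vertex mean, which depends on how
densely the outline was traced — sits at the origin. Distance ratios within
a plate are untouched. Clouds are pooled within populations with at least
four measured females, one randomly chosen replicate per female.

Each pooled cloud gets a Gaussian-kernel density estimate. The default
bandwidth matrix is the closed-form normal-reference (normal-scale) matrix
$H = n^{-1/3}\hat\Sigma$ (for $d=2$): deterministic, rotation-equivariant,
and adequate for a permutation test whose calibration we verify by
simulation. A two-stage unconstrained plug-in selector is available
(`select_bandwidth(..., "plugin")`): order-4 integrated density-derivative
functionals are estimated with a normal-reference Gaussian pilot using exact
fourth-order Gaussian derivative tensors, and the resulting AMISE estimate
is minimized numerically over positive-definite matrices in a log-Cholesky
parameterization.

Two populations are compared by the integrated squared error between their
density estimates,
$$T = \int \left(\hat f_A(x) - \hat f_B(x)\right)^2 dx,$$
computed *exactly* (no grid) via the Gaussian convolution identity
$\int \phi_{H_1}(x-a)\,\phi_{H_2}(x-b)\,dx = \phi_{H_1+H_2}(a-b)$, so the
three terms of $T$ are pairwise kernel sums with kernels $2H_A$, $2H_B$ and
$H_A+H_B$. The null distribution is obtained by permutation with the
**female cloud as the exchangeable unit**: sensilla within one female share
a plate and are not independently exchangeable, so whole clouds are
relabeled between the two populations and bandwidths re-selected within
every replicate. The p-value uses the add-one estimator
$(1 + \#\{T^\ast \ge T\})/(n_{\mathrm{perm}}+1)$; ties count as exceedances,
so identical inputs give $p = 1$ and no test ever reports $p = 0$. A
point-level permutation is available behind a flag for comparison, but note
that with few females the number of distinct female-level relabelings is
finite (e.g. $\binom{12}{6} = 924$ at 6 + 6), which bounds the attainable
p-value above the add-one floor.

We chose the permutation route over reproducing any particular existing
tool's asymptotic null because a permutation test's operating
characteristics are verifiable from first principles — the acceptance suite
checks that the size at $\alpha = 0.05$ sits inside the exact binomial 99%
interval over 500 null simulations and that power increases with a planted
location shift. Across population pairs, raw p-values are adjusted by
Benjamini–Hochberg; the FDR is recomputed whenever a population is excluded
(`run_config(exclude_populations = ...)`).

Density surfaces for display are evaluated on a 151×151 grid with a margin
of 3 bandwidth standard deviations; if the Riemann sum deviates from 1 by
more than 1% the grid is refined once and a warning raised. Percentile
bands (`percentile_contours()`) are highest-density regions: the
"75th-percentile" region is the set of densest cells holding the top 25% of
probability mass, so regions nest by construction.

## Mean plate shapes

Outlines are resampled to 200 landmarks: the lower and upper medial plate
corners as fixed landmarks plus 198 semilandmarks (`resample_outline()`).
The default placement is **equal arc length** within each corner-to-corner
segment, allocated proportionally to segment length — deterministic and
invariant to digitization density. The legacy procedure of drawing 198
existing vertices uniformly at random is available (`mode = "random"`,
seed-reproducible); it injects avoidable sampling noise, which is why it is
not the default. How the original protocol allocated its random points
between the two outline segments is not documented; both modes are provided
rather than asserting one.

Population mean shapes come from generalized Procrustes analysis
(`gpa_align()`): center, scale to unit centroid size, rotate each
configuration to the running consensus by the optimal orthogonal rotation
with reflections excluded (orientation is standardized upstream), recompute
the consensus, iterate to a 1e-10 consensus movement or 100 iterations.
Optional semilandmark sliding moves each semilandmark along the tangent
direction estimated from its cyclic neighbors to the point nearest the
consensus, corners never moving. Two deliberate simplifications: the
sliding criterion is minimized Procrustes distance (not bending energy,
which is out of scope here), and sliding runs only during the first few
iterations (`slide_passes`, default 3). Minimum-distance sliding leaves a
semilandmark's position *along* the outline unconstrained — a gauge freedom
— so unbounded repeated sliding lets points drift along the curve; a small
fixed number of passes removes most tangential digitization noise while
keeping the superimposition convergent. Sliding is off by default.

## Population-level statistics

To avoid pseudoreplication every population contributes one value per
trait: the mean over its females, a single female standing for its
population when $N = 1$ (`aggregate_populations()`; `min_n` reproduces the
$N \ge 4$ sensitivity subset). The battery (`run_comparison_battery()`)
runs, per trait: the two-species contrast (Welch's unequal-variance t), the
three sympatry-class contrast within the widespread species
(Kruskal–Wallis), the two-class contrast within the restricted species
(Welch), and the sympatric-versus-allopatric variance contrast (Bartlett) —
RCD can reduce variance without moving means. Coverage proportions are
arcsine-square-root transformed ($\arcsin\sqrt p$, the standard
variance-stabilizing form) before testing. All p-values are two-sided. No
multiple-testing correction is applied across the trait battery — the FDR
adjustment belongs to the pairwise KDE table only; this mirrors the study
design the package reimplements and is worth keeping in mind when reading
battery output. Body size never corrects counts: the count-versus-abdomen
regression is reported (`linear_regression()`) but its null result means no
correction is applied.

## The synthetic world

`generate_study()` builds complete studies against the bundled site
manifest (`table1_manifest()`): 13 populations of *E. anna* (29 females)
and 19 of *E. carunculatum* (74 females) over 28 distinct sites, each
sympatric, locally allopatric, or allopatric. (Published summaries of this
design sometimes count 28 populations for the widespread species; 28 is the
count of distinct *sites* across both species, while the site table itself
lists 19 — the manifest follows the site table.)

Defaults encode the published trait regime, chosen once:

* counts: truncated normal (≥ 3), rounded; means 49 (*E. anna*) and 28
  (*E. carunculatum*) — the planted species difference of 21; within-
  population SDs 9 and 7, making a twofold count range inside a population
  unremarkable, as observed; between-population SDs 4 and 3.5;
* plate outlines: superellipses (exponent 2.5, aspect 0.55) with low-order
  radial perturbation, 600–1100 vertices matching digitized tracing
  density, lognormal areas around 43,000 and 30,000 µm²; radial outlines
  are star-shaped and therefore simple by construction;
* placement: two-component truncated Gaussian mixtures in plate-relative
  coordinates, rejected against the outline — medially biased and spread
  for *E. anna* (coverage ≈ 0.66, density ≈ 1.6 per 1000 µm²), a compact
  lateral cluster for *E. carunculatum* (coverage ≈ 0.30, density ≈ 3.0);
* replicates: two per female with 1 µm coordinate jitter, a ±1.5 SD
  recount error, and a 2% broken-socket rate — tuned so replicate
  correlations sit near the reported 0.95 regime; 19% of females are
  digitized from the left plate and stored mirrored, exercising the
  orientation path end-to-end;
* sympatry effects (`effect_config()`): additive count shift and placement
  displacement for sympatric populations, both **zero by default** — the
  null world matching the study's finding of no RCD.

What the generator does *not* emulate: the spacing regularity of real
sensilla fields (Gaussian mixtures produce somewhat smaller
nearest-neighbor distances than the published ≈ 19 µm at equal density —
real fields look inhibited, like a hard-core process), any within-female
left–right asymmetry structure beyond noise, three-dimensional plate
curvature, and collection-year or preservation effects. A green test
therefore establishes that the *pipeline* behaves correctly under a
plausible data regime, not that the generator is a generative model of real
plates. The true within-female spatial dependence is unknown; the mixture
is a modeling choice.

Per-population seeds derive from the master seed and the population label
by a rolling hash, so any subset of populations regenerates identically in
isolation; every stochastic operation takes an explicit seed and the
pairwise table derives per-pair seeds from the master seed and the sorted
pair label.

## Numerical choices and degenerate inputs

* Polygon area/centroid: shoelace with absolute value, winding-invariant;
  collinear polygons are errors, not zeros.
* Convex hull: counterclockwise, lexicographically smallest vertex first,
  collinear boundary vertices pruned — byte-stable output.
* Boundary sensilla count as inside the plate (tolerance scaled to plate
  size).
* Duplicate sensilla give zero nearest-neighbor distances with a warning —
  a QC matter, not an error.
* Zero-sensilla coordinate files are errors: the study design guarantees
  sensilla, so an empty file indicates a digitization failure.
* Degenerate (sub-3-point) sensilla sets: count and NND kept, hull-based
  traits missing.
* The capacity count is exact up to $2^{53}$ and errors beyond rather than
  silently losing precision.

## Worked example

```{r example, eval = FALSE}
manifest <- table1_manifest()
study <- generate_study(manifest, seed = 1)
result <- run_pipeline(study$records, manifest,
                       run_config(min_n = 4, n_perm = 199, seed = 1))
result$log
#> [ingest] 206 plate records, 32 manifest populations
#> [ingest] mirrored 34 left plates
#> [qc] replicate correlations: sensilla_count 0.985, plate_area 1,
#>      abdomen_length 0.958
#> [traits] 103 females, 32 populations
#> [spatial] 15 population pairs tested, 0 significant at FDR 0.05
#> [shapes] 6 population mean shapes
```

Six *E. carunculatum* populations reach the four-female eligibility rule,
giving $\binom{6}{2} = 15$ pairwise KDE tests; with no planted sympatry
effect the FDR-adjusted table is null, as it should be.

## Known limitations

* The pairwise KDE table's exact adjusted p-values from the original study
  are not a reproduction target: they depend on archived specimen data and
  on the original tool's (undocumented) bandwidth selector and null; the
  package validates its test by calibration instead.
* Minimum-distance sliding is a simplification of bending-energy sliding;
  for display-quality mean outlines the arc-length landmarks with sliding
  off are recommended and are the default.
* The permutation test needs at least two (practically, four or more)
  females per population; single-female populations enter scalar-trait
  analyses only.
* Pure-R kernel sums are exact but quadratic in point count; pooled clouds
  beyond a few thousand points will be slow.
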