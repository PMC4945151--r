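---
title: "Quantifying astrocyte-process confinement at cortical borders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte-process confinement at cortical borders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Astrocyte processes in several mammalian cortices stop abruptly at
functional tissue borders — the septa between somatosensory barrels, the
rim of primary auditory cortex, the IIIa/IIIb sublaminar border and the
blob/inter-blob mosaic of primate V1 — while blood capillaries cross the
same borders freely. The field's standard way to quantify this is
line-intercept stereology on traced drawings: straight test lines are
superimposed on the border (or at controlled offsets from it) and on
matched interior positions, the fiber crossings of each line are counted,
and confinement is read off the border-to-interior crossing ratio, density
profiles across the border, and the associated two-sample statistics.

`astroborder` re-implements that entire measurement chain as a reusable,
tested pipeline, and pairs it with a synthetic generator of
boundary-confined fiber morphologies so every step can be validated against
known ground truth. Raw traced drawings from the original experiments are
not available; the generator is therefore a first-class component, not a
test fixture.

## The generative model

**Region maps.** Labeled planar partitions in micrometres (x right, y up):
a rows-by-arcs barrel mosaic (cores surrounded by septa inside a background
margin), a disc in a surround (A1 in A2), a laminar strip with a straight
border at y = 0 (IIIa above, IIIb below), and a periodic ellipse mosaic
(blobs at a 1 mm period). All placement and counting happen in vector
space; rasterization is an optional export.

**Astrocyte arbors.** Somata follow a homogeneous Poisson point process
with a per-class intensity. Each soma emits `Poisson(5)` branches; a branch
is a persistent random walk with 5 um steps, Gaussian turning (sd 0.3 rad)
and exponentially distributed total length (mean 60 um). These morphometric
defaults are free parameters: no published morphometry constrains them for
this analysis, so they were chosen once as plausible for protoplasmic
astrocytes (arbor diameter on the order of 100 um) and are all exposed in
`generator_config()`. When a step changes region class it attempts a border
crossing that succeeds with probability `p_cross`; on failure the branch is
truncated exactly at the border and terminates — termination, not
reflection, is the simplest mechanism consistent with processes that
"stop" at borders. Implementation detail: walks are generated unconfined
and truncated post hoc at their first failed crossing draw, which is
distributionally identical to step-level rejection and vectorizes well. A
double border crossing within a single 5 um step (possible only at slivers
or corners far narrower than any generated septum) would be seen as one
class change; none of the generated layouts can produce it along
measurement lines.

**Capillaries.** An isotropic Poisson process of short straight segments
(default 25 um), midpoint-sampled, never clipped at class borders. For a
homogeneous density this is the classical "fibers ignore borders" null.

**Section thickness.** Cutting thinner sections is modeled as i.i.d.
whole-polyline retention (probability `retention`), because the published
comparison constrains only two facts — a ~35% count reduction at 4 um vs
8 um and an unchanged septa/core ratio — and both follow from any
per-fiber thinning; full 3-D growth and slicing would add unidentifiable
parameters.

## The stereological identity and calibration

For isotropic fibers of length density $\rho$ (um/um$^2$), a straight test
line of length $L$ is crossed on average
$$\mathbb{E}[\text{crossings}] = \frac{2 L \rho}{\pi},$$
so a published group mean $m$ inverts to $\rho = \pi m / (2L)$
(`calibrate_generator()`). For the capillary process the identity is exact
and calibration is purely analytic. Confined arbors lose fiber length to
border truncation (strongly so inside 50 um septa), so their per-class soma
intensity is rescaled by a pilot run of the full
scene → place → count chain: expected crossings are exactly linear in soma
intensity, making one linear correction sufficient. A border-confinement
strength can also be solved from a septal-line target by bisection
(`calibrate_p_cross()`), since the septal mean is monotone in `p_cross`.

Each experiment preset calibrates each region class to its published
50-um-offset (or center-line) group mean with `p_cross = 0`, which
decouples the classes. The published means at 200 um offsets differ only
insignificantly from the 50 um ones and cannot be matched simultaneously by
a single class density; the 50 um constants are the calibration anchors.

**A limitation worth knowing.** Termination at borders creates a density
depletion halo roughly one branch length (~60 um) wide on each side of a
border. Lines at 50 um offsets sit inside this halo, lines at 200 um
outside it, so the synthetic 50-vs-200 um within-region comparison shows a
gradient where the published data show none. The halo width is set by the
free branch-length parameter, not by anything the crossing data constrain.
Green calibration-recovery tests therefore establish that the measurement
chain is unbiased and correctly calibrated — not that the generator's
spatial correlation structure matches real astrocyte tissue.

## Measurement constructs

* **Septal/core line matrices** (`place_septal_and_core_lines()`): one
  375 um line per inter-barrel border, centered on the septum centerline
  (the midline between the two facing core edges — the published
  procedure says only "center of the barrel border") at its arclength
  midpoint, oriented along the border; a paired core line of identical
  length and orientation at the first adjacent core's centroid. Only
  barrels with spans in the 350-450 um selection window qualify, and a
  septum shorter than the line is skipped and logged.
* **Offset lines** (`place_offset_lines()`): at arclength stations along a
  border, lines parallel to the footprint-averaged local tangent at each
  offset on both sides (50 um lines at 50/200 um for the disc border;
  375 um lines for the laminar border). "Border orientation" is the
  tangent averaged over the line's footprint, which is robust to vertex
  noise. Stations are half-open and tie-break toward the lower arclength,
  so line sets are exactly reproducible.
* **Blob lines** (`place_blob_lines()`): 500 um vertical lines at blob
  centers, inter-blob centers, and each blob's right edge plus a
  configurable margin gap (default 50 um) for the "left margin of the
  inter-blob" — the published construction does not state that distance.
* **Density bands** (`place_density_bands()`): `count` rectangles (10 by
  default; 25 x 100 um rodent preset, 30 um wide human preset) centered on
  the border, axes perpendicular to the local tangent, evenly spaced. The
  human band length is not published; 100 um is used so the two presets
  share their profile windows.
* **Landmark alignment** (`estimate_landmark_transform()`): closed-form 2-D
  least-squares rigid (optionally similarity) fit to matched
  penetrating-arteriole points; the published workflow aligned drawings by
  such landmarks but never states whether scale was allowed, so rigid is
  the default and scale is a flag. Layers III/V re-use the layer-IV line
  matrix after this alignment rather than extracting their own (blurrier)
  borders.

## Counting rules and numerical choices

* Crossings are transversal intersections between the open measurement
  segment and polyline edges under a side-change rule: an edge counts iff
  its endpoints lie on opposite sides of the line's carrier (points
  exactly on the carrier are assigned to the positive half-plane) and the
  intersection parameter is strictly inside the open segment. Each
  geometric crossing — including one through a shared polyline vertex —
  counts exactly once, reproducibly, even on degenerate synthetic
  geometry. A branch crossing a line twice counts twice ("branch
  crossings", not branches); per-curve deduplication is available but off
  by default.
* Density profiles assign each 1 um slab of a band the fiber arclength
  clipped to it divided by slab area; positions are anchored at the border
  (0) with the inner side negative. The profile conserves total clipped
  length to numerical precision.
* `percent_drop()` uses windows of -50..-10 um (inner) and +10..+50 um
  (outer), excluding a +-10 um transition zone; the published drops do not
  state their windows. Note the published density drops (37%, 66%) and the
  drops implied by the crossing means (~47%, ~51%) are not interchangeable
  measures.
* The septa/core ratio defaults to the per-scene ratio of means; the mean
  of per-pair ratios (zero-denominator pairs excluded and logged) is the
  config-selectable secondary definition, since the published histograms do
  not state which was used. For null checks ("ratio = 1") the pooled
  ratio of grand means is used instead: with only a few lines per scene,
  the per-scene estimator has an upward Jensen bias of order the squared
  coefficient of variation of the denominator (~+6% on 2 x 2 maps).
* Statistics: pooled-variance Student's t (the published dfs equal
  n1 + n2 - 2, ruling out Welch), one-way ANOVA on natural-log ratios with
  Tukey HSD (base-invariant; natural log documented for reproducibility),
  Pearson correlation, and group summaries with t-based 95% CIs. The
  published t, Cohen's d and CI values are not recoverable from the
  published means, s.e.m.s and ns by these standard formulas; the package
  implements the standard formulas and validates significance through a
  power property instead (below).

## The confinement sweep: why two soma configurations

Two published idealizations conflict under any single configuration: a
septa/core ratio of ~0 at `p_cross = 0` requires septal soma intensity 0
(otherwise septum-resident fibers keep the ratio near 0.2), while a ratio
of exactly 1 at `p_cross = 1` requires a stationary (uniform-intensity)
field — with core-only somata the septum sits in a missing-source deficit
of roughly $2w/(\pi R)$ for septum width $w$ and branch reach $R$, i.e.
tens of percent. `sweep_confinement()` therefore defaults to
`mode = "core_only"` (exact 0 at p = 0, monotone non-decreasing ratio) and
provides `mode = "uniform"` for the exchangeable p = 1 null.

## Seeds, determinism, and scales

Every component draws from a named stream derived from one root seed
(`derive_seed()`), so adding a component never perturbs the others, and a
re-run with the same seed and configuration is bit-for-bit identical down
to the serialized GeoJSON. Scene counts per preset were fixed a priori by
a design-stage noise budget: the acceptance rule equates a 5% tolerance
with ~3 standard errors, so scene counts were chosen to push each
measured grand mean's total standard error (pilot and measurement phases
combined, using measured overdispersion of 2-3 relative to Poisson) to
about 1.2-1.7%, within a runtime budget of under three minutes per preset
on one CPU. They were not adjusted after comparing against the targets.

## What the synthetic world does and does not establish

The generator reproduces the statistical structure the measurements
assume: per-class isotropic fiber density, hard border confinement,
unconfined capillaries, landmark-aligned frames, and binomial section
thinning. It does not emulate staining variability, tracing error,
arbor-arbor repulsion (domain tiling), anisotropy near vessels, or real
border curvature beyond the four layouts. Green tests therefore validate
the measurement and statistics chain and the calibration identities — they
are not evidence about biology, and the published group means enter only
as calibration constants.

## Known limitations

* The depletion-halo artifact described above.
* Multi-page TIFF export is replaced by plain-text PGM pages
  (`write_raster_pgm()`); no TIFF writer exists in the supported stack.
* Imported real data must arrive as vector curves plus labeled region
  polygons (GeoJSON); segmentation of raster micrographs is out of scope.
* `extract_borders()` matches exactly shared polygon edges; imported maps
  with mismatched shared vertices would need snapping upstream.
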