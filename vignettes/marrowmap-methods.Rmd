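---
title: "Quantifying the spatial anatomy of haematopoiesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial anatomy of haematopoiesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowmap)
```

marrowmap quantifies where blood is made. Its inputs are tables of
segmented cells exported from whole-mount bone-marrow imaging — one row per
cell with a stage label, a 3D centroid in µm and a radius — together with a
capsule description of the sinusoidal and arteriolar vasculature. From
these it measures the spatial organisation of haematopoiesis: how far
stem and progenitor cells sit from each other and from vessels, whether
those distances differ from random expectation, and where the discrete
"production sites" are that turn committed progenitors into mature blood
cells. This vignette documents the models, the parameters that matter, the
synthetic tissue used for validation, and the numerical choices.

## Radius-corrected distances

All distances are surface-to-surface *gaps* in 3D. For two cells with
centres $c_a, c_b$ and radii $r_a, r_b$,

$$ g(a,b) \;=\; \lVert c_a - c_b \rVert \;-\; r_a \;-\; r_b, $$

and for a cell against a vessel modelled as a capsule (polyline $P$ with
radius $R$),

$$ g(a, V) \;=\; \min_{p \in P} \lVert c_a - p \rVert \;-\; R \;-\; r_a. $$

Subtracting *both* participating radii makes $g \le 0$ mean physical
contact, which is what the biology cares about (a CFU-E "decorating" a
sinusoid touches it). Where a segmented record carries no measured radius,
the catalogue mean radius for its type is substituted
(`cell_type_catalog()` holds the 22 imaging-measured mean diameters, from
the 8.67 µm CD41^−^ LT-HSC to the 4.38 µm erythrocyte). Negative gaps are
reported unclamped — interpenetration of segmented spheres is real signal
about packing, not an error. *Direct contact* is defined as
$g \le 0.5\,$µm rather than $g \le 0$: segmentation jitter makes exact
zero brittle, and 0.5 µm is far below a cell radius, so the classifier is
insensitive to the choice over any plausible range.

Nearest-neighbour queries run either as dense all-pairs scans or through a
uniform-grid spatial index; the two paths are required (and tested) to
agree exactly, with the grid's ring-expansion bound widened by the target
radius spread so that varying radii cannot break exactness.

## The empirical random-placement null

Whether a cell type is *enriched* near a structure is judged against an
empirical null, not a parametric one: pseudo-cells are drawn from the
positions of **all** segmented haematopoietic cells in the window (tens of
thousands per 35-µm slice), at the same per-type counts as observed,
without replacement within a replicate, and pushed through exactly the
same distance code path as the observed cells. The default is 150
replicates (configurable; 100–200 is customary). This null inherits every
large-scale inhomogeneity of the real cell field — marrow boundaries,
vessel volume exclusion, local density gradients — which a uniform-space
null would miss.

The observed distances are pooled and compared against the pooled null
distances. Pooling (rather than a median-of-medians across replicates)
matches how per-cell distance dot plots are usually compared; the
per-replicate medians are retained in the `null_distribution` object for
diagnostics. The comparison dispatches through the normality-gated rule
below; a call is *enriched* when $p \le \alpha$ and the observed median is
below the null median, *depleted* in the opposite direction. Under
exchangeable inputs the false-call rate sits at the nominal $\alpha$
(checked by simulation at $\alpha = 0.05$ over 100 runs).

## Confetti clonality

The four-colour Confetti reporter labels a random ~7.3% of cells with one
of GFP/YFP/RFP/CFP; shared colour proxies shared clonal origin. Because
GFP shares its imaging channel with the dump stain, green cells are
discarded before any clonal analysis (`filter_dump_channel()`). A site is
*monoclonal* when ≥ 2 labelled non-green members all carry one colour,
*oligoclonal* at ≥ 2 colours, and *unlabelled* below two labelled members
— one labelled cell carries no clonal information, a threshold this
package sets explicitly since no published minimum exists.

Same-colour distance questions ("do daughter cells stay near their
labelled mother?") are tested by permuting the colours over the fixed
coordinates, preserving per-colour counts. The statistic is the median gap
from each labelled progeny cell to the nearest same-colour focal cell. The
p-value is the two-sided permutation rank with the add-one correction; for
≤ 8 cells with few distinct arrangements the null is enumerated
exhaustively and the p-value is exact.

## Production-site detection

The detectors codify the anatomical definitions of the four lineage
sites:

* **Erythroid** — CFU-E in direct sinusoid contact are linked
  single-linkage under a `string_link_gap_um` of 10 µm (about one CFU-E
  diameter; the linkage distance is a package default, chosen because
  published strings are contiguous, touching chains of cells).
  Linkage is constrained to one connected sinusoid chain; a cell touching
  two crossing chains belongs to both for linkage purposes, which prevents
  a grazing contact from splitting a genuine string. Components of ≥ 3
  cells are strings. Erythroblasts, reticulocytes and erythrocytes within
  50 µm of a string member (50 µm being the median distance expected for
  random cells) are attached to their nearest string, ties broken toward
  the lowest string id. Late erythroblasts are further decomposed into
  clusters by single linkage at 10 µm.
* **B lymphoid** — every CLP seeds a candidate site; pre-pro B, pro B and
  pre B cells within 150 µm attach to their nearest CLP. Arteriole
  proximity is reported as an attribute of the site, never used as a
  filter, so atypical CLPs remain visible.
* **Neutrophil and mono/DC** — a focal progenitor (GP or MDP) in direct
  sinusoid contact, plus immature progeny (PN; monocytes and cDC) within
  50 µm, nearest-assigned. Progenitors without sinusoid contact are
  reported as unanchored rather than silently promoted to sites. The
  per-site cDC fraction of progeny is reported as the fate ratio. These
  myeloid rules condense the published description (focal progenitor with
  clustered progeny on a dedicated sinusoid); the thresholds sit in
  `site_params()` so they can be re-tuned if more detailed definitions
  become available.

Site densities are counts per mm² of the x–y-projected marrow area — the
natural normalisation for a thin optical slab.

## Statistical procedures

Two-sample comparisons dispatch on normality: Student's t (two-tailed,
unpaired) when both samples pass Shapiro–Wilk at $\alpha = 0.05$,
Mann–Whitney otherwise. The Shapiro gate is this package's concrete
choice of normality check; samples beyond the test's 5000-observation
limit are screened on an evenly spaced order-statistic subsample, and
constant samples are routed to the rank test. Two proportions are
compared by Pearson chi-square on the 2×2 table with Yates continuity
correction (df = 1); the correction is the default because it reproduces
the published transplant-homing comparison (4/5 vs 1/73 detected,
$p = 1.96 \times 10^{-9}$) at its printed precision, and an uncorrected
mode is available. The marker screen selects imaging-compatible surface
markers: uniformly expressed (≥ 90% of events above background) at ≥ 10³
absolute fluorescence over background in at least one HSPC type, and
absent (≤ 10%) from at least one other; the 90/10 fractions are package
defaults for "uniform" and "absent", which the source describes only
qualitatively.

## The synthetic marrow generator

Real raw images are microscope-native and out of scope, so validation
runs on synthetic scenes with known ground truth. `simulate_marrow()`
emulates one 35-µm optical slice of sternal marrow as an axis-aligned
slab (default 2400 × 1200 × 35 µm, ≈ 2.9 mm², with the bone-facing
planes at the y-extremes standing in for endosteum):

* **Vessels** as capsules: 40 tortuous sinusoids (radius 10 µm) and 12
  longer, straighter arterioles (radius 5 µm), confined so the whole
  capsule stays inside the slab; a quarter of sinusoids sprout a child
  segment, giving branch points where two or more lumens connect.
* **Background pool**: 60,000 unclassified haematopoietic cells placed as
  complete spatial randomness (CSR) over the mask — within the observed
  48,964–81,248 cells per slice. On real data the null resamples real
  segmented positions; CSR is the neutral synthetic stand-in, and it is
  still the pool *positions* that the null draws from, so the procedure
  is unchanged.
* **HSPCs**: soft-core sequential rejection sampling — a hard core at
  half the 100-µm repulsion scale, exponential soft penalty to the full
  scale — biased toward megakaryocyte surfaces and away from arterioles.
  The mechanism is invented (only the observed dispersion is published);
  it is the simplest process reproducing single cells with > 100 µm
  median spacing. With all weights and the repulsion at zero the process
  provably reduces to CSR, which is what the calibration tests exploit.
  Default counts per scene (7 LT-HSC, 10 ST-HSC, 4 MPP2, 8 MPP3) follow
  the published per-segment densities.
* **pre CFU-E** are placed as a contact mixture: 60% seated directly on a
  sinusoid surface, the rest at > 5 µm clearance from all vessels,
  matching the published contact fraction. The default of 30 per scene
  overrepresents their physiological abundance to give the contact
  estimate a stable denominator.
* **Erythroid sites**: string sizes are drawn from a discretised gamma
  clipped to [3, 23] with mean 8 and sd 4 (the published range and mean;
  the gamma is this package's choice of shape). Members are laid
  touching along one sinusoid chain with the radial direction
  parallel-transported through bends, and the generator verifies
  contiguity (consecutive surface gaps ≤ 8 µm) and ≥ 30 µm clearance
  from other strings, retrying the span otherwise — distinct anatomical
  structures do not interpenetrate. Each site buds two small
  early-erythroblast clusters and one late-erythroblast cluster
  (sizes gamma-clipped to [19, 96], mean 40, sd 12 — the published range
  and mean; the ±4 printed with that mean is its s.e.m., so the spread
  is a package choice), plus reticulocytes and erythrocytes within
  50 µm.
* **B sites**: CLPs on or near arteriole surfaces, ≥ 320 µm apart so that
  150-µm capture zones cannot contest cells; per-stage counts are drawn
  from discretised normals at the published 2 ± 1 pre-pro B, 3 ± 2 pro B
  and 16 ± 8 pre B, placed at stage-increasing distances within 150 µm.
* **Myeloid sites**: GP (neutrophil) or MDP (mono/DC) on distinct
  sinusoid chains with progeny within 50 µm. No two lineages share an
  anchor chain.
* **Confetti**: clone structure first, then independent Bernoulli(0.073)
  labelling; a labelled cell shows its clone's colour. Strings, B sites
  and myeloid sites draw members from ≥ 2 clones; each erythroblast
  cluster inherits a single string clone. Structure clones carry
  *distinct non-green* colours: green is unreadable by design (dump
  channel), and a ground truth that cannot in principle be recovered
  would make recovery tests meaningless. Background cells are singleton
  clones over the full four-colour set, so the overall labelled fraction
  and colour mix stay faithful.

Presets (`steady_state`, `phlebotomy_d2`, `gcsf_sternum`, `gcsf_tibia`,
`aged`) encode the anatomical endpoints of the modelled conditions by
changing site counts and compositions only — they are endpoints, not
mechanistic stress models.

### What passing tests do and do not show

The generator reproduces the *statistical geometry* the analysis assumes:
counts, sizes, spacings, contact relations, clone structure. It does not
model segmentation error beyond sub-µm surface jitter, anisotropic optics,
partial cells at slab boundaries, vessel calibre variation along a
segment, or differentiation kinetics. Recovery of planted parameters
therefore validates the *detectors and statistics*, not the biology of any
particular tissue; on real exports the capture radii and linkage gaps in
`site_params()` are the knobs to revisit first.

## Numerical choices and degenerate inputs

* Determinism: one seed fully determines a scene; the pipeline folds its
  run seed into each stage.
* Ties in nearest-assignment break toward the lowest site id, making
  partitions reproducible.
* Zero-length vessel polylines are skipped with a warning in
  morphometry; an empty requested network is valid and flagged.
* Fewer than 3 observed distances yields an `insufficient-data` result,
  not an exception; a single Confetti colour yields a `no-test` result.
* Daughter-track interpolation is linear and only across adjacent frames
  (≤ 1 frame interval); larger gaps raise a missing-data error rather
  than guessing. Separation uses the strict > 50 µm rule.
* Permutation p-values use the add-one convention except in exhaustive
  mode, where they are exact.

## Validation problem sizes

The shipped validation uses 20 seeded default scenes (~61,000 cells each)
for parameter recovery — string sizes, cluster sizes, B-site composition,
contact fraction, HSPC dispersion — 100 exchangeable runs for null
calibration, ≤ 6-cell toys for exhaustive permutation checks, and
1,000-cell scenes for index-vs-brute-force equality. These sizes hold the
Monte-Carlo error of every recovered quantity well inside its acceptance
band while keeping a full validation run in minutes on one core.

## Known limitations

* The slab-with-planar-endosteum idealisation has no published geometry
  behind it beyond the 35-µm window; curvature of the real endosteal
  surface is not represented.
* Myeloid site definitions condense a one-sentence published description;
  the formal supplementary definitions were not available when these
  defaults were fixed.
* "Oligoclonal" has no published quantitative definition; the ≥ 2-colour
  rule is explicit and adjustable.
* The pipeline treats one scene at a time; it does not track sites across
  time points or infer stress states from single snapshots.
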