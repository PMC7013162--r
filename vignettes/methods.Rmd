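---
title: "Methods: seed tomography, germination kinetics and seedling elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed tomography, germination kinetics and seedling elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedphenom)
```

`seedphenom` models a three-assay seed phenotyping platform for sugar
beet: X-ray microtomography of dry seeds, multi-camera germination
time courses at three temperatures, and time-lapse seedling elongation
under green (inactinic) light. Every assay has a synthetic generator
with exact ground truth, so the complete measurement chain can be
validated numerically without scanner or camera hardware. This
vignette explains the underlying models, the main parameters (with
units and defaults), and the numerical choices.

## 1. The seed model and the tomography generator

A sugar beet seed is modelled as four compartments:

* **seed coat** (pericarp): an ellipsoidal shell, default outer
  semi-axes 1.8 × 1.7 × 1.4 mm, thickness 0.2 mm;
* **perisperm**: the central nutrient storage body, an ellipsoid of
  semi-axes 0.8 × 0.7 × 0.55 mm;
* **embryo**: the ring-shaped embryonic plant encircling the
  perisperm, a partial torus (ring radius 1.1 mm, tube radius 0.2 mm,
  85% of a full turn);
* **internal cavity**: a small empty space inside the coat (radius
  0.2 mm), dark in the scan.

Each class renders at a constant gray level (background 20, embryo
120, perisperm 160, coat 210, cavity 50 on a 0–255 scale) plus
clipped Gaussian noise (default SD 5). The defaults put the smallest
class gap (embryo vs perisperm) at 30 gray levels, i.e. six noise
SDs — a contrast regime in which watershed segmentation is expected to
reach Dice ≥ 0.90 per class. `validate_phantom_spec()` rejects
geometrically impossible specs and class gaps under three noise SDs.

```{r phantom}
spec <- phantom_spec()
ph <- make_seed_phantom(spec, rng_seed = 1)
ph$tomogram
table(ph$labeling$labels)
```

A scan (`make_scan()`) places 25 jittered, rotated copies on a grid
at 0.1 mm voxel spacing — coarser than the single-seed default
(0.05 mm), as one volume must hold the whole tray — with a guaranteed
minimum surface-to-surface gap (0.5 mm) so that connected components
individualize seeds correctly. Truth tables record per-seed voxel
tallies directly from the rendered labels.

## 2. Segmentation chain

The chain mirrors an automated tomography protocol:

1. **Denoise** (`denoise()`): cube median filter (radius 1) or
   renormalized Gaussian.
2. **Mask** (`threshold_mask()`): the foreground mask is strictly
   `I > tau`; `tau = "auto"` uses Otsu's bimodal split. The cavity
   (gray 50) falls below `tau` and is deliberately *not* foreground.
3. **Individualize** (`individualize_seeds()`): 26-connectivity
   connected components; speck components under 10% of the median
   component volume are discarded; a count differing from the expected
   25 warns rather than errors.
4. **Compartments** (`segment_components()`): per seed instance, the
   enclosed cavity is recovered as a hole of the foreground (the
   complement is examined with 6-connectivity, the topological dual of
   the 26-connected foreground); intensity bands for embryo, perisperm
   and coat come from an exhaustive three-class Otsu on the solid
   foreground; markers are obtained by eroding each band until it
   shrinks below half its size; a marker-controlled watershed then
   floods the gradient-magnitude relief.

One refinement matters numerically. A pure gradient relief is
*symmetric* across a two-class interface, so the final one-voxel
interface shell is decided by flooding order, not by data; even at
zero noise roughly 1–2% of voxels end up mislabeled. The flooding
priority therefore adds a gray-level affinity term,
`|I(v) − mean(band)|`, with weight 1 by default
(`segment_config(affinity_weight = 0)` restores the plain watershed).
With piecewise-constant data the resulting partition is exact, which
the test suite asserts voxel-for-voxel.

```{r segment}
inst <- structure(
  list(intensities = ph$tomogram$intensities,
       mask = threshold_mask(denoise(ph$tomogram))$mask,
       offset = c(0L, 0L, 0L), seed_index = 1L,
       spacing = ph$labeling$spacing),
  class = "seed_instance")
seg <- segment_components(inst)
sapply(c(1, 2, 3), function(cl)
  dice_coefficient(seg$labels == cl, ph$labeling$labels == cl))
```

## 3. Morphometry

Per compartment, `compute_features()` reports volume (voxel count ×
voxel volume), surface area, the dimensionless 3D shape factor
`VA3d = A³/(36πV²)` (1 for a sphere, larger otherwise), the
volume-equivalent spherical diameter `(6V/π)^(1/3)`, and the filling
factor (compartment volume over the filled whole-seed envelope).

Surface area uses a triangulated 0.5-isosurface computed by *marching
tetrahedra* on a Gaussian-smoothed (σ = 1 voxel) binary indicator.
Smoothing first removes the voxelization staircase: counting exposed
voxel faces (`method = "voxel_faces"`, kept as an oracle) overestimates
a smooth sphere's area by ~50%, while the smoothed isosurface
reproduces it to well under 2% at a 25-voxel radius. Marching
tetrahedra was chosen over classic marching cubes because the
six-tetrahedra decomposition needs no case lookup tables and has no
ambiguous configurations. All features are exactly scale-equivariant
in the voxel spacing. `qc_filter()` drops empty (no embryo) and
malformed seeds (shape factor outside [0.9, 8], filling factor outside
[0, 1], compartment volume outside median ± 3 scaled MADs) before
`summarize_features()` builds genotype means and SDs.

## 4. Germination kinetics

Germination assays run at 5, 10 and 20 °C with protocols fixed by
`germ_protocol()`: final counts after 28, 15 and 6 days respectively,
an extra early count after 17 days at 5 °C, and images every 4 h at
5 °C / 2 h otherwise. The generator draws per-seed germination times
from a lognormal (median ≈ 120 h at 10 °C by default), with a
non-germinating fraction (default 5%). In image mode, a germinated
seed shows a small displacement (2 px) and a radicle outgrowth
(1 px/h, capped at 12 px — the generator emulates the protrusion phase
the detector keys on; uncapped radicles would grow into neighbouring
seeds' regions, which belongs to the elongation assay).

`detect_events()` calls germination at the first frame where the
seed's centroid moves ≥ 2 px or a new outgrowth beyond the dilated
day-0 contour reaches ≥ 5 px; seeds that never trigger are censored at
the last frame, and a median per-seed displacement above 5 px aborts
with a camera-motion error. Statistics are closed-form:

* **MGT** `= Σnᵢtᵢ/Σnᵢ` over germinated seeds only;
* **T50/T70**: linear interpolation on the cumulative curve, which is
  built over the *sown* population (`n_total`), so a genotype that
  never reaches 50% gets `NA` ("not reached") rather than a
  renormalized value;
* **rates**: percentage of sown seeds germinated by a cutoff.

```{r kinetics}
mgt(tibble::tibble(time_h = c(24, 48), n = c(10, 10)))
curve <- build_curve(tibble::tibble(time_h = c(rep(100, 4), rep(120, 2)), n = 1),
                     n_total = 10, grid = c(100, 120))
time_to_percent(curve, 0.5)
```

## 5. Seedling elongation

Boxes of 10 seeds grow in darkness under green LEDs, imaged in
backlight at 9 px/mm every 4 h for three weeks; radicles grow downward
and shoots upward, inclined ~10° from vertical. All signal lives in the
green channel (`green_channel()`); objects are dark on a bright field.

`detect_hgerm()` finds each seed's germination hour (first frame with
a visible ≥ 5 px outgrowth). `measure_lengths()` splits the seedling
mask at the dilated seed body and classifies each organ part by its
net vertical direction (gravitropism): downward parts are radicle,
upward parts shoot. Organ length is the geodesic path length of the
part — breadth-first search from the body outward, walk-back from the
deepest pixel — with the path resampled every 8 px before summing
Euclidean segments; naive chain-code summation would overestimate an
inclined 1-px line by several percent (staircase effect). Per-seed
regions are full-height lanes cut midway between seed centers, since
organs traverse the whole image height. Length series are clipped
non-decreasing, and **RadLg** is read 168 h (seven days) after each
seed's *own* Hgerm by linear interpolation between the bracketing
frames; the offset is configurable.

```{r radlg}
sim <- make_elongation_series(elongation_sim_spec(
  n_seeds = 1, germination_times = 100, radicle_rate = 0.25,
  shoot_rate = 0.12, duration = 400))
radlg_at_offset(sim$tracks[[1]], offset = 168)
```

## 6. The phenotype table

`assemble_table()` joins the three assays into one row per genotype
with exactly 28 ontology-coded variables (`phenotype_schema()`):
13 tomograph variables — seed mass is *ingested* balance data, as no
imaging stage can produce mass — 13 germination variables across the
three temperatures, and 2 elongation variables. Headers are
normalized to ASCII (`MGT_5C[CO_333:1000311]`) so they are
byte-identical across platforms; codes are kept verbatim, including
the shared codes (T50 and T70 both CO_333:1000330). Missing assays
leave `NA` cells and a sidecar reason table; rows are never silently
dropped, and duplicate genotype ids error.

`run_pipeline()` drives the full experiment. `detail = "summary"`
computes morphometry from the generators' analytic geometry (volumes
scale as the cube, areas as the square of the per-seed size factor)
while running the real QC, summary, kinetics and elongation code, so
the full 202-genotype table builds in seconds; `detail = "imaging"`
runs the complete voxel and frame chains and is meant for small
rosters. Structured logs record the thresholds actually used.

```{r pipeline}
res <- run_pipeline(experiment_config(genotypes = c("demo1", "demo2"),
                                      seeds_per_scan = 4,
                                      germ_seeds_per_temp = 10,
                                      elong_seeds = 3, rng_seed = 1),
                    detail = "summary")
dim(res$table)
res$table[, 1:4]
```

## Problem sizes and runtime

The package's own reference problem sizes: one 25-seed scan of about
230 × 230 × 46 voxels generates and individualizes in a few seconds; a
full 202-genotype summary run takes tens of seconds; single-phantom
segmentation (~80³ voxels) runs in about a second. These sizes keep
the whole validation suite desk-scale while still exercising every
code path at realistic resolutions.
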