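---
title: "Methods: simulating ITV delineation strategies across motion ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating ITV delineation strategies across motion ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package studies how the choice of internal-target-volume (ITV)
delineation strategy interacts with the *range* of respiratory tumor motion.
Everything is computed on a digital stand-in for a commercial respiratory
motion phantom: a sphere of radius 1.5 cm (intensity 0, CT-number-like)
embedded in a uniform low-density medium (intensity −700), translating
sinusoidally along the superior–inferior (SI) axis,

$$ z(t) = A \cos\!\left(\tfrac{2\pi t}{T}\right), $$

with amplitude $A$ (half the peak-to-peak range) and period $T = 4$ s
(15 cycles per minute). Time $t = 0$ is maximum inhale. Only the
lung–target contrast matters; segmentation is threshold-relative.

Five planning target volumes (PTVs) are built per motion range:

| strategy | ITV construction | margin |
|---|---|---|
| GS | union of GTVs segmented on all 10 phase images | 5 mm isotropic |
| FB | GTV segmented on the free-breathing scan | 5 mm axial, 10 mm SI |
| FB-Aug | FB GTV ∪ phase-0% GTV ∪ phase-50% GTV | 5 mm isotropic |
| AIP | GTV segmented on the voxelwise phase average | 5 mm isotropic |
| MIP | GTV segmented on the voxelwise phase maximum | 5 mm isotropic |

Each alternative is compared to GS with the PTV ratio
$R_x = \mathrm{PTV}_x / \mathrm{PTV}_{GS}$ and the Dice similarity
coefficient; for pure SI motion the continuum ITV is a capsule
(spherocylinder), giving an analytic oracle
$V(r, L) = \tfrac{4}{3}\pi r^3 + \pi r^2 L$ with $L = 2A$, against which
the voxel pipeline is validated (within 5% at default resolution).

## Acquisition models

**Phase-sorted 4DCT.** The respiratory cycle is divided into ten uniform
bins centred on the labels 0%, 10%, …, 90%, with bin 0% centred on the
cosine maximum (maximum inhale) and bin 50% on maximum exhale. A real
phase-binned image integrates projection data across its bin, so each phase
image is the uniform time-average of 8 rasterized snapshots placed at the
midpoints of 8 equal sub-intervals of the bin (midpoint quadrature; bin
boundaries, shared by adjacent bins, are not double-counted). Residual
intra-bin motion therefore slightly elongates each phase target — the
phase-0% SI extent exceeds the 3.0 cm sphere diameter by less than the
within-bin excursion bound $A\,(1-\cos(\pi/10))$ — and slightly shortens
the recovered envelope relative to the full excursion (the 50%-duty edge
sits at $\approx 0.993A$ rather than $A$). A `"center"` integration mode
(single snapshot per bin) is available.

**Free-breathing helical scan.** Sequential slab acquisition: 2 cm axial
slabs (sixteen 1.25 mm slices), 0.5 s per slab, couch moving inferior to
superior. The slab at couch position $z$ holds the phantom state over the
time window in which that slab was acquired; by default each slab is the
uniform time-average of 8 snapshots across its window, emulating
reconstruction from projections collected during the tube rotation — this
is what dilutes the apparent density at the periphery of a fast-moving
target. A `"snapshot"` mode freezes each slab at its window start. The
scanner's true pitch and reconstruction parameters for the cohort are not
public, so all four knobs (slab thickness, slab time, direction,
integration) are explicit parameters; results involving FB are reported per
scan start phase and summarized across 8 uniformly spaced start phases.

**Projections.** MIP and AIP are voxelwise maximum and mean over the ten
*binned* phases, the standard clinical workflow. Projecting over all
pre-binning snapshots instead can capture a larger excursion at the price
of noise and blur; it is deliberately not the default and not implemented
as a separate mode — the binned-phase projection is the workflow being
evaluated.

## Numerical conventions

* **Segmentation** emulates single-observer manual contouring by a relative
  threshold at 50% of the lung→target contrast (boundary inclusive)
  followed by largest 6-connected component. A fixed relative threshold is
  reproducible where a human observer is not; the 50% level recovers the
  static sphere volume within 2% at default resolution. Empty segmentations
  warn and return an empty mask rather than failing.
* **Margin expansion** is morphological dilation with an ellipsoidal
  structuring element whose semi-axes are the margins in physical units —
  rounded corner behaviour, matching how treatment-planning systems grow
  contours, rather than a per-axis box. Whether clinical systems expand
  ellipsoidally or box-wise per axis is not documented; ellipsoidal growth
  is assumed because the analytic capsule oracle assumes rounded growth.
  By default the semi-axes are inflated by half a voxel per axis
  (`surface_correction = TRUE`): a binary mask undersamples the structure
  it represents (boundary voxel centres lie on average half a voxel inside
  the true surface), and the pure centre-to-centre convention additionally
  loses a thin lattice shell, a systematic 3–4% volume deficit at
  millimetre voxels. The corrected expansion tracks the analytic capsule
  PTV within +0.1% to +2.1% across the 1–4 cm sweep (a controlled sub-voxel
  overshoot, up to ≈5% for the isolated sphere-growth case); the
  uncorrected convention remains available.
* **Geometry.** Boolean and overlap operations require grids to agree
  within 10⁻⁶ cm; nothing is resampled implicitly. Voxel spacing defaults
  to 0.1 × 0.1 × 0.125 cm (z matching the 1.25 mm slice width); the grid is
  auto-sized to target + motion + 1.5 cm headroom.
* **Dice conventions.** Two empty masks give DSC = 1 (identical sets), one
  empty gives 0; used only in degenerate tests.
* **FB summary across start phases.** A single free-breathing scan has an
  unknowable start phase, so the sweep acquires 8 uniformly spaced ones.
  Their distribution is strongly skewed: at most start phases interplay
  *truncates* the target, but when the couch chases the ascending target
  (start phases near maximum exhale) the image *smears* it into a much
  larger volume — at the 4 cm range the FB PTV spans 27–84 cc over start
  phases. Time-averaged indicator imaging approximately conserves the
  expected imaged volume, so the start-phase *mean* hides the decline that
  a typical scan shows. The headline FB columns are therefore start-phase
  *medians* (the typical single-scan outcome, which declines monotonically
  with range: 43.9/43.5/43.0/40.8 cc); the means are reported alongside in
  `*_mean` columns.
* **Clinical summaries.** The cohort table ships as a validated CSV
  (17 patients, motion vectors 0.1–2.2 cm). Means are arithmetic; standard
  deviations are reported as sample (n−1) by default with the population
  variant available, since published tables rarely state the convention
  (the cohort's FB-Aug PTV-ratio spread matches the population convention,
  the others the sample convention). The ±10% PTV-ratio acceptance window
  uses inclusive bounds [0.90, 1.10] — the convention that reproduces all
  three published window percentages (14/17, 11/17, 7/17) simultaneously —
  and percentages are rounded to the nearest integer.

## What the phantom shows — and what it cannot

The generator reproduces the study conditions: fixed period, fixed
amplitude, rigid spherical target, one-dimensional SI motion, high
lung–target contrast. Under these conditions:

* the gold-standard PTV grows linearly with range and matches the capsule
  oracle;
* MIP segmentation at a common threshold recovers the union of the ten
  phase targets *exactly* (a voxel crosses the threshold in the maximum
  image iff it crosses it in some phase), so simulated MIP DSC is 1.0 and
  $R_{MIP} = 1.00$. The small MIP overshoot and DSC < 1 observed with
  human contouring are inter-image contouring variability, which a
  deterministic threshold cannot emulate;
* AIP at a 50% threshold keeps only voxels occupied half the cycle, which
  for sinusoidal dwell times approximates the static sphere and at large
  amplitude develops dumbbell-shaped level sets — so simulated AIP volumes
  are much smaller than clinically contoured AIP volumes (a human working
  on a lung window includes far fainter blur) and are *not* monotone in
  range. Clinical AIP behaviour is represented by the cohort table, not by
  the phantom;
* the free-breathing strategy degrades with range (median decline above)
  and is the least faithful strategy at the 4 cm range.

A "virtual patient" mode adds synchronous lateral/AP motion components and
per-cycle amplitude/period jitter, with the ground-truth motion recorded
both as the amplitude-vector norm and as the peak-to-peak motion vector
$M = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}$ (the quantity measured
clinically from centroid extrema).

Not modelled: tumor deformation, irregular patient-specific breathing
waveforms beyond Gaussian jitter, CT reconstruction physics
(projections/sinograms, scatter, noise), observer variability, nearby
structures of similar density, and dosimetry. Passing phantom tests
therefore demonstrates correctness of the geometry/acquisition/metrics
pipeline under idealized conditions, not clinical performance — the cohort
table carries the clinical evidence.

One cohort-level discrepancy is reported rather than resolved: the
published FB acceptance-window figure (34%) is not reproducible from the
published per-patient ratios under any natural boundary convention; the
package computes 4/17 ≈ 24% and reports that value.

## Problem sizes

Default experiments use the full study resolution (0.1 × 0.1 × 0.125 cm,
grids up to 61 × 61 × 81 voxels), ten bins × 8 snapshots, and 8 FB start
phases; the four-range sweep runs in well under two minutes on one CPU.
Unit tests exercise the same code paths on coarser grids (0.15–0.25 cm
voxels) where only topology or algebra, not sub-percent volumetric
accuracy, is being asserted.
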