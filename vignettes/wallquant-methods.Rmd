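---
title: "Methods: models, parameters and design choices in wallquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in wallquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallquant)
```

wallquant quantifies the cell-wall level of mCherry-tagged proteins in
budding yeast relative to a co-imaged reference strain, and provides the two
companion analyses such studies rely on: one-site saturation binding
(Kd/Bmax) and quantitative mating-efficiency statistics. This vignette is
the package's own account of how each piece works, which knobs matter, and
where genuinely open design choices were resolved.

## The ratiometric imaging workflow

Wall fluorescence in absolute camera units is not comparable between
acquisitions: illumination, exposure and focus drift. The workflow therefore
images every tester strain (cytosolic CFP) together with a reference strain
(cytosolic Citrin) in the same field, and reports the tester/reference ratio
of the per-cell statistic

$$\bar I_{\mathrm{wall}} \;=\; \frac{\sum_{p \in \mathrm{wall}} I_{\mathrm{mCherry}}(p)}{|\mathrm{wall}|}.$$

Processing order is: sum projection of the Z-stack, cell segmentation, wall
segmentation, measurement, interior-size filtering, identity assignment,
then the group comparison. Segmenting and measuring in the 2-D sum
projection (rather than in 3-D) follows the ordering of the workflow steps
themselves — summation comes first — and makes the published interior-size
window (2400–55,000 pixels) directly interpretable as projected pixel
counts. The core assumptions are that cells are well separated in the
field, that each cell carries exactly one cytosolic marker, and that the
projection's wall band is where the wall-anchored signal concentrates.

## Cell segmentation from cytosolic markers

The combined Citrin + CFP projection is cell-filled, but with two caveats:
the marker is excluded from the wall itself, and the projected cytosol
intensity tapers toward the rim (fewer optical sections intersect the
cytosol near the cell edge). A single global threshold would clip both.
`segment_cells()` therefore uses:

1. **Hysteresis thresholding.** Seed pixels above the Otsu threshold (256
   histogram bins over the image's own range, which makes the decision
   exactly invariant to a constant offset on all channels) are extended into
   every connected pixel above a lower cut placed at
   `median + hysteresis_fraction × (otsu − median)`. The image median is a
   robust background estimate while cells are sparse. The default
   `hysteresis_fraction = 0.1` keeps the lower cut far above realistic
   noise (tens of ADU in a 28-section sum) while recovering the tapering
   rim to sub-pixel accuracy on noiseless scenes.
2. **Cleanup.** Hole filling, removal of objects below `min_object_pixels`
   (default 100 — a speck filter, two orders of magnitude below the
   biological interior window), optional watershed splitting of touching
   cells on the Euclidean distance map (`watershed_tolerance`, default 1),
   and optional exclusion of border-touching cells (default on: their wall
   band would be truncated).
3. **Outward growth.** Each cytosol mask is grown by `wall_width` pixels
   (Euclidean criterion; contested pixels go to the nearest cell, ties to
   the lower label) to reconstruct the cell outline including the
   marker-free wall annulus. The growth radius includes a quarter-pixel
   allowance for the half-pixel offset between a discrete mask boundary and
   the continuous cell outline; on noiseless synthetic scenes this centers
   the recovered wall band on the true one (per-cell IoU ≥ 0.98, wall-mean
   recovery within 5%).

Labels are renumbered in raster order (top-left object first), so repeated
runs are bit-identical.

`wall_width` defaults to 3 pixels: at the ≈65 nm/pixel sampling of a 100×
objective on an sCMOS camera this is ≈200 nm, a plausible optical width for
the yeast cell wall. It is configurable (`segmentation:` block of the YAML
config), and the oracle suite passes for widths 2–5 when the generative
shell thickness matches.

`segment_wall()` defines the wall of each cell as the pixels whose
Euclidean distance to the nearest background pixel is at most `wall_width`
— a rotation-invariant erosion criterion, unlike a square structuring
element. Cells whose interior would be empty are flagged degenerate and
excluded from measurement rather than silently measured.

## Measurement, filtering, classification

`measure_cell()` computes exact min / max / integral of all three channels
over the wall and interior pixel sets, in double precision (a 16-bit,
28-section sum cannot overflow). Two published operating constants are
applied downstream, both exposed in `classification_params()`:

* **Interior window 2400–55,000 pixels**, read as a *closed* interval; the
  boundary cases (2399/2400 and 55,000/55,001) are pinned by tests.
* **Identity thresholds 200 ADU** on the *interior maxima* of the summed
  projection: reference iff Citrin > 200 and CFP < 200, tester for the
  mirror pattern, all else unclassified (kept in the table, excluded from
  statistics — exclusion is auditable). Equality falls in neither strict
  inequality, hence unclassified.

Two judgment calls deserve a note. First, the channel-to-identity mapping
follows the strain design (reference strain expresses Citrin, testers CFP);
a `swap_identity_channels` switch restores the opposite reading for users
whose convention differs. Second, a 200-ADU threshold on a summed
projection presupposes an essentially dark background: with a camera offset
of $o$ ADU per section, every summed pixel carries $o \times n_z$ (2800 for
the default 100 ADU × 28 sections), which exceeds 200 before any
fluorescence. On raw-offset data the thresholds must be raised by
$o \times n_z$, or the offset subtracted upstream; the classification test
scenes therefore run at offset 0, while segmentation and wall-measurement
scenes keep the default offset, which they tolerate by construction.

## Field statistics

`compare_strains()` reports group means ± s.d. of the per-cell means
("mean of the mean"), their ratio (arithmetic means, matching that
presentation), and a two-sided Mann–Whitney U test. The exact U
distribution is used when both groups have ≤ 20 tie-free observations, the
tie-corrected normal approximation with continuity correction otherwise;
both branches are available explicitly and agree to < 0.01 in p at
n = 20. Sidedness and tie handling are not dictated by the workflow's
published description; two-sided tests and midranks are the conservative
defaults. A warning (not an error) is raised below `min_n = 80` cells per
group, the customary minimum for this comparison. Welch's *t* (with
Welch–Satterthwaite degrees of freedom) and the star code
(* < 0.05, ** < 0.01, *** < 0.001, strict inequalities, "n.s." otherwise)
serve the replicate-level mating comparisons.

## One-site binding

Specific binding follows $B = B_{max} L / (K_d + L)$ on *total* ligand —
the standard free ≈ total approximation. Because protein (≈100 pmol) and
ligand (100–500 pmol) amounts can be comparable in these assays, a
depletion-corrected mode (`depletion = TRUE`) solves the mass-balance
quadratic for bound ligand instead. Nonspecific binding is handled as a
matched protein-free series subtracted point-wise (the default, mirroring
the experimental control), not co-fit.

Units: such assays report ligand in pmol but Kd in µM without always
stating the assay volume. The package deliberately fits in whatever
concentration unit the user declares and defaults to treating inputs as µM;
converting pmol to µM requires a volume the caller must supply.

Numerically, `fit_binding()` runs Levenberg–Marquardt on
$(\log K_d, \log B_{max})$: positivity is structural, conditioning is
better, and the spurious $K_d \to 0$ "constant model" corner that plain LM
can fall into on noisy low-concentration points is unreachable. A small
multi-start over $K_d$ (0.2×, 1×, 5× the median ligand concentration)
guards the remaining flat directions; the lowest-RSS convergent fit wins.
Standard errors come from the Gauss–Newton Hessian at the optimum, mapped
back by the delta method. Fits where the largest ligand concentration is
below the fitted Kd carry a `weak-saturation` flag: the plateau is then
extrapolated, not measured. Noiseless model data are recovered to ≤ 1e-6
relative error across Kd = 1–200 µM; at 5% replicate noise with 8 points
the median of 200 Monte-Carlo refits stays within 10% of the generative
value at all three anchor affinities (13.08, 111, 114 µM).

## Mating statistics

Efficiency is diploids / total per replicate; the summary reports the mean
and *sample* s.d. (n−1 denominator — the published "means ± s.d." leaves
this open), and the Welch test is applied to replicate-level efficiencies,
matching how such figures present four independent determinations. Four
replicates of 10⁴ titered colonies detect a 0.3 vs 0.03 efficiency contrast
at p < 0.001 in ≥ 95% of simulations.

## What the synthetic generator does and does not emulate

`generate_field()` renders ellipsoidal cells with a cytosol-filled interior
(one marker per strain), a wall shell of configurable thickness carrying
mCherry either uniformly or as a polarized crescent (axis + half-angle;
180° reproduces the uniform shell), a constant camera offset, and
first-order sCMOS noise: `Poisson(signal × poisson_scale)/poisson_scale +
Normal(0, gaussian_sd) + offset`, quantized to integer ADU. Geometry
defaults follow the acquisition the workflow describes — 28 sections at
300 nm — and the shell thickness defaults to 3 voxels, cohering with the
3-pixel wall band at ≈65 nm/pixel. Camera bit depth (16-bit) and offset
(100 ADU) are configuration defaults, not asserted facts about any
particular instrument. A single integer seed drives one generator per call,
and the caller's RNG state is restored afterwards.

Ground truth includes the 3-D label and wall-mask volumes, per-cell voxel
counts, and `true_mean_wall_mcherry`: the mean of the *noiseless projected*
mCherry over the cell's true projected wall band — i.e., what a perfect
measurement in the projection would report, offset included. Defining truth
in measurement space keeps the oracle comparison meaningful; a 3-D
"shell intensity" truth would differ from any projection-based measurement
for geometric reasons alone.

Deliberately not modeled: point-spread blur, deconvolution artifacts,
photobleaching, stage drift, buds and bud scars, autofluorescence. Passing
the oracle suite therefore demonstrates correctness of the segmentation and
accounting machinery on clean geometry, not robustness to optical
aberrations of real microscopes.

Overlap between cells aborts generation beyond `overlap_tolerance`
(default 0 voxels: ground truth would be ambiguous); tests raise the
tolerance to build touching clumps for the watershed path, in which case
contested voxels belong to the later cell.

## Problem sizes used by the test suite

Tests run the full pipeline at the native 28-section depth with 320×320
fields and three cells of 31–40 pixel lateral radius (interiors just above
the 2400-pixel window), 50 such fields in the oracle suite; binding
recovery uses 200 Monte-Carlo refits per affinity; the Mann–Whitney
null-calibration uses 2000 simulated fields of 80 cells per group. These
sizes make every statistical check meaningful while keeping the whole suite
under a few minutes on one core.

## Known limitations

* 2-D measurement after projection is the default and the tested path; the
  3-D interpretation of the interior-size window is not implemented as a
  parallel mode — the projected reading is the one this package commits to.
* The identity thresholds are raw-intensity cuts; there is no per-field
  background estimation for classification.
* The Mann–Whitney exact branch enumerates nothing beyond n = 20 per group;
  larger groups always use the corrected normal approximation.
* Binding fits assume homoscedastic Gaussian replicate noise; no weighting
  or robust loss is offered.
* No multiple-testing correction across fields: the workflow performs
  single pairwise comparisons per figure, and so does the package.
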