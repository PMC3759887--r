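---
title: "Methods: automated gamma-H2AX focus scoring with cell-cycle sorting"
author: "fociscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated gamma-H2AX focus scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fociscan)
```

# The scoring problem

Ionising radiation produces DNA double-strand breaks, and each break
recruits phosphorylated histone H2AX (gamma-H2AX) into a microscopically
visible immunofluorescent focus. Counting foci per nucleus is therefore a
sensitive dosimeter — down to the few-mGy range of a mammogram — but manual
counting is slow and subjective, and the count is confounded by the cell
cycle: G2 cells carry roughly twice the gamma-H2AX background of G1 cells
(twice the genome), S-phase cells show a rough pan-nuclear signal from
replication stress, and M cells are brightly pan-nuclear. An automated
scorer must therefore (i) find nuclei, (ii) count discrete foci, and
(iii) sort every nucleus by cell-cycle phase before averaging.

fociscan implements this workflow for multichannel z-stacks (DAPI +
gamma-H2AX + pericentrin) and pairs it with a synthetic image generator
whose ground truth makes the whole pipeline testable end to end.

# Pipeline

## Nucleus segmentation

Nuclei are segmented on the maximum-intensity projection of the DAPI
channel: Otsu threshold, hole filling, connected components, and a
minimum-size prefilter at the debris gate (50 points). Touching nuclei are
*deliberately not split* by watershed: the workflow resolves them
downstream, because a merged object either exceeds the upper area gate
(250 points) or carries 3-4 pericentrin signals, and both conditions
invalidate it. Objects touching the field border are flagged and excluded.

Nuclear area is stored in scanner "points", a proprietary linear rescaling
of pixel area. Only linearity is assumed; `points_scale` (default 0.03
points/px) is a free calibration factor chosen so that G1 nuclei of the
synthetic samples fall in the 50-130-point G1 gate.

## Spot detection

Foci and pericentrin spots are detected per focal plane with a
difference-of-Gaussians band-pass (sigma 1.5 / 5 px) followed by a fixed
intensity threshold; each connected supra-threshold footprint is one spot.
Footprints that fuse at the threshold are counted as **one** spot — this
reproduces the merge-driven undercounting ("saturation") seen at high
dose, which is part of the behaviour being modelled, so no declumping is
applied. Per-plane detections whose centroids fall within one reference
diameter on adjacent planes are merged, so a spot spanning several planes
counts once. Spots are assigned to the nucleus containing their centroid;
pericentrin, which sits at the centrosome beside the nucleus, is assigned
after dilating the nuclear masks by 5 px. A maximum-diameter gate accepts
spots up to 280% of the reference spot diameter (4 px), rejecting large
debris and grossly fused clusters.

Thresholds (default 2000 on the 16-bit scale for both channels) are fixed
per run, mirroring an acquisition protocol with constant exposure and
camera settings; no per-field adaptation is performed. The band-pass is
applied by cyclic FFT convolution with a cached kernel; since the kernel
integrates to approximately zero, the wrap-around at field borders only
mixes in near-zero background response.

## Cell-cycle sorting and validity

Each nucleus is gated by area — debris (< 50 points), G1 (50-130), G2
(130-250), overlapped/polyploid (> 250) — with boundaries assigned
G1 at 50 and G2 at 130 and 250, because the G2-marker calibration
population was observed at both ends of the 130-250 range. The gates can
be re-calibrated from any labelled G2 population with
`calibrate_area_gates()` (gate = min and max of the labelled areas).

The pan-nuclear test computes, within the nuclear mask on the gamma-H2AX
projection, the supra-threshold coverage and the coefficient of variation
of supra-threshold intensity. Coverage above 0.8 with CV below 0.6 (or
with two pericentrin signals) is M; coverage above 0.5 with CV above 0.6
is S; otherwise the nucleus is interphase and its foci are countable.
These thresholds are package defaults validated against the generator's
pattern renderings only; the source observations are qualitative.

A cell is *valid* (scorable) iff it shows 1 or 2 pericentrin signals, its
area class is G1 or G2, and it is interphase. Zero pericentrin means the
marker was not captured; >= 3 signals mean touching nuclei scored as one.
Valid cells join the class group (pericentrin count, capped focus count) —
the full cross product {1,2} x {0..10} of 22 groups. (The workflow this
reimplements reports "20 class groups" for the same criteria; 2 x 11 = 22,
and which two combinations were excluded there is not recoverable, so the
full cross product is kept.)

## Statistics

`summarize_sample()` reports the mean and SE of the capped focus count
over valid cells, the 0-10 histogram, and the mean brightest-focus
intensity, optionally stratified by G1/G2. The brightest-focus mean is
taken over cells with at least one detected focus — a cell without foci
has no brightest focus, and including zeros would fold the dose-dependent
fraction of zero-focus cells into what is meant to be an intensity law.
Dose contrasts use a two-sided Mann-Whitney U test with midranks: exact
permutation enumeration when both groups have at most 8 cells, otherwise
the normal approximation with tie-corrected variance and continuity
correction. No multiple-testing adjustment is applied. The
intensity-dose relationship and manual-vs-automatic agreement are ordinary
least-squares fits.

# The synthetic sample generator

`generate_sample()` draws a cell population and renders it into
three-channel z-stacks (default four planes, 2.1 um apart, 1280 x 1024 px,
16-bit). The defaults encode the study conditions of exponentially growing
human mammary epithelial cells scored 2 h after irradiation:

* **Focus counts** are Poisson. The default rate table pins the measured
  dose means — 1.12 (0 Gy), 4.75 (0.5 Gy), 5.23 (1 Gy) — with a linear
  `control + 7.26/Gy` fallback for other doses; the measured means are
  visibly sub-linear (saturation), which is why a table rather than a pure
  linear law is the default. G2 cells add `(multiplier - 1) x control`
  background, multiplier 2 by the genome-doubling argument (no measured
  value exists).
* **Phases**: 16% G2 (matching the measured large-area fraction at 70%
  confluence), optional S (5%) and M (2%) pattern cells, remainder G1.
* **Nuclear areas** are uniform on 50-130 points (G1/S) and 130-250 (G2/M),
  rendered as hard-edged ellipses with axis ratio 0.75-1.
* **Foci** are isotropic 3-D Gaussians (FWHM 3 px + 1 px/Gy, peak
  12000 + 10000/Gy, 5% CV, axial sigma 1.5 um) sampled onto the planes at
  a uniform depth. By default foci are placed uniformly in the nucleus so
  that overlap-merging emerges naturally with dose; `allow_focus_overlap =
  FALSE` enforces a minimum pairwise separation of 2.2 FWHM for
  detector-validation runs.
* **Pericentrin**: one spot per G1/S cell, two for M and half of G2 cells,
  placed near the nuclear periphery. Integrated intensity is coupled to
  nuclear area through a Gaussian copula on ranks whose Pearson parameter
  `2 sin(pi rho_s / 6)` yields the target Spearman correlation (default
  0.4942, the measured value).
* **Patterns**: S cells get a smoothed lognormal texture (~70% coverage,
  high CV); M cells a uniform bright fill plus two separated pericentrin
  spots.
* **Camera**: baseline 500, Gaussian read noise sd 20, values clamped and
  quantised to 16 bits. Geometry, pixel size (0.1075 um) and intensity
  scales are package choices — no camera specification exists to match.

All randomness derives from `seed`; identical configurations produce
bit-identical images and ground truth.

## What the generator does and does not emulate

It reproduces the *statistical* structure that the scoring stages exercise:
bimodal areas, Poisson counts with phase background, dose-scaling focus
size/brightness (hence overlap saturation), the pericentrin-area
correlation, pan-nuclear patterns, and optional touching nuclei. It does
not attempt photorealism: no chromatic aberration, no uneven illumination,
no focus drift, no real PSF, hard-edged nuclei without chromatin texture.
Passing tests therefore demonstrate that the pipeline recovers known
parameters under this idealised imaging model, not that it would match a
particular microscope without threshold re-calibration.

# Numerical choices and degenerate inputs

* Boundary conventions are explicit: area gates as above; the diameter
  gate is inclusive (`<=`); a blank or uniform field yields zero nuclei
  (a quasi-global Otsu foreground is rejected).
* Cross-plane merging uses one reference diameter (4 px) as the radius;
  spots separated by more than that on adjacent planes stay distinct.
* The focus-merge switch for two equal Gaussian spots happens slightly
  beyond footprint contact (at separation `s` with `s^2 = 4 r1^2 +
  8 sigma_c^2 ln 2`, tail addition), which the tests use as the analytic
  bound.
* Zero valid cells is an error carrying a QC breakdown; fewer valid cells
  than `minimum_nuclei` (default 1000 per sample) is a warning flag.
* Degenerate gate calibrations (fewer than 2 areas, or all equal) are
  rejected.

# Validation scale

The acceptance-style checks run the full image pipeline at the study's
own scale: 1000 cells per dose for rate recovery, repeatability,
saturation direction and the pericentrin-area correlation, and 2000 cells
per dose for the three-dose intensity linearity fit; population-level laws
of the generator (Poisson means, copula correlation) are additionally
verified at n = 10000 on the ground-truth layer, where rendering is not
required. These sizes keep the whole validation suite runnable on a
laptop-class machine in well under half an hour.

# Known limitations

* `points_scale` is a free linear factor; absolute agreement with any
  scanner's "points" unit is not claimed.
* S/M pattern thresholds are tuned to the generator's renderings; real
  S-phase textures vary with labelling chemistry.
* The pericentrin dilation margin trades off marker capture against
  stealing spots from neighbouring cells; with the non-touching layout the
  trade-off is invisible, with dense real cultures it is not.
* The Mann-Whitney normal approximation is used above group size 8; for
  the 1000-cell groups this is standard, but p-values in the far tail are
  approximation-limited.
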