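---
title: "Methods: simulated tomosynthesis, texture features, and observer performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated tomosynthesis, texture features, and observer performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tomotex` implements a complete in-silico study of how acquisition
geometry and projection-domain filtering shape second-order image texture
and lesion detection–localization performance in digital breast
tomosynthesis (DBT). This vignette is the package's own account of the
models, the parameters that matter, the numerical choices, and what the
synthetic world does and does not establish.

## 1. The phantom generator

A compressed breast is modelled as a slab of tissue (default 50 mm thick
at 0.2 mm isotropic voxels) whose in-plane support is a half ellipse with
a flat chest wall, wrapped in a one-voxel skin rind. The interior is
partitioned into Voronoi compartments around uniformly seeded sites; a
one-voxel ligament sheet is carved on the low-index side of every
compartment boundary; whole compartments are then assigned greedily to
adipose or fibroglandular tissue until the realized volumetric glandular
fraction (VGF = fibroglandular / (adipose + fibroglandular + ligament))
is as close as possible to the target. The generator's contract is
*structural variability* across seeds and a VGF within ±5 percentage
points of target — it makes no claim to any particular anatomical growth
model.

Tunables: `vgf_target` (fraction), `grid_shape` (voxels), `voxel_size`
(mm, default 0.2), `target_compartment_mm3` (default 512 mm^3, an 8 mm
cube; the reduced study below uses 64 mm^3 because real parenchymal
texture is fine-grained relative to an 8 mm mass).

Lesions are digitized spheres (default 8 mm): a fibroglandular voxel at
the requested depth (measured along the compression axis from the
detector-side surface) is chosen uniformly among feasible centres
(seeded), and every voxel within `diameter/2` of it is relabelled —
background removed, not blended. A non-positive diameter is a caller
error; an infeasible depth raises a placement error the caller may retry.

Attenuation coefficients ship as a small nominal table (1/mm on a
15–40 keV grid) with the orderings that matter downstream: adipose <
fibroglandular ≤ lesion at every energy, air negligible. They are
config-replaceable (`read_material_table`).

## 2. Projector and detector cascade

X-ray transmission uses Siddon ray tracing through the voxel grid
(half-open voxel convention, ties to the lower-index voxel; the traversal
conserves the analytic box chord to 1e-9). For each detector pixel the
per-material path lengths `L_m` give the expected counts

    I = I0 * sum_E w(E) exp( - sum_m mu(m, E) L_m ),

with `I0 = fluence_per_mGy * total_dose / P` counts per pixel per view
(dose split evenly over the `P` views; default total dose 1.5 mGy). The
geometry is a rotating source over a 60° arc about a centre 50 mm above a
stationary detector (source–detector 650 mm, source–centre 600 mm,
config-overridable; the source paper states neither distance). The
detector cascade applies, in order: Poisson sampling of the quanta (per
energy bin when the spectrum is polychromatic), a Gaussian blur of stated
FWHM standing in for focal-spot plus scintillator blur, a gain, and
additive Gaussian electronic noise. Disabling all noise and blur returns
exactly `gain * input`.

The dose-to-fluence constant is a single documented proportionality —
only *relative* noise across `P` matters for every analysis here.

## 3. Wiener filter

The space-variant adaptive Wiener filter operates on each projection:

    out = m + max(v - v_n, 0) / max(v, v_n) * (in - m)

with `m`, `v` the mean and unbiased variance of a sliding window (default
5×5, symmetric reflection padding) and `v_n` the additive-noise variance,
estimated in `"auto"` mode as the median of the local variances (in
smooth regions local variance is mostly noise, so the image-wide median
tracks the noise floor). Zero assumed noise is the identity; shrinkage is
pixelwise monotone in `v_n`. The filter assumes locally additive noise;
no Poisson-aware adaptation is attempted, matching its stated design
goal.

## 4. Reconstruction and slabs

Projections are air-normalized to line integrals `-log(I / I0)` using the
projector's known reference, ramp-filtered along the source-motion axis
in the frequency domain, and back projected voxel-wise with `1/P`
weighting (bilinear detector interpolation). Two numerical choices
deserve note:

* **Photon-starvation floor.** Counts are clamped at `min_counts = 0.5`
  before the log: electronic noise can push raw values to or below zero,
  and a pixel cannot inform attenuation beyond its noise floor. Without
  this floor, near-zero counts produce unbounded line-integral spikes
  that dominate every downstream statistic.
* **Slice bookkeeping.** Reconstruction uses 0.2 mm slices by default
  (matching phantom voxels) so lesion depth bookkeeping survives
  slabbing; display slabs are contiguous non-overlapping means (maximum
  intensity optional) of `floor(depth / thickness)` groups, and truth
  metadata attaches to the slab whose interval contains the lesion
  centre (`floor(depth / thickness)`, 0-based).

A 3D Butterworth filter (default cutoff 0.25 cycles/pixel, order 4 — the
order is not stated in the source and is config-exposed) apodizes the
volume; its gain is exactly 1 at DC and `1/sqrt(2)` at the cutoff. The
breast mask is geometric — the phantom's support footprint resampled onto
the reconstruction grid — never an image threshold.

## 5. Texture features

Slabs are quantized to `levels` grey levels (default 256) by linear
min–max binning over the masked pixels; a **global-range mode**
(`quantize(range =)`) clamps into a fixed window instead. Lattice ROIs
(default 35 px ≈ 9.45 mm at the 0.27 mm display pixel) tile the mask's
bounding box in row-major order; only tiles fully inside the mask are
kept.

Per ROI, 13 features are computed with 1-based grey values `i = 1..N`:

* **GLCM** (`d = 1`; 0°, 45°, 90°, 135°; symmetric; features averaged
  over the four matrices): Correlation
  `(Σ ij G - μx μy)/(σx σy)`, Homogeneity `Σ G/(1+|i-j|)`, Energy
  `Σ G²`, Entropy `-Σ G log2 G` with `0 log 0 = 0`. Correlation is
  undefined on a zero-variance ROI and reported missing (excluded from
  the direction average) rather than silently zero.
* **NGTDM** (`n = 1`, complete neighbourhoods only): `D(i)` sums
  `|i - neighbourhood mean|` over centre pixels of level `i`; Contrast,
  Coarseness, Busyness, Complexity follow the classical definitions with
  sums restricted to levels of nonzero probability. Coarseness carries an
  `1e-12` guard (constant ROIs otherwise diverge); Busyness with a zero
  denominator is missing.
* **RLM** (four directions, features averaged): maximal-run counts per
  scan line; every pixel lies in exactly one maximal run per direction,
  so `Σ j R(i,j)` equals the pixel count — an invariant the tests enforce
  for every direction. SRE, LRE, GLN, RLN, RP follow the classical
  definitions.

Every matrix and every feature is validated to 1e-12 against independent
brute-force implementations (explicit loops, direct summation) on
hundreds of random ROIs.

Per-condition summaries pool lesion-present and lesion-absent slabs (the
averaging in the source makes no distinction), reporting mean, SD and ROI
count per feature; conditions with zero ROIs are reported, not dropped.
ROIs overlapping the lesion are included by default (exclusion is a
flag).

## 6. LROC scoring and the synthetic observer

The localization-corrected AUC is the Wilcoxon statistic over all
(present, absent) pairs with the present trial credited only when marked
within 15 pixels (inclusive — "within" is read as ≤) of the true centre;
rating ties contribute one half. The implementation is exactly equivalent
to exhaustive pair counting.

Human readers are replaced by a parametric observer. Each test trial
draws a latent score `z + d' * truth`, `z ~ N(0,1)`. Ratings 1–4 cut the
latent scores at the *session's empirical quartiles* — a deliberate
deviation from fixing cuts at the null quartiles, which would give absent
trials rating 4 with probability 0.25 and cap the AUC at 0.875,
contradicting the required near-perfect behaviour of a strong observer. A
present trial is "perceived" when its latent score exceeds the session
median; perceived trials mark the true centre plus isotropic Gaussian
error, others guess uniformly over the breast mask. All random draws are
made up front per trial, so a fixed seed gives common random numbers
across detectability values and the AUC–detectability curve is monotone
by construction; `estimate_detectability()` inverts it.

Known limitation: at zero detectability with a *small* localization
error, chance-perceived trials still mark near the truth, leaving the AUC
above chance; the chance level `π 15² / area` is reached in the stated
large-error limit.

## 7. The reduced-scale study world

`reduced_study_options()` states the desk-scale world used by
`run_trend_study()` and the acceptance trend criterion. Each choice is a
realism argument, made once:

| parameter | value | why |
|---|---|---|
| phantom grid | 48×48×96 @ 0.5 mm | full ~50 mm compressed thickness: the out-of-plane smear span `z·tan(30°)` must exceed the 8 mm lesion for artifact reduction to act at the lesion scale |
| compartments | 64 mm³ (4 mm) | parenchymal texture is fine-grained relative to the lesion |
| detector pitch | 0.3 mm (recon 0.6 mm) | the source system's detector is several times finer than its display pixel; sparse-view streaks must stay sharp on the display grid |
| fluence | 3×10⁴ photons/px/mGy | keeps every view above photon starvation at P = 45 while noise remains well above one grey-level width and below the anatomy span |
| electronic SD | 10 counts | per-view electronic noise grows ∝ P at fixed total dose — the high-P degradation mechanism |
| blur FWHM | 0.15 mm | a thin scintillator; heavier blur erases the noise growth that drives the high-P trend |
| slabs / levels / ROI | 2 mm, 64, 12 px | scaled versions of 1 mm / 256 / 35 px |

The trend study quantizes with a fixed per-phantom window pooled over the
clean slabs of all conditions (the global-range mode): at this scale the
per-image min–max is renormalized by whichever disturbance is largest,
which would measure the *range* of artifacts and noise rather than their
texture. The full-scale design's anatomic dynamic range makes per-image
min–max safe there; it is the package default.

The observer's detectability is driven by a lesion contrast-to-noise
summary measured on simulated slabs:

    d' = k * contrast / sqrt( disk_sd² + pixel_sd² )

with `contrast` the lesion-disk difference of the *noiseless*
reconstruction pair (the deterministic signal the geometry delivers,
including artifact-induced loss), `disk_sd` the SD of lesion-sized
disk-averages of the noisy lesion-absent slab (lesion-scale clutter), and
`pixel_sd` its per-pixel SD (streaks and noise). The pixel term makes the
observer *masking-limited*: a pure matched filter would average pixel
noise over the full lesion aperture and, at realistic count levels, would
never be noise-limited — contrary to human readers. The efficiency
`k = 6` maps the studied conditions into the AUC 0.6–0.85 operating
range; every claim the acceptance criterion asserts is an *ordering*, and
orderings are invariant to `k`.

What a green trend criterion establishes: in this stated world, the
unfiltered arm's mean AUC rises from P = 3 to P = 11 and falls by P = 45;
the Wiener-filtered arm rises and does not fall; filtering helps the
noisiest condition; and the five concave-down features (Homogeneity,
Energy, Busyness, GLN, LRE) versus six concave-up features (Entropy,
Contrast, Complexity, SRE, RP, RLN) show their curvature signs in at
least 18 of 20 seeds. What it does not establish: magnitudes comparable
to human-reader AUC values, full-scale (760×240 at 0.27 mm) behaviour,
polychromatic-spectrum effects, or scatter and detector-lag physics
(out of scope by design).

## 8. Correlation analysis

Per-feature Pearson coefficients are computed over condition means only:
the unfiltered arm, the filtered arm, and the pooled arms (the combined
column pools the 2×|subset| points, not the average of two coefficients).
Features with `|r| ≥ 0.85` in all three columns — compared at printed
4-decimal precision and with `≥`, so a coefficient printing 0.8500
qualifies — are highlighted. Concavity of a feature-versus-P curve is the
sign of the quadratic coefficient of a least-squares parabola (≥ 4
points), declared indeterminate when the curvature's peak-to-edge effect
is below 1% of the value range. A packaged reference matrix
(`reference_correlation_table()`) carries the published 13×3 worked
example at its printed precision; the highlighting rule recovers exactly
nine features, and exactly two (GLCM Correlation, NGTDM Coarseness) are
low in all three columns.

## 9. Degenerate inputs and tie-breaks (summary)

Constant images quantize to level 0 (documented, not an error); constant
ROIs give Energy 1 / Entropy 0 / Homogeneity 1, missing GLCM Correlation
and Busyness, and guarded Coarseness. Rays tangent to voxel faces go to
the lower-index voxel. Ties among feasible lesion centres break by seeded
uniform choice. The Wiener filter with zero local and assumed variance
returns the pixel unchanged. `slab_volume` requires the thickness to be a
multiple of the slice spacing. All stage outputs are bit-reproducible
under fixed seeds; every derived seed stays below 2^31.
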