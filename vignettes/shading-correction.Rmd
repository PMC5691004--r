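---
title: "Image-domain shading correction for CBCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-domain shading correction for CBCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model,
the estimation procedure, the tunable parameters and the numerical
decisions behind them, what the synthetic phantoms do and do not
establish, and the known limitations.

## The model and its assumptions

Cone-beam CT volumes acquired for on-board treatment guidance carry
smooth, spatially varying intensity errors — shading — dominated by
scatter, with contributions from bowtie filters, beam hardening and
detector nonidealities.  The package models the observed volume as a
multiplicative corruption of the truth,

$$ I_0 = I \cdot B, $$

with $B$ a strictly positive, dimensionless, *low-frequency* bias
field.  Three assumptions do all the work:

1. **Low frequency.**  Shading varies slowly in space; anatomy is
   comparatively high-frequency.  Anything the low-pass estimation
   chain can represent is attributed to $B$; everything else survives
   the division untouched.
2. **Radial structure.**  In circular scan geometry shading tends to be
   globally or locally radial about the rotation center, which makes a
   polar-coordinate representation the natural smoothing domain: one
   wide median along the angle, low-order polynomials along the radius.
3. **Water-like soft tissue.**  The absolute scale of a multiplicative
   field is unidentifiable from one image ($I_0 = (cI)(B/c)$).  The
   calibration step pins it by anchoring the unmasked soft-tissue body
   voxels to water.  The residual error this induces equals the true
   mean soft-tissue CT number (a few tens of HU), consistent with the
   residual errors clinical evaluations of this scheme report.

### Value domain

The division runs in relative attenuation, $\mu_{rel} = HU/1000 + 1$
(water 1, air 0), never in HU: HU values cross zero in soft tissue, so
a multiplicative model in HU is ill-posed, while in $\mu_{rel}$ the
field is dimensionless and $\approx 1$.  The choice also makes the
final calibration a pure unit conversion — any constant linear
attenuation coefficient of water cancels between scaling and
conversion.  Conversion is affine, so it commutes with interpolation;
the package exploits this by detecting the air boundary on the HU polar
slice and converting the same grid to $\mu_{rel}$ exactly.

## The estimation chain

Per transverse slice (processed independently, then fused in 3D):

1. **Centering.**  The processing center is the centroid of the largest
   connected component above the body threshold (-300 HU).  The
   centroid is deterministic and translation-equivariant; the slice is
   *not* resampled — the polar transform simply runs about this point.
   A configurable `center_offset` exists because a ring structure
   exactly concentric with the processing origin is a degenerate input
   (see Limitations); shifting the origin slightly is the mitigation.
2. **Structure masking.**  Bone and fiducials (> 100 HU) and gas
   pockets ([-750, -500] HU) are thresholded, cleaned by a binary
   opening (disk radius 1) and padded by a dilation (radius 2), then
   filled with water (0 HU).  The opening removes speckle that is noise
   rather than anatomy; the dilation covers partial-volume rims.  The
   filled slice exists *only* for bias estimation: the corrected image
   is always the original divided by the (smooth) field, so the fill
   value can never leak into the output.  A slice whose masks cover
   more than 90% of its body is rejected (identity bias, logged).
3. **Polar transform.**  600 radial x 360 angular bins; cubic
   (Keys) interpolation both ways; the radial step is chosen so the
   outermost bin reaches the farthest slice corner (600 bins covers the
   largest half-diagonal).  Angular bin centers sit at
   $(j+0.5)^\circ$; the angular axis is periodic everywhere.
4. **Air flagging.**  Per angle, the boundary is the radial bin with
   the maximum outward gradient.  Two numerical choices matter:
   the gradient is expressed in HU *per voxel* — the 600-bin radial
   axis oversamples the image several-fold, so a per-bin threshold
   would silently scale with geometry — and a ~2-voxel partial-volume
   margin inside the boundary is flagged as well, because
   interpolation spreads the body/air edge and the contaminated bins
   otherwise drag the high-order radial fit (on a uniform phantom this
   margin reduces the bias error near the edge by two orders of
   magnitude).  Angles whose strongest gradient stays under the floor
   (100 HU/voxel) contain no body and are dropped entirely.
5. **Directional low-pass.**  First pass: for each angle, the median
   over a wide circular angular window (invalid bins excluded), then an
   order-8 polynomial fitted along the radius of each angle's median
   profile.  Second pass: a radial median of width 1 bin (i.e. none, by
   default) and an order-3 polynomial along the radius.  The wide
   median supplies the angular smoothing and the robustness against
   anatomy (a structure spanning less than half the window cannot move
   a median); the polynomials supply radial smoothness and extrapolate
   the field across masked and air bins.  Fits run on a domain rescaled
   to $[-1, 1]$; a profile with fewer valid points than the order falls
   back to its median as a constant (counted in the per-slice log).
6. **Fusion and division.**  Per-slice fields return to Cartesian space
   (periodic-angle cubic interpolation, constant radial extrapolation
   beyond the outermost bin), are stacked, 3D-median-filtered (3x3x3 by
   default — the smallest kernel that removes inter-slice outliers),
   clamped to [0.2, 5], scale-anchored (soft-tissue median of the field
   equals the soft-tissue median of the image), divided out, and
   converted to HU.

### The direction of the polynomial fits

The published construction is ambiguous about whether the first-pass
order-8 polynomial runs along the radius of each angle's median profile
or along the angle at each radius.  This implementation follows the
radial reading (the published illustration of the fit shows a 1D
*radial* profile), with the angular smoothing coming entirely from the
wide median window; the alternative is available as
`angular_fit_axis = "angular"` in `correction_config()`.  On the
synthetic phantoms the radial reading recovers all three shading
classes within a fraction of a percent RMS, which is why it is the
default.

### The precorrection round

Half-fan acquisitions with a bowtie filter produce a *global ring*: a
largely uniform shading level inside a ring transition and a different
level outside.  An order-3 radial polynomial cannot represent a step,
so a dedicated first pass handles it: per slice, one full-circle radial
median profile (all angles share it; each angular bin is counted
exactly once); the transition band is the contiguous run of radial
derivative magnitudes exceeding 5x their median around the global
maximum; the precorrection bias is the inner mean below the band, the
outer mean above it, and the profile itself across it, normalized so
the inner level is 1 (a precorrection fixes relative shading only —
absolute scale belongs to the main round's calibration).  Slices
without a detectable band get an identity precorrection.

One numerical subtlety: the band-finding derivative is taken over a
~4-voxel window rather than one radial bin.  The oversampled radial
axis makes single-bin differences interpolation-noise dominated; with a
1-bin derivative the 5x-median test intermittently missed the band on
noisy slices.  The window is scale-free (specified in voxels) and small
against any plausible transition.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `bone_threshold` | 100 | HU | published threshold; also captures fiducials |
| `gas_range` | [-750, -500] | HU | published threshold |
| `body_threshold` | -300 | HU | safely between lung/air and soft tissue |
| `n_radial` x `n_angular` | 600 x 360 | bins | published polar grid |
| `angular_width_deg` | 80 | deg | published pelvis setting; use 40 for head |
| `radial_width_bins` | 1 | bins | published radial width (no radial median) |
| `order_angular` / `order_radial` | 8 / 3 | – | published fitting orders |
| `median3d_kernel` | 3x3x3 | voxels | smallest inter-slice outlier filter; no published value exists |
| `precorrection` | TRUE | – | site-driven: on for half-fan/bowtie (ring) cases |
| `clamp_lo` / `clamp_hi` | 0.2 / 5 | – | positivity guard for extrapolated bins |
| `open_radius` / `dilate_radius` | 1 / 2 | voxels | speckle removal / partial-volume margin |
| `downsample_factor` | 2 | – | the bias is low-frequency; estimating it on a coarser grid is sanctioned and ~4x cheaper |
| `boundary_gradient_floor` | 100 | HU/voxel | well under any body/air edge, above anatomy |
| `transition_deriv_factor` | 5 | – | scale-free band threshold |

Determinism: the correction itself contains no randomness; the only
seed in the package drives phantom noise.

## What the phantom establishes — and what it does not

`phantom_spec()` defaults to a pelvis-scale stated world: 256 x 256 x 32
voxels at ~1.37 mm (an in-plane extent of ~350 mm, downsampled from
clinical 512^2 — legitimate because the estimated field is
low-frequency), an elliptical water body (semi-axes 150 x 110 mm,
0 HU), bone/gas/contrast inserts exercising exactly the masking
thresholds, additive Gaussian noise of 20 HU (clinical CBCT soft-tissue
ROIs show standard deviations of that order), and shading amplitudes
engineered to ~-250 HU of soft-tissue error — the magnitude reported
for uncorrected clinical volumes.  Ring levels default to 0.75 inside /
1.0 outside; the other classes use amplitude 0.25 lobes peaking at the
body center.

A green phantom suite establishes that the chain recovers
*within-model* shading — smooth, radially structured, multiplicative —
through noise, masking, resampling and fusion, and that anatomy
(bone/gas inserts) survives.  It does **not** establish clinical
performance: real scatter is not exactly multiplicative-smooth, real
anatomy is not elliptical, real soft tissue is not 0 HU (the water
anchor then contributes its mean as residual error), and no
registration error exists here because truth and test share a grid.

## Degenerate inputs and tie-breaks

* Empty (all-air) slices, mask-covered slices, and angles with no valid
  bins fall back to an identity bias, logged per slice; they never
  abort a volume.
* A fit with fewer valid points than its order returns the valid
  median as a constant; a slice with no valid angle returns all ones.
* Medians of even counts average the two central values; full-circle
  median windows count each angular bin exactly once.
* All-equal radial profiles produce no transition band, hence an
  identity precorrection.
* Volumes with no voxel above the body threshold are a pipeline error.

## Limitations

* High-frequency shading (e.g. scatter structure near metal) is
  invisible to a low-pass chain and remains.
* Contrast is retained, not restored: a projection-domain refinement
  would be needed to recover contrast lost to scatter, and is out of
  scope here.
* Ring structures exactly concentric with the processing origin are
  adversarial for the radial median; the `center_offset` parameter is
  the documented mitigation.
* The water anchor biases the output by the true mean soft-tissue CT
  number; against a planning-CT reference this appears as a residual
  error of a few tens of HU.
* Inputs must already be registered to any reference used for metrics;
  the package performs no registration.
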