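---
title: "Methods: quantifying keratin network geometry, flow and traction forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying keratin network geometry, flow and traction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keratrack)
```

keratrack quantifies three aspects of keratin intermediate-filament (KF)
biology in micropattern-confined epithelial cells: the **geometry** of the
filament network (segment length, curvature, orientation), its **dynamics**
(keratin flow fields and rotational migration of confined cell groups), and
the **forces** the cells exert on their substrate (traction force microscopy).
Because live-cell recordings of this kind are rarely shareable at full scale,
the package ships a synthetic-scene generator that produces every input the
analysis stages consume, with exact ground truth, so each stage can be
validated end to end.

This vignette documents the models, the parameters that matter, the numerical
choices, and the limits of what the synthetic validation demonstrates.

## Containers and conventions

Images are stored as `image_stack` objects: numeric arrays in fixed
`(z, y, x)` order (`(t, z, y, x)` for time series) with pixel size, z-step and
frame interval attached. Coordinates are 0-based pixel indices with pixel
centers at integer positions; physical coordinates are micrometers. This
convention round-trips unambiguously through multi-page TIFF (`read_stack()`
/ `write_stack()`; integer data are stored losslessly at 16 bit, continuous
data at 32 bit with the intensity scale recorded in a JSON sidecar).

Extracted filaments are `filament_segment` objects — ordered polygonal chains
of 3D vertices in micrometers — and a set of segments plus the junction nodes
linking them forms a `filament_network`. PIV results are `vector_field`
grids; reconstructed tractions are `traction_field` grids in Pa.

## Segment geometry

**Length.** Following the convention used for KF network analysis, segment
length is the *chord*: the Euclidean distance between the two end vertices,
not the contour length. `segment_arclength()` provides the contour length;
chord ≤ arc always, with equality only for collinear chains.

**Curvature.** The curvature of a segment is the magnitude of the derivative
of the unit tangent with respect to arc length, `|dT/ds|`, averaged over the
chain. We read "second derivative of the smoothed tangent vector with respect
to arc length" as this classical curvature — the second derivative of the
smoothed *position* with respect to arc length — since a literal second
derivative of the tangent would be the third position derivative, which does
not measure bending. The estimator:

1. resamples the polyline at uniform arc spacing `resample_ds_um`
   (default 0.25 µm; the *effective* spacing after nearest-integer
   subdivision is used in all subsequent formulas);
2. Gaussian-smooths each coordinate along the arc;
3. takes centered second differences and averages their norms over interior
   samples, excluding a margin equal to the smoothing support at either end
   (reflection padding would otherwise flatten curvature near the ends).

By default the smoothing scale is coupled to the resampling step,
`smooth_sigma_um = 2 * resample_ds_um`. The coupling matters: with a *fixed*
physical sigma, Gaussian smoothing attenuates a curve's coordinate amplitude
by `exp(-sigma^2 kappa^2 / 2)`-type factors, which puts a constant bias floor
under the estimate no matter how finely one resamples. Coupling sigma to the
step makes both the smoothing bias and the discretization error scale as
`ds^2`, so halving the step reliably quarters the error — on a 10 µm-radius
circle the estimate converges as 5.0e-4 → 1.2e-4 → 3.1e-5 for
ds = 0.5 → 0.25 → 0.125 µm. Segments too short to support the stencil return
`NaN` with a `reason` attribute rather than a silently wrong number.

Curvature is reported **per segment** as the mean over interior samples; the
per-vertex values can be pooled by the caller if a pooled histogram is wanted
instead. This choice (mean, not max or integral) is the package's own — both
conventions appear in the literature.

**Orientation.** Each segment is translated into its xy chord vector (last
minus first vertex). The default polarity, `as_traced`, keeps the signed
chord so that sum vectors retain a direction, mirroring signed orientation
summaries of whole networks. Because keratin filaments are apolar, an
`axial` mode maps angles to [0°, 180°). Radial histograms use 24 bins of 15°
weighted by chord magnitude — binning is presentation only; the sum vector is
always the exact component-wise sum.

## Centerline extraction

The package does not re-implement stretching open active contours: that
algorithm belongs to the external snake tools it interoperates with (a
`read_tsoax_snakes()` reader ingests their text output, with the accepted
dialect pinned to the documented fixture). Instead, `ridge_enhance()` +
`extract_centerlines()` provide the same contract — image in, polylines out —
via a classical ridge pipeline:

1. **Hessian ridge filter**, plane by plane: the most negative eigenvalue of
   the Gaussian-scale Hessian, scale-normalized (`sigma^2`), maximized over
   scales (default 1.2 and 2 px, bracketing the PSF width), normalized to
   [0, 1] over the stack.
2. **Non-maximum suppression** along the per-pixel ridge normal (the
   eigenvector of the principal eigenvalue), so that parallel filaments a few
   pixels apart are never merged by a generous threshold.
3. **Threshold at `tau`** (default 0.008, the operating point used for KF
   networks in snake-based extraction; here it applies to the normalized
   ridge response — a documented divergence from the snake tools' internal
   meaning). The response floor — `median + 3*MAD`, the robust level of
   ridge responses that pure noise produces — is subtracted and renormalized
   first. On clean images the floor is ~0 and this is a no-op; on noisy
   images it bounds ridge *extent*, since 0.008 of the maximum would
   otherwise fall below the noise floor and connect everything.
4. **Thinning** (Zhang–Suen) to a one-pixel skeleton, **branch splitting**
   (skeleton pixels with more than two neighbors split paths; each path
   re-attaches one adjacent branch pixel so segments meet at junctions),
   pruning of paths shorter than `min_length_px` (default 10 px).
5. **Hysteresis validation**: a path is kept only if its *peak* response
   exceeds `median + 8*MAD` of the response image. `tau` delimits how far a
   ridge extends; the validation threshold decides whether it is a structure
   at all. Bright punctate particles seed high peaks but produce only short
   fragments, which pruning removes.
6. **End trimming**: a filament's ridge response halves at its tip, so end
   vertices below 40% of the path's median response are overshoot past the
   true endpoint and are dropped.
7. Paths are resampled at `spacing_px` (default 2 px) and each vertex gets a
   z coordinate from the response-weighted centroid along the stack.

On simulated networks at peak signal-to-noise ≥ 5 (after the default
denoising), recall and precision against ground-truth centerlines at 1.5 px
matching tolerance are both above 80% (typically 90–99%); this is checked by
the test suite on 47 µm disc scenes with 15 filaments at 256² resolution.

The paper-style workflow restores images with a trained content-aware model
before extraction; training such a model is out of scope here.
`denoise_stack()` (Gaussian, median, or Richardson–Lucy deconvolution)
stands in front of the ridge filter as classical preprocessing, and
externally restored stacks pass through verbatim with `method = "none"`.

## Network assembly

`link_nodes()` clusters vertices of *different* segments lying within a
linking radius ε (default 2 px, matching the snake point spacing; the
proximity rule is stated without a value in the source workflows, so ε is
exposed). Clustering is single linkage — the connected components of the
within-ε graph — implemented with a cell-list neighbor search; clusters with
at least two vertices from at least two segments become junction nodes at the
member centroid. The implementation is verified against a brute-force O(n²)
single-linkage oracle on hundreds of random instances, and is deterministic
under input reordering (nodes are canonically ordered by centroid).

## Flow and rotation

`compute_flow_field()` measures keratin flow between consecutive frames by
windowed cross-correlation (the classical approach for KF flow), maximum
projecting z first. The correlation engine:

* zero-padded (linear, not circular) cross-correlation per 32 px window at
  50% overlap, with **full per-lag zero-normalized correlation** — means and
  energies are computed over the actual overlap region of every lag, which
  removes the bias that window-global normalization leaves on shifts of a
  few pixels;
* 3-point Gaussian sub-pixel peak fit per axis (parabolic fallback where a
  log fit is undefined);
* featureless windows are flagged invalid (never zero); a normalized median
  test (residual over neighborhood median, threshold 2, noise floor 0.1 px)
  invalidates outliers. Invalid vectors are excluded from every aggregate,
  and the invalid fraction is reported.

On constructed translations of bead textures the estimator recovers integer
shifts to < 0.05 px and a 2.6 px sub-pixel shift to < 0.01 px on average,
with |bias| < 0.1 px across 0.5–5 px.

When a mask is supplied, windows must lie **entirely** inside it
(`mask_coverage = "full"`): windows straddling the specimen edge mix moving
texture with empty background and overestimate flow magnitudes; with
center-only masking such windows read up to ~80% high near the pattern rim
while fully interior windows are accurate to < 1%.

`mean_flow_rate()` averages |v| over valid in-mask windows and frames and
returns the radial profile of rate versus distance from the pattern center —
on peripheral-flow scenes (speed growing with radius) the profile increases
monotonically outward, the qualitative signature reported for confined
keratinocytes.

`rotation_rate()` estimates the angular velocity of a rotating confined cell
group. Two refinements proved essential on filament textures and are worth
recording:

* **Aperture problem**: a window dominated by one straight filament only
  constrains the motion component normal to the filament; the along-filament
  component collapses toward zero and a plain tangential average reads up to
  15% low. The angular velocity is therefore a weighted least-squares fit of
  the rigid-rotation displacement model to the PIV vectors with each
  window's *structure tensor* (summed gradient outer products) as the weight
  metric — the unobservable component carries no weight.
* **Centroid attribution**: a PIV vector reports the motion of the texture
  inside its window; near the specimen edge that texture is off-center, and
  attributing the vector to the geometric window center misassigns its
  radius. Vectors are attributed to the window's intensity centroid, and
  windows not fully inside the mask are excluded (the pattern rim is
  rotation-invariant and otherwise drags estimates toward zero).

With both refinements a rigid 2°/frame rotation imaged at 3 min/frame is
read as 38–41 deg/h against the true 40 deg/h, consistent between 32 px and
64 px windows, with the sign flipping exactly under time reversal (positive
= anticlockwise in the Cartesian, y-up sense).

## Traction force microscopy

The TFM chain is: drift alignment → bead PIV → regularized Fourier-transform
traction cytometry (FTTC).

**Drift alignment** (`align_drift()`) uses whole-frame phase correlation with
a matrix-multiply DFT refinement on an upsampled local grid. The cross-power
spectrum is *spectrally weighted* rather than fully whitened
(`R / (|R| + 1e-6 max|R|)`): full whitening amplifies noise-dominated
frequencies and can derail the peak on smooth textures, while the weighted
form is still exact for clean translations. Same contract as template
matching the stressed against the relaxed bead frame: one global translation.

**Boussinesq model.** For tangential traction on an elastic half-space the
Fourier-domain Green's tensor is

$$\hat G(k) = \frac{2(1+\nu)}{E\,k^3}
  \begin{pmatrix}(1-\nu)k^2+\nu k_y^2 & -\nu k_x k_y\\
                 -\nu k_x k_y & (1-\nu)k^2+\nu k_x^2\end{pmatrix},$$

with `E` the substrate Young's modulus (default 11 000 Pa — the 11 kPa
polyacrylamide used for keratinocyte TFM) and ν the Poisson ratio (default
0.5, the incompressible-gel convention; the source protocol does not state a
value). `forward_displacement()` applies \(\hat u = \hat G \hat t\) per mode
on a periodic grid with the zero mode nulled (force balance); it is both the
generator of synthetic bead displacements and the forward operator in
round-trip validation.

**Inversion** (`reconstruct_traction()`) solves, per mode,
\(\hat t = (\hat G^T\hat G + \lambda^2 s I)^{-1}\hat G^T\hat u\) in closed
2×2 form, where `s` is the mean diagonal of \(\hat G^T \hat G\) over nonzero
modes — this makes λ dimensionless and transferable across grid sizes and
moduli. Invalid PIV vectors are interpolated first (inverse-distance; the
filled fraction is reported), and the grid is zero-padded to twice its size
before the FFT to suppress periodic-boundary artifacts, cropped after. In
round-trip *validation* the inverse is run unpadded (`pad = FALSE`) to match
the periodic forward operator that generated the fixture — an
operator-consistency choice; padding remains the default for real image
pairs and is exercised by the pipeline-level tests. λ defaults to 1e-4
(effectively unregularized, appropriate for clean data); `lambda_sweep()`
tabulates the L-curve and suggests a corner value for noisy data. At λ = 0 an
ill-conditioning guard refuses near-singular inversions.

Validation: a force-balanced Gaussian traction dipole (±500 Pa, 8 µm patch
sigma, 24 µm separation) on a 256² grid at 0.23 µm spacing round-trips with
< 0.001% relative RMS error noiseless, and with 0.1 px Gaussian displacement
noise the error is ~11% after tuning λ on a five-point grid
(10^0.25 … 10^1.25) spanning the L-curve corner. The reconstructed L2 norm
decreases monotonically with λ, and a pure drift (uniform displacement)
reconstructs to zero traction.

**ROI statistics** (`roi_traction_stats()`) report the arithmetic mean and
maximum traction magnitude, the vector sum, and a radial histogram of the
in-ROI traction vectors (same construction as segment orientation
histograms).

## Synthetic scenes: what they emulate, and what they do not

`simulate_filament_network()` draws smooth cubic-spline filaments through
4–8 control points generated by a persistent random walk (heading jitter
`curvature_scale`, default 0.35 rad), confined to the micropattern mask and
sampled at quarter-pixel arc spacing. Each bundle carries a smooth ±30%
intensity profile along its length, and punctate keratin particles (the
sub-resolution precursor pool seen in the cell periphery; default one per
filament) are scattered inside the mask. Both features matter for motion
analysis realism: perfectly uniform straight filaments are pathological PIV
textures (see the aperture problem above). Rendering deposits curve samples
with trilinear weights, blurs with a separable Gaussian PSF (σ_xy 0.3 µm,
σ_z 0.6 µm by default), adds background, and applies Poisson shot noise plus
Gaussian read noise. The Poisson draw uses one uniform per voxel
(inverse-CDF), so under a fixed seed voxels with unchanged expected signal
get bit-identical noise — this is what makes the photoablation locality
check exact.

Flow series advect curve points per frame: uniform translation, inward
radial flow with speed growing linearly to the pattern edge, or rigid
rotation. Points reaching the mask boundary freeze and the series is flagged
`clipped`. Traction scenes build Gaussian traction patches (with the
residual net force from truncating the tails at the frame edge removed, so
the discrete field is balanced to machine precision), solve the forward
problem at pixel resolution, and render fiducial beads (isotropic Gaussians,
σ 1.2 px) displaced by the interpolated forward solution.
`simulate_cell_group()` partitions the pattern into Voronoi territories with
one contractile dipole per cell, and `simulate_ablation()` removes one
cell's filaments and scales all patch amplitudes — the synthetic analog of
single-cell photo-oxidation.

What the generator does **not** emulate: realistic optical aberrations
beyond a Gaussian PSF, out-of-focus haze, filament bundling dynamics and
crossing-number statistics of real KF networks, bead displacement in z (the
package is deliberately 2D-TFM), and any motion more complex than the three
prescribed modes. Passing the synthetic validation therefore demonstrates
the correctness of the measurement chain under known ground truth — not that
biological images of arbitrary quality will segment equally well. The
default scene parameters (47 µm discs, 0.23 µm pixels, 5 z-planes at 0.5 µm,
bundle peak ~35–100 counts over ~10 counts background with 3 counts read
noise, 3000 beads per field) were chosen once as representative of confocal
recordings of this assay and are used unchanged by the test suite and the
acceptance script.

## Per-cell analyses and the ablation report

`per_cell_partition()` assigns each segment to the cell mask containing the
majority of its vertices; `run_pipeline(mode = "ablation")` analyzes each
cell on a territory-masked crop of the image, which makes per-cell
statistics strictly local — the analyses of untouched cells are bit-identical
before and after ablating a neighbor (the per-cell analog of analyzing
individual cells and their surroundings separately). `report_ablation()`
pairs the per-cell segment statistics (Mann–Whitney p-values via
`compare_groups()`: exact enumeration for small untied samples, normal
approximation with tie correction otherwise), the orientation sum vectors,
and the ROI traction means; on the simulated scenario with tractions scaled
by 0.8, the reported reduction is 18–23% across cells and seeds.

## Problem sizes and determinism

All validation runs on 256² frames (64–128² for unit fixtures), 5 z-planes,
3–4 time points, 256² FTTC grids and four-cell groups; the full test suite
completes in a few minutes on one core. Every simulator is bit-reproducible
from its seed; every pipeline run writes its resolved configuration and
reruns to byte-identical CSV outputs. `scripts/acceptance.R` recomputes the
headline numbers of this vignette from scratch for any seed.

## Known limitations

* Centerline extraction works on the maximum projection and assigns z per
  vertex afterwards; filaments crossing in xy at different z are traced as
  planar crossings, not resolved in 3D.
* `tau` is interpreted on the normalized, floor-subtracted ridge response;
  numeric equality with snake-tool settings is not implied.
* No filament tracking across time; segments are per-frame.
* Traction reconstruction is 2D on a semi-infinite substrate: no
  finite-thickness correction, no z-traction, no cell-boundary-constrained
  (BEM/FEM) variant.
* The Mann–Whitney utility compares two samples; it does not correct across
  the many segment-property comparisons a full study would make.
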