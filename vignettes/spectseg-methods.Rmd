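---
title: "Segmentation and quantification methods in spectseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation and quantification methods in spectseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectseg)
```

## The problem

Dosimetry in radionuclide therapy (for example ^177^Lu-DOTATATE treatment of
neuroendocrine tumours) needs the mean activity concentration in each tumour,
estimated from quantitative SPECT images. Two steps dominate the error
budget: *segmentation* — where is the tumour boundary in a noisy,
low-resolution emission image — and *partial-volume correction* — how much of
the tumour's signal has been displaced out of the delineated volume by the
system's point-spread function (spill-out). `spectseg` implements three
semi-automatic segmentation methods that all start from the same rough,
operator-style initialization VOI, the recovery-coefficient quantification
layer that converts VOI count statistics into activity concentration, the
evaluation metrics used to compare methods, and a synthetic phantom simulator
so the whole study design runs at desk scale.

## Segmentation methods

**Fixed threshold (FT).** The threshold is 42% of the maximum voxel value
inside the initialization VOI; VOI voxels at or above it are object. 42% is
the conventional figure for emission imaging. FT is included as the baseline:
it is cheap, widely used, and fragile — a single hot noise voxel moves the
threshold. No connectivity repair is applied, so at high noise FT produces
scattered voxel islands; that behaviour is part of the method and is reported
as such by the study harness.

**Modified Otsu (OM).** Otsu's criterion selects the threshold maximizing the
between-class variance \(w_0 w_1 (\mu_0 - \mu_1)^2\). Reconstructed SPECT
values are floating point, so instead of binning a histogram every unique
voxel value in the VOI is treated as a candidate threshold; any real
threshold strictly between two consecutive unique values classifies
identically, so nothing is lost. Candidates with equal objective are resolved
toward the *lowest* threshold (the larger, more conservative object); the
boundary convention is that values `<= t` are background and values `> t`
are object. The classification is invariant under increasing affine
intensity transforms, which the test suite asserts.

**Fourier surfaces (FS).** A closed deformable surface is parameterized by
truncated Fourier series in two surface coordinates \(u \in [0, 2\pi)\),
\(v \in [0, \pi]\):

\[
q(u,v) = a_{q,0,0} + 2 a_{q,0,1}\cos v + 2\sum_{l=1}^{K-1} c_{q,0,l}\sin(lv)
 + 4\sum_{m=1}^{K-1}\sum_{l=1}^{K-1}
   \big[c_{q,m,l}\cos(mu) + d_{q,m,l}\sin(mu)\big]\sin(lv)
\]

for each coordinate \(q \in \{x, y, z\}\). All \(\sin(lv)\) terms vanish at
\(v = 0, \pi\), so the surface closes at the poles by construction. Low
orders can only express slowly varying shapes, which is exactly the noise
resistance wanted for emission images. The implementation uses equal orders
in both directions; the reduced basis above (no \(\cos(lv)\) terms beyond
\(l = 1\), no \(\cos\cos\)/\(\sin\cos\) cross terms) is implemented exactly
as stated — the classical Fourier-descriptor family is larger, but the
reduced basis is sufficient to express smooth star-shaped tumour surfaces
and keeps the parameter count at \(3\,[2 + (K-1) + 2(K-1)^2]\).

The surface is driven by an edge-strength objective

\[
B = \frac{\sum_{i,j} \big[\nabla I \cdot \mathbf{n}(u_i, v_j)\big]\,
          \delta(u_i, v_j, \nabla I)}
         {\Big(\sum_{i,j} |\mathbf{n}(u_i, v_j)|\Big)^{\alpha}}
\]

evaluated on an \(N_1 \times N_2\) midpoint lattice (poles excluded so
normals are nonzero). \(\nabla I\) is the image gradient precomputed on the
voxel lattice and sampled trilinearly at surface points; \(\mathbf{n}\) is
the analytic cross product \(\partial r/\partial u \times
\partial r/\partial v\), whose magnitude is the area element. The area
normalization with exponent \(\alpha\) keeps \(B\) from growing by mere
surface inflation; values well below 1 are needed because gradients in
low-resolution emission images are too weak to balance the shrinking
tendency of full normalization. The default \(\alpha = 0.7\) and
\(N_1 = N_2 = 36\) are the values used throughout the synthetic study.

**The rectifier \(\delta\).** Normals are first oriented explicitly outward
(flipped where they point toward the surface's centre coefficient point
\((a_{x,0,0}, a_{y,0,0}, a_{z,0,0})\)). For a *hot* object the intensity
falls outward at the true edge, so contributions with
\(\nabla I \cdot \mathbf{n}_{out} < 0\) are kept (entering positively,
\(\delta = -1\)) and wrong-way gradients are discarded (\(\delta = 0\)); a
cold-object flag inverts this. With the explicit outward orientation the
handedness of the \((u, v)\) parameterization becomes irrelevant, which is
why the package resolves \(\delta\) this way. A diagnostic mode forcing
\(\delta \equiv 1\) on the raw (unflipped) normals turns the numerator into
a discrete closed-surface flux; for a spatially constant gradient it
vanishes — exactly for ellipsoids, and at second order in the sampling
density for general coefficient sets — which the test suite uses as a
geometry oracle.

**Initialization.** An order-2 surface (an ellipsoid) is estimated from the
image: Otsu classification inside the initialization VOI, a morphological
closing, retention of the largest connected component, centre of mass as the
centre, principal components of the member-voxel coordinates (the Hotelling
transform) as axis directions, and semi-axis lengths chosen by downhill
simplex to include as many object voxels and as few non-object VOI voxels as
possible (started from \(\sqrt{5}\,\sigma\) along each principal axis, the
exact relation for a uniform solid ellipsoid).

**Optimization.** \(B\) is maximized with the downhill simplex method over
all coefficients, with order escalation \(K = 2 \to 3 \to 4\); appended
coefficients start at zero. Within each order the simplex is re-initialized
from the incumbent until the objective change between consecutive restarts
falls below a relative `1e-3` ("did not change appreciably") or 5 restarts
are reached. The initial simplex perturbs carried-over coefficients by 5% of
the mean initial semi-axis and freshly appended ones by 2%. The returned
surface never scores below its initialization — if the optimizer fails to
improve, the initialization is returned.

**Voxelization.** Candidate voxels (padded bounding box of a dense
\(144 \times 72\) surface sampling) are classified by the sign of
\((\mathbf{x}_{vox} - \mathbf{p}^*) \cdot \mathbf{n}^*\), where
\(\mathbf{p}^*\) is the nearest sampled surface point (found by a
coarse-to-fine search on the sample lattice) and \(\mathbf{n}^*\) its
outward normal — a tangent-plane signed-distance test, first-order accurate
between samples. High-order surfaces can fold, so the raw classification is
repaired: holes are filled and islands disconnected from the centre point
are removed (`solidify()`), using 6-connectivity with the image border
assumed outside. A surface smaller than one voxel yields the single voxel
containing its centre point.

## Quantification

Spill-out is corrected with recovery coefficients measured on sphere
phantoms: the ratio of the concentration estimated inside the true sphere
VOI to the true concentration, as a function of sphere volume. The two-
parameter model

\[ R(V) = \frac{1}{1 + (a/V)^b} \]

is fitted by unweighted least squares (the fitting procedure is a package
choice; positivity of \(a, b\) is enforced by log-parameterization). By
construction \(R\) is increasing, bounded in \((0,1)\), and \(R(a) = 1/2\) —
\(a\) is the half-recovery volume. The concentration estimate is

\[ C = \frac{n}{R(V_{tum})\; \varepsilon\; v_{vox}} \]

with \(n\) the mean count rate per voxel in the VOI, \(\varepsilon\) the
system sensitivity and \(v_{vox}\) the voxel volume. The VOI enters twice —
through \(n\) and through \(R(V_{tum})\) evaluated at the *estimated*
volume — so segmentation volume errors propagate into \(C\) exactly as they
do in practice. The study harness crosses the image used for delineation
with the image measured on (AS/AS, AS/ASR, ASR/ASR) because
resolution-compensated reconstructions recover counts better but delineate
worse.

## Evaluation metrics

Per tumour over \(N\) noise realizations: the relative mean error
\(\bar E = \bar V / V_{ref} - 1\) (trueness), the relative standard
deviation \(\mathrm{rSD}\) with the \(N-1\) denominator (precision), and the
relative root-mean-square error \(\mathrm{rRMSE}\) with the \(N\)
denominator (accuracy). They satisfy
\(\mathrm{rRMSE}^2 = \bar E^2 + \mathrm{rSD}^2 (N-1)/N\) identically, which
the tests verify to `1e-12`.

The Dice similarity coefficient is computed *geometrically*: member voxels
are treated as rectangular cuboids and the overlap volume is the exact
summed intersection of cuboids, obtained by contracting one mask through
three per-axis interval-overlap matrices. This lets masks live on grids with
different spacing and origin (phantom grid vs reconstruction grid); on
identical grids it reduces exactly to voxel-count Dice. Grids with relative
rotation are rejected throughout the package. DSC distributions are
summarized as 50th (10th, 90th) percentiles with the linear-interpolation
convention (R quantile type 7; the convention is a package choice). The DSC
of two empty masks is defined as 0 with a degeneracy flag.

## The phantom simulator

The simulator stands in for Monte Carlo photon transport plus iterative
reconstruction; the segmentation and quantification layers only ever see
reconstructed images, so the emulation reproduces the *image-level* failure
modes at desk scale:

* **piecewise-constant activity maps** with spherical, ellipsoidal or
  "lumpy" tumours (radius modulated by a smooth seeded low-order directional
  perturbation — tumours in such studies are relatively round). Tumours are
  rasterized as exactly the \(N\) voxels closest in normalized radial
  distance, with grid-symmetry ties broken deterministically, so the
  rasterized volume matches the target within one voxel;
* **Gaussian point-spread blur** (separable, kernel truncated at
  \(4\sigma\)) for resolution loss and spill-out;
* **count scaling** folding sensitivity, acquisition time and decay into a
  single expected-counts-per-concentration factor;
* **Poisson noise**, voxel-wise, with a per-realization substream seed so
  every realization is reproducible independently of evaluation order;
* an optional **edge-enhancement overshoot** — the expected image plus
  `edge_enhancement` times the difference between it and a copy blurred
  twice as wide (an unsharp mask) — emulating the high rim values seen in
  resolution-compensated reconstructions. Negative values are clipped to 0
  before the Poisson draw.

What the emulation does **not** contain: photon transport, collimator
response, attenuation and scatter physics, iterative-reconstruction noise
correlations (our noise is voxel-independent Poisson; OS-EM noise is
spatially correlated), anatomical background structure, and pharmacokinetic
time-activity behaviour. Passing tests therefore demonstrate correctness of
the segmentation/quantification machinery and the *directions* of the
classic effects (spill-out shrinks recovery with volume, edge overshoot
shrinks threshold VOIs, noise breaks FT first), not clinical performance.

## Default study conditions

The benchmark configuration (`default_study_config()`) uses three tumours of
2.75, 8.89 and 40.0 cm^3 (a lumpy sphere, an ellipsoid and a larger lumpy
sphere) on a 2.5 mm cubic grid in a 10:1 tumour-to-background concentration
ratio — a typical contrast for somatostatin-receptor imaging. Thirty noise
realizations are generated per condition. Two count levels emulate an early
and a late imaging time point: the early preset puts about \(10^5\) expected
counts in the 40 cm^3 tumour, the late preset 1/50 of that, mimicking the
early/late noise contrast of a long-lived therapeutic radionuclide. Each
preset is imaged AS-like (FWHM 12 mm, no edge enhancement) and ASR-like
(FWHM 8 mm, overshoot amplitude 0.5): resolution compensation narrows the
PSF but adds the edge artefact. Initialization VOIs are the true masks
dilated by 10 mm, created once per tumour and shared across all
realizations, presets and methods. Recovery curves are calibrated per
preset/image type from noise-free sphere phantoms of 1-40 cm^3 centred in a
cold elliptical-cylinder field of view (semi-axes 20 cm and 10 cm).

## Numerical choices

* **Gradient kernels**: 3-D Prewitt-style 3×3×3 operators — the central
  difference along the target axis averaged over the 3×3 transverse
  neighbourhood, normalized so a unit-slope-per-mm ramp yields 1. Borders
  use edge replication, so constant images give exactly zero everywhere.
* **Out-of-grid sampling** returns 0 (count images decay to zero).
* **Connectivity**: 6-connectivity for background flood fill and component
  labelling (a conservative hole definition); the closing structuring
  element is the full 3×3×3 cube. Outside the grid counts as background for
  dilation; erosion does not eat border-touching members.
* **Surface sampling**: midpoint nodes \(u_i = 2\pi i/N_1\),
  \(v_j = \pi (j + 1/2)/N_2\); the v-midpoint rule makes the sampled area of
  a unit sphere accurate to well under 1% at 72×72.
* **Simplex**: R's Nelder-Mead (`stats::optim`) with per-parameter scaling
  to realize the 5%/2% initial perturbations; stage convergence `reltol
  1e-3`, max 3000 evaluations per stage.
* **Nearest-point search** in voxelization: coarse decimation factor 4 on
  the 144×72 lattice, then a local fine window (u wraps, v does not).
* **RC fit**: Nelder-Mead followed by BFGS on `(log a, log b)`, started
  from the interpolated half-recovery volume and \(b = 1\).
* **Ties and degeneracies**: Otsu ties go to the lowest candidate; FT uses
  `>=`; empty VOIs, non-positive maxima, degenerate histograms and
  zero-area surfaces raise errors; a voxelization whose seed lands in the
  background falls back to the raw classification.

## Problem sizes in the shipped tests

The test suite and the acceptance script are sized for a single CPU: the
synthetic images are 32-52 voxels per axis, the benchmark study uses the
three-tumour phantom on a 96×40×40 grid with 30 realizations, and the
Monte-Carlo Dice oracle uses 10^6 points per case. Determinism of the study
pipeline is asserted byte-for-byte on a reduced two-realization instance of
the same code path, and the full benchmark is run once per suite execution.

## Known limitations

* Only axis-aligned grids; no resampling, registration, or DICOM.
* The FS method assumes a single, roughly star-shaped object; surfaces
  cannot split or merge, and strongly non-convex shapes are outside the
  basis' reach at \(K \le 4\).
* The Otsu-based initial ellipsoid inherits Otsu's bias on skewed
  histograms; at very low counts the initial object can be fragmented.
* Recovery correction assumes sphere-like geometry and the calibration
  contrast; shapes with high surface-to-volume ratio will deviate.
* The simulator's Poisson noise is voxel-independent, unlike reconstructed
  SPECT noise; absolute noise-level comparisons with reconstructed data
  should not be made.
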