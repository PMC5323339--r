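# spectseg

Tumour segmentation and activity quantification for quantitative SPECT, aimed
at radionuclide-therapy dosimetry (e.g. ^177^Lu-DOTATATE treatment of
neuroendocrine tumours). Estimating the mean absorbed dose to a tumour
requires its volume and mean activity concentration from SPECT images — both
dominated by two error sources: where the segmentation puts the tumour
boundary, and how much signal the poor spatial resolution has displaced out
of the delineated volume (spill-out). `spectseg` is for physicists and
image-analysis researchers who want to run, compare and stress-test the
standard semi-automatic delineation strategies together with the
recovery-coefficient quantification layer, entirely in R and without access
to Monte Carlo photon-transport simulations or patient data.

## What it implements

Three segmentation methods, all seeded by the same rough initialization VOI
drawn around the object with a margin:

* **FT** — fixed threshold at 42% of the VOI maximum.
* **OM** — modified Otsu: every unique voxel value is a candidate threshold;
  the candidate maximizing the between-class variance
  *w₀w₁(μ₀ − μ₁)²* is chosen (no histogram binning).
* **FS** — a deformable closed surface parameterized by Fourier descriptors,

  *q(u,v) = a₍q,0,0₎ + 2a₍q,0,1₎cos v + 2Σₗ c₍q,0,l₎ sin(lv)
  + 4Σₘₗ [c₍q,m,l₎cos(mu) + d₍q,m,l₎sin(mu)] sin(lv)*,  q ∈ {x, y, z},

  fitted by maximizing the edge strength
  *B = Σᵢⱼ [∇I·n(uᵢ,vⱼ)] δᵢⱼ / (Σᵢⱼ |n(uᵢ,vⱼ)|)^α* with the downhill simplex
  method and order escalation K = 2 → 3 → 4, then voxelized by a
  nearest-surface-point sign test with hole/island repair.

Quantification corrects spill-out with a recovery curve
*R(V) = 1/(1 + (a/V)^b)* fitted to sphere-phantom calibrations, and estimates
the concentration as *C = n / (R(V_tum)·ε·v_vox)*. Evaluation metrics are the
relative mean error, rSD and rRMSE over noise realizations, and a Dice
similarity coefficient computed geometrically from exact cuboid overlaps so
masks on different voxel grids can be compared. A synthetic phantom simulator
(Gaussian PSF blur, count scaling, Poisson noise, optional edge-enhancement
overshoot emulating resolution-compensated reconstructions) drives the whole
study design; `run_study()` reproduces the benchmark end to end from a single
seed. See the methods vignette (`vignettes/spectseg-methods.Rmd`) for models,
defaults and numerical choices.

## Worked example

Build a 20 cm³ lumpy tumour on a 2.5 mm grid, image it with a 12 mm FWHM
PSF and Poisson noise, segment with OM and FS, and quantify with a matched
recovery curve:

```r
library(spectseg)

grid    <- voxel_grid(c(48, 48, 48), spacing = 2.5,
                      origin = c(-58.75, -58.75, -58.75))
tumour  <- tumour_spec(centre = c(0, 0, 0), volume_cm3 = 20, shape = "lumpy",
                       lumpy_amplitude = 0.12, lumpy_seed = 4)
phantom <- build_phantom(phantom_spec(tumour, grid, background = 0.1))
acq     <- acquisition_spec(fwhm_mm = 12, count_scale = 40, seed = 7)
image   <- simulate_reconstruction(phantom$activity, acq, realization_index = 1)
voi     <- make_initialization_voi(phantom$truth$masks[[1]], margin = 10)

om <- otsu_segment(image, voi)
fs <- fs_segment(image, voi)
#> <threshold_result> method OM, threshold 16, 1410 voxels (22.031 cm^3)
#> FS: 1237 voxels, 19.328 cm^3 (true 20.000 cm^3)

dice_cross_grid(om$mask, phantom$truth$masks[[1]])$dsc  # 0.871
dice_cross_grid(fs,      phantom$truth$masks[[1]])$dsc  # 0.943

phs <- rc_phantom(c(1, 2, 5, 10, 20, 40))
cal <- calibration_from_acquisition(acq, grid)
rcs <- sapply(phs, function(p)
  measure_rc(expected_reconstruction(p$activity, acq), p$true_mask, 1, cal))
rc  <- fit_rc_curve(sapply(phs, function(p) p$volume_cm3), rcs)
#> <rc_curve> R(V) = 1 / (1 + (a/V)^b), a = 6.902 cm^3, b = 0.5816

estimate_concentration(image, fs, rc, cal)
#> <concentration_estimate> C = 1.0687 (n = 27.59, V = 19.328 cm^3, R = 0.645)
```

The FS surface recovers the volume to 3% and the true unit concentration to
7% after recovery correction (the residual includes the 10:1 background).
`run_study(default_study_config(seed = 1))` runs the full three-tumour,
30-realization benchmark over early/late count levels and AS/ASR-like image
types and summarizes volume errors, DSC percentiles and concentration errors
in a tidy tibble; `write_study_outputs()` emits `results.csv`, `cases.csv`
and `report.md`.

A thin command-line wrapper lives at `inst/cli/spectseg.R`
(`segment`, `compare-masks`, `calibrate-rc`, `quantify`, `run-study`).

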