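# conemosaic

Quantification of the cone photoreceptor mosaic and agreement analysis
between retinal imaging modalities, in R.

High-resolution ophthalmoscopes resolve individual cone photoreceptors,
and the spatial statistics of the resulting point pattern — cone density
and spacing — are sensitive biomarkers of retinal health. When the same
retina is imaged by two devices (say, a research-grade adaptive-optics
scanning light ophthalmoscope and a clinical high-magnification
scanning-laser module) or marked by two graders, the question becomes:
*do the numbers agree?* This package implements the full measurement and
agreement chain for that question, plus a synthetic-data generator and an
in-silico study runner so every stage is testable without patient images.

## What it computes

For cone coordinates in a co-localized region of interest (ROI, default
200 × 200 µm):

- **Bound Voronoi cone density** — cells of the Voronoi tessellation that
  are finite and lie entirely inside the ROI; density = n_bound / Σ(bound
  cell areas). On a hexagonal lattice of spacing *s*:
  *d* = 2/(√3 · s²), so 10 µm spacing ⇔ 11,547 cones/mm².
- **NND** — mean nearest-neighbor distance over points inside the ROI.
- **ICD** — mean distance to Voronoi (Delaunay) neighbors over bound
  cells. NND ≤ ICD always.

Image scale from ocular biometry:

- angular scan: scale = (θ/I_s) · RMF · (AL/24), with RMF = 291 µm/deg
  for a 24 mm schematic eye;
- Ronchi-calibrated scanner: scale = T/(f₁·T_s) · (180/π) · RMF · (AL/24).

Agreement statistics: one-way random-effects ICC
(MSB−MSW)/(MSB+(k−1)MSW) with the Searle F-based 95% CI; Bland-Altman
bias ± 1.96·SD limits of agreement with CIs; percent bias
100·bias/grand-mean; OLS regression of paired differences on covariates;
and closed-form minimum-detectable-difference power calculations.

Image processing: FFT translational frame registration with subpixel
peak interpolation, quality-ranked frame averaging, and
difference-of-Gaussians cone detection with greedy non-maximum
suppression and manual add/remove edits.

## Worked example

```r
library(conemosaic)

# image scale for an 8-degree, 768-pixel scan of a 24.31 mm eye
g <- scan_geometry(theta = 8, i_s = 768, al = 24.31)
print(g)
#> scan geometry: 8 deg / 768 px, AL 24.31 mm (RMF 291 um/deg @ 24 mm)
#>   scale: 3.07040 um/px

# a synthetic mosaic at the parafoveal density scale, and its metrics
mos <- generate_mosaic(12375, field_size = c(240, 240), jitter_sd = 1.1, seed = 7)
print(mos)
#> cone mosaic: 686 cones in 240 x 240 um (nominal 12375 cones/mm^2, s = 9.66 um)
#>   jitter 1.10 um, dropout 0.00, seed 7

mosaic_metrics(mos$points, roi(origin = c(20, 20)),
               grader = "grader1", modality = "AOSLO", roi_id = "P01_superior")
#> mosaic metrics [P01_superior/AOSLO/grader1]
#>   bound density: 12360 cones/mm^2 (446 bound / 490 in ROI)
#>   NND 7.79 um, ICD 9.79 um
```

The bound density recovers the nominal 12,375 cones/mm² within 0.2%
despite 1.1 µm positional jitter; jitter pulls the mean NND (7.79 µm)
below the lattice spacing while the ICD (9.79 µm) stays near it.

A full simulated two-device, two-grader study:

```r
res <- run_study(study_config(seed = 11))
print(res)
#> in-silico study: 24/30 analyzable participants, 48 ROIs
#>   inter-device bound_density: bias 3159.70 (23.5%)
#>   inter-device nnd: bias -0.24 (-3.5%)
#>   inter-device icd: bias -1.21 (-12.6%)
```

The configured 24.1% symmetric density deficit for the second modality is
recovered as a 23.5% Bland-Altman percent bias on this single replicate;
`res$intergrader` holds per-modality ICC and Bland-Altman results, and
`res$interdevice$*$vs_eccentricity` the difference-vs-eccentricity
regressions.

`verify_paper_arithmetic()` recomputes the headline summary arithmetic of
the device comparison (spacing biases from modality means, density
percent bias, success rate, detectable difference) from bundled printed
inputs and reports pass/fail per check.

A thin CLI over the same functions is installed at
`inst/scripts/conemosaic.R` (subcommands `scale`, `metrics`, `detect`,
`run-study`, `verify`).

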