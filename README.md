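# sfamuscle

Spatial frequency analysis (SFA) of B-mode ultrasound images of skeletal
muscle, with the reliability-statistics toolkit needed to validate such
measurements, and a ground-truth phantom simulator.

## The problem

Longitudinal B-mode scans of healthy muscle show a quasi-periodic
light–dark banding: hypoechoic muscle fascicles separated by hyperechoic
perimysium. Ordinary grayscale statistics (echo intensity, histogram
moments) ignore this spatial organisation. SFA quantifies it directly in
the frequency domain: every admissible square kernel inside a polygonal
region of interest (ROI) is zero-padded, Fourier transformed, highpass
filtered, and summarised by four parameters which are then averaged over
all kernels of the ROI:

| Parameter | Definition | Tissue meaning |
|---|---|---|
| PSFR | √(u²ₘₐₓ + v²ₘₐₓ), radius (mm⁻¹) of the largest non-DC magnitude of F(u,v) | dominant band spacing (its reciprocal, in mm) |
| Mmax | max F(u,v) | strength of the dominant banded pattern |
| Mmax % | 100 · Mmax / Σ F(u,v) | band prominence against total spectrum |
| Sum | Σ F(u,v) | overall spectral magnitude ≈ image brightness |

Defaults follow the established muscle protocol: 96 × 96 px kernels
(6.6 mm at 0.06875 mm/px), zero-padding to 128 × 128, overlapping kernels
at stride 1, fully-contained-in-ROI admissibility, and a radially
symmetric order-2 Butterworth highpass with −3 dB cutoff at 1.0 mm⁻¹ to
suppress low-frequency artefacts.

Because such measurements only matter if they are repeatable, the package
also implements the reliability toolkit used to validate them:
two-way-ANOVA intraclass correlation coefficients (consistency and
absolute agreement, with F-based 95% CIs and poor/moderate/good/excellent
banding at 0.5/0.75/0.9), Sørensen–Dice mask overlap, standard error of
measurement (SEM = √MS_E, SEM% against the grand mean), paired t tests,
and ICC-based sample-size planning. A seeded speckle-phantom generator
with known band frequency and a ratings simulator with known true ICC
give every statistic a ground-truth test surface.

## Worked example

```r
library(sfamuscle)

# a phantom with banding at 0.75 mm^-1 (one band every 1.33 mm)
spec <- phantom_spec(band_freq = 0.75, band_contrast = 0.6, seed = 42)
ph   <- generate_phantom(spec)
mask <- rasterize_roi(ph$roi, dim(ph$image$pixels))
analyze_roi(ph$image, mask, sfa_config())
#> <sfa_parameters> PSFR 0.7955 mm^-1 | Mmax 154912 | Mmax% 1.275 | Sum 1.22822e+07 (169 kernels)
```

The recovered PSFR (0.80 mm⁻¹) is within one frequency bin
(1/(128 · 0.06875) = 0.114 mm⁻¹) of the generator's 0.75 mm⁻¹; its
reciprocal, 1.26 mm, is the dominant band spacing the phantom was built
with. Mmax and Sum are in arbitrary spectral units (machine-dependent in
real scans); Mmax % says the dominant band carries ~1.3% of the total
spectral magnitude.

```r
# reliability of a simulated test-retest experiment (true ICC = 0.8)
tb <- generate_ratings(ratings_spec(subject_sd = 2, error_sd = 1, seed = 7),
                       parameter = "psfr")
icc(tb, form = "absolute_agreement", model = "two_way_mixed")
#> ICC(A,1), two-way-mixed = 0.878 [0.605, 0.968] (good)
s <- sem(tb); c(s$sem, s$sem_pct)
#> SEM = 0.829, SEM% = 0.8%
icc_sample_size(0.75, 0, 0.05, 0.80, 2)
#> [1] 10
```

## Command line

An `Rscript` wrapper is installed under `exec/sfa`; equivalently call
`sfamuscle::sfa_cli(c(...))`:

```sh
sfa simulate --type phantom --out-prefix ph --seed 1
sfa analyze --images 'ph.png' --rois 'ph.roi.json' --out results.csv
sfa reliability --ratings ratings.csv --protocol test_retest --out report.csv
sfa samplesize --rho-alt 0.75 --rho-null 0 --alpha 0.05 --power 0.80 --k 2
```

Every results file gets a YAML sidecar with the fully-resolved
configuration; all commands are deterministic given config + seed.

## Layout

- `R/` — image/ROI/ratings I-O, SFA core, reliability statistics,
  synthetic generators, CLI.
- `vignettes/sfa-methods.Rmd` — model, parameter and design notes.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
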