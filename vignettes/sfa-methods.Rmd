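---
title: "Spatial frequency analysis of muscle ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial frequency analysis of muscle ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfamuscle)
```

## The measurement model

Longitudinal B-mode images of healthy skeletal muscle exhibit a
quasi-periodic banding — hypoechoic fascicles separated by hyperechoic
perimysium — superimposed on speckle. `sfamuscle` quantifies that
organisation in the spatial frequency domain. For a polygonal ROI drawn
inside the muscle belly, the pipeline is:

1. rasterize the ROI to a boolean mask (pixel centers, even-odd rule,
   boundary inclusive);
2. enumerate every kernel of `kernel_px × kernel_px` pixels (default 96,
   i.e. 6.6 mm at the default 0.06875 mm/px spacing) whose square lies
   *entirely* inside the mask, on a stride grid (default stride 1 = all
   possible overlapping kernels);
3. zero-pad each kernel to `pad_px × pad_px` (default 128) and take the
   modulus of the unnormalised 2-D DFT, with physical frequency axes
   u (lateral) and v (axial) in mm⁻¹ derived from the per-axis pixel
   spacing — anisotropic spacing is supported, the default case is
   square pixels;
4. multiply by a radially symmetric Butterworth highpass
   |H(r)|² = 1/(1 + (c/r)^(2m)) with cutoff c = 1.0 mm⁻¹ and order
   m = 2, so that the squared gain at the cutoff is exactly 1/2
   (−3.0103 dB) and the DC bin is nulled;
5. extract four parameters per kernel — PSFR (radius of the largest
   non-DC magnitude), Mmax (that magnitude), Mmax % (100·Mmax/Sum), and
   Sum (total magnitude over all bins) — and average each arithmetically
   over all kernels of the ROI.

### Assumptions

* The banding of interest lives between the highpass transition and
  Nyquist; muscle PSFR values around 0.7–0.9 mm⁻¹ sit just below the
  1.0 mm⁻¹ cutoff, which is why a *low-order* (soft-shouldered) filter
  is used — a sharp filter would crush them.
* Spectral magnitudes (Mmax, Sum) are in arbitrary units that depend on
  machine settings and the DFT normalisation; only their ratios and
  their reliability across repeated measurements are interpretable.
  Intensity linearity is exact: scaling all pixels by c scales Mmax and
  Sum by c and leaves PSFR and Mmax % unchanged (tested).
* Full-containment kernel admissibility deliberately excludes kernels
  touching the ROI boundary so that bright aponeurosis edges cannot leak
  into the spectra.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `kernel_px` | 96 | px | spans ≈ 6.6 mm, several fascicle bands, at the default spacing |
| `pad_px` | 128 | px | frequency bin width 1/(128·spacing) ≈ 0.114 mm⁻¹; finer sampling of the peak |
| `stride_px` | 1 | px | "all possible" overlapping kernels; raise for speed on large ROIs |
| `hp_cutoff` | 1.0 | mm⁻¹ | attenuates beam-profile / TGC shading while keeping muscle-band peaks visible |
| `hp_order` | 2 | — | soft transition; order-2 gain at half cutoff is 1/√17 ≈ 0.24 |
| pixel spacing | 6.6/96 ≈ 0.06875 | mm/px | the value implied by a 96 px kernel spanning 6.6 mm; override per acquisition, DICOM-style metadata is not available in PNG/PGM |

## Numerical choices

* **Zero-padding position.** The kernel occupies the top-left corner of
  the padded array with trailing zeros; the magnitude spectrum is
  invariant to this placement (a spatial shift only changes phase).
* **Peak search.** The DC bin is excluded; exact ties are broken first
  by smaller radius, then by row-major bin order, making the reported
  PSFR deterministic. Conjugate-symmetric pairs give identical radii by
  construction.
* **Sum domain.** All `pad_px²` bins after filtering, DC included (the
  filter has nulled it). Absolute magnitudes are normalisation-dependent
  anyway; Mmax % is invariant to the choice.
* **Degenerate spectra.** An all-zero (filtered) spectrum returns all
  parameters 0 with a `degenerate` flag; PSFR is defined as 0 there.
* **Rasterization.** Pixel centers sit at integer 0-based coordinates
  (x = column, y = row); containment is tested with an even-odd rule,
  boundary inclusive, and verified against an independent exhaustive
  point-in-polygon oracle in the tests.
* **ICC confidence intervals.** Consistency form: exact F interval.
  Absolute agreement: the standard Satterthwaite-df construction. For
  strongly negative estimates in tiny samples these formulas are
  undefined; the package then reports `NA` bounds rather than `NaN`
  (reference implementations behave identically, which was verified
  against an independent tool during development).
* **Paired t degeneracies.** Zero-variance differences are flagged:
  all-zero gives t = 0, p = 1; constant nonzero gives ±Inf, p = 0.

## Reliability statistics: design choices

* **ICC labelling.** The muscle-SFA literature labels its mixed-model
  absolute-agreement ICC "ICC(3,1)", although under the Shrout–Fleiss
  convention ICC(3,1) is the *consistency* form. To avoid that
  ambiguity, `icc()` takes explicit `form` and `model` arguments and
  every result carries a label such as `ICC(A,1), two-way-mixed`. For
  single-rater point estimates the random/mixed distinction affects only
  the label. The CLI protocols map: intra-rater and test-retest →
  mixed/absolute-agreement; inter-rater → random/consistency.
* **Reliability bands.** poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤
  excellent. The conventional inequalities are open on both sides at the
  thresholds; estimates exactly on a threshold are assigned the higher
  band, a deterministic rule stated here once.
* **SEM.** √MS_E from the two-way table; SEM% divides by the grand mean
  of all cells (for a two-trial table, the mean of the two trials). A
  zero grand mean flags SEM% as undefined.
* **Sample size.** The ANOVA-F/log construction
  n = 1 + 2k(z₁₋α/2 + z_power)²/((k−1)(ln C₀)²),
  C₀ = (1 + kρ₀/(1−ρ₀))/(1 + kρ₁/(1−ρ₁)), with two-sided α, rounded up.
  With ρ₁ = 0.75, ρ₀ = 0, α = 0.05, power 0.80, k = 2 it yields 10
  subjects. Precision/assurance-style variants of ICC planning exist;
  the hypothesis-test form is used because it is the classical
  construction for testing an ICC against a null value and reproduces
  standard planning numbers with these inputs.
* **No multiplicity correction** is applied to paired t tests; reports
  are per parameter × group.

## What the synthetic generators do and do not emulate

`generate_phantom()` builds a multiplicative speckle field — an
exponential-intensity envelope smoothed by a Gaussian point-spread
function of `speckle_scale` (default 0.3 mm, the resolution-cell scale
of a 2–10 MHz linear array) — modulated by
1 + contrast·cos(2π·f·s) along the band normal, clipped at zero, with a
rectangular ROI inset one kernel from the image edges. This reproduces
the *first-order* statistics that matter for SFA: speckle with a
controllable correlation length plus a banded pattern of known frequency,
orientation and depth. It does **not** model beam physics (no Field-II
style acoustics), log compression, attenuation/TGC, fascicle curvature or
pennation, out-of-plane decorrelation, or anisotropic speckle. A green
PSFR-recovery test therefore establishes that the spectral pipeline
measures what the generator injected — not that any particular scanner
produces unbiased PSFR in vivo.

`generate_ratings()` draws y_ij = μ + b_i + r_j + e_ij with independent
normal components, so the true consistency ICC σ_b²/(σ_b² + σ_e²) is
known exactly. Every generator takes an explicit seed and restores the
caller's RNG state; there is no hidden global randomness.

### A note on ICC recovery at small n

For n = 10 subjects, k = 2 raters and true consistency ICC 0.8, the
single-rater estimator is (9F − 1)/(9F + 1) with F ~ F(9, 9). Its exact
expectation (by quadrature, computed in the tests) is 0.76509 — a
small-sample downward bias of 0.035, while its median is exactly 0.8.
Recovery tests that compare a Monte Carlo *mean* of estimates against the
true value must therefore either use a band wider than the bias or
compare against the exact expectation; the test suite does the latter for
the defensible check and documents the former where a fixed wider band is
asserted.

## Known limitations

* Image input is PNG (8-bit write, 8/16-bit read) and plain PGM
  (bit-exact 8/16-bit); TIFF and DICOM are not read, so pixel spacing
  must be supplied by the caller.
* Absolute Mmax/Sum values are not comparable across DFT normalisations
  or machines; only ratios and within-protocol reliability are.
* `analyze_roi()` at stride 1 computes one 128×128 FFT per admissible
  kernel; very large ROIs (tens of thousands of kernels) are better run
  with a modest stride, which changes the kernel sample but not the
  estimand.
* The Butterworth family/order of the highpass is a documented choice;
  only the −3 dB point is anchored by the measurement convention, and
  both are configurable.
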