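---
title: "Nuclear morphometry, chromatin condensation and traction microscopy: methods and design"
author: "nucmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucmorph)
```

This vignette is the package's own account of what it computes, which
assumptions it makes, and why the open design choices were settled the way
they were. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The measurements

## Boundary invaginations from signed curvature

A nucleus imaged in a spread cell is, to first order, an ellipse in its
focal plane. Traction-force imbalance indents its outline. We
operationalise an *invagination* as a contiguous arc of the boundary
contour with sufficiently negative signed curvature:

1. The DAPI channel is smoothed (Gaussian, σ = 1 px), Otsu-thresholded,
   hole-filled and labelled; border-touching and sub-minimum components
   are removed (`segmentNuclei()`).
2. The 0.5 iso-contour of the smoothed binary mask is traced by marching
   squares, giving subpixel vertices, then resampled to uniform arc-length
   spacing (0.5 px by default) and oriented counterclockwise
   (`extractContour()`).
3. Contour coordinates are smoothed by a *periodic* Gaussian of physical
   scale σ = 0.4 µm, re-resampled to uniform arc length (smoothing
   contracts high-curvature segments, and both the central-difference
   formulae and the turning-number identity assume |dp/ds| = 1), and
   κ = (x′y″ − y′x″)/(x′²+y′²)^{3/2} is evaluated by central differences
   (`curvatureProfile()`).
4. Maximal runs with κ < −κ_min, merged across the start/end seam and at
   least L_min long, are invagination calls (`detectInvaginations()`).

**Sign convention.** With counterclockwise orientation, positive κ is
locally convex. "Negative curvature at the outer edge" is then literally
an inward indentation. The discrete total turning Σκ·Δs equals 2π for
every simple closed contour; the tests assert this within 1 % on every
phantom family, which guards the whole chain (segmentation → contour →
resampling → differentiation) at once.

**Thresholds.** No published threshold exists for "invaginated", so the
defaults are explicit and size-scaled: κ_min = 0.25/R_eq (R_eq = √(A/π)),
L_min = 2 % of the perimeter. Scaling by R_eq makes the call invariant
under magnification changes (tested). The defaults were calibrated once
so that convex phantoms at the benchmark noise level produce zero false
positives; both are config-overridable.

## Wrinkle scoring

Wrinkles are folds of the nuclear surface, visually distinct from
boundary invaginations; in 2D micrographs they appear as dark ridge lines
crossing the nuclear interior (most visible in a lamin stain). The
detector (`wrinkleScore()`):

- smooths the shell channel at the ridge scale (σ = 0.25 µm),
- forms the Hessian by finite differences and takes the larger
  eigenvalue, which is positive over dark valley lines (units converted
  to intensity/µm²),
- applies hysteresis thresholding (high 1.0, low 0.4) and Zhang–Suen
  thinning, and
- reports ridge-centerline length per unit nuclear area (µm/µm²), plus a
  binary "wrinkled" call at a density threshold (default 0.02 µm/µm²)
  calibrated on ridge-free vs ridged phantoms. The binary call is an
  explicit operationalisation, not a claim of equivalence with visual
  scoring.

The nuclear rim is itself a strong curvature feature at the detection
scale, so the scored region is the mask eroded by a *physical* margin
(default 1.0 µm ≈ 3σ of the combined rim/detection scale). A fixed 2 px
margin was tried first and leaves the rim's inner tail inside the scored
region, roughly doubling the measured density on phantoms; the physical
margin removes that bias and scales correctly across magnifications. The
ground-truth ridge length of the generator is reported inside the same
eroded region, so recovery is compared like-for-like.

## Chromatin condensation parameter (CCP)

Condensed chromatin produces bright foci and dark "free space" inside the
nucleus, i.e. visible internal edges. CCP is the number of in-mask Sobel
edge pixels divided by the nuclear cross-sectional area in pixels —
a dimensionless density in [0, 1], higher = more condensed, less
accessible chromatin.

- The 3×3 Sobel kernels are unnormalised (a vertical step of height h
  peaks at 4h).
- The convolution runs on the in-mask region with replicate padding at
  the mask boundary (out-of-mask pixels filled from the mean of their
  defined 8-neighbours, two passes — enough for the 3×3 support), so the
  nuclear rim does not register as edge.
- The gradient threshold rule is explicit and logged: Otsu on the
  in-mask gradient histogram (default; an in-package masked-histogram
  Otsu, since whole-image implementations cannot restrict to the mask),
  a fixed fraction of the in-mask maximum, or an absolute cutoff. The
  relative rules make CCP exactly invariant under affine intensity
  rescaling aI + b (a > 0).
- Because the normalisation is per pixel, CCP is resolution-dependent:
  compare values only at a fixed pixel size (logged with every result).

One caveat surfaced during development: "blurring can only suppress
edges" holds at a *fixed* absolute cutoff but not under the adaptive
rules, which re-adapt to the blurred gradient histogram and can classify
more pixels as edges. The suppression property is therefore tested with
the original image's Otsu cutoff held fixed.

## 3D geometry, shape and intensity readouts

Volume = voxel count × voxel volume; area = the largest single-plane
cross-section; height = occupied z-extent ((z_max − z_min + 1) × z-step).
Height-by-extent was chosen because no operational definition is
standard; it is one z-step quantised, which the tests acknowledge.
Spreading area, aspect ratio and orientation come from second central
moments (with the 1/12 px² pixel-variance correction). Mean intensity
supports optional background subtraction (histogram mode of the
out-of-mask pixels) — opt-in, since relative intensities are often
reported uncorrected. The nucleocytoplasmic ratio is mean in-nucleus over
mean in (cell − nucleus); the positive fraction is the strict exceedance
fraction.

## Traction force microscopy

The TFM chain is: drift alignment → PIV → FTTC → per-cell summary.

**Drift** (`alignDrift()`): phase correlation locates the integer shift
robustly; the subpixel part comes from a 3-point Gaussian fit on the
*raw* cross-correlation surface (the phase-correlation peak is a
Dirichlet kernel whose side lobes break log-Gaussian fitting).

**PIV** (`pivDisplacement()`): zero-mean normalised cross-correlation per
interrogation window (default 32 px, 50 % overlap). The displaced window
is then re-read at the integer peak and the correlation repeated until
the residual integer peak vanishes (iterative window offset), which
removes in-plane-loss bias and makes uniform integer displacements
recover exactly. Subpixel refinement evaluates the correlation surface at
fractional lags by matrix DFT (0.02 px grid, parabolic polish) — a
3-point Gaussian fit was tried first and shows classic peak-locking near
half-pixel shifts. Vector quality is the primary/secondary peak ratio;
low-quality vectors are replaced by the median of their neighbours and
flagged. The remaining subpixel error at realistic bead densities
(0.02/px², ~20 beads per window) is dominated by the cross-bead
correlation background, ~0.09 px RMS.

**FTTC** (`fttcTraction()`): in Fourier space the Boussinesq elastic
half-space relates surface displacement and traction by u(k) = G(k)·T(k)
with

    G(k) = 2(1+ν)/(E k³) · [ (1−ν)k² + ν k_y²,  −ν k_x k_y
                              −ν k_x k_y,        (1−ν)k² + ν k_x² ]

The inverse applies the zeroth-order Tikhonov filter
(G² + λ²I)⁻¹G per wavevector (G is symmetric, so this is a closed-form
2×2 solve), sets the zero-frequency component to zero (no net force — a
physical constraint of a cell on a substrate), and transforms back.
ν defaults to 0.5, the incompressible-polyacrylamide convention; E is a
user input (gels of 2–40 kPa are typical).

**Regularisation selection.** λ can be fixed, chosen by the L-curve
corner (Menger curvature over a 20-point log grid, flat tail excluded),
or by generalized cross-validation computed exactly from the per-mode
filter factors. On gridded spectral inversions the finite Nyquist bounds
the solution norm, which flattens the L-curve's vertical branch and makes
the corner under-select λ by about a decade; GCV lands near the
oracle-optimal λ on noisy phantom round trips and is the recommended
automatic choice. Both selectors log the chosen λ.

**Grid and windowing.** R's mixed-radix FFT handles any grid size, so the
displacement field is inverted on its own grid without interpolation to a
power of two. A Hann taper is available (`window = "hann"`) for fields
that do not decay inside the field of view, but is off by default because
it biases reconstructed magnitudes.

## Cohort statistics

`conditionFractions()` reports, per condition, the pooled fraction of
invaginated/wrinkled nuclei *and* the mean ± SD of per-replicate
fractions — cohort sizes like "n = 50 over 3 technical replicates" are
ambiguous about pooling, so both summaries are always emitted (they
coincide for equal-sized identical replicates; tested).
`anovaTukey()` wraps `stats::aov` + `stats::TukeyHSD`, with the
conventional star thresholds (0.05, 0.01, 0.001, 0.0001). The degenerate
all-groups-identical-and-constant case is reported as F = 0, p = 1 (the
raw 0/0 would otherwise surface numerical noise). The test suite checks
the implementation against hand-computed sums of squares and
`ptukey` to 1e-8 and calibrates the null type-I error over 5,000
simulations.

# The phantom generator

All tests run on synthetic images with exact ground truth
(`makeNucleusPhantom()`, `makeCohort()`, `makeTfmPair()`).

**Boundary.** r(θ) = r_ellipse(θ) − depth·R_eq·bump(θ), where each lobe
is a cosine bump (1 + cos 2πu/w)/2 of angular width w (default 1.1 rad).
For the documented depth/width ranges each lobe produces exactly one
contiguous negative-curvature arc, verified analytically on a dense polar
grid (8,192 samples, closed-form radius, high-resolution differences) —
this is the analytic oracle the detector is scored against. Overlapping
lobes and pinching depths are rejected. Rasterisation antialiases the
boundary over one pixel, which is what gives segmentation its subpixel
contour accuracy.

**Chromatin texture.** `makeCondensationTexture(level)` draws
round(60·level) bright Gaussian foci (σ 0.3 µm) with amplitude growing in
level, plus round(15·level) dark voids (σ 0.4 µm). Foci positions for
lower levels are a prefix of the draw at higher levels (nested design at
fixed seed), so the internal edge density increases strictly with level —
the monotonicity contract that calibrates CCP. At the default nuclear
size the pooled CCP–level Spearman ρ across 10 levels × 20 seeds exceeds
0.95; at much smaller nuclei the foci crowd and merge, which flattens the
high end of the curve — the calibration curve is defined at the default
geometry.

**Wrinkles.** Dark Gaussian-profile valleys (depth 0.4, σ 0.25 µm) along
straight chords of the interior, in the lamin-like shell channel; a 2D
projection stands in for the true 3D upper surface because wrinkles are
scored from 2D micrographs. Chord parameters are drawn nested (first k of
a fixed panel of 8), so ridge length grows strictly with the requested
count. Ground truth records the centerline segments and their length
inside the same eroded region the detector scores.

**Noise.** Poisson shot noise (gain = photons per intensity unit) plus
additive Gaussian read noise. Both are off by default so the generator
can serve as an exact oracle; the package's stated benchmark condition
for detector performance (used by the cohort generator and the
sensitivity/specificity benchmark) is Gaussian sd 0.02 of the unit
dynamic range plus Poisson gain 200 — chosen once as a realistic
mid-range SNR for stained nuclei, before the benchmarks were run.

**Beads.** Rendered at subpixel centers via the pixel-integrated Gaussian
profile (σ 1 px, density 0.02/px²), displaced by the spectrally computed
Boussinesq forward solution of mean-subtracted Gaussian traction patches.
The same forward operator underlies the FTTC inverse, so forward–inverse
round trips on the *same* grid are exact by construction; the tests
therefore simulate forward on a 256² pixel grid and invert on a 4×
coarser sampled grid, making the round trip a genuine discretisation +
inversion test.

**What the phantoms do not emulate:** optical PSF blur and spectral
bleed-through, intensity vignetting, touching nuclei, mitotic figures,
out-of-focus texture. Passing tests demonstrate correctness of the
computations under the stated image-formation model, not robustness to
every real-microscope artefact; the explicit thresholds exist precisely
so users can recalibrate on their own data.

# Problem sizes and numerical choices

The test suite and the acceptance script use: 200-phantom
invagination benchmarks (four depth classes), 10 × 20 CCP calibration
curves, 256² TFM fields with 64² or 32² inversion grids, 5,000-run ANOVA
null calibrations, and 150-nucleus cohorts (50 × 3 replicates) — sizes
chosen so the full suite completes in a few minutes on one CPU while
keeping binomial/Monte-Carlo noise well inside the asserted tolerances.

Other numerical decisions worth knowing:

- Canonical axis order is `(y, x, channel, z)` with 0-based pixel
  indices and centers on integers: R arrays are column-major and
  matrices index as [row = y, col = x], so this is the order in which a
  channel plane *is* a plain R matrix. One fixed convention prevents
  curvature/PIV sign errors; accessors (`getChannel()`) hide the layout.
- The baseline TIFF writer cannot embed resolution tags, so `writeImage()`
  emits a JSON sidecar (`<path>.meta.json`) with pixel size, z-step,
  channel names and the intensity scale; `readImage()` prefers embedded
  resolution tags, then the sidecar, then falls back to 1.0 µm/px with a
  warning rather than failing — phantoms are self-calibrated and a hard
  failure would block otherwise-valid pipelines.
- Images are stored as 32-bit float TIFF scaled into [0, 1]; the scale is
  recorded and undone by `readImageScaled()`.
- Contour extraction refuses masks touching the image border (no closed
  iso-contour exists); segmentation excludes such nuclei by default, the
  standard practice for per-nucleus morphometry.
- Ties and degenerate inputs: blank images yield an empty segmentation
  with a warning (not an error); zero-variance ANOVA groups are handled
  as described above; `positiveFraction` uses strict exceedance.

# Known limitations

- Watershed splitting of touching nuclei is off by default; the intended
  inputs are isolated spread-cell nuclei.
- Wrinkle and invagination binary calls depend on explicit thresholds;
  defaults are phantom-calibrated, not biologically canonical.
- CCP is magnification-dependent by construction; only within-experiment
  comparisons at fixed pixel size are meaningful.
- TFM is 2D (in-plane) on a semi-infinite substrate: no finite-thickness
  correction, no 3D traction, no force-at-adhesion (BEM/TRPF) variant.
- The statistics module implements one-way ANOVA + Tukey; replicate
  structure is reported, not modelled (no mixed effects).
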