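# nucmorph

Quantitative image analysis of cell-nucleus mechanics readouts in
fluorescence microscopy, for cell-mechanics and mechanobiology labs that
score nuclear deformation, chromatin condensation and cellular traction
from standard widefield/confocal data.

When the intracellular force balance changes — myosin II inhibition, soft
substrates, actin-cap disruption, LINC-complex knockdown — the nucleus
deforms in two distinct ways: boundary **invaginations** (inward
indentations of the nuclear outline) and surface **wrinkles** (fold/ridge
structures on the upper nuclear surface). Both correlate with chromatin
condensation and hence transcriptional accessibility. This package turns
those readouts into reproducible, threshold-explicit computations:

- **Segmentation & contours** — Otsu segmentation of the DAPI channel,
  subpixel boundary contours (marching squares at the 0.5 level of a
  smoothed mask), uniform arc-length resampling, counterclockwise
  orientation.
- **Curvature & invagination calling** — signed curvature
  κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2} along the contour; an invagination
  is a contiguous arc with κ < −κ_min (default κ_min = 0.25/R_eq, with
  R_eq the equivalent-area radius) of length ≥ 2 % of the perimeter. For
  any simple contour Σκ·Δs = 2π, which the package verifies continuously.
- **Wrinkle scoring** — Hessian ridge detection at a configured scale on
  the lamin-like channel, hysteresis thresholding, skeletonization;
  reported as ridge-centerline length per unit nuclear area (µm/µm²).
- **CCP (chromatin condensation parameter)** — Sobel edge pixels inside
  the nucleus divided by the nuclear cross-sectional area in pixels; a
  dimensionless density in [0, 1], higher = more condensed chromatin. The
  gradient threshold rule (Otsu on the in-mask gradient, fraction-of-max,
  or fixed) is explicit and logged.
- **3D geometry and intensity readouts** — nuclear volume, largest
  cross-section area, z-extent height; spreading area, aspect ratio,
  orientation from second moments; mean intensities, nucleocytoplasmic
  ratios, positive-cell fractions.
- **Traction force microscopy** — phase-correlation drift alignment;
  particle image velocimetry with iterative window offsetting and
  upsampled-correlation subpixel refinement; Fourier-transform traction
  cytometry (FTTC) inverting the Boussinesq half-space Green tensor
  u(k) = G(k)·T(k) with zeroth-order Tikhonov regularisation
  (λ fixed, L-curve, or GCV-selected).
- **Synthetic phantoms with exact ground truth** — lobed-ellipse nuclei
  (each cosine-bump lobe yields exactly one negative-curvature arc),
  ridge folds, chromatin texture with a documented level-to-edge-density
  mapping, and bead image pairs displaced by a known traction field — so
  every stage of the pipeline is testable without microscope data.
- **Cohort statistics** — per-condition invaginated/wrinkled fractions
  (pooled and per-replicate), one-way ANOVA with post hoc Tukey HSD and
  the conventional significance stars.

## Worked example

```r
library(nucmorph)

spec <- PhantomSpec(nInvaginations = 2L, invaginationDepth = 0.3,
                    nWrinkles = 3L, condensationLevel = 0.5, seed = 42L)
ph <- makeNucleusPhantom(spec)
ph$image
#> ImageStack: 160 x 200 px, 3 channel(s) [DAPI, lamin, marker], 1 plane(s)
#>   pixel size 0.1 um

measureNuclei(ph$image)
#>   invaginated nInvaginations wrinkled ridgeLengthDensity areaUm2 aspectRatio orientationDeg    ccp
#> 1        TRUE              2     TRUE             0.2706  135.54      1.2947        16.1542 0.2115
```

The detector recovers both generated lobes and the wrinkle folds; the
ridge-length density of 0.27 µm/µm² sits within 20 % of the generated
centerline density, and the CCP of 0.21 reflects the mid-level chromatin
texture. Condition-level comparisons use the same machinery the paper
workflows use:

```r
set.seed(1)
vals <- c(rnorm(15, 10, 1), rnorm(15, 12, 1), rnorm(15, 10.5, 1))
fit <- anovaTukey(vals, rep(c("control", "blebbistatin", "nocodazole"),
                            each = 15))
#> F = 20.54, p = 6.00e-07 (****)
fit$tukey[, c("pair", "pAdj", "stars")]
#>                      pair         pAdj stars
#> 1    control-blebbistatin 7.001406e-07  ****
#> 2 nocodazole-blebbistatin 1.048587e-04   ***
#> 3      nocodazole-control 2.851698e-01    ns
```

See `vignettes/nucmorph-methods.Rmd` for the full model description,
parameter defaults and design rationale.

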