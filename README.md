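# coce — compression optical coherence elastography of colorectal tissue

Targeted biopsy during colonoscopy needs a way to find the stiffest, most
malignant part of a tumour *before* sampling it. Compression optical
coherence elastography (C-OCE) answers this by compressing the tissue
through a pre-calibrated silicone reference layer while recording a series
of complex-valued OCT B-scans, and mapping the local **tangent Young's
modulus** at a standardized applied stress. In colorectal tissue the
stiffness ranges separate morphology directly: mucosa/adenoma are tens of
kPa, tumour stroma spans 92–515 kPa, glandular (gland-like) cancer
520–950 kPa, and non-glandular high-grade cancer exceeds 950 kPa, while
extracellular mucin returns no signal at all. Thresholding a stiffness map
at 520 kPa therefore localizes cancer, and a small feature table
(stiffness classes present, gland-like nests, fraction of non-signal area)
calls the morphological subtype.

This package is a complete, self-contained implementation of that
pipeline for R users working on quantitative elastography:

* **Phantom simulator** — labelled silicone–tissue sandwiches with
  speckle, a Gaussian PSF (15 µm axial / 25 µm lateral at 1310 nm),
  nonlinear tissue mechanics and exported ground truth
  (`phantom_spec()`, `build_phantom()`, `simulate_compression_series()`,
  `make_cohort()`).
* **Strain estimation** — the phase-gradient "vector method": complex lag
  products averaged over an 80–100 µm window with the phase extracted
  last, recovering interframe strains up to ~1% without phase unwrapping
  (`vector_strain()`, `cumulate()`).
* **Stiffness mapping** — silicone-referenced stress calibration and the
  tangent modulus between 3 and 5 kPa, reported at 4 kPa
  (`silicone_stress()`, `build_stress_strain()`, `tangent_modulus_map()`),
  wrapped by the one-call estimator `coce_fit()` with `print`/`summary`/
  `plot`/`coef` methods.
* **Segmentation & subtype calling** — threshold classes, connected-
  component morphometry, non-signal quantification within the superficial
  500 µm, and the subtype decision table (`coce_segment()`,
  `classify_pixels()`, `subtype_call()`).
* **Agreement statistics** — Pearson correlation, Bland–Altman bias and
  95% limits of agreement, one-tailed pooled t-test, and the
  `mean ± sd [min; max]` reporting style (`run_agreement_experiment()`).

The central quantity is the tangent modulus

E_t = Δσ / Δε evaluated over the stress window σ ∈ [3, 5] kPa,

with σ obtained from the reference layer as σ = E_sil · ε_sil and ε from
axial gradients of the interframe phase Δφ = (4πn/λ)·u.

## Worked example

Two 724 kPa gland-like nests embedded in 295 kPa stroma under a 300 µm
silicone layer, compressed to 6 kPa over 60 frames at 25 dB SNR:

```r
library(coce)

spec <- phantom_spec(
  depth_px = 250, lateral_px = 160, lateral_pixel_um = 12.5,
  silicone_thickness_um = 300, E_sil = 100,
  classes = list(mechanical_class(1, "stroma", E0 = 280, beta = 3.75),
                 mechanical_class(2, "gland",  E0 = 688, beta = 9)),
  background = 1,
  shapes = list(shape_ellipse(500, 300, 220, 160, 2),
                shape_ellipse(1400, 450, 220, 160, 2)))

sim <- simulate_compression_series(
  build_phantom(spec),
  acquisition_spec(n_frames = 60, max_stress_kPa = 6, snr_db = 25, seed = 42))

fit <- coce_fit(sim$series)
fit
#> C-OCE tangent Young's modulus fit
#>   standardized stress 4 kPa (window 3-5 kPa), silicone 75 rows, E_sil 100 kPa
#>   tissue mean stiffness: 361.2 kPa (98.6% of pixels valid)

summary(fit)
#> Tissue stiffness (kPa): 361 ± 139 [289; 751]
#> C-OCE segmentation: subtype call LOW_GRADE_CRAC
#>   520-950 kPa: TRUE | >950 kPa: FALSE | gland-like: TRUE | signal loss: 0.0%
#>   cancer area: 12.8% of tissue
#>   class areas (% of tissue): NON_SIGNAL 1.9, LOW 0.0, STROMA 85.3, CANCER_GLAND 12.8, VERY_HIGH 0.0

coef(fit)
#>          LOW       STROMA CANCER_GLAND    VERY_HIGH
#>           NA     301.2404     686.4280           NA
```

The fit recovers the stroma background near its true 295 kPa, the nests
near their true 724 kPa, classifies them as gland-like structures in a
softer background — the low-grade adenocarcinoma signature — and measures
a cancer area of 12.8% against a rasterized ground truth of 15.8% (the
~50 µm strain-window resolution erodes nest rims, a bias the Bland–Altman
analysis makes visible across a cohort). `plot(fit)` renders the map with
the standard palette (soft tissue in warm reds, cancer in turquoise/blue,
non-signal in white).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/coce.R simulate    --subtype cribriform --fraction 0.3 --seed 5 --out sim1
Rscript inst/cli/coce.R reconstruct --in sim1/series --out sim1/map.tif
Rscript inst/cli/coce.R segment     --in sim1/map.tif --out sim1/report.json
Rscript inst/cli/coce.R evaluate    --cohort 30 --seed 1 --out eval1
```

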