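---
title: "Quantitative compression elastography of colorectal tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative compression elastography of colorectal tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement this package models

Compression optical coherence elastography (C-OCE) turns an OCT scanner
into a quantitative stiffness camera. A layer of pre-calibrated, highly
linear silicone is placed on the tissue and the sandwich is slowly
compressed by the output window of the probe while a series of
complex-valued B-scans (on the order of one hundred) is recorded. Between
consecutive frames every scatterer moves toward the probe by the local
axial displacement $u(z,x)$, which advances the interferometric phase by

$$\Delta\phi(z,x) = \frac{4\pi n}{\lambda}\, u(z,x),$$

with $\lambda$ the central wavelength (1.31 µm here) and $n$ the tissue
refractive index. The axial gradient of $\Delta\phi$ is the interframe
strain. Because the silicone is linear, its strain reports the applied
stress ($\sigma = E_{sil}\,\varepsilon_{sil}$); plotting tissue strain
against silicone-derived stress gives a per-pixel stress–strain record,
and the local slope — the **tangent Young's modulus** — evaluated at a
standardized stress is the quantity mapped. Standardization matters
because soft tissue is pronouncedly nonlinear: the tangent modulus can
change several-fold over a few kPa, so moduli are only comparable at the
same stress. This package evaluates the secant slope between the frames
where the stress schedule crosses 3 kPa and 5 kPa (linear interpolation in
stress) and reports it at the 4 kPa centre.

Colorectal stiffness ranges then segment the map into morphological
classes: low-stiffness tissue (mucosa/submucosa/adenoma, tens of kPa),
tumour stroma (92–515 kPa), glandular cancer (520–950 kPa) and
non-glandular, very stiff cancer (>950 kPa); mucin and wide gland lumina
return no backscatter and appear as non-signal. A decision table over
these features calls the morphological subtype (low-/high-grade
adenocarcinoma, cribriform pattern, mucinous adenocarcinoma).

## The forward model (`phantom_sim`)

The simulator generates exactly the data the reconstruction inverts,
plus ground truth.

**Mechanics.** Each pixel follows the affine tangent-modulus law
$E_t(\sigma) = E_0 + \beta\sigma$ — the simplest law with a
stress-dependent slope. Local strain under stress $\sigma$ is the closed
form $\varepsilon(\sigma) = \beta^{-1}\log(1 + \beta\sigma/E_0)$
(reducing to $\sigma/E_0$ for $\beta = 0$). Mechanics is a 1-D series
stack per lateral column: stress is uniform along a column and strains
add in series, which is precisely the regime the silicone calibration
assumes. Lateral coupling, probe–silicone stiction and silicone thinning
are neglected. Compression is applied from the top and compressive
strain is **positive** throughout the package.

**Optics.** Fully developed speckle is simulated as a circular complex
Gaussian scatterer field scaled by each class's backscatter amplitude and
convolved with a Gaussian point-spread function (15 µm axial, 25 µm
lateral FWHM at the defaults). The speckle realization is frozen across
frames and only the phase advances with $u(z,x)$, so interframe
decorrelation comes solely from strain and additive complex Gaussian
noise (default SNR 25 dB) — matching the assumption of the phase-resolved
method. Non-signal classes (mucin) have zero scattering amplitude and
carry noise only. Because phase is applied after the PSF convolution,
the noiseless interframe phase equals $(4\pi n/\lambda)\,\Delta u$ to
machine precision, which the test suite verifies.

**Defaults and why.** Axial pixel 4 µm (oversamples the 15 µm axial
PSF); grid 500 × 512 px ≈ 2 × 2 mm; silicone layer 300 µm at
$E_{sil}$ = 100 kPa; 100 frames to 6 kPa maximum stress so that the 3–5 kPa
window is fully crossed. The refractive index is not a measured
instrument constant here; 1.4 is the typical soft-tissue value and it is
configurable. The per-frame stress increment is validated against the
estimator's 1% interframe strain limit and the simulator refuses
schedules that violate it. Tests and the acceptance analyses use reduced
grids (≈150–300 depth × 32–160 lateral px, 30–60 frames) purely as a
problem-size choice; the physics is scale-free in these dimensions.

**Cohort templates.** `make_cohort()` draws subtypes from a mix that
mirrors a surgical series dominated by non-cancerous samples. Template
stiffnesses are the measured class means (mucosa 58, adenoma 46, stroma
295, glandular cancer 724 kPa); non-glandular foci are placed at
1100 kPa — inside the reported 703–1418 kPa range — rather than at the
954 kPa mean, because a homogeneous focus simulated at the class mean
would straddle the 950 kPa class boundary at reconstruction noise level
and produce a physically meaningless speckled two-class mix. Tissue
classes carry a mild nonlinearity ($E_0 = 0.95\,E_4$,
$\beta = 0.05\,E_4/4$) so the true tangent modulus at 4 kPa equals the
class value exactly. Every template structure is at least one analysis
ROI (110 × 110 µm) in both extents: the high-grade focus, in particular,
never degenerates into a sheet thinner than the method's 40–50 µm
resolution, which would be undetectable by construction rather than by
defect. Mucinous templates fill ≈75% of the superficial 500 µm band with
mucin pockets; cribriform templates place three laterally spaced gland
rings whose lumina are wide enough (≥ ~100 µm of pure mucin beyond the
averaging window) to remain non-signal after window averaging.

## Strain estimation (`strain_estimation`)

The estimator follows the "vector method" family: complex signal values
are treated as vectors in the complex plane and the phase is singled out
at the very last stage, so no unwrapping is ever performed. Details that
were open in its published sketches are fixed here as follows:

* the interframe field is $F = \overline{a}\,b$ for consecutive frames
  $a, b$;
* an axial **lag product** $P(z,x) = \overline{F(z,x)}\,F(z+\ell,x)$
  with lag $\ell$ = 3 px (12 µm) encodes the local phase gradient;
* $P$ is averaged **as complex values** over a rectangular window
  (default 100 × 100 µm, the upper end of the instrument's practical
  80–100 µm range), and
  $\varepsilon = \arg(\bar P)\,\lambda/(4\pi n \ell \Delta z)$;
* windows are truncated at the borders; a pixel is invalid when less
  than half its window is in-image or when
  $|\bar P| < 0.25 \sum |F(z)||F(z+\ell)|/N$ — incoherent averaging, the
  signature of noise-only (non-signal) pixels. The 0.25 floor sits far
  above the $\approx N^{-1/2} \approx 0.05$ incoherent expectation for a
  325-sample window and far below the ≈1 coherent value, so the decision
  is not delicate.

With the 1.31 µm wavelength and these defaults the lag phase reaches
$\pi$ only at ≈1.9% interframe strain, so the stated 1% working range is
recovered with margin even where the raw phase map wraps many times
across the depth. Cumulative strain is the running sum of interframe
estimates in the laboratory frame, without advecting pixels between
frames; at the ≤10% total strains used here the resulting misregistration
is below the averaging window and is absorbed by the reconstruction
tolerances — a documented approximation, not an oversight. Validity masks
intersect across the series.

## Stress calibration and the modulus map (`stiffness_mapping`)

Stress is estimated per lateral column from the mean cumulative silicone
strain (a simplified stand-in for full local stress standardization; a
config switch provides a frame-global alternative). Rows within half an
averaging window plus one lag of the silicone–tissue interface are
excluded from the silicone average because window averaging mixes tissue
strain into them. The silicone band is taken from metadata when present;
otherwise the topmost depth-uniform strain band is auto-detected (row
medians within 2% of the top of the image). Uniformity rather than
linearity is the detection statistic because a linear *tissue* under a
linear loading schedule is itself perfectly linear — linearity cannot
separate the layers, depth-uniformity can.

Per pixel, strain is interpolated in stress (not frame index) to the
window endpoints, and $E_t = \Delta\sigma/\Delta\varepsilon$. Pixels are
masked when the strain increment is non-positive, when more than 30% of
their frames were invalid, or when the recovered modulus exceeds
5000 kPa — several-fold beyond the stiffest colorectal tissue observed,
hence an artifact. Stress schedules that decrease by more than 2% of the
maximum indicate failed silicone tracking and raise an error; smaller
noise dips are repaired by a running maximum.

When reporting a tissue mean (`tissue_mean_stiffness()`), rows within
50 µm of the interface are excluded: the map's spatial resolution is
about half the processing window, so those rows are silicone–tissue
mixtures by construction.

## Segmentation and subtype decision (`segmentation_subtyping`)

Classification uses half-open intervals, upper-exclusive except the top
class, with the 515–520 kPa gap between the printed stroma maximum and
the cancer threshold assigned to stroma (conservative toward fewer false
cancer calls). Class presence in the feature vector requires at least one
8-connected component covering a full analysis ROI (110 × 110 µm, one
7 × 7 speckle block) so single speckle outliers cannot flag a sample.
"Gland-like structures" are operationalized as ≥2 such components of the
glandular class covering <70% of the signal area — discrete stiff nests
in a softer background, not one contiguous field; the three constants are
configuration keys because no numeric rule is published.

Non-signal is quantified within 500 µm of the silicone–tissue interface
(not the image top), as the OCT signal rarely penetrates deeper, and the
fraction is taken of the *total* band area. The mucinous call requires
signal loss in **at least half** of that band; the scan in the acceptance
analysis therefore switches at exactly 50%. A loss floor of 2% separates
"no loss" from genuine dropout so that sporadic reconstruction dropouts
do not push a clean low-grade sample into the cribriform branch.
Inconsistent feature combinations (e.g. dominant mucin loss together
with gland-like nests) return `INDETERMINATE` rather than a forced call.

A known limitation: on reconstructed (blurred) maps, the rim of a very
stiff focus passes through the 520–950 kPa band and can form thin
glandular-class rings; with several separate stiff foci these rings can
mimic gland-like nests. The templates avoid this by using a single
dominant focus, and real analyses should treat subtype calls near this
boundary with care — the cancer/non-cancer decision itself is unaffected.

## Agreement statistics (`agreement_stats`)

Pearson correlation (with the $t$-transform p-value), Bland–Altman bias
and 95% limits of agreement ($\pm 1.96\,s_d$, sample SD; an exact-$t$
multiplier is available), and the classical pooled-variance one-tailed
Student's t-test (Welch behind a flag, since the pooled test is the one
named in the field's reporting conventions). Summary statistics print as
`mean ± sd [min; max]`; the bracket order is min-then-max, which is how
every published instance is actually printed even when the label says
otherwise. Degenerate t-tests (both groups constant, equal means) return
p = 0.5 with a warning rather than erroring mid-cohort.

## What the synthetic data does and does not show

The phantoms reproduce the features the reconstruction depends on:
fully developed speckle with the instrument's resolution, phase-encoded
displacement, additive noise, a linear reference layer, mildly nonlinear
tissue, non-scattering mucin, and class geometries at realistic scales.
They do **not** emulate depth-dependent attenuation, refraction at the
silicone interface, lateral mechanical coupling, strain-induced speckle
decorrelation beyond noise, probe stiction, or tissue advection past the
pixel grid. Passing the recovery and agreement tests therefore validates
the estimator chain under its own model assumptions; it does not certify
performance on clinical data, where those neglected effects set the
error floor. The near-unity cancer-area correlation on the default
cohort (r ≈ 0.998, computed by `scripts/acceptance.R`) should be read in
that light.

## Numerical choices

* Window sizes are converted to odd pixel counts; complex box sums use
  integral images, so the cost is independent of window size.
* Stress interpolation ties break toward the earlier frame.
* All randomness flows through explicit seeds (`local_seed()` restores
  the caller's RNG state); identical spec + seed is bit-reproducible.
* The frame-series container stores doubles losslessly (Arrow Feather +
  JSON metadata); float map exports are 32-bit TIFF normalized by a
  scale factor recorded in the JSON sidecar, because the TIFF writer
  clips samples outside [0, 1].
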