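---
title: "Methods: OCT attenuation fitting, SVM classification, and Raman preprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT attenuation fitting, SVM classification, and Raman preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attenuskin)
```

This vignette records the models the package implements, the assumptions
behind them, the numerical choices made where the design was genuinely
open, and — importantly — what the synthetic-data generator does and does
not establish. It states no empirical result that the test suite does not
itself compute.

## 1. The OCT attenuation model

An OCT A-scan is a depth profile of backscattered intensity. Because the
probe light traverses the tissue twice, the decay below the surface follows
the two-way Lambert–Beer law

$$I(z) = I_0\, e^{-2\mu z},$$

with $\mu$ the total attenuation coefficient (absorption plus scattering).
Estimated from raw image intensities, the fitted decay rate is effectively
$\mu$ *times the tissue refractive index* (1.33–1.55), which is why
plausible fitted values reach about 1.6 rather than 1. The package calls
this quantity `attenuation_b` and deliberately does not try to divide the
refractive index back out.

**Depth units.** `fit_attenuation()` measures $z$ in millimetres below the
surface (`pixels × pixel_spacing`), so `b` is an effective 1/mm value. A
`per_pixel = TRUE` flag measures $z$ in pixels instead; the two coincide
when `pixel_spacing = 1`, which is how the unit tests express
pixel-domain examples. The mm default was chosen because with realistic
axial sampling (a few µm/pixel) a *per-pixel* decay constant of order 1
would extinguish the signal within two pixels — no finite-window fit could
recover it — whereas an effective 1/mm value of order 1 decays gently
across the default 150-pixel window and matches the magnitudes a clinician
would report.

**Surface detection** is the global intensity maximum, ties broken
shallow: the bright air–tissue specular reflection marks the origin of the
decay. A flat (all-equal) A-scan has no surface and errors.

**The fit** minimizes the sum of squared errors of $a e^{-2bz}$ on *linear*
intensities. For fixed $b$ the optimal amplitude has the closed form
$a(b) = \langle y, u\rangle/\langle u, u\rangle$ with $u = e^{-2bz}$, so the
problem reduces to a 1-D minimization in $b$, solved with Brent's method.
The bracket and the starting candidate come from an ordinary regression on
the log intensities, restricted to the leading stretch of the window still
above $10^{-3}$ of its peak — otherwise a fully decayed tail (clamped at a
small positive value before the log) drags the slope toward zero. The
log-linear candidate is kept and whichever of the two has the smaller SSE
is returned. Three consequences:

* noiseless data refit exactly (the log regression is already exact there,
  and a zero-residual start costs nothing — a classic failure mode of
  Gauss–Newton implementations);
* the nonlinear SSE can never exceed the log-linear fallback's, which the
  property suite asserts;
* the fit is scale-equivariant: scaling an A-scan by $k$ scales $a$ and
  RMSE by $k$ and leaves $b$ and $R^2$ unchanged.

Fitting on linear intensities (not log) was chosen so that the reported
RMSE is in intensity units, consistent with treating the deep noise floor
as additive. $R^2 = 1 - SS_{res}/SS_{tot}$ over the window; the degenerate
case $SS_{tot} = 0$ is defined as 1 when the residuals also vanish and 0
otherwise. Non-convergence is flagged per column, never fatal for a
B-scan; flagged columns are excluded before binning with a logged count.

**Fit window.** A fixed, configurable 150 pixels below the surface. The
end of the informative decay is not knowable per A-scan without a noise
model, so a fixed window keeps all fits — and therefore the binned
features — identically defined.

## 2. Features and classification

Per A-scan the pipeline keeps four quantities: `b`, `R²`, RMSE and the
surface intensity. Every 5 consecutive A-scans are binned; each bin
contributes the arithmetic mean and the *sample* SD (n−1 denominator —
"standard deviation" alone is ambiguous, so the convention is documented
and tested against the frozen case {1,1,1,1,5} → √3.2) of each quantity:
8 features. Trailing incomplete bins are dropped so all bins are
identically distributed; 1000 fitted A-scans per sample thus give exactly
200 instances, and six samples give 1200.

The classifier is a linear support vector machine with cost $C = 1$,
implemented in-package as L2-regularized hinge-loss dual coordinate
descent (the LIBLINEAR algorithm) with a deterministic cyclic sweep, since
no SVM library is available in the target environment. The bias is an
augmented constant feature. MM is fixed as the positive class so weight
signs are reproducible.

Open choices and how they were resolved:

* **Standardization** (on by default, toggleable): features are
  standardized with training-fold statistics only; a linear SVM at fixed
  $C$ on raw mixed-scale features would let the largest-scale feature
  dominate.
* **Folds**: stratified by class, seeded; classes are shuffled
  independently and dealt round-robin, so per-class and total fold sizes
  each differ by at most one, and every instance is scored out-of-fold
  exactly once. Pooled out-of-fold accuracy gives the "1163 of 1200"-style
  counting of the per-sample report.
* **ROC**: per fold, the empirical ROC is built from decision scores with
  tied scores grouped, so its trapezoidal area equals the midrank
  Mann–Whitney statistic exactly (the suite checks equality to 1e−12
  against an independent rank-sum oracle). Fold curves are interpolated
  onto a fixed 101-point FPR grid anchored at (0,0) and (1,1); the mean
  and SD across folds summarize them. The reported mean AUC is the mean of
  the exact fold AUCs, not the area of the interpolated mean curve.
* **Per-sample report**: for each sample, the proportion of instances
  predicted consistent with the sample's type; a majority verdict uses
  proportion > 0.5. This mirrors how a per-lesion call would be made from
  many instance-level predictions.

## 3. Raman preprocessing

Order: despike → smooth → normalize → (group statistics on
background-containing spectra) → arPLS baseline removal → corrected group
statistics and difference spectra. Normalization precedes baseline
removal deliberately; every applied step is appended to the spectrum's
`processing_log`.

* **Cosmic-ray removal**: channels whose modified z-score
  ($0.6745\,|d - \tilde d|/\mathrm{MAD}$) of the *second difference*
  exceeds 8 are replaced by linear interpolation from the nearest clean
  channels (one-sided at the ends, where one-sided second differences are
  used so boundary spikes remain detectable). Known limitation: the
  statistic assumes the second difference is noise-dominated. On a
  strictly noiseless spectrum with narrow bands the MAD collapses to the
  background-curvature scale and band cores would be flagged; with any
  realistic noise level the threshold of 8 is far above band curvature.
* **Smoothing**: Savitzky–Golay, window 11, order 3 (defaults;
  parameters unstated upstream). Edge half-windows are filled by
  evaluating the boundary-window polynomial fit, so polynomials up to the
  chosen order are reproduced exactly everywhere.
* **Normalization**: division by the trapezoidal integral over the
  800–1800 cm⁻¹ fingerprint region. Area normalization was chosen over
  max- or vector-norm because it is robust to a single dominant band; it
  is scale-invariant and idempotent by construction.
* **arPLS**: iterate solving $(W + \lambda D^\top D)\,z = W y$ with the
  second-difference penalty $D$, then reweight with the logistic rule
  $w_i = \bigl(1 + e^{\,2(d_i - (2\sigma_{d^-} - m_{d^-}))/\sigma_{d^-}}\bigr)^{-1}$,
  $d = y - z$, where $m_{d^-}, \sigma_{d^-}$ are the mean and SD of the
  negative residuals: channels well above the running baseline (peaks)
  lose weight and the baseline relaxes under them. Defaults
  $\lambda = 10^5$, ratio tolerance $10^{-6}$, 50 iterations; hitting the
  cap returns the last iterate with a warning (at these tolerances the
  weight vector often keeps drifting microscopically after the baseline
  has stabilized — the warning is informational). Limitation: on a
  *noiseless* peak-free spectrum the reweighting becomes hypersensitive
  (the residual scale is curvature, not noise) and the baseline sags below
  steep background; with any realistic noise the baseline tracks a
  peak-free background to well under one noise SD, which is what the
  acceptance suite asserts.
* **Group statistics**: pointwise mean and Student-t CI half-width
  $t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}$ per channel, plus 20 equally spaced
  display positions; difference spectra use unpooled Welch intervals with
  per-channel Welch–Satterthwaite degrees of freedom. Spectra must share
  an axis; `regrid_spectra()` interpolates linearly and logs the step.

## 4. What the synthetic generator emulates — and what it does not

The OCT generator produces, per A-scan: a rectified-Gaussian noise floor
above a jittered surface index; from the surface, the two-way exponential
decay at a per-A-scan effective attenuation drawn from the class
distribution, under multiplicative log-normal speckle plus the additive
floor. Class defaults are BN μ ~ N(1.2, 0.15) and MM μ ~ N(0.8, 0.15)
truncated positive — chosen so the maximum fitted values over ~1000
A-scans approach the ≈1.6 ceiling that the refractive-index product
implies, with BN above MM. Speckle SD defaults to 0.2 log-units and the
floor to 0.5 intensity units against a surface amplitude of 100; these are
stylized but give fit-quality features realistic spread. Ground truth
(per-column μ, surface index) always travels with the data.

Not emulated: physically rigorous speckle statistics (fully developed
speckle has unit contrast; here the B-scan pixels are treated as
multi-scan averages), confocal/sensitivity roll-off, multi-layer tissue,
per-sample attenuation offsets between lesions of the same class, and any
class difference other than μ. Consequently a green classification test
establishes that the pipeline is correct and that μ separation of this
size is recoverable — not that melanoma is clinically separable at these
accuracies. One measured consequence, recorded by the acceptance suite:
because the classes differ *only* in μ, the attenuation-pair feature set
{mean_b, sd_b} is already Bayes-sufficient and the remaining six features
act as noise dimensions, so the all-8-feature SVM scores marginally (≈0.1
percentage points) *below* the attenuation-only model on this synthetic
world — the opposite ordering from the clinical study, where fit-quality
features carry independent lesion information. The corresponding
acceptance expectation is intentionally left failing rather than adjusted.

With multiplicative speckle the surface pixel is the global maximum with
high probability rather than almost surely (a deep speckle excursion can
exceed it); this is harmless for attenuation estimation because shifting
the fit origin down the decay only rescales the fitted amplitude, and the
noiseless invariants pin the exact case.

The Raman generator builds a natural cubic spline autofluorescence
background through five control points (brighter in MM), Gaussian bands at
1008, 1158, 1525 cm⁻¹ (carotenoid, higher in MM) and 1450, 1655 cm⁻¹
(CH₂–CH₃ and amide-I, higher in BN), Gaussian noise (SD 8 counts), and a
Poisson number of single-channel cosmic spikes. Band positions are
literature positions; amplitudes and the background shape are free
calibration choices, not reproductions — the source figures were not
parameterized. Grid: 800–1800 cm⁻¹ at 1 cm⁻¹.

## 5. Reproducibility

Every generator and the cross-validation split are pure functions of
(configuration, seed). The pipeline derives per-stage seeds from one
global seed as `(seed mod 2^16) · 2654435761 + stage_id (mod 2^31 − 1)` —
exact in double precision — so stages are independently re-runnable.
`run_pipeline()` writes a manifest (config snapshot, MD5 digests, package
version, timestamp); reruns with the same configuration are byte-identical
except for the manifest timestamp, which the test suite verifies on
`report.json`.
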