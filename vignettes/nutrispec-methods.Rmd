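---
title: "Methods: PLS nutrient quantification from FTIR-PAS spectra and tolerance-interval assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS nutrient quantification from FTIR-PAS spectra and tolerance-interval assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Manures and digestates are re-used as bio-based fertilizers, but their
nutrient content varies so much between animals, farms and processes that
dosing them rationally requires a per-batch analysis. Wet-chemistry
reference methods (ICP-OES, flow-injection analysis) are accurate but slow
and expensive. Mid-infrared photoacoustic spectroscopy (FTIR-PAS) measures
the absorption spectrum of a dried, milled sample in minutes, and — because
the photoacoustic signal shape is insensitive to sample morphology — is a
promising rapid alternative. The open question is not whether a calibration
can be built (it can, with partial least squares regression), but whether
its *errors are small enough for fertilization practice*. `nutrispec`
implements both halves of that question: the calibration pipeline and an
error-tolerance assessment framework that classifies each prediction as
acceptable or not against policy-derived accuracy limits.

Throughout, concentrations are in mg g⁻¹ of dry matter, numerically
identical to g kg⁻¹; spectra live on the instrument grid 4000–400 cm⁻¹ at
4 cm⁻¹ resolution (901 channels).

## The model chain

### Pre-treatment

Each training set defines a `preprocess_state`: the mean training spectrum
serves as the reference for multiplicative scatter correction (MSC), and
the per-channel means of the corrected training spectra define the
subsequent mean-centering. MSC fits every spectrum $s$ to
$s \approx a + b\,r$ by least squares over all 901 channels and returns
$(s - a)/b$; a spectrum constructed as $b\,r + a$ is recovered exactly, and
the correction is idempotent. Test spectra are corrected with the
training-derived state only — nothing is ever re-estimated from test data.

A note on operation order. Descriptions of this kind of pipeline often say
"mean-centered followed by MSC". Taken literally with column-wise
centering that recipe is ill-posed: the mean of column-centered training
spectra is identically zero, so there is no reference left to fit against,
and the fitted gain of any centered spectrum against a fixed reference
collapses toward zero. `nutrispec` therefore performs MSC on the raw scale
against the mean training spectrum and centers afterwards; the two
operations are the same two classical steps, composed in the only order in
which both are well defined.

The Z-score assessment can optionally work on log₂-transformed
concentrations. `log2_transform()` refuses nonpositive values with their
indices rather than applying a silent offset: panels whose ranges reach
zero (e.g. ammonium-N) need an explicit caller-chosen handling.

### PLS regression (NIPALS)

`fit_pls()` implements the classical NIPALS algorithm with X-deflation.
On centered data it extracts components sequentially,

$$X = T P' + F_x, \qquad Y = U Q' + F_y,$$

and assembles the original-space coefficients $B = W (P'W)^{-1} Q'$ so that
$Y = X B + E$. The inner iteration (needed only for multi-response PLS2)
stops when the weight vector moves by less than $10^{-10}$ or after 500
iterations. The bilinear identities above and the mutual orthogonality of
the score vectors are enforced by construction and verified in the test
suite to $10^{-8}$; with as many components as the rank of $X$, PLS
predictions coincide with ordinary least squares, which the tests check
against an independent normal-equations solution.

PLS1 (one analyte at a time, with an independently selected component
count) is the default, matching how per-element results are usually
reported; PLS2 (all analytes jointly, one shared component count) is
available via `pls_mode = "pls2"`. Neither is asserted to be "the" correct
choice; with strongly correlated analytes PLS2 can borrow strength across
responses, at the price of a compromise component count.

### Data splitting and component selection

`stratified_split()` shuffles within each source (cow manure, digestate,
chicken manure, pig manure) under a seeded RNG and apportions the global
test count — $\lceil 0.3\,n \rceil = 37$ of 122 — across sources by
largest-remainder rounding. On the default panel this reproduces the
familiar per-source composition 40/17, 19/9, 11/5, 15/6.

`loocv_select()` chooses the number of latent variables by leave-one-out
cross-validation *on the training set only*: for every left-out sample the
pre-treatment, the centering and the full NIPALS decomposition are re-derived
from the remaining samples, so the held-out spectrum can never leak into
the model. Each fold is fitted once at the largest candidate count
(default `A_max = 20`) and predictions for all smaller counts fall out of
the nested score recursion, which keeps the 85-fold LOOCV fast. The MSE
curve is computed on the original concentration scale (not the
preprocessed or log scale), and the selected $A^\*$ is the smallest count
attaining the minimum, with ties — within a relative slack of $10^{-8}$ of
the curve's range — broken toward fewer components. If a fold exhausts the
rank of its spectra below `A_max`, its last achievable prediction is
carried forward and the result is flagged.

### Assessment criteria

Three views of the same test-set predictions:

1. **Conventional statistics** (`compute_metrics()`): RMSE, $R^2$, and the
   ratio of performance to deviation RPD = SD(reference)/RMSE. The SD uses
   the $n-1$ denominator (the chemometrics convention; configurable), and
   the identity RPD·RMSE = SD holds exactly. RPD above 2.5 is commonly
   read as "good", above 3 as "excellent" — but these labels say nothing
   about fitness for a concrete application.
2. **Z-score Shewhart chart** (`compute_zscores()`): standardized errors
   $Z_i = (Y_i' - Y_i)/\sigma_{max}(Y_i)$, where $\sigma_{max}$ is the
   maximum allowed random SD from the policy table (nitrogen: 0.25 g kg⁻¹
   up to 2.5 g kg⁻¹, then $0.1\,Y$; phosphorus pentoxide: 0.075 g kg⁻¹ up
   to 0.5 g kg⁻¹, then $0.15\,Y$). Control limits are drawn both at
   $\pm 1.96\,\mathrm{SD}(Z)$ (the empirical 95 % band; 1.96 is the
   two-sided standard-normal quantile) and at the fixed ±2σ/±3σ lines;
   both are reported because either convention is defensible. The default
   mode standardizes on the original concentration scale. A `log2` mode
   transforms both values first and transfers $\sigma_{max}$ to the log
   scale by the delta method, $\tilde\sigma = \sigma_{max}/(Y_i \ln 2)$ —
   the policy limit is stated in g kg⁻¹ and some explicit transfer rule is
   needed; the two modes are never silently mixed.
3. **Error-tolerance intervals** (`tolerance_bands()`): per-sample bands
   $[Y_i - \epsilon_i,\; Y_i + \epsilon_i]$ with $\epsilon_i$ the maximum
   allowed random error (nitrogen: 0.5 g kg⁻¹ below the 2.5 g kg⁻¹
   threshold, $0.1\,Y_i$ above; P₂O₅: 0.15 g kg⁻¹ below 0.5 g kg⁻¹,
   $0.2\,Y_i$ above). A prediction is acceptable iff it falls inside its
   band (closed at both ends; the boundary convention is ours — sources
   do not state one). The within-limit percentage, e.g. 35 of 37 = 94.6 %,
   is the headline number of this method. Unlike the Z-score chart it
   assumes nothing about the error distribution.

Two wrinkles are worth naming. For nitrogen, one also finds
$\epsilon = 0.11\,Y$ in use, chosen to *guarantee* a ±10 % allowance;
`default_tolerance_specs(k_eps_n = 0.11)` provides it, 0.10 is the
default, and the discrepancy is documented rather than resolved. For
phosphorus, the policy limits are stated on the P₂O₅ basis while models
predict elemental P; the shipped spec declares its basis and carries the
explicit conversion factor 2.2914 (the P₂O₅/P mass ratio), which the
pipeline applies to both reference and predicted values before assessing.
How published studies handled this conversion is typically not stated; here
it is explicit and logged in the report.

`classification_oracle()` recounts acceptable predictions by a deliberate
brute-force loop, kept as a separate code path so the vectorised
classification can be cross-validated against it (the test suite does so
on 1000 seeded instances).

## The synthetic data generator

Real panels of this kind are not openly archived, so the package ships a
first-class generator that emulates the *statistical structure* such a
study assumes, making every downstream stage testable without any
download.

**Concentrations.** A Gaussian copula draws correlated standard normals
and maps each margin through the quantile function of a normal truncated
to the analyte's concentration range, with the location parameter
calibrated by root finding so the expected value equals the analyte's
target mean. Quantile mapping (rather than clipping) keeps every draw
strictly inside its range with no probability mass at the bounds. Because
a nonlinear margin attenuates Pearson correlation, the latent correlation
matrix is pre-compensated pairwise — for each pair the latent correlation
whose *induced* output correlation equals the target is solved by
Gauss–Hermite quadrature and root finding (the NORTA construction) — so
the emitted table's correlations match the targets rather than an
attenuated copy of them. Default ranges and means follow the wet-chemistry
summary of a 122-sample manure/digestate panel (total N 13.2–44.12, mean
25.16 mg g⁻¹, and so on); nitrate-N, negligible in such dried panels, has
an invented placeholder margin (0.01–0.9, mean 0.15) and is documented as
such.

The default correlation targets are numeric calibrations of qualitative
statements — 0.90 for pairs described as highly correlated (TN with
ammonium-N, total P with bicarbonate-extractable P), 0.75 within the
S/Ca/Na/Fe/Zn group and for TP with Mg and Ca, 0.10 for nitrate-N against
everything, 0.30 elsewhere. Per-source mean shifts (in margin-SD units,
recentred against the sample counts so panel means are preserved) make the
four sources distinguishable, emulating between-farm composition
differences.

**Spectra.** Each clean spectrum is a constant organic-matrix background
plus a concentration-weighted sum of Gaussian bands. The band library
places 1–4 bands per spectrally active analyte in the regions where dried
biowaste absorbs (O–H/N–H stretching near 3400 cm⁻¹, aliphatic C–H at
2850–2926 cm⁻¹, carbonate features in 3100–2900 and 2600–2300 cm⁻¹, amide
bands near 1365/1090/1050 cm⁻¹, phosphate and inorganic anions below 1300
cm⁻¹); centers, widths and strengths are invented defaults declared in the
panel definition, not measured constants. Potassium and nitrate-N are
spectrally inactive by default — K because of its weak photoacoustic
absorption, nitrate because of its negligible concentration — so any
predictive skill for them can only arise through their correlation with
active constituents, mirroring the mechanism suspected in real data (and
indeed both stay near $R^2 \approx 0.2$ in the shipped conditions).

The constant matrix background deserves a paragraph, because it is load
bearing. MSC assumes each spectrum is approximately an affine distortion
of a common reference. If spectra were *only* sums of analyte bands, the
fitted MSC gain would track each sample's total analyte load, and dividing
by it would destroy the linear concentration–spectrum relation the
calibration relies on (in an early version of this generator that effect
capped TN at $R^2 \approx 0.57$). Dried biowaste spectra are in reality
dominated by broad organic-matter absorption common to all samples; with
that matrix present (`matrix_amp`, default 1, peak absorbance ≈ 1.5) the
affine scatter model is well-posed and MSC behaves as intended.

**Nuisance terms.** The emitted spectrum is
$b\,\text{clean} + a + \text{baseline} + \text{noise}$ with per-spectrum
gain $b \sim N(1, 0.08)$, offset $a \sim N(0, 0.08)$, a random quadratic
baseline drift of amplitude 0.04 absorbance units, and i.i.d. per-channel
noise. All draws are standard normals scaled by the configured amplitudes,
so two configurations sharing a seed share the same realisation and differ
only by scale — which is what makes "more noise must not help" a coupled,
seed-fixed comparison rather than a statistical one. The noise level
`noise_sd = 0.035` was calibrated once so that the full default pipeline
lands in the performance regime such studies report (test $R^2 \approx$
0.92–0.99 and RPD ≈ 4–10 across active analytes; nitrogen within-limit
percentage in the mid-90s); it is a stored default, not a hard-coded
constant.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: photoacoustic signal physics (thermal
diffusion, cell resonance, saturation), moisture and CO₂ interference
bands, nonlinear detector response, wavelength-dependent scatter, particle
size effects, and any non-Gaussian measurement artefacts. The generator
demonstrates that the *pipeline* is correct and well-behaved under the
structural assumptions of the analysis, not that FTIR-PAS achieves any
particular accuracy in the field.

## Numerical choices and degenerate inputs

* NIPALS convergence: weight change < $10^{-10}$, max 500 iterations;
  PLS1 needs exactly one pass.
* Rank exhaustion (deflated X or X–Y covariance below $10^{-24}$ of its
  initial squared norm) is an error in `fit_pls()` — reported with the
  achievable maximum — and a truncation inside LOOCV folds.
* LOOCV tie-break: smallest component count within $10^{-8}$ of the range
  of the MSE curve above its minimum, so a flat tail of a noiseless curve
  selects the generative count rather than the largest candidate.
* MSC gain floor $10^{-8}$: flatter spectra are rejected by row index
  rather than corrected into garbage.
* `tolerance_spec` enforces strictly positive limits; zero-variance
  responses, constant reference vectors and perfect predictions are
  flagged (`r2_defined`, `rpd_defined`) rather than returning NaN.
* Sub-seeds for the generator and the splitter are derived from the
  global seed by fixed offsets, kept inside the 32-bit integer range.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
the default 122-sample × 901-channel panel for end-to-end checks (five
seeds for the seed-averaged performance criterion), panels of 1000–2000
samples for margin and correlation fidelity, and 1000 seeded small
instances for the metric identity and the classification-oracle
equivalence. These sizes keep a full run in the low minutes on one core
while leaving the Monte-Carlo tolerances (±0.07 on correlations, 5 %
relative on means) comfortably above sampling noise.

## Known limitations

* The band library and correlation targets are plausible calibrations,
  not measurements; absolute performance numbers on synthetic data carry
  no metrological meaning.
* MSC-then-center is the only pre-treatment order offered (see above);
  derivatives, SNV and smoothing are deliberately absent, matching
  pipelines that report "no further pre-processing".
* Tolerance specifications ship only for nitrogen and P₂O₅; other
  nutrients lack published error allowances, so their assessment stops at
  RMSE/R²/RPD.
* The Z-score method presumes approximately normal errors; the package
  reports it alongside the distribution-free tolerance intervals rather
  than choosing between them.
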