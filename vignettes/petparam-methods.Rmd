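---
title: "Kinetic models, parametric methods and their validation in petparam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models, parametric methods and their validation in petparam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

petparam quantifies dynamic brain PET of reversible tracers — the motivating
application is a ¹¹C-labelled synaptic-density tracer with a white-matter
(centrum semi-ovale type) reference region — at two levels: regional
non-linear regression against gold-standard compartment models, and fast
voxel-wise parametric imaging with linearized and basis-function
estimators. A synthetic-data module generates input functions, regional
TACs, 4D phantoms and paired test–retest sessions with known ground truth,
so the whole pipeline is validated end to end without any clinical data.

Units are fixed package-wide: time in minutes, activity concentration in
kBq/mL, rate constants in min⁻¹, K₁ in mL·cm⁻³·min⁻¹, V_T in mL/cm³.
Every source of randomness takes an explicit seed.

## The forward model

Tissue kinetics follow the reversible one-tissue compartment model with
fractional blood volume (1T2k_VB):

$$C(t) = (1 - V_B)\,K_1\,[C_p \ast e^{-k_2 t}](t) + V_B\,C_{WB}(t),$$

with $C_p$ the metabolite-corrected plasma parent curve and $C_{WB}$ whole
blood. Derived quantities: $V_T = K_1/k_2$, $DVR = V_T/V_T'$,
$BP_{ND} = DVR - 1$, $R_1 = K_1/K_1'$, and the apparent efflux rate
$k_{2a} = k_2^{SRTM}/(1+BP_{ND})$ (primes denote the reference region).
The $(1-V_B)$ scaling of the tissue term is the package-wide convention;
a flag disables it, since published implementations differ and rarely
state their choice.

Frame values are time-averages of the model curve over each frame
(`frame_sample()`), which is the physically correct model of frame
binning; mid-time point evaluation is available as an option. Getting this
right matters: treating frame values as point samples of a curved TAC
biases reference-curve reconstruction enough to move SRTM estimates by
~2%.

## Synthetic data

* **Input function** (`make_input_function()`): a Feng-type bolus — linear
  rise times a fast exponential plus two exponential tails — is the
  de-facto simulation standard and integrable in closed form, which the
  test suite exploits as an oracle. Defaults emulate a ~350 MBq bolus:
  plasma peak ≈ 70 kBq/mL at ~45 s, delay 0.5 min. The parent fraction
  declines exponentially from 1 to a plateau of 0.25 with a 20-min time
  constant; whole blood is total plasma divided by a constant
  plasma-to-whole-blood ratio of 1.3. Coefficients that would produce
  negative plasma are rejected.
* **Frame schedule** (`default_schedule()`): 19 frames over 60 min
  (1×15 s, 3×5 s, 3×10 s, 4×60 s, 2×150 s, 2×300 s, 4×600 s), the
  standard rebinning for fast ¹¹C tracers. Decay-correction factors use
  the ¹¹C half-life (20.364 min); default whole-scanner trues (3×10⁸
  total) follow a smooth uptake–washout head curve times physical decay.
* **Frame weighting** (`frame_weights()`): per-frame variance
  $\sigma^2 = dcf^2\,T/L^2$ with $T$ the frame trues and $L$ the frame
  length *in seconds*; fitting weights are $1/\sigma^2$, zero where
  $T = 0$. Only relative weights matter. All non-linear and
  basis-function fits are count-weighted by default; the linearized
  regressions are unweighted by default (flag to enable), matching common
  practice.
* **Noise** (`add_noise()`): zero-mean Gaussian per frame with SD
  proportional to $\sigma$, globally scaled so a stated reference frame —
  by default the TAC's peak frame — attains a target coefficient of
  variation. Gaussian noise with count-shaped variance is standard at
  tracer count levels; Poisson resampling is deliberately not used, since
  the variance model above is exactly what the weighting assumes.
* **Ground truth** (`default_truth()`): two grey-matter-like targets
  (V_T 20 and 15, K₁ 0.35 and 0.30) and a reference region with lower
  distribution volume (V_T 5, K₁ 0.25, k₂′ 0.05), V_B 0.05 everywhere —
  plausible for this tracer class. These are generator settings chosen
  once, not claims about any dataset. `make_reference_tac()` can also
  construct the degenerate regime in which k₂′ equals a target's k₂ₐ —
  the regime in which SRTM's $(k_2' - k_{2a})$ term is non-identifiable —
  and flags it in provenance.
* **Phantoms and cohorts** (`make_phantom()`, `make_trt_pair()`,
  `simulate_trt_cohort()`): every voxel's TAC is its region's noiseless
  TAC plus independent noise; test–retest pairs share the schedule and
  input family, scale named session-2 truth parameters by $(1+e)$ (a V_T
  effect is realised by scaling $k_2$ down, leaving delivery unchanged),
  and draw noise independently; cohorts add per-subject lognormal jitter
  (CV 0.1) on K₁ and k₂. The generator does *not* simulate scanner
  resolution, attenuation, scatter, motion, partial-volume effects or
  reconstruction — so passing tests demonstrate estimator correctness
  under the stated statistical model, not robustness to those physical
  effects.

## Estimators

* **NLR gold standards**: `fit_1t2kvb()` (K₁, k₂, V_B; bounds
  K₁∈[0,2], k₂∈[10⁻⁴,1], V_B∈[0,0.2]) and `fit_srtm()` on the SRTM
  operational equation
  $C = R_1 C' + R_1 (k_2' - k_{2a})\,[C' \ast e^{-k_{2a} t}]$.
  Both use bounded Levenberg–Marquardt; a deterministic five-point
  multi-start lattice always runs and the lowest-WRSS solution wins,
  because bounded LM can stall on a box bound from an unlucky start while
  still reporting convergence. SRTM fits whose $(k_2', k_{2a})$ estimates
  are nearly perfectly correlated (or whose difference collapses below 5%
  of k₂′) are flagged ill-conditioned — this reproduces the reference
  region degeneracy above.
* **Linearized methods**: plasma-input Logan (slope = V_T, default
  t\* = 10 min), reference Logan (slope = DVR, default t\* = 30 min; the
  $C'/k_2'$ term is included only when a k₂′ is supplied — by default no
  fixed k₂′ is used), and the multilinear reference tissue family at
  t\* = 10 min. Frames with mid-time ≥ t\* enter the fit; tissue integrals
  are zero-anchored trapezoids on frame mid-times, while the plasma
  integral is accumulated on the fine input grid (frame-binning the bolus
  peak would cost up to ~3% in Logan V_T). MRTMo/MRTM1/MRTM2 coefficient
  mappings follow from the exact one-tissue reference identity
  $\int C = DVR\,[\int C' + C'/k_2'] - C/k_2$ and are verified by
  noise-free recovery. MRTM3/MRTM4 denote software-specific variants
  without public operational equations; they ship as the MRTM1/MRTM2
  forms with count weighting switched on, are labelled non-canonical, and
  carry no validation claims. No automated t\* search is performed.
* **Basis-function methods**: RPM solves SRTM on a logarithmic grid of
  candidate k₂ₐ (default 0.01–0.1 min⁻¹, 30 points; log spacing is the
  natural choice for exponential rates), two linear coefficients per
  candidate, minimum weighted RSS wins; estimates whose best rate lies on
  a grid boundary are flagged. SRTM2 runs RPM, fixes k₂′ at the median
  voxel k₂′ over voxels with BP_ND above a threshold (default 3, chosen
  to select voxels dominated by specific signal), then refits each voxel
  with a single coefficient per candidate rate; if no voxel exceeds the
  threshold the median is taken over BP_ND > 0 with a prominent warning.
  Even counts use the midpoint-of-two median. Spectral analysis fits the
  TAC by non-negative weighted least squares on plasma-convolved
  exponential bases (default 0.01–0.1 min⁻¹, 50 points) plus the
  whole-blood curve as an additional non-negative regressor whose
  coefficient is V_B (a flag switches the blood regressor to total
  plasma); $V_T = \sum \alpha_i/\beta_i$, $K_1 = \sum \alpha_i$, both
  divided by $(1 - \hat V_B)$ so they are on the same scale as the
  $(1-V_B)$-convention compartment fit. Basis curves are precomputed once
  per (curve, grid) and reused across voxels — numerically identical to
  per-voxel computation and what makes voxel-wise fitting tractable.
* **Convolution engine** (`convolve_exp()`): curves are piecewise linear
  on their grid and each segment is convolved with $e^{-\theta t}$ in
  closed form, so the only discretisation error is the piecewise-linear
  representation; the suite checks agreement with an independent
  midpoint-Riemann oracle to <0.5%.

## Voxel-wise analysis

`fit_voxelwise()` applies any estimator over a masked 4D image. Voxel
fits are independent; basis methods run vectorised across the voxel
matrix, other methods loop with per-voxel failure capture. Failures
become NaN and are counted in the map metadata — never imputed. The
reference TAC for voxel-wise reference methods is the mean TAC over the
reference mask (regional, not voxel-wise). Maps carry provenance
(settings, k₂′\*, failure counts); `clamp_map()` provides explicit
clip-or-NaN hygiene with counts. No smoothing, registration or
partial-volume correction is performed.

## Validation and repeatability statistics

`agreement()` is OLS with intercept (r² = squared Pearson; a
through-origin option exists because identity-line comparisons are
sometimes constrained). `trt()` implements the paired ×200 convention
$(retest - test)/(retest + test) \times 200$ and its absolute form —
bounded by ±200 for positive inputs, with non-positive pair sums excluded
and counted. `bias()` is the signed percent difference against a
conventional estimate. `icc_2way()` is the two-way absolute-agreement
average-measures ICC from the explicit ANOVA decomposition,
$ICC(A,k) = (MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$, with the F-based
confidence interval stepped up to average measures; degenerate inputs
(ICC ≤ 0) are reported as computed, not clipped. Both signed TRT (as in
regional tables) and absolute TRT maps (`trt_map()`, across-subject mean
and SD on a common grid) are provided side by side.

## The validation suite and its problem sizes

The acceptance layer regenerates everything from a seed and checks, at
sizes chosen to keep a full run within a couple of minutes on one CPU:

* noise-free recovery on a 27-point truth grid (K₁ × V_T × V_B);
  plasma-input methods see blood-bearing TACs, reference methods the
  blood-free counterparts (reference-tissue theory assumes blood-free
  one-tissue kinetics on both sides, and a V_B term would otherwise
  contribute a model error that has nothing to do with the estimators);
* oracle equivalences (convolution, ICC, OLS, frame variance/TRT/bias
  arithmetic);
* noise-bias properties at 10% COV with 200 replicates on the
  high-binding target, where the documented error-correlation mechanism
  of graphical methods operates;
* map-vs-ROI consistency on a 20×20×10 three-region phantom, plus
  voxel-estimate-vs-truth agreement slopes at 5% COV;
* a test–retest cohort of 8 subjects (10×10×5 phantoms), null and
  −25% V_T effect; the whole-brain summary is the in-mask map mean, which
  averages out the grid-quantisation jitter that single-TAC basis
  estimates exhibit;
* SRTM2 two-pass internal consistency and its threshold-fallback
  contract.

## Known limitations

* **SRTM2 with data-driven k₂′\* overestimates BP_ND under noise in this
  phantom regime.** The default truth tops out at BP_ND = 3.0 — exactly
  the pool threshold — so the k₂′ pool is the upward noise tail, whose
  k₂′ errors are anticorrelated with the BP_ND errors; the pooled median
  k₂′\* comes out low and pass-2 BP_ND high (truth-agreement slope ≈ 1.3
  at 5% COV, where RPM shows ≈ 1.04). This mirrors the overestimation
  reported for SRTM2 against SRTM on real data of this tracer class. With
  k₂′ fixed externally at the true value the slope is ≈ 1.0 and the
  per-voxel variance drops below RPM's — the property that motivates the
  method.
* **Spectral-analysis V_T carries a positive voxel-noise bias** (NNLS
  positivity puts spurious mass on slow rates, amplified by 1/β in V_T):
  ≈ +15% at 5% COV, visible already at 2.5%. Regularised SA variants that
  mitigate this are out of scope. Regional (low-noise) SA is accurate to
  <0.1% noise-free.
* Basis-grid discretisation limits RPM/SRTM2 noise-free accuracy to ~2%
  at 30 bases (log step ~8%); errors shrink under grid refinement, which
  the suite checks by doubling.
* The generator's omissions listed above (resolution, PVE, motion,
  reconstruction) mean real-data performance can differ, particularly for
  small regions.
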