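---
title: "Speckle contrast, the multi-exposure model, and the synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle contrast, the multi-exposure model, and the synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(speckleflow)
```

## The measurement

Laser speckle contrast imaging (LSCI) illuminates tissue with coherent light
and records the interference ("speckle") pattern of the backscattered field.
Moving scatterers — red blood cells, chiefly — decorrelate the field on a
characteristic time scale $\tau_c$, and a camera integrating over an exposure
$T$ blurs the pattern in proportion to how many decorrelation times fit into
the exposure. The degree of blurring is quantified by the speckle contrast

$$K = \frac{\sigma}{\langle I \rangle},$$

the ratio of the standard deviation to the mean of the recorded intensities,
taken either over a small spatial window of one frame (*spatial* processing:
full frame rate, coarse spatial resolution), per pixel across many frames
(*temporal* processing: full spatial resolution, low temporal resolution), or
as the average of many spatially processed frames (*noise-reduced*
processing, the default for quantitative work). `speckleflow` computes all
three (`spatial_contrast()`, `temporal_contrast()`,
`noise_reduced_contrast()`), always with the population (divide-by-$N$)
standard deviation, since $K$ is a moment ratio, not a sample-inference
quantity. A configuration flag switches to the $N-1$ form for sensitivity
checks.

At fixed wavelength $\lambda$ the scatterer speed is inversely proportional
to the decorrelation time,

$$v = \frac{\lambda}{2\pi\tau_c},$$

so $1/\tau_c$ serves as the per-pixel flow proxy (`velocity_proxy()`,
`inverse_tau_map()`). Absolute calibration of this proxy to volumetric flow
is out of scope; only relative quantities are reported.

## The speckle correlation model

For a field whose autocorrelation decays exponentially,
$g_1(t) = e^{-t/\tau_c}$, the exposure-integrated speckle variance is

$$K^2(T) = \beta\rho^2\,\frac{e^{-2x} + 2x - 1}{2x^2}
  \;+\; 4\beta\rho(1-\rho)\,\frac{e^{-x} + x - 1}{x^2}
  \;+\; \upsilon_n, \qquad x = T/\tau_c .$$

The first term is the homodyne (dynamic–dynamic) contribution,
$\tfrac{2}{T}\int_0^T (1 - t/T)\,|g_1(t)|^2\,dt$; the second is the
heterodyne cross term between dynamic light (fraction $\rho$) and static
scatter; $\beta \in (0,1]$ absorbs speckle averaging by the detector
(speckle-to-pixel size mismatch, polarization); and $\upsilon_n \ge 0$ is the
exposure-independent floor from detector noise and the nonergodic variance of
static speckle. With $\beta = \rho = 1$, $\upsilon_n = 0$ the model reduces
to the single-term simplified form. Both bracketed terms approach finite
instantaneous-exposure limits (1 and $\tfrac12$), so the attainable ceiling
is $K^2 \to \beta\rho(2-\rho) + \upsilon_n$ as $x \to 0$
(`k_squared_ceiling()`).

Numerical choices:

* **Small-$x$ branch.** Below $x = 10^{-6}$ the closed forms lose all
  precision to cancellation ($e^{-2x} + 2x - 1$ is $O(x^2)$ against terms of
  size 1), so both brackets switch to four-term Taylor series. The series
  branch is validated against adaptive quadrature of the defining integrals
  to $10^{-12}$.
* **Inversion.** $K^2$ is strictly decreasing in $x$, so
  `invert_k_squared()` solves for $\tau_c$ by bracketed bisection on
  $\log x$ over $[10^{-12}, 10^{12}]$, 100 halvings, comfortably below a
  $10^{-9}$ relative tolerance. Observed $K^2$ must lie strictly inside
  $(\upsilon_n,\, \beta\rho(2-\rho)+\upsilon_n)$; in per-pixel maps, values
  at or above the ceiling are reported as $1/\tau_c = 0$ (no resolvable
  motion) and values at or below the floor are flagged in a `too_fast`
  companion mask rather than inverted.
* **Fitting.** `fit_mesi()` minimizes residuals in $K^2$ (the quantity
  plotted against exposure in multi-exposure protocols; a $K$-space option
  exists for sensitivity analysis), with bounds enforced by transformation —
  $\log\tau_c$, $\log\upsilon_n$, logit $\beta$ and $\rho$ — so the
  Levenberg–Marquardt solver (`minpack.lm::nls.lm`) runs unconstrained. The
  objective is multi-modal in $\log\tau_c$ for sparse exposure sets, so the
  fit multi-starts from 7 log-spaced $\tau_c$ guesses spanning
  $[0.1\min T,\, 10\max T]$ and keeps the best residual. Degenerate series
  (all $K^2$ equal) and non-convergence are flagged on the result, not
  thrown.

### The two-stage capillary protocol

`run_capillary_workflow()` reproduces the standard multi-exposure relative
flow analysis: the baseline (lowest) flow rate is fit jointly for $\beta$,
$\tau_0$ and $\upsilon_n$ with $\rho$ fixed at 1 — there is no static
scatterer between the optics and a glass capillary — and every other rate is
then fit for $\tau_c$ alone. Whether the second stage should also refit
$\upsilon_n$ is genuinely open; the default holds it fixed, on the grounds
that the noise floor is a property of the detector and illumination, not of
the flow, and a `refit_upsilon` flag exposes the alternative. Relative flow
is summarized as $\mathrm{relative}\ \tau = \tau_0/\tau_c$ against
$Q/Q_0$, with an ordinary least-squares linearity check
(`linearity_regression()`).

## The synthetic dynamic-speckle generator

No public raw data exist for this kind of instrument, so every stage is
validated against `simulate_stack()`, a physics-grounded forward model:

* Per pixel, a complex circular-Gaussian field evolves across substeps of
  one exposure by a first-order autoregressive update with coefficient
  $e^{-\Delta t/\tau_c}$, giving exactly the exponential field
  autocorrelation the closed-form model integrates. The closed form is
  therefore an *oracle* for the simulator, not an approximation to it.
* Dynamic and static field components mix with amplitudes $\sqrt{\rho}$ and
  $\sqrt{1-\rho}$; the static field is drawn once per stack, which is what
  makes the nonergodic $(1-\rho)^2\beta$ variance floor appear in spatial
  statistics exactly as $\upsilon_n$ predicts.
* Recorded intensity is the substep mean of the squared field magnitude,
  scaled to a target mean gray level, plus Gaussian detector noise, then
  optionally clipped and rounded to 8 bits. Statistical-oracle tests switch
  quantization off; camera-emulation defaults keep it on.
* Frames are independent realizations of the dynamic field (the pipeline
  nowhere uses inter-frame correlation), except that pixels with
  $\tau_c = \infty$ keep one frozen realization for the whole stack, so
  fully static scenes are constant across frames and exposures.
* Pixels are mutually independent — fully developed speckle, one speckle
  per pixel, hence $\beta \approx 1$ *for the ideal estimator*. Spatial
  speckle correlation (optical PSF) is deliberately not modeled; $\beta < 1$
  enters fits either analytically in fixture construction or through the
  estimator bias discussed below.

**Substep resolution.** The substep duration defaults to
$\min(T, \tau_c)/20$ (configurable), i.e. 20 substeps per decorrelation time
when $T > \tau_c$. At this resolution the discrete integration bias of
$K^2$ is about 0.2%, an order of magnitude below the Monte-Carlo standard
errors the statistical tests run at.

**Default detector settings.** Mean gray level 60 on the 0–255 scale —
8-bit cameras imaging speckle are operated well below half range because
fully developed speckle highlights reach several times the mean; at mean 60
under 2% of exponential-intensity pixels saturate. Detector noise defaults
to 2 gray levels where camera emulation matters and 0 in oracle tests.

### Phantoms

`make_capillary_phantom()` emulates a syringe-pump experiment: a rectangular
tube of fully dynamic scatter ($\rho = 1$) in a static background
($\rho = 0$), with tube $\tau_c(Q) = \tau_{\mathrm{baseline}}\,Q_0/Q$
(speed proportional to volumetric rate, $\tau_c \propto 1/v$). Defaults are
the seven pump rates 10–100 µL/min, the four exposures 4.96/8.97/15.43/27 ms,
and 80 frames per stack. The physical $\tau_c$ of blood at these rates is
not known, so `tau_at_baseline` (default 15 ms, which makes $x = T/\tau_c$
span roughly 0.3–18 across the grid) sets an arbitrary scale: only ratios of
decorrelation times are meaningful in the phantom.

`make_vessel_phantom()` builds a $\tau_c$ field with laminar vessels:
$v(r) = v_{\mathrm{center}}(1 - (r/R)^2)$ inside radius $R$,
$\tau_c = \lambda/(2\pi v)$, static at the no-slip wall and in the
background; overlapping vessels resolve to the faster (smaller $\tau_c$)
value. `inject_motion_blur()` convolves chosen frames with a normalized
horizontal box kernel and records the ground-truth indices, so motion QC can
be scored against truth.

## Frame quality control and masking

Motion during an exposure smears speckle and suppresses its contrast, so
`reject_motion_frames()` scores each frame by its whole-frame spatial
contrast and rejects frames below half the stack median (both the metric and
the threshold are stand-ins — acquisition software rarely documents its
criterion — and the threshold is exposed). On stacks with blur injected at a
one-in-sixteen rate this separates blurred from clean frames perfectly and
retains 94 of 100 frames.

The validity mask keeps gray values strictly between 20 and 255:
under-sampled pixels ($I \le 20$, signal lost to insufficient laser power)
and saturated pixels ($I = 255$) carry no quantifiable contrast. The
boundary semantics reconcile an ambiguity in common practice ("between
20–255" vs "$<20$"); both thresholds are arguments. Two caveats the user
should know:

* the stack-level mask is computed on the *temporal mean* frame, which for
  perfused tissue converges to the illumination level — but for a fully
  static region it never converges, and the lower threshold then truncates
  the static speckle histogram itself and biases its contrast. Uniformly
  illuminated phantom studies should set `mask_lower = 0`;
* masked pixels are excluded from every window, mean and fit downstream
  (verified by sentinel-poisoning tests), and spatial windows shrink to the
  valid in-bounds neighborhood rather than padding, so no fabricated
  intensities ever enter $K$. Neighborhoods retaining fewer than half of
  $\mathrm{window}^2$ members are marked invalid.

## What the windowed estimator does to $\beta$

The 5×5 windowed $K$ estimate is biased low by roughly 8–11% in $K^2$
(25 samples is a small draw for a variance), nearly uniformly in $x$. This
is precisely the kind of multiplicative factor the model's $\beta$ absorbs,
and the two-stage capillary protocol does so automatically by fitting
$\beta$ at baseline. Single-exposure inversions (`inverse_tau_map()`) have
no such stage, so $\beta$, $\rho$ and $\upsilon_n$ are explicit arguments
there; the package's own tests calibrate the effective $\beta$ once from an
ergodic uniform-$\tau_c$ simulation and pass it in, and real-instrument use
should do the equivalent with a flow phantom.

## Problem sizes and determinism

The validation suite runs at sizes chosen to put Monte-Carlo standard errors
near or below 1%: oracle checks average $\ge 10^4$ independent speckles per
exposure; mixed static/dynamic checks use eight replicate stacks so the
standard error honestly includes the frozen static realization; the full
capillary study simulates all 28 stacks of 80 frames at 32×48 px; vessel
profiling uses a radius-12 px vessel so the lumen is well resolved by the
5×5 window (with a 5×5 window, vessels a few pixels across leave wall
samples dominated by window mixing — visible in practice as flow apparently
extending past the wall). Every stochastic component runs under an explicit
seed, and identical seeds give bit-identical stacks, tables and maps.

## Known limitations

* One speckle per pixel: no spatial speckle correlation or optical PSF, so
  instrument $\beta$ must come from calibration, not simulation.
* Continuous flow only: no pulsatile waveform synthesis.
* Rejected frames are dropped, not registered or corrected.
* The exponential-$g_1$ model only; no Gaussian-spectrum alternatives.
* $1/\tau_c$ is a relative proxy; absolute flow calibration is not
  attempted.
* Static regions interact with the lower validity threshold as described
  above; quantization adds a small ($\tfrac{1}{12}$ gray-level$^2$) variance
  that is part of $\upsilon_n$ under camera emulation.
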