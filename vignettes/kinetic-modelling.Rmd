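---
title: "Kinetic modelling of multi-delay pCASL and CVR mapping with aslcvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of multi-delay pCASL and CVR mapping with aslcvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslcvr)
```

## The signal model

Pseudo-continuous arterial spin labelling (pCASL) magnetically inverts
arterial blood water for a labelling duration $\tau$ and images the brain
after a post-labelling delay (PLD). The control-minus-label difference
$\Delta M(t)$, sampled at several PLDs, traces the passage of the labelled
bolus through a voxel and carries the voxel's perfusion $f$ (CBF,
ml/100g/min), its arterial transit time $\Delta t$ (ATT, s), and — in
voxels containing macroscopic arteries — an arterial blood volume
fraction aBV.

The tissue compartment follows the standard single-compartment kinetic
model for continuous labelling. With $f' = f/6000$ (s$^{-1}$),
labelling efficiency $\alpha$, blood $T_{1b}$ and apparent tissue
$T_1'$:

$$
\Delta M(t) =
\begin{cases}
0 & t < \Delta t\\
2\,\alpha f' T_1' e^{-\Delta t / T_{1b}}\left(1 - e^{-(t-\Delta t)/T_1'}\right) & \Delta t \le t < \Delta t + \tau\\
2\,\alpha f' T_1' e^{-\Delta t / T_{1b}} e^{-(t-\Delta t-\tau)/T_1'}\left(1 - e^{-\tau/T_1'}\right) & t \ge \Delta t + \tau,
\end{cases}
$$

in units of the arterial equilibrium magnetization $M_{0a}$. Blood decays
at $T_{1b}$ for the duration of its transit and at $T_1'$ once exchanged
into tissue, which is why the blood-decay factor is frozen at
$e^{-\Delta t/T_{1b}}$ rather than decaying across the bolus plateau. Two
extensions produce a $2\times2$ grid of nested models:

* **Bolus dispersion.** Transport through the vascular tree spreads the
  bolus. The spread is modelled by convolving the input with a unit-area
  gamma-shaped kernel
  $k(t) = s^{1+sp}\,t^{sp}\,e^{-st}/\Gamma(1+sp)$ — a gamma density with
  shape $1+sp$ and rate $s$, mode at $t=p$. Sharpness $s$ (1/s) and
  time-to-peak $p$ (s) are inferred in $(\log s, \log sp)$ space.
* **Macrovascular component.** Labelled blood still inside arteries,
  destined for more distal tissue, adds
  $\Delta M_{a}(t) = \tfrac{\mathrm{aBV}}{100}\, 2\alpha\, e^{-t/T_{1b}}$
  over the bolus window starting at the arterial arrival time
  $\Delta t_a$ (optionally dispersed). Here the decay term follows the
  elapsed time, the convention of the macrovascular ASL model this
  component implements; the tissue term keeps the transit-frozen decay
  of the kinetic model above. `aslcvr` keeps both conventions
  deliberately — they are the forms under which each sub-model was
  originally validated — and the package's numeric-versus-closed-form
  cross-check pins the tissue convention down to $10^{-3}$.

The model codes are `noart_nodisp`, `art_nodisp`, `noart_disp` and
`art_disp`; `model_signal()` evaluates any of them at the
slice-corrected sample times $\tau + \mathrm{PLD}_i + k\,\delta_s$ for
slice $k$ (2D ascending readout, `slice_dt` $\delta_s$ per slice).

```{r curves, fig.width=6, fig.height=3.5}
p <- hemo_params(f = 60, att = 1.0, abv = 1.0, att_art = 0.5,
                 s = 7.39, p = 0.1)
co <- asl_constants()
tg <- seq(0, 4.5, by = 0.005)
autoplot(tissue_curve_numeric(p, co, tg, dispersed = TRUE))
```

## Numerical evaluation

Dispersed curves never require brute-force convolution with the kernel:
a boxcar convolved with the gamma kernel is a difference of gamma CDFs
(`pgamma`), and the $T_{1b}$-decayed arterial bolus admits an
exponential-tilting identity valid whenever $s > 1/T_{1b}$ (a gridded
convolution with the unit-area renormalized kernel covers the rare
small-$s$ excursions during fitting). The remaining tissue-residue
convolution $A \ast e^{-t/T_1'}$ runs on a uniform grid (default step
5 ms, end $\tau + \max \mathrm{PLD} + 0.5$ s) with an $O(n)$ recursive
exponential integrator: step integrals are evaluated in closed form for
piecewise-linear inputs — and exactly for the undispersed boxcar, whose
edges otherwise contribute first-order quadrature error. The sampled
kernel itself is renormalized to unit trapezoidal area so truncation
never loses bolus mass. Tests pin the undispersed numeric path to the
closed form and the dispersed path to an independent fine-grid
double-convolution oracle at the $10^{-3}$ level.

## Inference: linearized variational Bayes

`vb_fit()` approximates the posterior over $\theta$ (the model's 2–6
parameters) and the noise precision $\phi$ by a mean-field
MVN $\times$ Gamma factorization. Each iteration linearizes the forward
model around the current posterior mean (forward-difference Jacobian),
applies the conjugate Gaussian update, updates the noise Gamma
posterior, re-estimates the ARD prior precision on aBV as
$1/(\mu^2 + \sigma^2)$, and evaluates the variational free energy $F$, a
lower bound on the log model evidence. Updates that lower $F$ (possible
through linearization error) trigger up to five step-halvings toward
the previous mean; iteration stops when $|\Delta F| < 0.01$ (default)
or after 30 iterations. Singular updates are retried with a small ridge
and flagged as non-converged rather than failing.

Default priors: the perfusion amplitude is effectively unconstrained
(precision $10^{-12}$ in relative-signal units); ATT has mean 1 s and
precision 1; $\log s$ and $\log sp$ have means 2 and $-0.3$ with
precision 1; aBV carries the ARD prior; the arterial arrival time —
for which no standard default exists — uses mean 0.7 s, precision 1, on
the physiological grounds that arterial arrival precedes tissue arrival
(configurable). The noise precision prior is Gamma($10^{-6}$,
$10^{-6}$). The amplitude is initialized by matching the signal maximum
to the model peak at the prior ATT; everything else starts at its prior
mean.

In a conjugate linear-Gaussian limit (transit time pinned, noise
precision fixed) the fitted free energy reproduces the analytic log
marginal likelihood to $10^{-8}$ — the test suite keeps this as a
standing check on the evidence computation, since free energy is what
`compare_models()` ranks: per voxel the model with $F$ closest to zero
wins, with exact ties resolved toward the model with fewer parameters.

## Calibration, masks and condition contrasts

`calibrate_cbf()` converts the fitted relative perfusion to absolute
units voxelwise: $M_{0a} = M_0/\lambda$ from the unsuppressed
calibration image, with an optional (default on) saturation-recovery
factor $[1-e^{-TR/T_{1t}}]^{-1}$ for the finite calibration TR;
labelling efficiency (0.85) is already inside the forward model.
Constants default to consensus 3 T values ($T_{1b}=1.65$ s,
$T_{1t}=1.3$ s, $\lambda=0.9$ ml/g), all configurable; the apparent
tissue $T_1$ omits the perfusion correction term $f'/\lambda$ by
default (an opt-in flag enables it) since it changes $T_1'$ by under
1% at physiological perfusion.

Grey matter is `pve > 0.3` (strict), the arterial mask is
`aBV > 0.7` on the calibrated map from the dispersion + arterial model
— the threshold is read in percent-of-voxel units, with an override for
data calibrated differently. Cerebrovascular reactivity is

$$\mathrm{CVR} = \frac{100\,(\mathrm{CBF_{hyper}} - \mathrm{CBF_{normo}})/\mathrm{CBF_{normo}}}{\Delta P_{ET}CO_2} \; [\%/\mathrm{mmHg}],$$

with normocapnic CBF below 1 ml/100g/min excluded (and counted) — low
denominators otherwise produce unrealistically large ratios. `condition_deltas()`
reports hyper-minus-normo ATT (s and %) and aBV changes with the same
floor rule, and `regional_summary()` aggregates mean, sample SD
($n-1$) and voxel counts per region (ROIs intersected with GM, plus
whole-GM and arterial regions); report columns round to one decimal
while full precision is retained.

## The digital phantom

`make_phantom()` builds a desk-scale cylindrical head on a
$32\times32\times4$ grid: CSF core, WM annulus, GM rim, a one-voxel
arterial line crossing the head, background outside; four quadrant
pseudo-lobes partition the GM for regional summaries. Normocapnic
defaults are GM $f=60$, $\Delta t = 1.0$ s with mild dispersion
($s = e^2 \approx 7.39$ /s, $p = 0.1$ s); WM 20 and 1.3 s; arteries add
aBV $=1\%$ arriving at 0.5 s on GM-like tissue. Note the generator's
$p$ is deliberately not the prior-mean value
($e^{-0.3}/e^{2}\approx0.055$ s): a fitter should not be handed data
generated exactly at its prior. Hypercapnia multiplies CBF by 1.33,
shortens transit times by 15% and scales aBV by 0.7, with a synthetic
PETCO2 pair of 38.8/46.6 mmHg.

`simulate_acquisition()` evaluates every voxel's difference signal at
slice-correct times, scales by the voxel's $M_{0a}$ (derived from the
baseline image by the same relation the calibrator uses, so noiseless
round trips are exact), and emits control/label volumes as baseline
$\pm \Delta M/2$ plus independent white Gaussian noise per volume —
the subtraction then has noise SD $\sqrt{2}\,\sigma$, and averaging the
8 repeats gives $\sqrt{2}\,\sigma/\sqrt{8}$. By default $\sigma$ is set
so the per-PLD-averaged peak-GM SNR is 10. Everything is reproducible
from a single seed (the hypercapnic run offsets it so conditions draw
independent noise), and the generator leaves the session RNG untouched.

What the phantom does **not** emulate: background suppression,
EPI-related spatially varying noise, motion, partial-volume mixing at
tissue borders (the GM PVE map is binary by default), and any
macrovascular signal inside ordinary GM voxels — real grey matter
always contains some arterial contribution, the phantom's GM contains
none. Passing tests therefore demonstrate correctness of the
estimators under idealized noise, not robustness to real-data
artefacts. The zero-aBV choice for GM has one visible consequence:
free-energy model comparison over phantom GM favours the simplest
model, because the two extra parameters of the arterial component
cannot improve the evidence in voxels with literally no arterial
signal and six averaged PLDs give the dispersion misfit little room
above the noise floor at SNR 10. The package reports this comparison
honestly rather than engineering the phantom to reverse it; on data
with genuine macrovascular contamination the full model is the one to
reach for.

## Problem sizes and determinism

The test suite and the acceptance script fit the four models on the
GM + artery voxels of the default phantom (about 1 000 voxels,
~2 minutes on one core; undispersed voxels fit in ~3 ms, dispersed in
~40 ms) and run the end-to-end pipeline smoke on a reduced
$16\times16\times2$ grid. Voxel fits are deterministic; the only
randomness is simulation noise and the optional jittered restarts in
`fit_volume()`, both driven by explicit seeds.

## Known limitations

* Two-compartment exchange models, pulsed-ASL labelling and spatial
  (neighbourhood) priors are out of scope.
* The ARD treatment is the standard plug-in update; a fully Bayesian
  ARD hyperprior would change free energies slightly.
* Repeats are averaged per PLD before fitting (an 8-fold cost
  reduction); the noise posterior then describes the averaged series.
* Negative posterior means (possible at low SNR under the Gaussian
  posterior) are reported as-is, with zero-floored display variants
  alongside.
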