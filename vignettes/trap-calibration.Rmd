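---
title: "Calibrating an optical trap from detector trajectories"
author: "trapcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an optical trap from detector trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcal)
```

## The physical model

A dielectric microsphere held by a focused laser beam experiences, near the
focus, a restoring force proportional to its displacement: the trap is a
harmonic potential with stiffness $\kappa$ (N/m) per axis. The bead's
overdamped Brownian motion in that potential is an Ornstein–Uhlenbeck (OU)
process with relaxation rate $\lambda = \kappa/\gamma_0$, where
$\gamma_0 = 6\pi\eta r$ is the Stokes drag of a sphere of radius $r$ in a
solvent of dynamic viscosity $\eta$. Two standard consequences carry the
whole calibration:

* the one-sided power spectral density of the position is a Lorentzian,
  $P(f) = \frac{k_BT}{\pi^2\gamma_0\,(f_c^2+f^2)}$, with corner frequency
  $f_c = \kappa/(2\pi\gamma_0)$, so a spectral fit yields
  $\kappa = 2\pi\gamma_0 f_c = 12\pi^2\eta r f_c$;
* equipartition fixes the stationary positional variance,
  $\sigma_m^2 = k_BT/\kappa$.

The detector (a position-sensing photodiode watching the laser light
reflected off the bead) reports voltages, not positions. The *position
calibration constant* $\delta$ (nm per mV, or nm per dimensionless
"a.u." when the difference signals are normalized by the total intensity)
links the two. The $\sigma$-method computes it as
$\delta = \sigma_m/\sigma_{PSD}$, the ratio of the equipartition-predicted
spread to the spread of the (filtered) detector signal; the hydrodynamic
method instead compares a camera-measured bead displacement against the
detector's deflection. Throughout the package $k_B$ is fixed at
$1.38\times10^{-23}$ J/K, the value the calibration formulas use.

All internal arithmetic is in SI units (m, s, V, Pa·s, N/m); the reporting
layer converts to the units practitioners quote (pN/µm, nm/mV, nm/(a.u.)).

## The estimator behind `fit_lorentzian()`

Periodogram ordinates are exponentially distributed about the true
spectrum, so a plain unweighted regression of $1/P$ on $f^2$ is dominated
by the occasional near-zero ordinate ($E[1/P]$ does not even exist for a
raw periodogram). `fit_lorentzian()` therefore uses the analytical
least-squares solution of the Berg-Sørensen–style fit: it minimizes
$\sum_f \big(P(f)(\alpha + \beta u(f)) - 1\big)^2$, which is a
density-weighted linear regression of $1/P$ on the frequency basis $u$ with
a closed-form solution and finite moments. Every bin then contributes its
*relative* error, which is also what makes the fit scale-invariant.

Two bases are available:

* **continuum**, $u = f^2$: the textbook Lorentzian,
  $f_c = \sqrt{\alpha/\beta}$. Exact when the data really follow
  $A/(f_c^2+f^2)$ (the package's self-consistency tests refit generated
  Lorentzians to machine precision).
* **sampled**, $u = \cos(2\pi f/f_s)$: the exact spectral density of a
  harmonically trapped bead *observed at a finite sampling rate* (the
  sampled OU process is an AR(1) process, whose spectrum is the aliased
  Lorentzian). The regression recovers the autoregressive coefficient and
  hence $f_c$ with no aliasing bias at all.

The distinction matters quantitatively: at the package's reference
conditions ($f_c \approx 46$ Hz, 10 kHz sampling, fit band 5–2500 Hz) the
continuum fit applied to sampled data is biased high by about +8%, entirely
through aliasing, while the sampled basis is exact in expectation. The
calibration pipeline always uses the sampled basis on native-rate records.

The corner frequency is *defined* here as the fitted Lorentzian parameter.
Descriptions of $f_c$ as the point of maximum curvature of the log–log
spectrum are treated as just that — descriptions; the fit parameter is the
well-defined estimator.

The default fit band is 5 Hz to a quarter of the (effective) Nyquist
frequency: the lower edge excludes DC and slow drift, the upper edge stays
clear of the strongly attenuated top of the band. Both edges are plain
arguments.

### Block-averaged records

Acquisition at 100 kHz followed by 10-point blocking (the mode the
instrument class uses) is a decimating moving-average filter. Its magnitude
response is known exactly, and its in-band droop is *not* negligible: left
uncorrected it biases the fitted corner frequency by −7% to −13% over the
default band. When `calibrate_trap()` blocks a record itself, or is told
through `pre_blocked` (or the sidecar key `blocked_by`) that the
acquisition software already did, it divides the squared response out of
the spectrum and fits on the continuum basis; the residual deterministic
bias, evaluated on the closed-form folded spectrum, is below +0.4%. This is
not an aliasing correction of the physics — it merely inverts a filter that
the software applied and whose coefficients are known.

## Spike removal

Apparatus vibrations put high, narrow peaks into the force spectrum.
`remove_spikes()` compares every ordinate with the moving average of 20
points on each side of it (excluding the point itself; flanks shrink near
the edges) and replaces ordinates exceeding 5 times that local average —
both numbers are arguments; the flank width follows the typical choice, and
the factor 5 was fixed once as a level far above the scatter of
exponentially distributed ordinates (the 99.9th percentile of an
exponential is 6.9 times its mean, but a 41-point local mean concentrates
sharply, so genuine Lorentzian bins essentially never trip it while
interference lines tens of times above the continuum always do). Detection
runs against the *original* ordinates, so the edit has bounded support and
repairing a spectrum twice changes nothing further.

## Choosing the denoising window

The $\sigma$-method needs $\sigma_{PSD}$ from a moving-average-filtered
trajectory. Too little averaging leaves electronics noise in the spread;
too much removes genuine trajectory detail. As the window $w$ grows,
$\log\delta$ (equivalently $-\log\sigma_{PSD}$, since $\sigma_m$ only adds
a constant) first climbs at slope $\tfrac12$ while white noise dominates,
then bends onto a plateau once the noise is gone. `select_averaging_window()`
computes the discrete curvature (second divided differences) of
$\log\delta$ against $\log w$ on the candidate grid and returns the window
at the most negative curvature — the sharpest bend. A curve whose interior
curvature never drops below −0.02 is declared featureless (a clean record:
nothing to remove) and the smallest candidate is returned with a warning.
On trap records with noise several times the signal spread, the selector
lands at 10–20 points out of {1, 2, 5, 10, 20, 50, 100}, the same range the
filtering study on real records singles out; with noise-free input it falls
back to 1.

The power spectrum is always computed from the *unfiltered* (only blocked)
record — moving-average smoothing would distort the Lorentzian — while
$\sigma_{PSD}$ uses the filtered one. That asymmetry follows the method
definitions, not convenience.

## Trap potential by Boltzmann inversion

The stationary distribution obeys $P(x) \propto e^{-V(x)/k_BT}$, so the
normalized position histogram gives
$V(x) = -k_BT\,\ln\!\big(P(x)/P(x_{\min})\big)$ with the minimum aligned to
zero. Histograms use 100 equal-width bins spanning at least the mean ±5
standard deviations (extended to cover the data, so probabilities always
sum to one — that normalization is the partition function). Empty bins have
undefined potential and come back `NA`, never ±Inf. Mode detection for
double-trap records takes local maxima of a lightly smoothed histogram,
separated by at least 3 bins and at least 5% of the tallest peak (the last
condition rejects stray single-sample tail bins); per-mode Gaussian
parameters are moment estimates on the samples on each side of the valley.
`barrier_height()` smooths the reconstructed potential over ±2 bins before
locating its two minima, then reports the raw maximum between them, also
converted to eV at the record's temperature.

## What the simulator does and does not emulate

`simulate_bead()` propagates each principal axis with the *exact* OU
transition (mean decay $e^{-\lambda\Delta t}$, innovation variance
$(k_BT/\kappa)(1-e^{-2\lambda\Delta t})$), so there is no time-step bias at
any rate — a deliberate choice: parameter-recovery tests then probe the
estimators, not the integrator. The double-trap mode models the trap pair
as two inverted Gaussian wells along the line joining the centres (depth
and width per well, forces by analytic derivative) with an independent
harmonic transverse axis. The separable form is a choice: it makes the
axial marginal exactly Boltzmann in the axial potential, so Boltzmann
inversion can be validated without a dimensional-reduction bias. The axial
coordinate uses Euler–Maruyama; steps with
$\Delta t\,\kappa_{\max}/\gamma_0 > 0.1$ (well-bottom curvature
$\kappa = D/w^2$) are refused with a pointer to a higher rate. Note the
wells must overlap enough (centre separation of roughly 2–3 widths) that
the inter-well saddle lies well below the outer escape level; widely
separated Gaussian wells of modest depth let the bead escape outward, which
is faithful to the potential shape but rarely what a test wants.

`simulate_detector()` adds per-axis linear gain, white Gaussian electronics
noise, optional interference sinusoids, and an aggregated-channel baseline.
Defaults were fixed once from the instrument class being emulated: gain
$1.152\times10^5$ V/m (the reciprocal of an 8.68 nm/mV calibration
constant, reproducing a ~2.8 mV signal spread for the reference bead) and
0.1 mV noise on a 10 kHz effective record — a few percent of the signal,
i.e. a record that looks noisy raw and clean after modest averaging.

Not emulated: hydrodynamic memory and inertia (the spectrum is a pure
Lorentzian, with no frequency-dependent drag), detector bandwidth rolloff,
low-frequency drift, camera images, and 1/f electronics noise. Passing
tests therefore demonstrate correctness of the estimators under the stated
model, not robustness to every artifact of real instruments.

## Mixed-solvent viscosity

Stiffness conversion needs $\eta$. For a binary mixture the model follows
the standard excess-viscosity construction: the mole-fraction-weighted
linear baseline $\eta_{lin} = \eta_A(T)(1-x_B) + \eta_B(T)x_B$, per-isotherm
polynomial fits (order 3–6, power basis centred at $x_B = 0.5$ for
conditioning) of the excess $\eta^E = \eta_{exp} - \eta_{lin}$, and
temperature carried by the simplified Vogel–Fulcher–Tammann relation —
$\ln\eta$ linear in $1/T$ — which holds well over narrow ranges. The excess
vanishes at the pure endpoints by definition, so the isotherm fits include
those two zeros and the evaluated model reduces to the pure components
exactly at $x_B \in \{0, 1\}$.

A negative excess is physically common, and its logarithm is undefined; the
temperature regression therefore runs on $\ln|\eta^E|$ with a one-sign
consistency check across the isotherm series, falling back to a linear
regression of $\eta^E$ itself on $1/T$ (with a warning) when the series
changes sign. The built-in water reference table (15–35 °C, 1 K steps) is
generated from the standard three-parameter Vogel correlation for water,
$\eta = 0.02939\,e^{507.88/(T-149.3)}$ mPa·s, and evaluated through the
same VFT regression; at 297.25 K it gives 0.9126 mPa·s, within 0.3% of the
0.910 mPa·s the worked stiffness example uses (handbook tables themselves
differ at this level).

## Numerical choices and degenerate inputs

* DAQ range arithmetic is implemented exactly as specified for the board:
  unipolar $[0, V_{max}/g]$, bipolar $\pm V_{max}/(2g)$, one-bit resolution
  $V_{max}/(g\,2^{b})$. Whether the bipolar half-range is intended physics
  or should read $\pm V_{max}/g$ is ambiguous in the source material; it is
  implemented as printed, and both conventions satisfy the width identity
  tested (range width $= V_{max}/g$).
* Filter edge policy: the moving average shrinks its window at the record
  edges (output length = input length); FIR application zero-pads, with a
  documented start-up transient of $M$ samples; IIR recursion starts from
  zero state. The non-causal moving average requires an odd window and
  rounds an even request up with a message.
* Blocking drops a trailing partial block.
* PCA on a zero-variance record, histograms of constant records,
  single-well potentials passed to `barrier_height()`, fit bands without
  the corner, unstable IIR designs, and out-of-range viscosity queries all
  raise classed errors (`trapcal_*_error`) rather than returning NaN.
* Reproducibility: every stochastic generator takes an integer seed and the
  same seed reproduces the run bit for bit.

## Problem sizes used in the shipped checks

The package's own test suite and the bundled acceptance script size their
simulations as a scientist would for a desk validation: ten independent
100 s records at the 10 kHz effective rate (10^6 samples each) for the
corner-frequency and equipartition recovery runs; 100 s records per seed
for the stiffness/calibration-constant recovery across a 20× stiffness
range; a single 10^6-sample double-well run for the barrier recovery. With
these sizes the median fitted $f_c$ lands within a fraction of a percent of
its target and recovery medians sit well inside the 5% (κ, δ) and 15%
(barrier) contracts the tests assert.

## Known limitations

* The Lorentzian model carries no hydrodynamic, aliasing-filter or
  anti-aliasing corrections beyond the exact sampled basis; at corner
  frequencies approaching the Nyquist frequency the simple model itself is
  the limit.
* The $\sigma$-method inherits any residual noise in $\sigma_{PSD}$: noise
  that the averaging window cannot remove biases $\delta$ downward (noise
  inflates $\sigma_{PSD}$), which is why the window selector errs on the
  small side for clean records.
* Hydrodynamic calibration consumes camera displacements as numbers; no
  image analysis is provided.
* The double-trap position calibration holds within each well; between
  wells the detector response of a real instrument is not comparable, and
  the package makes no attempt to model that inconsistency.
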