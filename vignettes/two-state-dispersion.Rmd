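---
title: "Two-state exchange analysis of relaxation dispersion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state exchange analysis of relaxation dispersion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfit)
```

## The model

`rdfit` analyses relaxation dispersion data under the two-site
Bloch–McConnell model: a ground state GS and an excited state ES with
populations $p_{GS}$ and $p_{ES} = 1 - p_{GS}$ interconvert with
microscopic rates $k_{GS \to ES} = p_{ES}\,k_{ex}$ and
$k_{ES \to GS} = p_{GS}\,k_{ex}$, so that the total exchange rate is
$k_{ex}$ and detailed balance holds by construction
(`two_state_exchange()`).  Each probe nucleus carries a chemical-shift
difference $|\Delta\omega|$ between the states; dispersion data are
blind to its sign, so only magnitudes are fitted and reported.  Shift
differences are handled in ppm and converted per profile with
$\Delta\omega_{rad} = 2\pi\,\Delta\omega_{ppm}\,(\gamma_X/\gamma_H)\,B_{MHz}$,
the static field always being recorded as the proton Larmor frequency
(ratios: 0.25144 for carbon-13, 0.94094 for fluorine-19).

Assumptions shared by all forward models:

* exchange is two-site; linear three-site topologies are out of scope;
* radio-frequency pulses are ideal and instantaneous; off-resonance
  pulse effects are neglected;
* initial magnetization is populated at equilibrium $(p_{GS}, p_{ES})$
  in both states (exchange is fast relative to the recycle delay);
* intrinsic relaxation is state-independent within one profile
  ($R_2^{GS} = R_2^{ES} = R_2^0$), but $R_2^0$ is free per probe ×
  field × experiment type × temperature (SQ and MQ coherences relax
  differently, so they never share $R_2^0$).

## CPMG propagation and the detection convention

The CPMG frequency convention is $\nu_{CPMG} = 1/(2\tau)$ with $\tau$
the spacing between the centres of successive refocusing pulses, so the
pulse count is $N = 2\,T_{CPMG}\,\nu_{CPMG}$; every frequency on the
supported grids yields an integer $N$ and anything else is rejected as
a configuration error (tolerance 0.05 on $N$ absorbs values printed to
one decimal such as 83.3 Hz).

For the single-quantum experiment the 2×2 complex evolution matrix
(diagonal $-R_2 - k_{out} + i\Delta\omega$ per state, off-diagonal the
entry rates) is exponentiated analytically over $\tau/2$ and the echo
$\tfrac{\tau}{2} - 180^\circ - \tfrac{\tau}{2}$ is applied $N$ times,
with the ideal $180^\circ$ pulse acting as complex conjugation of the
magnetization.

Two conventions exist for turning the propagated magnetization into an
effective rate, and they differ by up to a few s⁻¹ in slow exchange:

* **`detection = "eigen"` (the default).**  $R_{2,eff}$ is the decay
  rate of the slowest-decaying mode of the two-echo cycle propagator
  $E\,\bar E\,\bar E\,E$ — equivalently, the propagated and initial
  magnetization are both projected on the dominant component before
  taking $-\log(\cdot)/T_{CPMG}$.  This is exactly the quantity the
  Carver–Richards closed form describes, which makes an analytic
  oracle available at $10^{-6}$ s⁻¹ across all exchange regimes, and it
  makes the MQ → SQ reduction at $\Delta\omega_H = 0$ exact.
* **`detection = "signal"`.**  The summed transverse magnetization is
  detected after explicit propagation,
  $-\log(|M(T)|/|M(0)|)/T_{CPMG}$, which additionally carries the
  amplitude factor of the minor mode.  This mimics integrating the
  full peak and is provided for comparison; both paths are validated
  against brute-force Runge–Kutta integration in the test suite.

Because generator and fit always use the same convention, recovery
studies are insensitive to this choice; it matters only when comparing
absolute $R_{2,eff}$ values across software.

The multiple-quantum (methyl TROSY) element propagates zero- and
double-quantum two-state amplitude vectors whose excited-state
evolution frequencies are $\Delta\omega_H - \Delta\omega_C$ and
$\Delta\omega_H + \Delta\omega_C$.  Every carbon refocusing pulse
interconverts ZQ and DQ; one proton refocusing pulse at $T_{CPMG}/2$
swaps coherence order with conjugation.  The exact placement of the
proton pulse relative to the carbon pulse blocks is not dictated by the
data model; the swap-at-midpoint scheme of the standard MQ dispersion
experiment is adopted.  Under eigenvalue detection the midpoint pulse
leaves the decay magnitude unchanged (the two halves are complex
conjugates), which is why the default rate can be computed from the
two-echo cycle of the ZQ channel alone.  SQ profiles are monotone
non-increasing in $\nu_{CPMG}$; MQ profiles may be non-monotone when
$\Delta\omega_H \neq 0$ and no monotonicity is asserted for them.

## On-resonance spin lock

`r1rho_onres()` builds the 6×6 two-state rotating-frame matrix —
$\{x, y, z\}$ per state with $R_2^0$, $R_1$, exchange rates, residual
offsets and the lock field $\omega_1 = 2\pi\nu_{SL}$ — and places the
carrier on the *observed* averaged peak: the offset of the dominant
component of the free-precession exchange matrix
(`free_precession_eigen()`), recomputed from the current parameters
during optimization.  This mirrors acquisition centred on the peak
maximum and avoids the error of assuming the population-average
position.

Two extraction paths are implemented and required to agree within 1%
over the supported spin-lock grids: the decay rate of the
rotating-frame eigenmode with dominant overlap with the lock axis
(default; note the naively slowest eigenvalue belongs to a precessing
mode with near-zero projection, so modes are ranked by their
contribution to the locked signal), and explicit matrix-exponential
propagation over the spin-lock times followed by a mono-exponential
fit.  A non-decaying propagated signal raises a numerical-fit error
rather than returning a rate.

## Fitting

`fit_global()` minimizes $\sum \left((y - \hat y)/\sigma\right)^2$ with
Levenberg–Marquardt trust-region least squares (`minpack.lm::nls.lm`,
finite-difference gradients).  Two-state dispersion fits are multimodal
in $(p, \Delta\omega)$, so every fit restarts from a grid over
$k_{ex} \in \{10^2, 10^3, 10^4\}$ s⁻¹ × $p_{GS} \in \{0.6, 0.9\}$ by
default; per start, $|\Delta\omega|$ is initialized from the dispersion
amplitude via the fast-exchange relation and $R_2^0$ from the
high-frequency plateau.  The best converged start wins; if no start
converges the per-start diagnostics are raised as an error.

Numerical and statistical choices:

* **Bounds.** $p_{GS} \in (0.5, 0.995)$ — fitting the ground state as
  the majority species resolves the $p \leftrightarrow 1 - p$ symmetry
  of dispersion data; $k_{ex} \in [10, 10^5]$ s⁻¹;
  $|\Delta\omega| \in [0, 10]$ ppm; $R_2^0 \in [0.1, 500]$ s⁻¹.  All
  overridable through `fit_schema()`.  Parameters that finish on a
  bound are reported in the result and raised as an identifiability
  warning (a flat profile, for example, drives $|\Delta\omega|$ to
  zero and leaves $k_{ex}$ undetermined).
* **Replicates.**  Replicate rates are averaged to one point per
  frequency with $\sigma$ = the sample standard deviation, then floored:
  0.2 s⁻¹ for carbon-13 CPMG data and 2 s⁻¹ for fluorine-19 data by
  default.  Flooring prevents points with accidentally low replicate
  scatter from dominating the fit; it also makes the resulting
  uncertainties deliberately conservative (see below).
* **$R_1$.**  An on-resonance lock tilts the magnetization to ≈ 90°,
  so the decay carries essentially no $R_1$ information; a free $R_1$
  simply drifts to a bound.  It is therefore held fixed (default
  2 s⁻¹, the kind of value an independent longitudinal measurement
  supplies) unless `fit_schema(fit_R1 = TRUE)`.
* **Scopes.**  `fit_temperature_series()` shares one $|\Delta\omega|$
  per probe across all temperatures and fields with independent
  $(p_{GS}, k_{ex})$ per temperature; intrinsic rates stay per
  temperature (whether they should be shared across temperatures is
  genuinely open; per-temperature is the safer default and is what the
  schema emits).  `fit_joint_nuclei()` shares $k_{ex}$ — and by default
  $p_{GS}$ — across nuclei at one temperature.  With a single
  temperature or nucleus the scoped schemas collapse to the global one,
  so the specialized fits reduce exactly to `fit_global()`.
* **Degrees of freedom.** $\chi^2_\nu = \chi^2 / (N_{points} -
  N_{free})$; constrained surface points keep the unconstrained
  $N_{free}$ so the surface value at the optimum equals the
  unconstrained $\chi^2_\nu$.

`monte_carlo_errors()` perturbs every rate by a centred Gaussian of its
$\sigma$, refits from the best-fit solution and reports per-parameter
standard deviations over the cycles (default 500; deterministic given
the seed, which is recorded).  Perturbation is applied at the rate
level, matching how the uncertainties are defined; more than 10%
failed cycles is an error.  Because $\sigma$ floors clip low replicate
scatter from below, Monte Carlo intervals tend to over- rather than
under-cover — the coverage test in the suite sits at the top of its
expected band for exactly this reason.

`chi2_surface()` fixes the probed parameter on a grid and re-optimizes
everything else from the best fit; failed grid points are flagged, not
dropped.  The suite checks that the Monte Carlo spread of $k_{ex}$
agrees with the $\chi^2_{min} + 1/dof$ profile-likelihood half-width
within a factor of two.

## The synthetic-data generator

Fixtures bundle ground-truth parameters, acquisition grids, a noise
model, replicate counts and a seed; regeneration from the same seed is
bit-identical.  Two study designs ship with the package:

* `fixture_c13_313K()` — five methyl probes, SQ + MQ CPMG at 500, 600
  and 800 MHz (six dataset blocks), $T_{CPMG}$ = 24 ms, the standard
  13-point frequency grid, duplicate acquisition, exchange truth
  $p_{ES} = 0.181$, $k_{ex} = 710$ s⁻¹.
* `fixture_f19_multiT()` — one fluorine probe, CPMG ($T_{CPMG}$ =
  16 ms) and 18-point on-resonance spin-lock grids at 500 and 600 MHz,
  five temperatures from 303 K to 313 K, triplicate acquisition;
  $p_{GS} = 0.50$ at every temperature, $k_{ex}$ linear from 445 to
  913 s⁻¹, $|\Delta\omega| = 0.15$ ppm.

Per-probe shift differences and intrinsic rates are not published
quantities; the fixtures carry explicit stand-ins, chosen once and
recorded in `R/synthetic.R`: carbon $\Delta\omega_C$ between 1 and
3 ppm and $\Delta\omega_H$ up to 0.2 ppm per probe, SQ/MQ $R_2^0$
between 15 and 26 s⁻¹ depending on field, and fluorine $R_2^0 =
115$ s⁻¹ — the value at which the dominant-eigenvalue linewidth
($R_{2,obs}/\pi$) of the apo fixture at 500 MHz and 313 K is ≈ 55 Hz —
with $R_1 = 2$ s⁻¹.

Noise is applied at the intensity level, where acquisition noise
lives: CPMG intensities are $I(\nu) = I_0 e^{-R_{2,eff} T_{CPMG}}$ with
multiplicative Gaussian noise of fraction $f = \text{floor} \times
T_{CPMG}$, so the replicate scatter of $R_{2,eff}$ lands on the
experiment's noise floor (0.2 s⁻¹ carbon, 2 s⁻¹ fluorine); spin-lock
decays use $f = 0.05$, which propagates through the exponential fit
over the five lock durations (0, 4, 8, 16, 32 ms) to a rate scatter of
about 2 s⁻¹.  Spin-lock data are simulated as mono-exponential decay at
the model rate $R_{1\rho}(\nu_{SL})$; the alternative of projecting the
fully propagated 6×6 magnetization can cross zero at low lock fields on
the slow-exchange side (where $\Delta\omega > k_{ex}$), which would
poison a log-linear extraction and does not correspond to how rates are
measured in practice.

What the generator deliberately does **not** emulate: spectral
(FID-level) effects — peak overlap, baseline and phase errors, $B_1$
inhomogeneity, off-resonance pulse imperfections — nor temperature
dependence of chemical shifts, probe-to-probe noise correlations, or
three-state kinetics.  Passing recovery tests therefore demonstrate
that the estimator is correct and well calibrated *under the model's
own assumptions*; they do not certify robustness to the systematic
errors of real spectra.

## Validation studies and problem sizes

The test suite runs entirely on generated data, at sizes chosen to
exercise the full designs while keeping a complete run in the
minutes range:

* propagator oracles: Carver–Richards agreement to $10^{-6}$ s⁻¹ over
  $k_{ex}/|\Delta\omega| \in [0.1, 100]$; brute-force Runge–Kutta
  integration of the MQ element at 1 µs steps; fast-exchange closed
  forms for CPMG and spin lock; MQ → SQ and no-exchange reductions;
* recovery at the fixtures' generating truths: the full
  multi-temperature fluorine design (20 profiles, 335 points, 31 free
  parameters) and the six-block methyl design (30 profiles, 390
  points, 42 free parameters), judged against the generating values;
* a 100-replicate stochastic study on the single-temperature fluorine
  fixture with 60-cycle Monte Carlo per replicate, checking median
  recovery and empirical 1σ coverage;
* 100-replicate simulation studies for turnover-rate and $K_D$
  recovery.

## Known limitations

* Two-site exchange only; no model selection against 3-state or
  no-exchange alternatives beyond the $\chi^2_\nu$ itself.
* Off-resonance $R_{1\rho}$ (tilted-frame, carrier scans) is not
  implemented; the carrier policy assumes on-resonance acquisition.
* Monte Carlo uncertainties inherit the conservatism of the $\sigma$
  floors; when replicate scatter genuinely exceeds the floor they are
  well calibrated, otherwise they over-cover.
* The population bound $p_{GS} > 0.5$ makes symmetric-exchange systems
  ($p_{GS} \approx 0.5$) sit at a constraint; estimates of $k_{ex}$
  and $|\Delta\omega|$ remain well behaved there, but $p_{GS}$
  uncertainties from Monte Carlo are one-sided.
* Temperature dependence is checked post hoc with `linear_trend()`;
  Arrhenius/van 't Hoff constrained fitting is out of scope.
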