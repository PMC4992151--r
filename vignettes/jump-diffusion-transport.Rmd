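---
title: "Jump-diffusion transport of microparticles in algal suspensions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jump-diffusion transport of microparticles in algal suspensions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainr)
```

This vignette is the methods account of `entrainr`: the model and its
assumptions, the estimator conventions, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## The model

A passive micron-sized particle in a dilute suspension of swimming microalgae
experiences three well-separated effects: thermal Brownian motion, small
loop-like displacements from the far-field flow of passing swimmers, and rare
near-contact **entrainment** events in which the particle is dragged along a
swimmer for many micrometres.  The package models the 2D projection of this
dynamics as a jump-diffusion process:

* while *diffusing*, the particle performs isotropic Brownian motion with
  diffusivity $D_{WJ} = D_0 + \alpha_{WJ} N_c$.  The slope $\alpha_{WJ}$
  coarse-grains all far-field effects *and* entrainment events shorter than
  the threshold $L_T$; no explicit flow fields are computed;
* jump initiations form a Poisson process in diffusive time with mean waiting
  time $\langle \Delta T_J \rangle = A_\text{wait}/N_c$, reflecting the
  encounter rate between the particle and the "active flux" $v N_c$ of
  swimmers;
* a jump is a straight run of end-to-end length $L = L_T + \mathrm{Exp}(L_J)$
  along a uniformly random direction, traversed at constant speed $L/\tau_J$
  for exactly $\tau_J$ seconds, during which the Brownian component is
  switched off.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `D0` | 0.40 | µm²/s | thermal diffusivity of a 1 µm bead |
| `alpha_WJ` | 0.33 | (µm²/s)/(10⁶ cells/ml) | far-field (+ sub-threshold jump) diffusivity slope |
| `L_T` | 7.5 | µm | jump-length threshold below which events are folded into `alpha_WJ` |
| `L_J` | 7.5 | µm | exponential tail scale of jump lengths above `L_T` |
| `tau_J` | 1.7 | s | jump duration (deterministic) |
| `A_wait` | 68.2 | s·(10⁶ cells/ml) | hyperbolic waiting-law coefficient |
| `v` | 49.1 | µm/s | mean swimming speed in the tracking geometry |

Concentrations are in units of 10⁶ cells/ml throughout (one unit =
10⁻⁶ µm⁻³); lengths in µm, times in s.  The defaults describe 1 µm
polystyrene beads among *C. reinhardtii* in a thin quasi-2D chamber and are
the conditions all default simulations emulate.

Two modelling assumptions deserve emphasis.  The jump duration is a
*deterministic* constant because its empirical distribution is much tighter
than that of the lengths; drawing it randomly would add a second nuisance
scale without changing any long-time quantity.  And jumps are *ballistic*
straight segments (consistent with the ballistic state of the continuum
model); an `"instant"` jump mode applies the whole displacement in one step
for studying the duration dependence of the diffusivity.

## The simulator

`simulate_ensemble()` integrates the process with an acceptance–rejection
initiation scheme: at each diffusing step one uniform variate is drawn, and a
jump starts when it falls in the centred interval of width
$\delta t / \langle \Delta T_J \rangle$; otherwise a Gaussian step of
per-axis variance $2 D_{WJ}\,\delta t$ is taken.  A new initiation is only
tested after the running jump completes, so the diffusive waits are geometric
with mean $\langle \Delta T_J \rangle$ — indistinguishable from exponential
at $\delta t = 0.004$ s.  The default step is 10× finer than a 25 fps camera
interval; validity requires $\delta t < \tau_J$ and
$\delta t / \langle \Delta T_J \rangle < 1$, both checked.

Each track consumes its own random stream, seeded from (master seed, track
index), so ensembles are reproducible regardless of how tracks are scheduled,
and `save_every` decouples the integration step from the recorded frame rate.

`simulate_sedimenting_ensemble()` adds a constant drift $-v_\text{sed}$ on
the vertical coordinate and mirror (fold-back) reflection at $y = 0$ and
$y = H$, applied also during jump segments.  Fold-back reflection is the
simplest scheme that preserves the uniform law when $v_\text{sed} = 0$, which
the tests verify.  Drift acts during jumps as well; at
$v_\text{sed} \sim 10^{-2}$ µm/s its displacement over one jump is
$\sim 0.05$ µm and has no measurable effect.

## Estimators

**MSD and diffusivity.**  `compute_msd()` time-averages squared
displacements over all overlapping pairs within each track and
ensemble-averages with pair-count weights; both coordinates contribute, so
pure diffusion gives $\mathrm{MSD} = 4Dt$.  `fit_diffusivity()` is ordinary
least squares with a free intercept on a lag window, default 2–20 s: beyond
the 1.7 s jump duration (so the asymptotic slope is sampled) yet short enough
for good pair statistics on a 200 s track.  The intercept absorbs
localization noise and the finite-$\tau_J$ offset.  The OLS standard error
underestimates the true uncertainty because MSD values at neighbouring lags
are strongly correlated; where tests need honest errors they use independent
per-track displacement estimates instead.

**Jump detection.**  `detect_jumps()` thresholds a windowed speed
(displacement over `smooth_window`, default 0.5 s, divided by the window).
The default threshold of 4 µm/s separates the thermal Brownian windowed speed
($\sqrt{4 D_0 w}/w \approx 1.8$ µm/s) from a typical jump speed
($15/1.7 \approx 8.8$ µm/s).  At higher concentrations the background is
$D_{WJ}$, not $D_0$, and a user can scale the threshold accordingly; the
parameter-recovery tests keep the default, restrict to detected events with
reported length $\ge L_T$ (the explicitly modelled population), and that
suffices.  Two conventions matter and are deliberate:

* an event's **time extent** runs between the centres of the first and last
  above-threshold windows, so `duration_s` tracks the true segment duration
  rather than the segment plus a smoothing window;
* its **reported length** is the end-to-end displacement over the full
  smoothing support of the run, which is unbiased for ballistic segments,
  while the *candidate filter* (`min_length`, default 3 µm) uses the
  displacement across the time extent only — short Brownian exceedances
  produce small extents and are discarded, keeping the false-positive rate on
  thermal Brownian tracks far below one event per 200 s track.

Because lengths are measured with noise near the detection limit, the tail
scale is best re-estimated with `jump_statistics(events, L_T = c)` at a cut
`c` safely above that limit (e.g. 10 µm): by memorylessness of the
exponential the excess mean above any cut estimates $L_J$.

**Waiting times.**  `waiting_time_stats()` reports two estimators.  The
*unbiased* one divides total observed diffusive time by the number of events
— insensitive to track duration.  The *naive* one is the maximum-likelihood
exponential scale (the mean) of gaps between consecutive initiations observed
within a track; finite tracks discard any gap extending beyond either end,
so this estimate is biased low.  For a Poisson process of rate $\lambda$
observed in a window of length $T$ the observed-gap density is proportional
to $(T-g)e^{-\lambda g}$, which for $1/\lambda = 43.7$ s and $T = 200$ s has
mean $\approx 32$ s — the package reproduces exactly this bias, which is why
naive gap fits on short tracks must not be used to calibrate the waiting
law.

**Displacement statistics.**  `displacement_pdf()` pools x and y
displacements (the process is isotropic) at a chosen lag; with
`exclude_jumps` it drops any pair whose interval overlaps a detected (or
ground-truth) event.  Non-Gaussianity is quantified by the modified kurtosis
$\kappa = \langle \Delta x^4 \rangle / (3\langle \Delta x^2 \rangle^2) - 1$,
zero in expectation for Gaussian data and 1 for a Laplace law.  This
definition was chosen as the natural "distance from the Gaussian limit";
other conventions differ only by affine rescaling of the same moment ratio.

## Continuum theory

The two-population transport model — densities of diffusing and ballistic
particles exchanging at rates $\lambda_d$ (diffusing→ballistic) and
$\lambda_b$ — closes at the level of three moments: the state-restricted
second spatial moments and the position–direction moment of the ballistic
population.  `msd_twostate()` integrates

$$M_d' = 4 D_{WJ} p_d - \lambda_d M_d + \lambda_b M_b,\qquad
  M_b' = 2 u C + \lambda_d M_d - \lambda_b M_b,\qquad
  C' = u\, p_b - \lambda_b C$$

with `deSolve` (tolerances $10^{-10}$/$10^{-12}$; the state probabilities are
carried redundantly so their conservation can be checked).  Short-time slope:
$4 x_d D_{WJ}$ with $x_d = \lambda_b/(\lambda_d+\lambda_b)$ — this is why
short-duration tracking sees only $D_{WJ}$.  The long-time closed form

$$D_\text{eff} = x_d\left[D_{WJ} + \frac{\lambda_d u^2}{2\lambda_b^2}\right]
 = x_d D_{WJ} + x_b \frac{u^2}{2\lambda_b}$$

was derived from the per-cycle renewal argument and is validated against
*both* the moment ODE's long-time slope (to 0.5%) and a direct two-state
Monte-Carlo simulation (to 3 standard errors) across a grid of rates and
speeds — a deliberate double-oracle contract, since the closed form is used
throughout.  Inverting $\lambda_d = \gamma v N_c$ against the waiting law
gives the entrainment cross-section
$\gamma = 1/(A_\text{wait} v \cdot 10^{-6}) \approx 299$ µm².

In the dilute regime ($\lambda_d \ll \lambda_b$) the diffusivity separates as
$D_0 + \alpha_{WJ} N_c + \lambda_d \langle L \rangle^2 / 2$ — the freely
jointed chain picture with exponential bond lengths
($\langle L^2 \rangle = 2\langle L \rangle^2$), independent of the jump
duration.  `deff_vs_concentration()` maps model parameters into the continuum
($u = (L_T + L_J)/\tau_J$, $\lambda_b = 1/\tau_J$), preserving mean run
length and duration but not $\langle L^2 \rangle$ exactly: the simulator's
fixed-duration, shifted-exponential jumps have
$\langle L^2 \rangle = 281.25$ µm² versus the continuum's 450 µm², so the
continuum curve sits above the per-cycle value for the simulated process.
This is a documented model-to-model approximation, not an error; tests
compare each prediction against its own oracle.  At high concentration the
curve saturates; because the far-field term keeps growing while $x_d \to 0$,
the limit is $u^2/(2\lambda_b) + \alpha_{WJ} A_\text{wait} \lambda_b$ — the
run-and-tumble plateau plus a finite far-field floor (about
$13$ µm²/s at the defaults, against a $\approx 66$ µm²/s plateau term).

## Macroscopic inversions

**Sedimentation.**  At steady state, settling at $v_\text{sed}$ balances
diffusion to give an exponential height profile of gravitational length
$l_g = D_\text{eff}/v_\text{sed}$ (Perrin).  `stokes_sedimentation_speed()`
uses $g\,\delta\rho\,d^2/(18\eta)$ with water viscosity 1.0 mPa·s by default
(≈21 °C, the culture temperature; a ±5% viscosity error propagates linearly
into $v_\text{sed}$ and hence into $D_\text{eff}$).
`fit_sedimentation_profile()` does weighted least squares of log-counts with
Poisson weights (weights ∝ counts) and by default drops bins with fewer than
10 counts to avoid log-of-small-count bias; whether to weight is a convention
choice, and the weighted form is the maximum-likelihood-like one for count
data.  A non-decaying profile is reported as an error rather than a huge
length.

**Band spreading.**  `band_profile_model()` solves 1D diffusion between
no-flux walls for a top-hat initial band by cosine series, adding terms until
their bound falls below $10^{-10}$ (the $t = 0$ case returns the exact
top-hat, avoiding Gibbs ringing).  `fit_band_spreading()` least-squares
matches full normalized profiles over the single parameter $D$ — full
profiles rather than the variance growth, because wall confinement in a 2 mm
channel breaks the free-space variance law at late times.  Profiles at
$t = 0$ carry no information about $D$ and are excluded.  The curvature-based
standard error underestimates the truth when bin noise is correlated by
normalization; the cross-method test therefore asserts consistency at the
two-sigma level of its problem size.

## Synthetic data: what it does and does not emulate

The generators emulate the three experiments with known ground truth:
finite 200 s tracks at 25 fps with Gaussian localization noise (default
0.05 µm, a typical sub-pixel centroid accuracy), steady-state sedimentation
profiles with Poisson counts at 10 fps-like statistics, and top-hat band
profiles relaxing diffusively.  The sedimentation generator samples the
analytic truncated-exponential steady state rather than running long Langevin
simulations — fast, and the Langevin route is covered separately by the
simulator tests, which also show its limits: with jump lengths (~15 µm) only
four times smaller than the gravitational length, the simulated confined
profile is exponential only to within ~5–10%, and equilibration from a
uniform start takes several multiples of $\bigl[D(\pi/H)^2 +
v_\text{sed}^2/4D\bigr]^{-1}$.

Deliberately *not* emulated: drift or stage registration errors,
track-linking mistakes, depth-of-field effects, variable track durations
(fixed 200 s is used; real tracking yields a duration distribution), swimmer
trajectories, and any near-field hydrodynamics.  Passing the recovery tests
therefore shows the estimator chain is correct and unbiased under the model's
own assumptions — not that the model captures every artefact of real
microscopy data.

## Problem sizes and tolerances in the test-suite

Statistical tests fix their seeds and use ensemble sizes chosen to keep the
whole suite under a few minutes while leaving 3-standard-error assertions
meaningful: e.g. 200–300 tracks for recovery tests, 1,000×2,000 s only in the
acceptance script's waiting-time recomputation, 27-point rate grids for the
double oracle, and $10^4$–$10^5$ particles for profile inversions.
Qualitative trend assertions (kurtosis decay, saturation curvature) are made
on widely separated points so that sampling noise cannot flip their sign.

## Known limitations

* The 2D model is a projection; no 3D simulation is provided.
* Sub-threshold entrainment is absorbed into $\alpha_{WJ}$; the split between
  "far-field" and "short jump" contributions is conventional, tied to $L_T$.
* The continuum mapping mismatches $\langle L^2 \rangle$ (above), so its
  absolute curves differ from the simulator's by up to ~35% at intermediate
  concentrations even though each is internally consistent.
* The jump detector assumes uniform frame intervals and isotropic noise; it
  has no sub-frame interpolation, so durations are quantized to the frame
  interval.
* Collective effects (swimmer–swimmer interactions, bioconvection) are
  outside the single-particle picture and all of its predictions.
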