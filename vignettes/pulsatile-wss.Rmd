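---
title: "Reconstructing pulsatile wall shear stress from 1D velocity waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pulsatile wall shear stress from 1D velocity waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(pulsewss)
```

## The problem

Wall shear stress (WSS) — the tangential viscous drag that flowing blood
exerts on the endothelium — is a central quantity in vascular physiology:
it regulates endothelium-dependent vasodilation and its oscillatory
component is implicated in both protective and atherogenic signalling.
In clinical practice WSS is almost always estimated from a single Doppler
velocity trace with the steady Poiseuille formula
$\bar\tau_w = 4\mu\bar U / R$, applied instant by instant
("quasi-steady").  That formula assumes the radial velocity profile is a
parabola at every moment, i.e. that the frequency content of the cardiac
cycle is negligible.  In conduit arteries it is not: at physiologic
Womersley numbers ($\alpha \approx 4$–$7$) the profile is blunted and
phase-lagged, and the wall shear responds to acceleration, not just to
instantaneous velocity.

`pulsewss` reconstructs the full time-varying solution from exactly the
two quantities a vascular laboratory can measure non-invasively — the
time-averaged lumen diameter and a one-dimensional velocity waveform
$U_{1D}(t)$ (cross-sectional mean or centerline) — and places the
quasi-steady Poiseuille estimate next to it so the two can be compared
like for like.

## The model

The waveform over one cardiac period $T$ is decomposed into one-sided
complex harmonics ($\omega = 2\pi/T$):

$$U_{1D}(t) = \mathrm{Re}\Big\{ B_0 + \sum_{n=1}^{N} B_n e^{in\omega t}
\Big\},$$

with $B_0$ the time-mean and, for a uniform $M$-point cycle,
$B_n = (2/M)\sum_k u_k e^{-in\omega t_k}$.  Each harmonic drives the
classical oscillatory pipe-flow solution for laminar axial flow in a
long, rigid, straight cylinder.  Writing
$\Lambda_n = \alpha\sqrt{n}\, i^{3/2}$ with
$\alpha = R\sqrt{\omega\rho/\mu}$, the reconstructed profile is

$$U(r,t) = 2B_0\Big(1-\tfrac{r^2}{R^2}\Big) + \mathrm{Re} \sum_{n=1}^{N}
B_n\,
\frac{1 - J_0(\Lambda_n r/R)/J_0(\Lambda_n)}
     {1 - 2J_1(\Lambda_n)/(\Lambda_n J_0(\Lambda_n))}\, e^{in\omega t},$$

where $J_0, J_1$ are Bessel functions of the first kind evaluated at
complex argument.  The per-harmonic radial shape is normalised by its own
area-mean (the denominator), so the cross-sectional average of $U(r,t)$
reproduces $U_{1D}(t)$ identically and the flow rate collapses to
$Q(t) = \pi R^2\, U_{1D}(t)$.  Differentiating at the wall gives the
shear series

$$\tau_w(t) = \frac{4\mu B_0}{R} + \mathrm{Re} \sum_{n=1}^{N} \mu B_n\,
\frac{-\Lambda_n J_1(\Lambda_n)/(R\,J_0(\Lambda_n))}
     {1 - 2J_1(\Lambda_n)/(\Lambda_n J_0(\Lambda_n))}\, e^{in\omega t},$$

and the oscillatory shear index over the cycle is
$\mathrm{OSI} = \tfrac12\big(1 - |\int_0^T\tau_w\,dt| /
\int_0^T|\tau_w|\,dt\big) \in [0, 0.5]$.

Three conventions are fixed once and tested:

* **Branch of $i^{3/2}$**: $e^{i3\pi/4}$, so $\Lambda_n$ has positive
  imaginary part.  The opposite branch yields the complex-conjugate
  solution; this one is the standard oscillatory-flow choice.
* **Sign**: $\tau_w$ is reported positive in the antegrade (mean-flow)
  direction.  The literal wall gradient $dU/dr|_{r=R}$ of forward flow is
  negative, so the wall factor carries a minus sign; retrograde
  (proximally directed) shear is negative.  In the $\alpha \to 0$ limit
  every harmonic factor reduces to the quasi-steady value $+4\mu/R$.
* **Centerline input**: the formulas above consume mean velocity.  A
  centerline recording is adapted by halving $B_0$ (parabolic steady
  component) and dividing each $B_n$ by the harmonic's centerline shape
  value $(1 - 1/J_0(\Lambda_n)) / (1 - 2J_1/(\Lambda_n J_0))$, so the
  reconstructed $U(0,t)$ reproduces the measurement.  As $\alpha \to 0$
  each factor tends to the parabolic value 2.

## A worked example

```{r example}
w <- synth_template("brachial_like", heart_rate = 70)
vessel <- template_vessel("brachial_like")
fit <- wss_analysis(w, vessel)
tidy(fit)
glance(fit)
```

```{r example-plot}
autoplot(fit)
```

The quasi-steady comparator underestimates systolic peak WSS by roughly
40–55% across the built-in templates and heart rates, reports zero OSI
whenever the velocity never reverses, and can only change sign when the
measured velocity does — the pattern that motivates using the pulsatile
solution for shear-stimulus quantification.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| viscosity `mu` | 4.5e-3 | Pa s | Newtonian whole-blood value used throughout |
| density `rho` | 1060 | kg/m^3 | whole-blood density |
| harmonics `N` | 20 | – | captures physiologic waveforms to sub-percent reconstruction error; configurable, capped by the Nyquist limit of the sampling |
| radial grid | 101 points on `[0, R]` | – | profile export and quadrature cross-checks to <0.1% |
| time grid | 200 points per cycle | – | resolves the 20th harmonic with 10 samples per oscillation |
| resampling | `max(256, 4(2N+2))` points | – | periodic cubic interpolation of non-uniform input bounds spectral leakage |

Diameter, not radius, is the public input (`vessel_spec(diameter = )`)
because that is what is measured clinically; conversion happens at the
boundary, as do cm/s, ms and mm unit conversions in the file readers and
the command-line tool.

## The synthetic generator

`synth_cosine()` produces the canonical single-harmonic test input
(mean 0.20 m/s, period 1.0 s by default): with only $B_0$ and $B_1$
non-zero, every stage of the pipeline is checkable by hand.

`synth_template()` produces deterministic multi-harmonic waveforms from
three fixed harmonic tables that emulate the classic Doppler appearance
of conduit arteries: a monophasic common-carotid-like wave (velocity
antegrade throughout) and triphasic brachial- and femoral-like waves
(forward systolic phase, early-diastolic reversal, small secondary
forward wave).  The accompanying vessels (`template_vessel()`) are sized
so the rest-state Womersley numbers are 4.3, 4.2 and 4.8 at
70 beats/min, and cycle means are derived from the rest / fear /
exercise Reynolds numbers (797/769/1150 carotid, 708/677/1044 brachial,
1393/1475/3141 femoral) of a young-adult systemic-circulation model, so
a heart-rate sweep over 70/100/150 beats/min spans
$\alpha \approx 4.2$–$7$.  The harmonic tables were drawn once, by
shaping sums of periodic Gaussian pulses until the wave classes held
(monophasic: min ≥ 0; triphasic: min < 0 < mean), and are committed as
fixtures; they are not fits to any measured recording.

What the generator does **not** emulate: measurement noise and spectral
broadening of Doppler envelopes, beat-to-beat variability, waveform
shape changes with heart rate (the same table is replayed at every
rate), vessel compliance, and any axial variation.  Tests passing on
these templates therefore demonstrate the correctness of the *solution*
given a periodic band-limited waveform, not robustness to every artifact
of clinical data; the optional seeded `jitter` argument exists for
rough robustness probes.

## Numerical choices

* **Complex Bessel functions.**  No Bessel routine for complex argument
  exists in the base/recommended stack, so $J_0$ and $J_1$ are computed
  by Miller's downward recurrence, normalised against
  $e^{\mp iz} = J_0 + 2\sum_k (\mp i)^k J_k$ with the sign chosen per
  half-plane so the normalising sum does not cancel.  This is accurate to
  near machine precision for $|\mathrm{Im}\,z| \le 600$ (verified against
  high-precision references); beyond that only the ratios
  $J_1/J_0$ and $J_0(zs)/J_0(z)$ are representable in doubles and they
  switch to Hankel asymptotic forms.  The switchover corresponds to
  $\alpha\sqrt{n} \approx 850$, far beyond physiology.
* **Degenerate harmonics.**  $J_0(\Lambda_n)$ has no zeros on the
  $e^{i3\pi/4}$ ray, but the factors are still guarded: a vanishing
  denominator raises a classed numerical error naming the harmonic and
  $\alpha$ rather than propagating NaN.
* **Periodicity and drift.**  The decomposition treats the cycle as
  exactly periodic.  Cycle-to-cycle drift is detected as the
  discontinuity of the periodic extension (quadratic extrapolation of
  the last three samples to $t = T$) and removed as a mean-preserving
  linear ramp; estimated discontinuities below 0.1% of the signal range
  are ignored so that clean band-limited input passes through
  unmodified.
* **Integrals.**  Time integrals (OSI, cycle means) use the trapezoid
  rule with periodic closure; radial quadrature uses composite Simpson.
  On the `[0, T)` grids used throughout, periodic trapezoid integration
  is spectrally accurate.
* **The independent oracle.**  `fd_pulsatile()` time-marches the
  unsteady axisymmetric momentum equation
  $\rho\,\partial_t u = G(t) + \mu\,\tfrac1r\partial_r(r\,\partial_r u)$
  with Crank–Nicolson stepping (unconditionally stable, so the step is
  set by accuracy) and second-order spatial differences, from the steady
  profile of the mean gradient until successive cycles differ by less
  than $10^{-6}$ in relative L2 norm.  The test suite verifies the
  analytic solution against it to <1% of peak velocity at
  $\alpha \in \{2, 4, 7\}$ on a 201 x 400 grid, checks second-order
  spatial convergence, and closes the velocity-driven loop: the area-mean
  of the finite-difference solution, fed back through the velocity-driven
  method, recovers the finite-difference wall shear to <1% of peak.
  Wall shear cross-checks difference the analytic profile on an 801-point
  radial grid.  These problem sizes keep the whole suite at roughly ten
  seconds on one core.

## Design decisions

* The flow-rate operation returns $\pi R^2 U_{1D}(t)$ directly.  The
  per-harmonic bracket that appears when the profile is integrated over
  the cross-section cancels algebraically (each shape function has unit
  area-mean by construction), and the quadrature cross-check confirms the
  identity numerically.
* "Time-averaged" WSS is reported two ways — the median over time
  samples and the trapezoid cycle mean — because the literature uses the
  term for both; method-comparison percentages are computed from the
  median, with the mean-based figure alongside.
* Comparison percentages are referenced to the Womersley value, which is
  treated as the reference method: `pct_diff_peak > 0` means the
  quasi-steady estimate underestimates peak shear, `delta_osi > 0` means
  it misses oscillatory shear.
* The quasi-steady comparator is evaluated from the same band-limited
  Fourier representation and on the same time grid as the pulsatile
  solution, so differences between methods reflect physics, not
  discretisation.
* The pressure-driven solution (`pressure_profile()`) takes harmonics of
  $-\partial p/\partial x$; substituting a single harmonic into the
  momentum balance fixes its coefficient as $-iG_n/(\rho n\omega)$ per
  harmonic.  It exists as a comparator and as the analytic reference for
  the finite-difference oracle, not as the primary interface — pressure
  gradients are rarely measurable non-invasively, which is the point of
  the velocity-driven formulation.
* A waveform needs at least 4 samples to be constructed (enough for the
  steady component plus one harmonic after resampling); meaningful use
  of the default 20 harmonics wants at least 42 and realistically a few
  hundred samples per cycle.

## Limitations

The solution assumes laminar, fully developed, axial flow of a Newtonian
fluid in a straight, rigid, circular tube.  Stenosed, strongly curved or
bifurcating segments, transitional/turbulent regimes (high-rate femoral
flow, reactive hyperemia), non-Newtonian effects at low shear, wall
compliance and axial taper all violate the assumptions to varying
degrees.  The reconstruction is also only as good as its input: envelope
extraction artifacts and low frame rates limit the harmonics that are
actually present in a Doppler trace, and the harmonic count should not
exceed what the measurement resolves.
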