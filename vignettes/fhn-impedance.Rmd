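---
title: "The FitzHugh-Nagumo neuron as an electrical element: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FitzHugh-Nagumo neuron as an electrical element: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnec)
```

## The model

`fhnec` analyzes a two-variable excitable-membrane model written in
dimensional electrical form. The state is the membrane voltage $u$ (V)
and a slow internal recovery current $w$ (A), driven by an applied
current $I$ (A):

$$C_m \frac{du}{dt} = I - \frac{1}{R_I}\left(\frac{u^3}{3u_1^2} - u\right) - w,
\qquad
\tau_k \frac{dw}{dt} = \frac{u}{R_w} - b\,w,$$

with $C_m = \tau_m/R_I$. The cubic channel current has negative slope
for $|u| < u_1$: a built-in negative differential resistance (NDR),
which is the firing mechanism. The recovery current models the delayed
ion-channel conductance changes that repolarize the membrane; for an
excitable membrane it is slow, $\tau_k \gg \tau_m$.

### Parameters

| Parameter | Meaning | Units | Typical/default |
|---|---|---|---|
| `tau_m` | voltage response time | s | $10^{-2}$ (all presets) |
| `tau_k` | recovery response time | s | `tau_m / epsilon` |
| `R_I` | channel resistor | ohm | 0.5 (all presets) |
| `R_w` | recovery resistor | ohm | `R_I / r` |
| `b` | recovery modulation constant | — | 0.8–1.2 |
| `u_1` | NDR reference voltage | V | 1 |

The dimensionless ratios $\varepsilon = \tau_m/\tau_k$ (time scales)
and $r = R_I/R_w$ (resistances) organize the dynamics; either pair
(`tau_k`,`R_w`) or (`epsilon`,`r`) may be supplied and the conversion is
exact. Built-in presets `A`–`F` share $R_I = 0.5\,\Omega$,
$\tau_m = 10^{-2}$ s and vary $(b, r, \varepsilon)$; `fig1a`/`fig1c`
($b = 0.8$, $\varepsilon = 0.1$, $r = 0.4$ or $1$) illustrate the
bistable and monostable branches of the stationary curve. Preset `C`
stores $\varepsilon = 0.316$ exactly as tabulated; note that
$10^{-1/2} = 0.3162...$ shifts its Hopf voltage by about $1.4\times
10^{-4}$ V, which is why checks on this preset use a slightly wider
band than the $10^{-5}$-accurate presets D–F.

## Stationary structure

The steady-state drive is
$I(u) = (u^3/3u_1^2 - u)/R_I + u/(bR_w)$, an odd function. For
$r/b < 1$ it is N-shaped: three fixed points exist around $I = 0$
(a middle branch flanked by two turning points at
$u_{SN} = \pm u_1\sqrt{1 - r/b}$, where $dI/du = 0$ — the saddle-node
pair), merging in a pitchfork at $r = b$. For $r/b > 1$ the curve is
single-valued. `fixed_points()` solves the cubic in closed form
(trigonometric branch when three real roots exist, a numerically stable
Cardano branch otherwise), polishes each root with one Newton step, and
merges roots closer than $10^{-9}u_1$ (tangency at a saddle-node). The
test suite checks this solver against a dense sign-change scan with
$10^5$ grid points on random parameter draws.

## Linear stability and bifurcations

The Jacobian at bias $u$ (with $w = u/(bR_w)$) has
$\mathrm{tr}\,J \cdot \tau_m = (1 - u^2/u_1^2) - \varepsilon b$ and
$\det J \cdot \tau_m^2 = \varepsilon\,[\,b(u^2/u_1^2 - 1) + r\,]$.
These dimensionless forms (`trace_norm`, `det_norm`) are what
`stability_report()` reports, so the stability conditions read off
directly: a saddle for $\det < 0$ (the negative-$R_{dc}$ middle
branch), stable for $\mathrm{tr} < 0$, spiral versus node by the sign
of the discriminant. Eigenvalues are returned in absolute units (1/s)
from the characteristic quadratic; the suite cross-checks them against
a general-purpose eigen-decomposition.

The Hopf bifurcation is the root of $\mathrm{tr}\,J = 0$,
$u_H = u_1\sqrt{1 - \varepsilon b}$, which exists when
$\varepsilon b < 1$. `bifurcation_summary()` finds it by a bracketed
root solve of the trace on $(0, u_1)$ rather than by the closed form,
so the code path survives changes to the nonlinearity; the closed form
serves as the test oracle. Boundary classification uses a tolerance of
$10^{-9}$ on the normalized trace and $10^{-12}$ on the determinant —
far below the $10^{-4}$ precision of the reference values, so the
`non_hyperbolic` flag never absorbs a genuinely hyperbolic point of
interest.

## The equivalent circuit and its spectra

Linearizing at a bias and Laplace-transforming maps the model exactly
onto a parallel circuit: the membrane capacitor $C_m$, the channel
resistor $G_b = (u^2/u_1^2 - 1)/R_I$ (negative inside $|u| < u_1$), and
a series $R_a$–$L$ branch with $R_a = bR_w$ and $L = \tau_k R_w$ — a
*kinetic* inductor created by the slow relaxation of the recovery
current, with no magnetic element. The impedance is

$$Z(i\omega) = \frac{1}{i\omega C_m + G_b + \dfrac{1}{R_a + i\omega L}},$$

with $Z(0) = R_{dc} = 1/(G_b + 1/R_a)$, which equals $du/dI$ on the
stationary curve (the suite verifies this against a finite-difference
slope at relative tolerance $10^{-6}$, and that
$\mathrm{sign}(\det J) = \mathrm{sign}(1/R_{dc})$ everywhere). All
spectra end at the origin as $\omega \to \infty$ because the model has
no series resistance.

### The Nyquist link

Writing $Z(s) = (R_a + sL)/[\,s^2C_mL + s(C_mR_a + LG_b) +
(R_aG_b + 1)\,]$ shows that the *admittance* $Y = 1/Z$ vanishes exactly
at the Jacobian eigenvalues: under current drive, a free oscillation is
a voltage mode that requires no external current modulation,
$Y(s)\,\tilde u = \tilde I = 0$. `impedance_zeros()` returns these
roots from the quadratic; they match the eigenvalues to $10^{-9}$
relative over a thousand random draws in the suite. At the Hopf bias
the pair is purely imaginary, so the measured spectrum *diverges* at
the real frequency $\omega_H = \sqrt{\det J}$ — the package's
frequency-domain bifurcation detector. (It is the admittance, not the
impedance, that passes through zero there; the two are easy to
conflate because the same quadratic governs both.)

### Spectral taxonomy

`classify_spectrum()` assigns one of five regimes by a decision
cascade, each step tied to circuit quantities:

1. **NEGATIVE_RDC** — $G_b + 1/R_a < 0$: the spectrum starts on the
   negative real axis. The bias sits on the unstable middle branch and
   is not observable at steady state without an added series resistor.
2. A finite-frequency real-axis crossing of the spectrum
   ($\mathrm{Im}\,Z = 0$ at $\omega_x > 0$) exists precisely when
   $L > C_m R_a^2$, i.e. $\varepsilon < r/b^2$ — for $b = 1$ (every
   positive-$R_{dc}$ preset) this is the familiar loop condition
   $\tau_k > R_aC_m$, i.e. $\varepsilon < r/b$. The sign of
   $\mathrm{Re}\,Z$ at the crossing equals the sign of
   $-\mathrm{tr}\,J$ (algebraic identity
   $\mathrm{Re}\,Y(\omega_x) = -C_m\,\mathrm{tr}\,J$):
   **HIDDEN_NDR** when negative — positive $R_{dc}$ but negative real
   impedance at high frequency, the signature of an unstable (spiking)
   fixed point; **INDUCTIVE_LOOP** when positive — the fourth-quadrant
   loop of a stable bias. The crossing is located by a sign change on a
   60-points-per-decade scan refined by bisection, not from the closed
   form, so the classifier generalizes.
3. With no crossing: **BENT_ARC** if the spectrum touches the axis
   (tangency within $10^{-9}|R_{dc}|$, the exact boundary
   $\varepsilon = r/b^2$) or if the high-frequency tail makes a visible
   negative-real excursion, $\max_\omega(-\mathrm{Re}\,Z) >
   0.01\,R_{dc}$; otherwise **RC_ARC**. The 1% threshold is a shape
   judgment: with the NDR present ($|u| < u_1$) the real part is always
   slightly negative at high frequency, and the excursion grows from
   0.02% of $R_{dc}$ deep in the fast-recovery regime
   ($\varepsilon \gg r/b$, a visually plain arc) to about 8% where the
   arc visibly bends along the axis.

A caution on plotting: the package stores $Z$ untransformed and only
`plot()` negates the imaginary axis (the electrochemistry convention,
where the inductive loop appears in the fourth quadrant).

The default frequency window $[10^{-3}/\tau_k,\ 10^3/\tau_m]$ rad/s at
60 points per decade spans both relaxation times with three decades of
margin, so both the dc and the capacitive asymptotes used by the
classifier are reached.

## Time domain

`fhn_simulate()` integrates the full equations with `deSolve`'s
`lsoda`, which switches automatically to a stiff (BDF) method — the
operative regime for $\varepsilon \ll 1$, where the limit cycle is a
relaxation oscillation with near-discontinuous voltage jumps. Default
tolerances are `rtol = 1e-8`, `atol = 1e-10`; halving them changes a
reported limit-cycle period by less than 0.1% (tested). Output is
resampled to at least 2000 points; the perturbation protocol uses
20000 so that each fast spike carries enough samples for sub-grid peak
interpolation.

`perturbation_response()` reproduces the step protocol: sit at the
fixed point nearest $u = 0$ (the middle branch on which the bistable
and oscillatory experiments are centered), kick the voltage by
$\Delta u$ (default $+1$ V), integrate for
$200\max(\tau_k, \tau_m)$. The `max` matters: for the fast-recovery
presets ($\varepsilon > 1$) the slow time is $\tau_m$, and a horizon of
$200\tau_k$ would end long before the relaxation completes.

`oscillation_metrics()` discards the first half of the record as
transient, finds voltage peaks by parabolic interpolation through the
three samples around each discrete maximum, and classifies:
*sustained* (≥ 5 peaks, period and amplitude coefficients of variation
below 1%), *jump to sink* (terminal fixed point differs from the one
nearest the initial condition — checked before ring-down, because a
bistable jump typically rings down at the *new* sink), *damped* (≥ 3
peaks with monotone envelope, measured relative to the nearby
equilibrium; ring frequency from mean peak spacing, decay rate from a
log-linear envelope fit), *monotonic decay*, or an explicit
"inconclusive" error recommending a longer horizon. On a stable
spiral, the measured ring frequency and decay rate match
$|\mathrm{Im}\,\lambda|$ and $|\mathrm{Re}\,\lambda|$ to well within
1% and 5% respectively (tested with a 0.01 V kick).

### Subcritical onset

The Hopf here is subcritical with a canard-like explosion: just
*above* $u_H$ (stable fixed point) a large-amplitude limit cycle
coexists in a narrow bias band, reachable with a 1 V kick though not
with a small one; just *below* $u_H$ the observable cycle is already
large and its frequency sits below the linear resonance
$\sqrt{\det J}$ (at 73% for preset C, about half for `fig1c`). Two
consequences for testing: (i) Hopf consistency — "spiking iff
$|u^*| < u_H$" — is probed with the 1 V kick below threshold and a
0.01 V kick above it, since the criterion concerns local stability,
not basins; (ii) the resonance frequency bounds the onset spiking rate
from above and fixes its scale, but does not predict it to 10%.

## What the built-in models do and do not show

The presets exercise every regime the classifier knows — plain RC arc
(A), bent arc (B), inductive loop (D at a stable bias), hidden NDR
(C inside the Hopf voltage), negative dc resistance with bistable
jumps (E) and with spontaneous spiking (F) — and all quantitative
anchors (Hopf voltages/currents to $10^{-4}$, ring frequencies,
period solver-independence) are recomputed by the test suite and the
acceptance script rather than stored. All of this concerns the
deterministic, single-neuron, constant-drive model: no noise, no
coupling, no fit of measured spectra (the package is a forward model),
and no continuation of limit-cycle branches — the sub/supercritical
distinction above is observed from simulations, not computed from
normal-form coefficients. Problem sizes are modest by design: spectra
use a few hundred frequencies, scans a few hundred biases, and the
bias-sweep simulations 10 biases per side per model.
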