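# fhnec

Frequency- and time-domain analysis of the FitzHugh–Nagumo (FHN) neuron
model, written in dimensional electrical form. The package is for
computational neuroscientists and neuromorphic-hardware designers who
want to read a neuron's dynamical regime — resting, damped ringing,
spiking, bistable switching — off its small-signal impedance spectrum,
the quantity an experiment or a memristive device actually measures.

## The model

Membrane voltage $u$ (V) and recovery current $w$ (A) under applied
current $I$ (A):

$$C_m \dot u = I - \tfrac{1}{R_I}\left(\tfrac{u^3}{3u_1^2} - u\right) - w,
\qquad
\tau_k \dot w = \tfrac{u}{R_w} - b\,w, \qquad C_m = \tau_m/R_I .$$

Linearized at a bias voltage, the model **is** an equivalent circuit:
membrane capacitor $C_m$, a negative differential resistance
$R_b = R_I/(u^2/u_1^2-1)$ (negative for $|u|<u_1$), and a series
$R_a$–$L$ branch ($R_a = bR_w$, $L = \tau_k R_w$) — a kinetic inductor
from the slow recovery variable. The impedance
$Z(i\omega) = \left[i\omega C_m + G_b + (R_a+i\omega L)^{-1}\right]^{-1}$
has its admittance zeros exactly at the Jacobian eigenvalues, so the
Nyquist criterion reads stability and the Hopf bifurcation
($\mathrm{tr}\,J = 0$ at $u_H = u_1\sqrt{1-\varepsilon b}$, with
$\varepsilon = \tau_m/\tau_k$) directly from the spectrum: at the Hopf
bias the spectrum diverges at the real frequency $\sqrt{\det J}$.
Spectra are classified into five regimes (RC arc, bent arc, inductive
loop, hidden NDR, negative $R_{dc}$), and full nonlinear simulations
(spikes, relaxation oscillations, bistable jumps) cross-validate the
linear picture.

## Worked example

```r
library(fhnec)

bifurcation_summary("fig1c")
#> Bifurcations:
#>   Hopf: u_H = 0.95917 V, I_H = 1.06787 A (and the mirror pair)
#>   saddle-node: none (r/b >= 1)
```

The `fig1c` preset ($R_I = 0.5\,\Omega$, $b = 0.8$, $\varepsilon = 0.1$,
$r = 1$) loses stability at $\pm 0.959$ V: below that bias voltage the
fixed point is an unstable focus and the neuron spikes; the
corresponding drive current is $\pm 1.068$ A.

```r
classify_spectrum(0.5, "C")
#> [1] "HIDDEN_NDR"
#> attr(,"crossing_omega")
#> [1] 52.853
#> attr(,"Re_at_crossing")
#> [1] -1.152074
```

Preset C biased at 0.5 V has positive dc resistance but its spectrum
crosses the real axis at a *negative* value at 52.9 rad/s — hidden
negative impedance, the fingerprint of a spiking (limit-cycle) bias.
The time domain agrees:

```r
oscillation_metrics(perturbation_response("C", stationary_current(0.5, "C")))
#> Oscillation metrics: sustained_oscillation
#>   period = 0.138738
#>   amplitude_pp = 3.19954
```

and the bistable preset E at zero drive jumps from the saddle to a
sink:

```r
oscillation_metrics(fhn_simulate("E", I = 0, u0 = 0.1, w0 = 0, t_end = 50))
#> Oscillation metrics: jump_to_sink
#>   terminal_u = 1
```

`hopf_table()` tabulates the Hopf voltages of presets A–F (A and B,
with fast recovery $\varepsilon b > 1$, never destabilize and report
`NA`). A thin command-line front end over the same functions lives at
`inst/cli/fhnec.R` (subcommands `steady`, `stability`, `bifurcations`,
`scan`, `impedance`, `classify`, `simulate`, `perturb`, `hopf-table`).

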