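---
title: "Delayed feedback control of network oscillations: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed feedback control of network oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcnet)
```

## The problem

Sparse recurrent networks of spiking neurons settle, for moderate coupling,
into an asynchronous-irregular (AI) state: single neurons fire with
Poisson-like statistics while the population rate is stationary. When the
recurrent coupling grows too strong, the stationary rate loses stability
through a supercritical Hopf bifurcation and the network enters a
synchronous-irregular (SI) state — single-neuron firing stays irregular but
the population rate oscillates. Persistent SI oscillations are the
signature of several pathologies (beta oscillations in Parkinson's disease
being the canonical example), and they also degrade the network's ability
to represent incoming signals.

`dfcnet` implements a closed-loop remedy: delayed feedback control (DFC).
A controller observes the instantaneous population rate $v(t)$, filters it
with a kernel $m$, delays it, scales it by a gain $K$ and injects the
result as a current common to all stimulated neurons,

$$I_C(t) = K\,(m \star v)(t - d_c)\,,$$

with the sign chosen so that the injected current counteracts the net
recurrent feedback. The package provides (i) a fast compiled simulator of
the spiking networks, (ii) the mean-field linear-stability theory that
predicts for which $(K, d_c)$ control succeeds, and (iii) the spike-train
metrics used to show that control restores function, not just statistics.

## Network model

Leaky integrate-and-fire neurons with membrane time constant $\tau_m$,
threshold $v_\theta$, reset $v_r$ and absolute refractory period
$t_{ref}$; all currents are expressed in mV (membrane resistance
absorbed). Each ordered pair of neurons is connected with probability
$\epsilon$; every connection carries weight $J/C$ where $J$ is the total
coupling and $C = \epsilon N$ the expected in-degree, so the mean
recurrent drive is independent of the realised graph. A presynaptic spike
arrives after delay $d$ and injects an alpha-function current
$s(t) = (t/\tau_s)e^{1-t/\tau_s}$. External drive is white:
$\mu + \sigma\sqrt{\tau_m}\,\eta_i(t)$, independent across neurons.

The integration uses the exact exponential propagator of the membrane and
of the two-state alpha-kernel system between grid points (`dt` = 0.1 ms),
so the step only controls the alignment of threshold crossings to the
grid. Spikes are stamped at the first grid point at or after the
crossing; the membrane is clamped to the reset during refractoriness;
delays must be grid multiples and are rejected otherwise. Checking the
threshold only at grid points misses excursions inside a step and biases
first-passage rates low (about 10 % at `dt` = 0.1 ms for these
parameters); the simulator therefore applies the standard continuity
correction for discretely monitored diffusions, shifting the detection
threshold by $|\zeta(1/2)|/\sqrt{2\pi}\cdot\sigma\sqrt{dt/\tau_m}$,
after which simulated and analytic stationary rates agree to about 0.1 %.

## Default operating point

The study conditions fix $\mu = 14$ mV, $\sigma = 6$ mV, $\epsilon = 0.1$,
$\tau_s = 1$ ms (also written $\tau_r$), $d = 5$ ms, and a total coupling
$J = 200$ mV for the pathological state. The single-neuron parameters are
not uniquely fixed by those conditions, so the package defaults were
calibrated once, jointly, against the quantities the theory and the
simulations must reproduce together:

* critical coupling $J_{cr} \approx 115$ mV at the operating point,
* Poisson-like AI statistics (ISI CV and Fano factor $\approx 1$),
* an SI period consistent with a secondary differential-control domain
  near 23 ms.

This gives $\tau_m = 10$ ms, $v_\theta = 20$ mV, $v_r = 14$ mV,
$t_{ref} = 0.5$ ms (resting potential 0). The high reset — close to the
mean input — is what keeps firing fluctuation-driven (CV $\approx 1$) at
a respectable rate ($r_0 \approx 24.5$ sp/s); deep-reset variants that
also meet $J_{cr} \approx 115$ mV fire too regularly (CV $\approx 0.7$)
and are inconsistent with the AI statistics above. With these defaults the
theory gives $J_{cr} = 111.5$ mV and an SI frequency of about 56 Hz at
$J = 200$ mV.

```{r op}
op <- operating_point(14, 6)
op
critical_coupling(op)$J_cr
```

## Linear response and the characteristic equation

A rate perturbation $r_1 e^{\lambda t}$ survives the loop if it reproduces
itself after passing through the synapses and the neurons. The synaptic
transfer is $S(\lambda) = e\,\tau_s/(1+\lambda\tau_s)^2$ (times
$e^{-\lambda d}$); the neuron transfer $R(\lambda)$ is the linear response
of the white-noise-driven LIF neuron, built from the confluent
hypergeometric solutions of the perturbed Fokker–Planck operator
(Kummer functions with complex first argument; evaluated by direct series,
which converges rapidly for the operating points used here, and checked
against a 40-digit arbitrary-precision reference and against the
static-gain identity $R(0) = \partial r_0/\partial\mu$). Refractoriness
enters through the occupancy factor $1 - r_0 t_{ref}$.

With the inhibitory sign written explicitly, the closed-loop
characteristic functions are

$$F_{open} = 1 + J R S e^{-\lambda d}, \qquad
  F_{direct} = F_{open} - K R M e^{-\lambda d_c},$$

with the differential variant replacing $e^{-\lambda d_c}$ by
$e^{-\lambda d_{c1}} - e^{-\lambda d_{c2}}$ and enhancement flipping the
control sign; the box-kernel transfer is
$M(\lambda) = (1 - e^{-b\lambda})/\lambda$. The sign convention is pinned
down by an exact identity: with $K = \Delta J$, $m = s$ and $d_c = d$,
direct control cancels a coupling increment $\Delta J$ out of the
characteristic function identically (a unit test asserts this at 100
random $\lambda$ to $10^{-10}$).

Roots are found by dense grid seeding over
$\mathrm{Re}\,\lambda \in [-1000, 200]$ s$^{-1}$,
$\mathrm{Im}\,\lambda \in [0, 2\pi\cdot 200]$ s$^{-1}$ (conjugates added by
symmetry) followed by damped complex Newton polishing; a root is accepted
when $|F| < 10^{-9}$ and duplicates are merged at relative $10^{-5}$.
The rightmost real part decides stability; at $J = J_{cr}$ it vanishes to
machine precision.

## Control domains and robustness

`stability_landscape()` maps the rightmost eigenvalue over the
$(K, d_c)$ grid ($K \in [0,300]$ mV, $d_c \in [0,30]$ ms at 0.5 ms
resolution by default). Stable cells cluster into *control domains*;
`landscape_domains()` ranks them by area — the natural robustness measure,
since a larger domain tolerates larger errors in the controller
parameters — and reports each domain's centre on the effective-delay axis
($d_{c,eff} = d_c + b/2$ for the box kernel). Direct control yields one
principal domain centred at $d_{c,eff} = 7$ ms, matching the synaptic
effective delay $d + 2\tau_r$; differential control enlarges it and opens
a second domain one oscillation period later ($\approx 22$ ms here).

Two deliberate choices:

* Domains are ranked by area, not by their single deepest cell. On the
  $[0,300]$ mV gain box the globally deepest cell can sit in the
  $K > J$ corner, where the compensated network is effectively excitatory
  and the uniform-state linearisation is not trustworthy (simulations
  destabilise there); the area ranking reports the physically meaningful
  domain.
* The stability margin $B_{cr}$ at the main domain is computed at the
  gain minimising the rightmost eigenvalue *within the domain*, allowing
  $K$ beyond the display box (the minimum falls near $K \approx 460$ mV
  direct, $\approx 350$ mV differential). Differential control is
  strictly more robust than direct control, as expected from its extra
  phase freedom; the package's absolute margins ($\approx -207$ and
  $-155$ s$^{-1}$) are 20–30 % shallower than the reference values the
  calibration targets, a residual sensitivity to the unconstrained
  single-neuron parameters that we report rather than tune away.

## The controller in simulation

The simulated controller is strictly causal: at each 1 ms update it sums
the recorded population's spike counts over the window
$(t - d_c - b,\, t - d_c]$ (all strictly past), scales by $K/N_{rec}$,
and holds the current for the next update interval. The injected current
is bit-identical across stimulated neurons — control works *through* the
common input, not by decorrelating neurons. The sample-and-hold adds an
average lag of half an update step that the continuous-time theory omits;
at 1 ms updates this is well inside the $\pm 1$ ms width of the stable
domain.

Because direct control injects a nonzero-mean current and recurrence
shifts the operating point, all conditions are *rate compensated*:
`rate_compensate()` removes the analytic mean ($J r_0 e \tau_s$, minus
the static control contribution $K r_0 b$) and recurrent variance
($J^2 r_0 e^2 \tau_s / 4C$) from the external drive so that uncoupled,
coupled and controlled networks share the operating point. For the
two-population loop the analytic estimate can miss when the uncontrolled
state is synchronous; an optional fixed-point iteration (short simulation,
correction by the rate error over the static gain) is provided and used by
the E-I presets. Differential control needs no compensation — its control
signal averages to zero — and the replayed-noise comparator is compensated
by its trace mean.

The adaptive gain tuner (`adaptive_tune_gain()`) is a deliberately simple
heuristic for the case where $J$ is unknown: finite-difference *sign*
descent on the log band power of the population rate, with step size
$a_0/\mathrm{iter}^{0.6}$. Sign steps are used because the objective is
flat and noisy far below the effective gain; the tuner reliably enters
the analytic stable domain within ~15 iterations and agrees across seeds
to well under 20 %.

## Metrics

* **Fano factor**: variance/mean of per-neuron counts in 100 ms
  non-overlapping windows (window length is a convention, configurable),
  averaged over non-silent neurons.
* **ISI CV**: per-neuron sd/mean of interspike intervals, averaged over
  neurons with at least two intervals.
* **Oscillation index**: $P_T = \sum_{0 < f_k \le B} |X_k|^2/L^2$ of the
  mean-removed population spike-count series at 1 ms bins — the in-band
  share of the count variance, invariant to duration and to the mean.
  The band edge is $B = 125$ Hz by default ($250\pi$ rad/s); the literal
  alternative reading $250/\pi$ rad/s ($\approx 12.7$ Hz) is available as
  `band = "literal"` but would exclude the oscillation frequencies of
  interest. Reported as $\log_{10} P_T$. Under this convention an AI
  network at $N = 10^4$ and $r_0 \approx 22$ sp/s sits near 1.5 and the
  $J = 200$ mV SI state several decades higher; note the value scales
  with $N$ through the count variance, so cross-size comparisons must use
  the ordering, not the absolute level.
* **Pulse-packet AUC**: population-rate samples at $t_k + 10$ ms versus
  $t_k + 100$ ms across ten packets, ROC by exhaustive thresholds
  (equivalent to Mann–Whitney; ties count half).
* **SPIKE-distance**: the time-resolved, parameter-free dissimilarity
  profile, averaged over all train pairs and over analysis windows. The
  profile is piecewise linear between spikes, so window averages are
  integrated exactly from two interior evaluations per segment. The
  profile is defined on the *full recording* and only averaged within
  windows — clipping trains to 50 ms windows would leave one or two
  spikes per train and the auxiliary edge spikes would dominate. Each
  train carries auxiliary spikes at the recording edges; empty trains
  then contribute maximal dissimilarity rather than failing.

## Stimulus protocols

The function-recovery protocols use a 1000-neuron inhibitory network in
three conditions: healthy AI ($J = 50$ mV, about 45 % of critical),
pathological SI under direct DFC, and pathological SI quenched by strong
independent noise ($\sigma = 14$ mV, rate-matched). Rate coding is probed
by ten Gaussian pulse packets ($n_{pp} = 100$ spikes, $\sigma_{pp} = 10$
ms, centres $t_k = 200k + 200$ ms) delivered in full to 100 target
neurons; temporal coding by ten replays of a common train of 500 equally
spaced spikes in 50 ms. Input weights are not constrained by the study
conditions; the packet weight is 1 mV and the common-input weight 0.3 mV per spike
(about one and a half unitary recurrent weights $J/C$ of the full-size
network), chosen once so that the healthy network's temporal response to
the probe is unambiguous — the premise of the comparison. SPIKE-distance clusters are evaluated over the 100 stimulated
neurons, the subpopulation whose temporal structure the probe addresses.

## What the generator does and does not emulate

The synthetic conditions reproduce the dynamical regimes (AI, SI, controlled,
noise-quenched) of homogeneous sparse LIF networks with point-event
synapses and white external noise. They do not emulate conductance-based
synapses, heterogeneity of cell parameters, structured or spatial
connectivity, or measurement noise in the recorded population rate —
passing tests therefore demonstrate control of the idealised Hopf
instability, not performance on biological recordings. Finite-size
fluctuations beyond the mean field are present in the simulations but are
deliberately outside the analytic theory, which is why mean-field and
simulated stability boundaries disagree when $|J - K|$ is small.

## Problem sizes and reproducibility

Unit tests run the simulator at $N \le 2000$ and the landscapes on
reduced gain grids; the acceptance script recomputes everything at the
study sizes ($N = 10^4$, 4.5 s, three seeds; landscapes at
$31 \times 61$). All randomness flows from one integer seed split into
fixed streams (connectivity, noise, stimuli, controller), so attaching a
controller never perturbs the network's noise realisation, and identical
seeds give byte-identical spike files.

## Known limitations

* Single-neuron parameters are a calibration, not a measurement; analytic
  quantities that depend steeply on them (notably the absolute stability
  margins) inherit that uncertainty.
* The oscillation index is a population *count* statistic; its absolute
  level depends on $N$.
* The simulator's controller supports the box kernel only; the alpha
  control kernel exists in the mean-field layer for kernel-matching
  analyses.
* The adaptive tuner is a heuristic; it finds a workable gain, not the
  optimum.
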