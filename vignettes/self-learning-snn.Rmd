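---
title: "Delay-aware STDP, the shortest-pathway rule, and closed-loop conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-aware STDP, the shortest-pathway rule, and closed-loop conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snnanimat)
```

## The model

`snnanimat` simulates small spiking networks in which *where* a spike comes
from — and how long it takes to get there — decides what plasticity does.
Three ingredients interact:

**Neurons.** Each neuron follows the two-variable Izhikevich model

$$\frac{dv}{dt} = 0.04 v^2 + 5v + 140 - u + I(t), \qquad
  \frac{du}{dt} = a(bv - u),$$

with the reset rule: if $v \ge 30$, then $v \leftarrow c$,
$u \leftarrow u + d$ (a spike). The default parameters
$a = 0.02, b = 0.2, c = -65, d = 8$ give a regular-spiking cortical cell:
silent at rest (the fixed point is $v = -70$, $u = -14$), tonically spiking
under constant drive. The input current
$I(t) = \xi(t) + I_{syn}(t) + I_{stml}(t)$ sums white Gaussian noise of
variance $D$, synaptic input, and stimulus pulses.

**Synapses.** Transmission uses the Tsodyks–Markram three-pool scheme:
recovered resources $x$, active transmitter $y$, and an inactive pool
$1 - x - y$. Between spikes $y$ decays with $\tau_I = 10$ ms, the inactive
pool recovers into $x$ with $\tau_{rec} = 50$ ms, and the facilitation
variable $u_f$ relaxes to its baseline $U$ with $\tau_{facil} = 1$ s. On a
spike *arrival* $u_f$ facilitates ($u_f \leftarrow u_f + U(1 - u_f)$) and a
fraction $u_f x$ moves from $x$ to $y$. The postsynaptic current is
$I_{syn} = \sum_j g_j w_j y_j$ with $g = +20$ for excitatory and $-20$ for
inhibitory neurons, and weights $w \in [0, 1]$.

**Plasticity.** Excitatory synapses are plastic under a trace-based,
multiplicative STDP rule with two local variables: a postsynaptic trace
$s_i$ incremented at each postsynaptic spike, and a *delayed* presynaptic
trace $s_j$ incremented when a presynaptic spike **arrives**, i.e. at
emission time plus the axonal delay $\tau_{ij}$. Both decay with
$\tau_S = 10$ ms. A postsynaptic spike potentiates,
$\Delta w = \lambda (1 - w)\, s_j$; a presynaptic arrival depresses,
$\Delta w = -\lambda \alpha w\, s_i$; with $\lambda = 0.001$ and
$\alpha = 5$. The $(1-w)$ and $w$ factors are soft bounds keeping
$w \in [0, 1]$.

The arrival-time convention is the scientific heart of the package. In a
network with alternative routes to the same neuron, the fastest route's
spikes fire the target first; inputs arriving over slower routes then land
*after* the postsynaptic spike and are depressed. Run on the three-neuron
shortcut motif (`build_motif("shortcut")`) this yields the
**shortest-pathway rule**: STDP potentiates the fastest spike-conducting
pathway to a neuron and depresses slower alternatives. Axonal delays are
3 ms for "parallel" links and 4.2 ms for "diagonal" ones, proportional to
the interneuron distances of the sensorimotor layout.

## The sensorimotor network and conditioning

`build_robot_snn()` wires seven neurons: sonar-driven CS neurons N1/N2,
touch-driven US neurons N3/N4, steering motoneurons N5/N6 (N3→N5 and N4→N6
fixed at $w = 1$: the unconditional reflex always works), and a tonic
forward-drive neuron N7. N3 and N4 inhibit each other ($w = 1$,
$g = -20$; neuronal competition), and N1↔N2 are coupled by fixed excitatory
synapses ($w = 0.5$; synaptic competition between the CS channels). The
four CS→US couplings $w_{31}, w_{42}$ (parallel) and $w_{41}, w_{32}$
(diagonal) are plastic and summarised by
$w_P = (w_{31} + w_{42})/2$, $w_D = (w_{41} + w_{32})/2$
(`coupling_means()`); their ratio, oriented by the wiring, is the channel
selectivity.

**Stimuli** are 3-ms square current pulses at 10 Hz. Pairing delivers the
US train 10 ms after the CS train, so the CS-evoked spike arrives at the US
neuron a few milliseconds before the US-evoked spike — the timing the rule
potentiates.

**Classical conditioning** (`run_classical_conditioning()`): the paper-side
notion of a "cycle" is not defined precisely anywhere, so the package fixes
one cycle = one paired-stimulation episode on one side, 20 s long
(200 paired pulses), alternating left/right. After every cycle both sides
are probed **CS-alone** with plasticity frozen and noise off, so probes are
deterministic and can never train: a side has learned when its US neuron
fires at least one spike per two CS pulses *and* the contralateral US
neuron stays below that rate (lateralisation). `cycles_to_learn` is the
first cycle where both sides pass and keep passing one confirmation cycle.
Under the defaults this happens after roughly five episodes per side, and
after `swap_cs_inputs()` the opposite association is relearned in a
somewhat longer time — both numbers are computed by the test suite, not
assumed.

**Operant conditioning** (`run_operant()`): a differential-drive robot
(radius 0.09 m) in a 1-m² arena with three convex obstacles. Every control
period (10 ms) the sensors are read; an active sonar (obstacle edge within
0.15 m of the body, inside a forward fan) drives its CS neuron at 10 Hz,
an active bumper half drives its US neuron with the 10-ms lag; the network
advances with plasticity on; motoneuron activity maps to wheels
(N5 slows/reverses the right motor, N6 the left, base speed proportional
to N7's rate); the pose advances by a unicycle Euler step; on contact the
robot stops at the obstacle. Collisions are touch onsets; learning time is
the first moment after which a 60-s sliding window holds zero collisions
while sonar activations continue.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `dt` | 0.1 | ms | 3-ms pulses and 3/4.2-ms delays must be integer step counts; forward Euler is the reference scheme for this neuron model |
| `D` | 5.5 | current² per ms | intermediate noise; the regime where conditioning is robust |
| `amplitude` | 15 | current | one 3-ms pulse evokes exactly one spike (one pulse = one spike, clean temporal coding); at ≥30 each pulse evokes a doublet |
| initial plastic $w$ | U(0.07, 0.14) | – | below the CS-transmission threshold (~0.33 for a lone synapse under 10-Hz facilitated release), so an untrained CS evokes no response even through converging paths |
| `U` | 0.5 | – | baseline release probability; conventional value, config-exposed |
| `episode_ms` | 20000 | ms | the declared "cycle" operationalisation |
| `k_f`, `k_m` | 0.01, 0.6 | m, m/s per unit drive | forward speed ≈ 0.14 m/s at N7's ~14-Hz tonic rate; steering strong enough that a sustained 10-Hz reflex pivots the robot off an obstacle without breaking contact into rapid tap-release cycles |
| sonar fan | ±0.35 rad mount, 0.35 rad half-angle | rad | two angled cones forming a contiguous ±40° forward fan; narrower fans leave flank corridors invisible and produce unavoidable graze collisions |

## Numerical choices

* All decays (traces, $y$, $u_f$, recovery) use exact per-step exponential
  factors, applied by operator splitting; resource conservation
  $x + y + z = 1$ holds to machine precision, and a 10-ms trace decay over
  100 steps matches $e^{-1}$ to ~1e-15, which is what lets the trace path
  agree with a closed-form all-pairs oracle to 1e-9 over thousands of
  events.
* Within a step the order is: decays → queued arrivals (facilitation +
  release) → currents → Euler update and reset → potentiation for every
  postsynaptic spike → depression for every arrival → trace increments →
  enqueue of outgoing arrivals. Potentiation strictly precedes depression
  on same-step coincidences, and traces are incremented *after* the updates
  that consume them, so a spike never pairs with itself.
* The recovery-variable update uses the freshly updated $v$, matching the
  published reference integration scheme for this neuron model.
* Delays are rounded to the nearest step (4.2 ms → 42 steps) and delivered
  through a time-indexed ring buffer sized by the maximum delay; pending
  arrivals survive across simulation slices, so a run split into pieces is
  bit-identical to an unbroken one.
* **Noise convention.** The noise variance is interpreted per unit time
  (per-step draws scaled by $1/\sqrt{dt}$). The alternative — variance $D$
  per step — makes the noise physically inert at $dt = 0.1$ ms (even
  $D = 50$ produces zero spontaneous spiking), which would void every
  noise-dependent statement the model is supposed to exhibit. The per-time
  reading at $dt = 0.1$ ms is numerically identical to per-step variance
  $D$ at a 1-ms step, a plausible resolution for a real-time simulator of
  this size. `noise_per_time = FALSE` restores the per-step reading.

## What the simulated conditions do and do not show

The synthetic study conditions are the package's defaults: 10-Hz, 3-ms
pulse protocols with a 10-ms CS–US lag, $D = 5.5$, the seven-neuron
topology with 3/4.2-ms delays, a 1-m² arena with three convex obstacles and
a 0.09-m robot at ~0.14 m/s. Within them the suite computes: the
shortest-pathway sign pattern across 20 seeds at $D \in \{0, 5.5\}$;
classical learning with $w_P$ up / $w_D$ down and its reversal after the
input swap; collision rates that drop within a few minutes of simulated
operant time (median learning time ≈ 2 simulated minutes over 10 robots,
recomputed by `scripts/acceptance.R`); order sensitivity (US-before-CS
pairing does not learn).

Two honest caveats. First, the **noise window**: high noise ($D = 50$)
breaks learning here as it should — random spiking drags the weights
toward the multiplicative drift equilibrium and selectivity never forms —
but *low* noise ($D = 0.1$) does **not** break learning in this
implementation. Because the stimulus must be suprathreshold at $D = 0$
(the motif experiments require deterministic 10-Hz spiking without noise),
CS–US pairing is deterministic and potentiation cannot fail when noise is
merely absent. A low-noise failure would require marginally subthreshold
activation, which is incompatible with the same stimulus driving the
noise-free motifs; the corresponding acceptance expectation is left
failing rather than engineered around. Second, the animat is a kinematic
caricature: no inertia, slip, or sensor latency, a circular body, and
stop-at-contact collision handling. Passing tests show the *learning
mechanism* transfers to closed-loop behaviour under these idealised
conditions, not that the controller is ready for a physical platform.

## Problem sizes

The test suite runs motifs for 200 simulated seconds (2×10⁶ steps each),
classical conditioning for up to 16 episodes of 20 s, and ten 330-s operant
robots; the acceptance script re-runs the ten operant robots from scratch.
These sizes keep every experiment's full dynamic range (naive → learned →
relearned) while completing in minutes on one core.

## Known limitations

* Only regular-spiking neuron parameters; no bursting or LIF/AdEx variants.
* Inhibitory synapses are fixed; no triplet/BCM/reward-modulated rules.
* Structural plasticity is weight-based only; the topology never rewires.
* The operant environment develops less selectivity than classical
  conditioning (frontal approaches stimulate both sonars at once), so
  avoidance there leans partly on symmetric braking rather than pure
  lateralised turning — visible when comparing the `both_cs` schedule to
  lateral-only stimulation.

```{r example}
set.seed(1)
net <- build_motif("shortcut")
run <- run_network(net, pulse_train("N1"), duration = 200000)
setNames(run$net$synapses$w, paste0(net$synapses$pre, "->", net$synapses$post))
```
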