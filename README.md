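# snnanimat

Self-learning spiking neural networks controlling a simulated robot
(animat). The package is for computational neuroscientists and
neuroroboticists who want a small, fully reproducible model of associative
learning built from biologically grounded pieces: Izhikevich neurons,
Tsodyks–Markram short-term synapses, axonal conduction delays, and
trace-based multiplicative spike-timing-dependent plasticity (STDP).

## The science in one paragraph

Each neuron follows dv/dt = 0.04v² + 5v + 140 − u + I(t),
du/dt = a(bv − u), with the reset v ≥ 30 ⇒ v ← c, u ← u + d
(a = 0.02, b = 0.2, c = −65, d = 8). Synaptic currents are
I_syn = Σ g_j w_j y_j, with the released transmitter y_j following the
Tsodyks–Markram depression/facilitation dynamics (τ_I = 10 ms,
τ_rec = 50 ms, τ_facil = 1 s). Weights obey a two-trace STDP rule with
learning rate λ = 0.001 and asymmetry α = 5 in which **depression is
triggered when a presynaptic spike arrives** — at emission time plus the
axonal delay τ_ij — rather than when it is emitted. Delays therefore shape
plasticity: when two routes lead to the same neuron, the faster route fires
it first and the slower route's late arrivals are depressed. This
*shortest-pathway rule* is the mechanism behind everything else in the
package: a four-synapse sensory circuit with mutual inhibition and CS↔CS
coupling learns Pavlovian (classical) associations from paired
conditional/unconditional stimuli (3-ms pulses, 10 Hz, 10-ms lag), relearns
them when the sensor wiring is swapped, and — closed through a simulated
differential-drive robot with sonars (CS) and a front bumper (US) — learns
obstacle avoidance by operant conditioning.

## Worked example

```r
library(snnanimat)

# The shortest-pathway motif: a chain N1 -> N2 -> N3 plus a faster direct
# shortcut N1 -> N3 (3 ms vs 6 ms of total delay).
set.seed(1)
net <- build_motif("shortcut", D = 0)
net
#> <snn_network> 3 neurons, 3 synapses, t = 0 ms, dt = 0.1 ms
#>   N1->N2 w=0.500 g=+20 delay=3.0 [plastic]
#>   N2->N3 w=0.500 g=+20 delay=3.0 [plastic]
#>   N1->N3 w=0.500 g=+20 delay=3.0 [plastic]

run <- run_network(net, pulse_train("N1"), duration = 200000)
round(setNames(run$net$synapses$w,
               paste0(net$synapses$pre, "->", net$synapses$post)), 4)
#> N1->N2 N2->N3 N1->N3
#> 0.8676 0.0003 0.8674
```

After 200 s of 10-Hz stimulation of N1, the two links that carry the
fastest excitation to their targets are potentiated (0.5 → 0.87) while the
link made redundant by the shortcut — N2→N3, whose spikes always arrive
just after N3 has already fired — is driven to zero: path competition, not
anatomy, decided which synapse survives.

```r
# Classical conditioning on the seven-neuron sensorimotor network
set.seed(11)
robot <- build_robot_snn(n7_bias = 0)      # forward drive off, as in the protocol
out <- run_classical_conditioning(robot, conditioning_schedule("PA"))
out
#> <classical_run> wiring PA, 11 cycles run; cycles to learn: 10
#>   final w_P = 0.513, w_D = 0.014, selectivity w_P/w_D = 35.62
```

Ten alternating 20-s episodes (five per side) of paired CS–US stimulation
make the parallel couplings strong (w_P ≈ 0.51) and depress the diagonal
ones (w_D ≈ 0.01): the conditional stimulus alone now fires the correct
unconditional-pathway neuron on each side, verified by frozen CS-alone
probes. `swap_cs_inputs()` then forces relearning of the opposite
(diagonal) association, and `run_operant()` runs the same network in a
1-m² obstacle arena where collisions train avoidance on the fly.

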