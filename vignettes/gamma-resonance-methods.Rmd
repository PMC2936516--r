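---
title: "Model and methods: gamma resonance in a conductance-based cortical sheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: gamma resonance in a conductance-based cortical sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gammares` simulates a patch of primary visual cortex as a 1 mm x 1 mm
sheet of 3341 single-compartment Hodgkin-Huxley neurons (75% excitatory,
25% inhibitory) receiving one independent Poisson thalamocortical afferent
per cell, and measures how the *resonance* between the network's spontaneous
gamma rhythm and a sinusoidally modulated input rate shapes cortical
responsiveness. This vignette records the model equations, the parameter
choices that were genuinely open, the numerical scheme, and what the
synthetic-drive setting can and cannot tell you about real cortex.

## Membrane model

Each neuron obeys

$$C\,\dot V = -g_L (V - V_L) - G_{Na} m^3 h (V - V_{Na})
 - G_K n^4 (V - V_K) - g_E (V - V_E) - g_I (V - V_I),$$

with $C = 10^{-6}\,\mathrm{F/cm^2}$, $g_L = 50\times10^{-6}\,\mathrm{S/cm^2}$,
$V_L = -70$, $V_{Na} = 55$, $V_K = -80$, $V_E = 0$, $V_I = -80$ mV, and the
classic squid-axon rate functions for $m, h, n$ with
$G_{Na} = 120\times10^{-3}$, $G_K = 36\times10^{-3}\,\mathrm{S/cm^2}$.

**Resting potential.** With these conductances the potassium window current
at $-70$ mV is several times the leak current, so $V_L$ itself is not a
fixed point: the membrane rests at $-74.2$ mV. We examined voltage-shifting
the gating kinetics to force rest onto $V_L$: every shift that does so
either lands on an unstable sodium-window balance (shift $\approx -18$ mV,
a hyperexcitable state) or, for positive shifts, pushes the spike threshold
to $\approx -40$ mV, out of reach of physiological EPSPs. We therefore keep
the kinetics unshifted (`gate_shift = 0`, configurable). The rest state is
stable to $<10^{-3}$ mV over seconds, a few millivolts below the leak
reversal, and the single-EPSP spike threshold is $\approx 50\,\mu S/cm^2$ —
inside the 30-70 $\mu S/cm^2$ plasticity range, which is what makes the
thalamocortical strength an effective knob.

## Synapses and connectivity

Synaptic conductances are difference-of-exponential kernels
$\propto e^{-t/\tau_d} - e^{-t/\tau_r}$, peak-normalized to 1, with
$(\tau_d, \tau_r) = (3, 1)$ ms for excitatory and $(7, 1)$ ms for
inhibitory *source* populations (source-indexed, as the conductance
equations index the kernels by the presynaptic type). The feedforward
kernel reuses the excitatory shape; its peak amplitude $g_{max}$
(30-70 $\mu S/cm^2$) is the synaptic-plasticity parameter.

Recurrent coupling between neurons at cortical distance $r$ is
$W_{\sigma\sigma'}\, e^{-r/\lambda_{\sigma'}}$ with $\lambda_E = 200$,
$\lambda_I = 100\,\mu m$ (a Gaussian fall-off is available as a config
switch), deterministic all-to-all within a 600 $\mu m$ cutoff, no
self-connections. Neurons sit on a jittered grid (jitter 0.3 of the pitch)
with type labels assigned by a seeded shuffle to 2506 E / 835 I.

**Coupling weights.** The four $W_{\sigma\sigma'}$ are not published
constants; they are fixed by `calibrate_weights()`, a deterministic
multiplicative coordinate search whose acceptance criterion is scientific:
with static 40 spikes/s drive and $g_{max}$ at the low end of the
plasticity range, the population rate must show a single spontaneous
spectral peak at 38 Hz, inhibitory cells must fire about once per gamma
cycle, and excitatory cells well under once per cycle. The shipped defaults
(in $\mu S/cm^2$ peak conductance at zero distance)
$W_{EE} = 0.5$, $W_{EI} = 16$, $W_{IE} = 24$, $W_{II} = 2$
satisfy this at full scale; re-running the calibration from these values
accepts them in a single evaluation. $W_{EE}$ is additionally bounded by a
structural constraint: it must be small enough that the excitatory
population alone (E-I coupling removed) cannot sustain a recurrent bursting
rhythm, so that the gamma oscillation is attributable to the E-I loop. In this regime the rhythm is paced by
the inhibitory population (fast-spiking cells firing one synchronized
volley per cycle), consistent with the interneuron-gamma picture.

## Thalamocortical drive

Each neuron receives an independent inhomogeneous Poisson train with shared
rate $r(t) = r_0 + A \sin(2\pi f_{in} t + \phi)$ ($r_0 = 40$ spikes/s;
$A = 0$, 10, or 20 spikes/s; $f_{in}$ 25-55 Hz; $\phi = 0$ by default).
Trains are sampled by thinning against the peak rate, which is exact for
any modulation; each train's stream is keyed by (seed, neuron id), so
rasters are reproducible and invariant to population size. Independence is
what makes the input correlogram flat, as verified in the tests.

## Numerics

The integrator is exponential Euler (the standard scheme of the
compartmental simulators this model descends from) at $dt = 0.05$ ms, with
gate steady states and relaxation factors tabulated on a 0.02 mV grid and
linearly interpolated. Synaptic states decay analytically; a presynaptic
spike increments the two state variables of the matching channel by the
peak-normalized weight, which is exact for this kernel family. Spikes are
upward crossings of 0 mV with a 2 ms lockout. The dominant spectral peak
moves by well under 1 Hz when the step is halved, and single-neuron
trajectories match a 10x-finer reference to within 0.5 mV away from spikes
(0.2 ms on spike times). Simulations are bit-deterministic given (network,
input raster, config).

## Measurements

* **Population rate / spectrum**: spikes per 2 ms bin per neuron; Welch
  averaged periodogram (2 s Hann segments, 50% overlap, mean-subtracted).
  2 ms bins (Nyquist 250 Hz) are required for the 20-130 Hz search band.
* **Peak classification**: local maxima merged within 5 Hz, kept when they
  exceed 3x a ~20 Hz running-median local baseline, with harmonics of
  stronger peaks discarded and secondary peaks required to reach 2% of the
  strongest peak's power. Two surviving peaks = "coexisting", one =
  "resonant". The running-median baseline and harmonic/relative-power
  guards are needed because a strongly periodic spike train has harmonics
  and a sloping noise floor that a global median mistakes for coexistence.
* **ISI sharpness**: inverse coefficient of variation of type-pooled ISIs,
  capped at 100 for periodic trains.
* **Correlograms**: cross-neuron coincidences versus lag normalized by the
  independent-homogeneous expectation (baseline exactly 1), same-neuron
  pairs excluded, edge-corrected; computed via FFT on binned counts.
* **Response probability/delay**: fraction of input spikes followed by a
  spike of their target within 10 ms, and the mean latency; an absent
  response is "missing", never a zero delay. The 10 ms window is shorter
  than one gamma period at all studied frequencies.
* **Unpaired inputs**: spikes with no same-afferent neighbor within
  +/-20 ms (retention $e^{-2rw} \approx 0.20$ at 40 spikes/s, matched by
  the generator).
* **Gamma phase**: the population rate (1 ms bins) is band-passed +/-10 Hz
  around the dominant peak (2nd-order Butterworth, zero-phase), the
  analytic-signal phase is rotated so cycle maxima sit at 0 degrees; phases
  are negative on the rising flank.
* **Phase efficacy**: per-phase-bin response probability of unpaired
  inputs, normalized by the spike-count-weighted mean so the weighted mean
  is exactly 1. Values above 1 mark the pass band (before the cycle peak),
  below 1 the block band (after it).

## Experiment protocol and problem sizes

Sweeps use $f_{in}$ in 5 Hz steps over 25-55 Hz and $g_{max}$ in
5 $\mu S/cm^2$ steps over 30-70. The static reference is simulated once per
$g_{max}$ and seed and shared across input frequencies. Run lengths are 3-10
simulated seconds after a 0.5 s warmup discard (spectral measurements use
the longer runs, response-probability measurements pool several hundred
thousand input spikes per condition either way); repeats use 3 drive seeds
and enhancement is averaged across them. These durations give the spectrum
0.5 Hz resolution and the response probabilities standard errors in the
third decimal, at single-CPU desk scale. The quarter-scale fixture keeps
the 1x1 mm sheet and connection geometry, thins density to 835 neurons, and
multiplies the recurrent weights by the inverse count ratio so the expected
per-neuron recurrent drive is conserved; thinning density (rather than
shrinking the sheet) is what makes that rescaling exact in expectation.

## Observed behavior and limitations

With the calibrated defaults the spontaneous frequency rises monotonically
from ~37-38 Hz at $g_{max} = 30$ to ~62 Hz at 70, inhibitory rates track
the gamma frequency one-to-one throughout, and driving the network at its
spontaneous frequency collapses the spectrum to a single entrained peak,
sharpens ISI distributions, deepens correlogram modulation and raises
response probability — the resonance phenomenology the package exists to
measure. Two quantitative differences from the reference behavior are
worth knowing:

* the $f^s_{out}(g_{max})$ curve is concave here (fast early rise, gentle
  saturation), so the response-enhancement resonance point for a 50 Hz
  input sits near $g_{max} \approx 45$, not 60. Regimes with a convex
  curve were searched for (kinetic shifts moving the single-EPSP
  threshold, strong I-I self-inhibition, stronger E-cell recruitment) and
  not found: E-recruitment regimes destabilize into runaway at high
  $g_{max}$ before any late acceleration appears.
* the efficacy pass band has a flat top spanning roughly $-105$ to
  $-45$ degrees, so the single peak-bin statistic is degenerate across
  that plateau rather than pinned at $-90$.

The synthetic drive is deliberately minimal: stationary or sinusoidally
modulated rates, per-afferent independence, one afferent per neuron, no
retinal/LGN front-end, no corticothalamic feedback, no conduction delays,
no plasticity during a run ($g_{max}$ is fixed per simulation). Passing
tests therefore demonstrate properties of this idealized circuit, not of
real LGN input statistics; in particular, input-correlation-driven effects
are excluded by construction (that is the point of the unpaired-spike
control).
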