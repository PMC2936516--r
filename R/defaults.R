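# Frozen model defaults.
#
# GATE_SHIFT_DEFAULT = 0 keeps the classic squid-axon gating kinetics
# unshifted. With the default conductances the resulting resting potential
# of the full membrane equation is -74.2 mV, a few millivolts below the
# leak reversal: the potassium window current at rest is what makes the
# cells leaky integrators. Shifts that would move rest exactly onto the
# leak reversal either put the spike threshold out of reach of
# physiological synaptic drive (positive shifts) or land on an unstable
# sodium-window balance (large negative shifts); see resting_potential().
#
# WEIGHTS_DEFAULT holds the recurrent coupling weights (peak conductance at
# zero distance, uS/cm2) frozen by the calibration procedure
# (calibrate_weights()): with static 40 spikes/s drive and feedforward
# gmax at the low end of the plasticity range the spontaneous population
# oscillation peaks at 38 Hz, inhibitory cells fire about once per gamma
# cycle, and excitatory cells fire less than once per cycle.

GATE_SHIFT_DEFAULT <- 0

WEIGHTS_DEFAULT <- c(EE = 0.5, EI = 16, IE = 24, II = 2)

#' Resting potential of the model neuron
#'
#' Numerically locates the stable fixed point of the membrane equation with
#' all synaptic conductances zero, by relaxing the full dynamics from the
#' leak reversal.
#'
#' @param params an [neuron_parameters()].
#' @param settle_ms relaxation time, ms.
#' @return the resting potential, mV.
#' @export
resting_potential <- function(params = neuron_parameters(),
                              settle_ms = 2000) {
  r <- run_single_neuron(params, 0, 0, time_step = 0.05,
                         duration = settle_ms)
  tail(r$voltage, 1)
}
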