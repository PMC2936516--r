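# Parameter constructors and validation.
#
# User-facing units follow the conventions of the cortical modelling
# literature: capacitance in F/cm2, conductances in S/cm2 (feedforward and
# recurrent synaptic peaks quoted in uS/cm2), voltages in mV, times in ms,
# distances in um, sheet dimensions in mm.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)))
    stop_config(field, "must be a finite numeric value")
  if (any(x < lower)) stop_config(field, sprintf("must be >= %g", lower))
  if (any(x > upper)) stop_config(field, sprintf("must be <= %g", upper))
  x
}

#' Single-compartment Hodgkin-Huxley neuron parameters
#'
#' Membrane and channel constants of the model cortical neurons. Both
#' excitatory and inhibitory cells use the same single-compartment membrane
#' with sodium, potassium and leak currents plus synaptic conductances. The
#' sodium/potassium gating kinetics are the classic squid-axon rate functions,
#' evaluated at `V - gate_shift` so that the leak reversal (-70 mV) is the
#' resting potential of the full membrane equation.
#'
#' @param membrane_capacitance membrane capacitance, F/cm2.
#' @param leak_conductance leak conductance, S/cm2.
#' @param leak_reversal,na_reversal,k_reversal reversal potentials of the
#'   leak, sodium and potassium currents, mV.
#' @param exc_reversal,inh_reversal reversal potentials of excitatory and
#'   inhibitory synaptic currents, mV.
#' @param na_max_conductance,k_max_conductance maximal sodium and potassium
#'   channel conductances, S/cm2.
#' @param gate_shift voltage offset (mV) applied to the gating rate
#'   functions; the default places the resting state at the leak reversal.
#' @param spike_detection_threshold membrane potential (mV) whose upward
#'   crossing is recorded as a spike.
#' @param spike_lockout refractory lockout of the spike detector, ms.
#' @return an object of class `"hh_parameters"`.
#' @export
neuron_parameters <- function(membrane_capacitance = 1e-6,
                              leak_conductance = 50e-6,
                              leak_reversal = -70,
                              na_reversal = 55,
                              k_reversal = -80,
                              exc_reversal = 0,
                              inh_reversal = -80,
                              na_max_conductance = 120e-3,
                              k_max_conductance = 36e-3,
                              gate_shift = GATE_SHIFT_DEFAULT,
                              spike_detection_threshold = 0,
                              spike_lockout = 2) {
  p <- list(
    membrane_capacitance = check_num(membrane_capacitance,
                                     "membrane_capacitance", lower = 1e-12),
    leak_conductance = check_num(leak_conductance, "leak_conductance",
                                 lower = 0),
    leak_reversal = check_num(leak_reversal, "leak_reversal"),
    na_reversal = check_num(na_reversal, "na_reversal"),
    k_reversal = check_num(k_reversal, "k_reversal"),
    exc_reversal = check_num(exc_reversal, "exc_reversal"),
    inh_reversal = check_num(inh_reversal, "inh_reversal"),
    na_max_conductance = check_num(na_max_conductance, "na_max_conductance",
                                   lower = 0),
    k_max_conductance = check_num(k_max_conductance, "k_max_conductance",
                                  lower = 0),
    gate_shift = check_num(gate_shift, "gate_shift"),
    spike_detection_threshold = check_num(spike_detection_threshold,
                                          "spike_detection_threshold"),
    spike_lockout = check_num(spike_lockout, "spike_lockout", lower = 0)
  )
  if (p$inh_reversal > p$leak_reversal)
    stop_config("inh_reversal", "must be <= leak_reversal")
  if (p$leak_reversal >= p$na_reversal)
    stop_config("leak_reversal", "must be < na_reversal")
  structure(p, class = "hh_parameters")
}

# packed vector for the compiled integrator (uF, mS, mV, ms)
pack_neuron <- function(p) {
  c(p$membrane_capacitance * 1e6, p$leak_conductance * 1e3,
    p$leak_reversal, p$na_reversal, p$k_reversal, p$exc_reversal,
    p$inh_reversal, p$na_max_conductance * 1e3, p$k_max_conductance * 1e3,
    p$gate_shift, p$spike_detection_threshold, p$spike_lockout)
}

#' Difference-of-exponentials synaptic kernel parameters
#'
#' @param decay_time_constant,rise_time_constant kernel time constants, ms;
#'   decay must exceed rise. Defaults are (3, 1) ms, the excitatory kernel;
#'   inhibitory synapses use (7, 1) ms.
#' @param source_type `"E"` or `"I"`, the presynaptic population the kernel
#'   belongs to.
#' @return an object of class `"kernel_parameters"`.
#' @export
kernel_parameters <- function(decay_time_constant = 3,
                              rise_time_constant = 1,
                              source_type = c("E", "I")) {
  source_type <- match.arg(source_type)
  check_num(decay_time_constant, "decay_time_constant", lower = 1e-9)
  check_num(rise_time_constant, "rise_time_constant", lower = 1e-9)
  if (decay_time_constant <= rise_time_constant)
    stop_config("decay_time_constant", "must exceed rise_time_constant")
  structure(list(decay_time_constant = decay_time_constant,
                 rise_time_constant = rise_time_constant,
                 source_type = source_type),
            class = "kernel_parameters")
}

#' Distance-decayed recurrent connectivity specification
#'
#' Recurrent coupling between two neurons is `W[target_type, source_type]`
#' times a spatial factor that decays with their cortical distance. The decay
#' length is indexed by the presynaptic (source) population: 200 um for
#' excitatory axons, 100 um for inhibitory ones. Weights are quoted as the
#' peak synaptic conductance (uS/cm2) evoked in the target by one presynaptic
#' spike at zero distance.
#'
#' @param decay_length_exc,decay_length_inh spatial decay constants, um.
#' @param weight_EE,weight_EI,weight_IE,weight_II coupling weights, uS/cm2;
#'   the first subscript is the target population, the second the source
#'   (e.g. `weight_EI` scales I -> E synapses).
#' @param connection_radius_cutoff distance (um) beyond which neurons are
#'   unconnected; defaults to three excitatory decay lengths.
#' @param spatial_form `"exponential"` for `exp(-r/lambda)` or `"gaussian"`
#'   for `exp(-r^2/lambda^2)`.
#' @return an object of class `"connectivity_spec"`.
#' @export
connectivity_spec <- function(decay_length_exc = 200,
                              decay_length_inh = 100,
                              weight_EE = WEIGHTS_DEFAULT[["EE"]],
                              weight_EI = WEIGHTS_DEFAULT[["EI"]],
                              weight_IE = WEIGHTS_DEFAULT[["IE"]],
                              weight_II = WEIGHTS_DEFAULT[["II"]],
                              connection_radius_cutoff = 3 * decay_length_exc,
                              spatial_form = c("exponential", "gaussian")) {
  spatial_form <- match.arg(spatial_form)
  check_num(decay_length_exc, "decay_length_exc", lower = 1e-9)
  check_num(decay_length_inh, "decay_length_inh", lower = 1e-9)
  for (w in c("weight_EE", "weight_EI", "weight_IE", "weight_II"))
    check_num(get(w), w, lower = 0)
  check_num(connection_radius_cutoff, "connection_radius_cutoff",
            lower = max(decay_length_exc, decay_length_inh))
  structure(list(decay_length_exc = decay_length_exc,
                 decay_length_inh = decay_length_inh,
                 weight_EE = weight_EE, weight_EI = weight_EI,
                 weight_IE = weight_IE, weight_II = weight_II,
                 connection_radius_cutoff = connection_radius_cutoff,
                 spatial_form = spatial_form),
            class = "connectivity_spec")
}

#' Geometry of the model cortical sheet
#'
#' @param sheet_width,sheet_height sheet dimensions, mm.
#' @param neuron_count total number of neurons on the sheet.
#' @param excitatory_fraction fraction of excitatory neurons.
#' @param placement_jitter jitter of each neuron around its grid position,
#'   as a fraction of the grid pitch (0 gives a deterministic grid).
#' @return an object of class `"network_geometry"`.
#' @export
network_geometry <- function(sheet_width = 1, sheet_height = 1,
                             neuron_count = 3341,
                             excitatory_fraction = 0.75,
                             placement_jitter = 0.3) {
  check_num(sheet_width, "sheet_width", lower = 1e-9)
  check_num(sheet_height, "sheet_height", lower = 1e-9)
  if (!is.numeric(neuron_count) || length(neuron_count) != 1 ||
      neuron_count < 2 || neuron_count != round(neuron_count))
    stop_config("neuron_count", "must be an integer >= 2")
  check_num(excitatory_fraction, "excitatory_fraction", lower = 0, upper = 1)
  check_num(placement_jitter, "placement_jitter", lower = 0, upper = 0.5)
  structure(list(sheet_width = sheet_width, sheet_height = sheet_height,
                 neuron_count = as.integer(neuron_count),
                 excitatory_fraction = excitatory_fraction,
                 placement_jitter = placement_jitter),
            class = "network_geometry")
}
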