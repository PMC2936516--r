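# Structured configuration: every model constant is a named key with its
# default, grouped in sections, round-trippable through YAML.

#' Default configuration
#'
#' Nested list with sections `network`, `neuron`, `kernels`, `connectivity`,
#' `feedforward`, `drive`, `simulation`, `analysis`. Values follow the
#' user-facing unit conventions (see [neuron_parameters()] etc.).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    network = list(sheet_width_mm = 1, sheet_height_mm = 1,
                   neuron_count = 3341L, excitatory_fraction = 0.75,
                   placement_jitter = 0.3, seed = 0L),
    neuron = list(membrane_capacitance_F_cm2 = 1e-6,
                  leak_conductance_S_cm2 = 50e-6,
                  leak_reversal_mV = -70, na_reversal_mV = 55,
                  k_reversal_mV = -80, exc_reversal_mV = 0,
                  inh_reversal_mV = -80,
                  na_max_conductance_S_cm2 = 120e-3,
                  k_max_conductance_S_cm2 = 36e-3,
                  gate_shift_mV = GATE_SHIFT_DEFAULT,
                  spike_threshold_mV = 0, spike_lockout_ms = 2),
    kernels = list(exc = list(decay_ms = 3, rise_ms = 1),
                   inh = list(decay_ms = 7, rise_ms = 1),
                   feedforward = list(decay_ms = 3, rise_ms = 1)),
    connectivity = list(decay_length_exc_um = 200, decay_length_inh_um = 100,
                        cutoff_um = 600, spatial_form = "exponential",
                        weight_EE = unname(WEIGHTS_DEFAULT["EE"]),
                        weight_EI = unname(WEIGHTS_DEFAULT["EI"]),
                        weight_IE = unname(WEIGHTS_DEFAULT["IE"]),
                        weight_II = unname(WEIGHTS_DEFAULT["II"])),
    feedforward = list(gmax_uS_cm2 = 30),
    drive = list(mean_rate = 40, modulation_amplitude = 0,
                 modulation_frequency = 38, modulation_phase_deg = 0,
                 duration_s = 10, seed = 1L),
    simulation = list(time_step_ms = 0.05, duration_s = 10,
                      warmup_discard_s = 0.5, seed = 1L),
    analysis = list(rate_bin_ms = 2, segment_ms = 2000, overlap = 0.5,
                    band_low_Hz = 20, band_high_Hz = 130,
                    baseline_factor = 3, response_window_ms = 10,
                    isolation_window_ms = 20, n_phase_bins = 12L,
                    correlogram_max_lag_ms = 50, correlogram_bin_ms = 1)
  )
}

#' Read / write a configuration file
#'
#' YAML with one block per section; unspecified keys fall back to
#' [default_config()] values.
#'
#' @param file path to a YAML configuration.
#' @param config a configuration list.
#' @return `read_config` returns the merged configuration list;
#'   `write_config` returns `file` invisibly.
#' @export
read_config <- function(file) {
  user <- yaml::read_yaml(file)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Build model objects from a configuration
#'
#' @param config a configuration list (see [default_config()]).
#' @return list with `geometry`, `connectivity`, `neuron_params`, `kernels`,
#'   `drive`, `sim_config`, `gmax`.
#' @export
config_objects <- function(config = default_config()) {
  cf <- merge_config(default_config(), config)
  nw <- cf$network; ne <- cf$neuron; cn <- cf$connectivity
  list(
    geometry = network_geometry(nw$sheet_width_mm, nw$sheet_height_mm,
                                nw$neuron_count, nw$excitatory_fraction,
                                nw$placement_jitter),
    connectivity = connectivity_spec(
      decay_length_exc = cn$decay_length_exc_um,
      decay_length_inh = cn$decay_length_inh_um,
      weight_EE = cn$weight_EE, weight_EI = cn$weight_EI,
      weight_IE = cn$weight_IE, weight_II = cn$weight_II,
      connection_radius_cutoff = cn$cutoff_um,
      spatial_form = cn$spatial_form),
    neuron_params = neuron_parameters(
      membrane_capacitance = ne$membrane_capacitance_F_cm2,
      leak_conductance = ne$leak_conductance_S_cm2,
      leak_reversal = ne$leak_reversal_mV,
      na_reversal = ne$na_reversal_mV, k_reversal = ne$k_reversal_mV,
      exc_reversal = ne$exc_reversal_mV, inh_reversal = ne$inh_reversal_mV,
      na_max_conductance = ne$na_max_conductance_S_cm2,
      k_max_conductance = ne$k_max_conductance_S_cm2,
      gate_shift = ne$gate_shift_mV,
      spike_detection_threshold = ne$spike_threshold_mV,
      spike_lockout = ne$spike_lockout_ms),
    kernels = list(
      E = kernel_parameters(cf$kernels$exc$decay_ms,
                            cf$kernels$exc$rise_ms, "E"),
      I = kernel_parameters(cf$kernels$inh$decay_ms,
                            cf$kernels$inh$rise_ms, "I"),
      F = kernel_parameters(cf$kernels$feedforward$decay_ms,
                            cf$kernels$feedforward$rise_ms, "E")),
    drive = drive_spec(cf$drive$mean_rate, cf$drive$modulation_amplitude,
                       cf$drive$modulation_frequency,
                       cf$drive$modulation_phase_deg,
                       cf$drive$duration_s, cf$drive$seed),
    sim_config = simulation_config(cf$simulation$time_step_ms,
                                   cf$simulation$duration_s,
                                   cf$simulation$warmup_discard_s,
                                   seed = cf$simulation$seed),
    gmax = cf$feedforward$gmax_uS_cm2,
    analysis = cf$analysis,
    network_seed = nw$seed
  )
}

#' Build the network described by a configuration
#'
#' @param config a configuration list.
#' @param gmax optional feedforward peak conductance (uS/cm2) overriding the
#'   configured value.
#' @return a `"cortical_network"`.
#' @export
network_from_config <- function(config = default_config(), gmax = NULL) {
  ob <- config_objects(config)
  build_network(ob$geometry, ob$connectivity, ob$neuron_params, ob$kernels,
                feedforward_gmax = if (is.null(gmax)) ob$gmax else gmax,
                seed = ob$network_seed)
}
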