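# Network integration: R front end over the compiled exponential-Euler core.

#' Simulation configuration
#'
#' @param time_step integration step, ms (<= 0.1).
#' @param duration simulated time, s.
#' @param warmup_discard initial interval (s) removed from the returned
#'   raster and traces; the onset transient.
#' @param record_voltages integer vector of neuron ids whose membrane
#'   potential is recorded (empty for none).
#' @param record_every record every k-th step of the voltage traces.
#' @param seed integer seed recorded in the config echo (the integrator
#'   itself is deterministic; the seed governs input generation).
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(time_step = 0.05, duration = 10,
                              warmup_discard = 0.5,
                              record_voltages = integer(),
                              record_every = 1L, seed = 1) {
  check_num(time_step, "time_step", lower = 1e-6, upper = 0.1)
  check_num(duration, "duration", lower = 1e-9)
  check_num(warmup_discard, "warmup_discard", lower = 0)
  if (warmup_discard >= duration)
    stop_config("warmup_discard", "must be smaller than duration")
  structure(list(time_step = time_step, duration = duration,
                 warmup_discard = warmup_discard,
                 record_voltages = as.integer(record_voltages),
                 record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Integrate the network
#'
#' Drives every neuron with its feedforward afferent train (each input spike
#' evokes the feedforward kernel scaled to peak `feedforward_gmax`),
#' propagates recurrent spikes through the distance-decayed weight matrix,
#' and detects output spikes as upward threshold crossings with a refractory
#' lockout. Deterministic given `(network, input_raster, config)`.
#'
#' The warmup interval is removed: returned spike times (and voltage traces)
#' are shifted so time 0 is the end of warmup.
#'
#' @param network a [build_network()] result.
#' @param input_raster a [spike_raster()] with one afferent per neuron.
#' @param config a [simulation_config()].
#' @return an object of class `"simulation_result"`: `output_raster`,
#'   `input_raster` (warmup-trimmed), `voltage_traces` (time x neuron matrix
#'   or `NULL`), `config_echo`.
#' @export
run_simulation <- function(network, input_raster,
                           config = simulation_config()) {
  stopifnot(inherits(network, "cortical_network"),
            inherits(input_raster, "spike_raster"),
            inherits(config, "simulation_config"))
  n <- network$geometry$neuron_count
  if (input_raster$population_size != n)
    stop(sprintf(
      "input raster population (%d) does not match network size (%d)",
      input_raster$population_size, n), call. = FALSE)

  kk <- network$kernels
  res <- sim_network_cpp(
    W = network$W * 1e-3,  # uS -> mS/cm2
    is_inh = as.integer(network$types == "I"),
    neuron = pack_neuron(network$neuron_params),
    tau_e = c(kk$E$decay_time_constant, kk$E$rise_time_constant),
    tau_i = c(kk$I$decay_time_constant, kk$I$rise_time_constant),
    tau_f = c(kk$F$decay_time_constant, kk$F$rise_time_constant),
    in_id = input_raster$id - 1L, in_t = input_raster$time,
    gmax_f = network$feedforward_gmax * 1e-3,
    dt = config$time_step, duration = config$duration * 1000,
    record = config$record_voltages, record_every = config$record_every)

  w_ms <- config$warmup_discard * 1000
  dur_ms <- config$duration * 1000 - w_ms
  keep <- res$time > w_ms
  out <- spike_raster(res$id[keep], pmin(res$time[keep] - w_ms, dur_ms),
                      n, dur_ms)
  keep_in <- input_raster$time > w_ms
  inp <- spike_raster(input_raster$id[keep_in],
                      input_raster$time[keep_in] - w_ms, n, dur_ms)

  traces <- NULL
  if (length(config$record_voltages)) {
    nr <- as.integer(res$n_recorded_rows)
    traces <- res$voltage[seq_len(nr), , drop = FALSE]
    colnames(traces) <- as.character(config$record_voltages)
    tt <- res$voltage_time[seq_len(nr)]
    sel <- tt > w_ms
    traces <- traces[sel, , drop = FALSE]
    attr(traces, "time_ms") <- tt[sel] - w_ms
  }

  structure(list(output_raster = out, input_raster = inp,
                 voltage_traces = traces,
                 config_echo = list(config = config,
                                    feedforward_gmax = network$feedforward_gmax,
                                    network_seed = network$seed,
                                    n_neurons = n)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n  output: ")
  print(x$output_raster)
  cat("  input:  ")
  print(x$input_raster)
  invisible(x)
}

#' Integrate a single neuron under prescribed conductance waveforms
#'
#' Oracle harness for the membrane dynamics: one isolated neuron driven by
#' excitatory and inhibitory conductance waveforms sampled at the
#' integration step.
#'
#' @param neuron_params an [neuron_parameters()].
#' @param g_exc,g_inh conductance waveforms, S/cm2, one sample per step
#'   (scalars are recycled).
#' @param time_step integration step, ms.
#' @param duration simulated time, ms (defaults to the waveform length).
#' @return list with `time` (ms), `voltage` (mV), `spike_times` (ms).
#' @export
run_single_neuron <- function(neuron_params = neuron_parameters(),
                              g_exc = 0, g_inh = 0, time_step = 0.05,
                              duration = NULL) {
  if (is.null(duration))
    duration <- max(length(g_exc), length(g_inh)) * time_step
  nsteps <- ceiling(duration / time_step)
  ge <- rep_len(as.numeric(g_exc), nsteps) * 1e3  # S -> mS/cm2
  gi <- rep_len(as.numeric(g_inh), nsteps) * 1e3
  res <- sim_single_cpp(pack_neuron(neuron_params), ge, gi, time_step)
  list(time = seq_len(nsteps) * time_step, voltage = res$voltage,
       spike_times = res$spike_times)
}
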