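# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, expr, envir = .fixture_cache)
  .fixture_cache[[name]]
}

# quarter-scale network (835 neurons, drive-conserving weight rescale)
fixture_net <- function() cached("fixture_net", {
  make_fixture_network(0.25)$network
})

fixture_analysis <- function() default_config()$analysis

# 2.5 s static-drive run on the fixture network (0.5 s warmup discarded)
fixture_static <- function() cached("fixture_static", {
  run_condition(fixture_net(), drive_spec(40, 0, duration = 2.5, seed = 1),
                simulation_config(duration = 2.5, warmup_discard = 0.5),
                fixture_analysis())
})

# matched 38 Hz strongly modulated run (resonant drive for the fixture)
fixture_driven <- function() cached("fixture_driven", {
  fs <- fixture_static()$spectrum$dominant
  run_condition(fixture_net(),
                drive_spec(40, 20, fs, 0, duration = 2.5, seed = 1),
                simulation_config(duration = 2.5, warmup_discard = 0.5),
                fixture_analysis())
})

# the full-size default network (shared by the structural and acceptance
# checks; building the 3341^2 weight matrix takes a little while)
full_net <- function() cached("full_net", network_from_config())

run_static_full <- function(gmax, seed = 1, duration = 4.5) {
  cached(sprintf("static_full_%s_%s_%s", gmax, seed, duration), {
    net <- full_net()
    net$feedforward_gmax <- gmax
    run_condition(net, drive_spec(40, 0, duration = duration, seed = seed),
                  simulation_config(duration = duration,
                                    warmup_discard = 0.5),
                  fixture_analysis(), full = FALSE)
  })
}

# deterministic synthetic raster: every neuron fires periodically
periodic_raster <- function(n_neurons = 4, period = 25, duration = 1000,
                            jitter = 0) {
  times <- lapply(seq_len(n_neurons), function(i) {
    tt <- seq(period / 2, duration - 1e-9, by = period)
    if (jitter > 0) tt <- tt + runif(length(tt), -jitter, jitter)
    tt
  })
  spike_raster(rep(seq_len(n_neurons), lengths(times)), unlist(times),
               n_neurons, duration)
}
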