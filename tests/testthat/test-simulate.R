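# Network integration: determinism, rest state, warmup handling, single
# neuron behavior, and the emergent gamma rhythm at fixture scale.

test_that("a silent network stays silent and configs validate", {
  geo <- network_geometry(neuron_count = 30)
  cz <- connectivity_spec(weight_EE = 0, weight_EI = 0, weight_IE = 0,
                          weight_II = 0)
  net <- build_network(geo, cz, feedforward_gmax = 0, seed = 1)
  inp <- generate_poisson_raster(drive_spec(40, 0, duration = 1, seed = 1),
                                 30)
  sim <- run_simulation(net, inp, simulation_config(duration = 1,
                                                    warmup_discard = 0.1))
  expect_equal(length(sim$output_raster$time), 0)

  expect_error(simulation_config(time_step = 0.5), "time_step")
  expect_error(simulation_config(duration = 1, warmup_discard = 2),
               "warmup_discard")
  bad <- generate_poisson_raster(drive_spec(duration = 1), 10)
  expect_error(run_simulation(net, bad, simulation_config(duration = 1)),
               "does not match")
})

test_that("simulation is deterministic and respects warmup trimming", {
  net <- fixture_net()
  inp <- generate_poisson_raster(drive_spec(40, 0, duration = 1.2, seed = 4),
                                 net$geometry$neuron_count)
  sc <- simulation_config(duration = 1.2, warmup_discard = 0.3)
  s1 <- run_simulation(net, inp, sc)
  s2 <- run_simulation(net, inp, sc)
  expect_identical(s1$output_raster, s2$output_raster)
  expect_equal(s1$output_raster$duration, 900)
  expect_true(all(s1$output_raster$time > 0 &
                    s1$output_raster$time <= 900))
  expect_true(all(s1$input_raster$time > 0))
})

test_that("single neuron: rest, one spike per strong pulse, monotone f-I", {
  p <- neuron_parameters()
  flat <- run_single_neuron(p, 0, 0, duration = 500)
  expect_lt(max(abs(diff(flat$voltage[5000:10000]))), 1e-6)

  tt <- seq(0.05, 80, by = 0.05)
  pulse <- 120e-6 * synaptic_kernel(tt)
  one <- run_single_neuron(p, g_exc = c(numeric(2000), pulse))
  expect_equal(length(one$spike_times), 1)

  rates <- sapply(c(1e-4, 1.5e-4, 2e-4), function(g)
    length(run_single_neuron(p, g_exc = rep(g, 20000))$spike_times))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0)
})

test_that("static drive evokes a gamma-band rhythm at fixture scale", {
  cond <- fixture_static()
  sp <- cond$spectrum
  expect_false(is.na(sp$dominant))
  expect_gt(sp$dominant, 25)
  expect_lt(sp$dominant, 70)
  expect_gt(sp$peak_frequencies$prominence[1], 3)
})

test_that("I cells fire about once per gamma cycle, E cells far less", {
  cond <- fixture_static()
  net <- fixture_net()
  f <- cond$spectrum$dominant
  out <- cond$sim$output_raster
  dur_s <- out$duration / 1000
  rate_i <- sum(net$types[out$id] == "I") / sum(net$types == "I") / dur_s
  rate_e <- sum(net$types[out$id] == "E") / sum(net$types == "E") / dur_s
  expect_gt(rate_i / f, 0.8)
  expect_lt(rate_i / f, 1.2)
  expect_lt(rate_e / f, 1)
})

test_that("gamma vanishes when E-I coupling is removed", {
  cfg <- make_fixture_network(0.25)$config
  cfg$connectivity$weight_EI <- 0
  cfg$connectivity$weight_IE <- 0
  net <- network_from_config(cfg)
  # longer run than the other fixtures: with few Welch segments, noise
  # bumps alone can cross the 3x-baseline detection threshold
  cond <- run_condition(net, drive_spec(40, 0, duration = 9.5, seed = 1),
                        simulation_config(duration = 9.5,
                                          warmup_discard = 0.5),
                        fixture_analysis(), full = FALSE)
  # no spectral peak above 3x the local baseline
  expect_equal(nrow(cond$spectrum$peak_frequencies), 0)
})

test_that("the spectral peak is stable under time-step halving", {
  net <- fixture_net()
  # 4 s of analyzed activity so the peak estimate is steadier than the
  # 0.5 Hz grid
  inp <- generate_poisson_raster(drive_spec(40, 0, duration = 4.5, seed = 2),
                                 net$geometry$neuron_count)
  f_at <- function(dt) {
    sim <- run_simulation(net, inp,
                          simulation_config(time_step = dt, duration = 4.5,
                                            warmup_discard = 0.5))
    power_spectrum(population_rate(sim$output_raster, 2))$dominant
  }
  expect_lt(abs(f_at(0.05) - f_at(0.025)), 1)
})

isi_sharpness <- function(cond, ty) {
  s <- cond$isi$stats
  s$sharpness[s$type == ty]
}

test_that("resonant drive entrains the rhythm and sharpens synchrony", {
  stat <- fixture_static()
  drv <- fixture_driven()
  fs <- stat$spectrum$dominant
  # single peak at the driving frequency
  expect_equal(drv$spectrum$classification, "resonant")
  expect_lt(abs(drv$spectrum$dominant - fs), 1.5)
  # correlogram modulation depth grows under resonant drive
  depth <- function(cond) {
    cg <- spike_correlogram(cond$sim$output_raster,
                            cond$sim$output_raster, max_lag = 40)
    max(cg$normalized_coincidence, na.rm = TRUE) -
      min(cg$normalized_coincidence, na.rm = TRUE)
  }
  expect_gt(depth(drv), depth(stat))
  # ISI distributions sharpen (inverse CV grows) under resonance
  expect_gt(isi_sharpness(drv, "I"), isi_sharpness(stat, "I"))
})
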