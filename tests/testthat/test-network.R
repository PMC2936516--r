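# Network construction: geometry, spatial weighting, synaptic kernels,
# membrane dynamics.

test_that("default neuron parameters carry the published constants", {
  p <- neuron_parameters()
  expect_equal(p$membrane_capacitance, 1e-6)
  expect_equal(p$leak_conductance, 50e-6)
  expect_equal(p$leak_reversal, -70)
  expect_equal(p$na_reversal, 55)
  expect_equal(p$k_reversal, -80)
  expect_equal(p$exc_reversal, 0)
  expect_equal(p$inh_reversal, -80)
  k <- default_kernels()
  expect_equal(c(k$E$decay_time_constant, k$E$rise_time_constant), c(3, 1))
  expect_equal(c(k$I$decay_time_constant, k$I$rise_time_constant), c(7, 1))
  expect_error(neuron_parameters(inh_reversal = -60), "inh_reversal")
})

test_that("spatial factor is 1 at zero distance and decays exponentially", {
  cs <- connectivity_spec()
  expect_equal(spatial_factor(0, "E", cs), 1)
  expect_equal(spatial_factor(0, "I", cs), 1)
  # e-folding at one decay length: 200 um for E sources, 100 um for I
  expect_equal(spatial_factor(200, "E", cs), exp(-1), tolerance = 1e-12)
  expect_equal(spatial_factor(100, "I", cs), exp(-1), tolerance = 1e-12)
  d <- seq(0, 600, by = 10)
  expect_true(all(diff(spatial_factor(d, "E", cs)) < 0))
  expect_error(spatial_factor(-1, "E", cs), "non-negative")
  # gaussian variant
  csg <- connectivity_spec(spatial_form = "gaussian")
  expect_equal(spatial_factor(200, "E", csg), exp(-1), tolerance = 1e-12)
})

test_that("synaptic kernel is peak-normalized with the closed-form peak time", {
  kE <- kernel_parameters(3, 1, "E")
  kI <- kernel_parameters(7, 1, "I")
  expect_equal(synaptic_kernel(0, kE), 0)
  # argmax of exp(-t/td) - exp(-t/tr) at td*tr/(td-tr)*log(td/tr)
  tE <- 1.5 * log(3)
  tI <- 7 / 6 * log(7)
  expect_equal(tE, 1.6479, tolerance = 1e-4)
  expect_equal(tI, 2.2703, tolerance = 1e-4)
  tt <- seq(0, 30, by = 1e-3)
  expect_equal(tt[which.max(synaptic_kernel(tt, kE))], tE, tolerance = 2e-3)
  expect_equal(tt[which.max(synaptic_kernel(tt, kI))], tI, tolerance = 2e-3)
  expect_equal(max(synaptic_kernel(tt, kE)), 1, tolerance = 1e-6)
  expect_equal(max(synaptic_kernel(tt, kI)), 1, tolerance = 1e-6)
  expect_error(kernel_parameters(1, 1), "decay_time_constant")
})

test_that("build_network is deterministic and spatially consistent", {
  geo <- network_geometry(neuron_count = 150)
  cs <- connectivity_spec()
  n1 <- build_network(geo, cs, seed = 7)
  n2 <- build_network(geo, cs, seed = 7)
  expect_identical(n1$positions, n2$positions)
  expect_identical(n1$types, n2$types)
  expect_identical(n1$W, n2$W)

  # weights equal W_sigma,sigma' * exp(-r/lambda_source), zero self-coupling
  expect_true(all(diag(n1$W) == 0))
  wblock <- c(EE = cs$weight_EE, IE = cs$weight_IE,
              EI = cs$weight_EI, II = cs$weight_II)
  for (pair in list(c(2, 3), c(10, 140), c(55, 60))) {
    i <- pair[1]; j <- pair[2]
    r <- sqrt(sum((n1$positions[i, ] - n1$positions[j, ])^2))
    lam <- if (n1$types[j] == "E") cs$decay_length_exc else cs$decay_length_inh
    expected <- if (r > cs$connection_radius_cutoff) 0 else
      wblock[paste0(n1$types[i], n1$types[j])] * exp(-r / lam)
    expect_equal(unname(n1$W[i, j]), unname(expected), tolerance = 1e-12)
  }

  # distance monotonicity within a type pair
  ee <- which(n1$types == "E")
  i <- ee[1]
  js <- ee[-1]
  r <- sqrt(rowSums(sweep(n1$positions[js, , drop = FALSE], 2,
                          n1$positions[i, ])^2))
  o <- order(r)
  expect_true(all(diff(n1$W[i, js][o]) <= 1e-12))

  # all-zero coupling gives a purely feedforward network
  cz <- connectivity_spec(weight_EE = 0, weight_EI = 0,
                          weight_IE = 0, weight_II = 0)
  nz <- build_network(geo, cz, seed = 1)
  expect_true(all(nz$W == 0))

  expect_error(network_geometry(excitatory_fraction = 1.5),
               "excitatory_fraction")
  expect_error(network_geometry(neuron_count = 1), "neuron_count")
})

test_that("connectivity table round-trips the nonzero weights", {
  net <- build_network(network_geometry(neuron_count = 40), seed = 1)
  tab <- connectivity_table(net)
  expect_true(all(tab$weight > 0))
  expect_equal(nrow(tab), sum(net$W != 0))
  k <- sample(nrow(tab), 5)
  expect_equal(tab$weight[k], net$W[cbind(tab$target[k], tab$source[k])])
})

test_that("membrane derivatives respect current signs and the blocked fixed point", {
  p <- neuron_parameters(na_max_conductance = 0, k_max_conductance = 0)
  r <- hh_rates(p$leak_reversal, p)
  st <- list(V = p$leak_reversal,
             m = r[, "am"] / (r[, "am"] + r[, "bm"]),
             h = r[, "ah"] / (r[, "ah"] + r[, "bh"]),
             n = r[, "an"] / (r[, "an"] + r[, "bn"]))
  expect_equal(membrane_derivatives(st, p)$dV, 0, tolerance = 1e-12)

  # excitatory conductance depolarizes below V_E; inhibition hyperpolarizes
  # above V_I
  pfull <- neuron_parameters()
  st2 <- list(V = -60, m = 0.1, h = 0.5, n = 0.3)
  d0 <- membrane_derivatives(st2, pfull)$dV
  dE <- membrane_derivatives(st2, pfull, g_exc = 1e-4)$dV
  dI <- membrane_derivatives(st2, pfull, g_inh = 1e-4)$dV
  expect_gt(dE, d0)
  expect_lt(dI, d0)
  expect_error(membrane_derivatives(list(V = NaN, m = 0, h = 0, n = 0),
                                    pfull), "non-finite")
})

test_that("channel-blocked membrane relaxes to V_L with the 20 ms time constant", {
  p <- neuron_parameters(na_max_conductance = 0, k_max_conductance = 0)
  # push the neuron to -60 mV with a brief conductance step, then release
  r <- run_single_neuron(p, g_exc = c(rep(2e-4, 4000), rep(0, 8000)),
                         time_step = 0.05)
  v <- r$voltage[4001:12000] - p$leak_reversal
  t <- (seq_along(v) - 1) * 0.05
  tau_fit <- -1 / coef(lm(log(v / v[1]) ~ t - 1))[1]
  expect_equal(unname(tau_fit),
               p$membrane_capacitance / p$leak_conductance * 1000,
               tolerance = 0.01)
})

test_that("resting state is a stable fixed point near the leak reversal", {
  p <- neuron_parameters()
  rest <- resting_potential(p)
  expect_lt(abs(rest - p$leak_reversal), 5)
  # after settling, membrane stays put to within 0.1 mV for a further 1 s
  r <- run_single_neuron(p, 0, 0, time_step = 0.05, duration = 3000)
  late <- r$voltage[r$time > 2000]
  expect_lt(max(abs(late - rest)), 0.1)
})

test_that("integration matches a 10x finer reference", {
  p <- neuron_parameters()
  # conductance waveform: three feedforward EPSPs, the last two summating
  # to a spike
  dt <- 0.05
  tt <- seq(dt, 200, by = dt)
  g <- 40e-6 * (synaptic_kernel(pmax(tt - 50, 0)) +
                  synaptic_kernel(pmax(tt - 120, 0)) +
                  synaptic_kernel(pmax(tt - 122, 0)))
  g[tt <= 50] <- 0
  coarse <- run_single_neuron(p, g_exc = g, time_step = dt)
  ttf <- seq(dt / 10, 200, by = dt / 10)
  gf <- 40e-6 * (synaptic_kernel(pmax(ttf - 50, 0)) +
                   synaptic_kernel(pmax(ttf - 120, 0)) +
                   synaptic_kernel(pmax(ttf - 122, 0)))
  gf[ttf <= 50] <- 0
  fine <- run_single_neuron(p, g_exc = gf, time_step = dt / 10)

  expect_equal(length(coarse$spike_times), 1)
  expect_equal(length(fine$spike_times), 1)
  expect_lt(abs(coarse$spike_times[1] - fine$spike_times[1]), 0.2)

  vf <- fine$voltage[seq(10, length(ttf), by = 10)]
  # compare away from the spike (within 3 ms of it the trajectories are
  # near-vertical and tiny time offsets dominate)
  away <- abs(tt - coarse$spike_times[1]) > 3
  expect_lt(max(abs(coarse$voltage[away] - vf[away])), 0.5)
})

test_that("network engine agrees with the single-neuron oracle", {
  # a one-neuron network driven by input spikes must reproduce the
  # single-neuron integration of the equivalent conductance waveform
  geo <- network_geometry(neuron_count = 2, excitatory_fraction = 1)
  cz <- connectivity_spec(weight_EE = 0, weight_EI = 0, weight_IE = 0,
                          weight_II = 0)
  net <- build_network(geo, cz, feedforward_gmax = 45, seed = 1)
  spikes <- c(40, 110, 113)
  inp <- spike_raster(rep(1L, 3), spikes, 2, 250)
  sim <- run_simulation(net, inp,
                        simulation_config(duration = 0.25,
                                          warmup_discard = 0,
                                          record_voltages = 1L))
  dt <- 0.05
  tt <- seq(dt, 250, by = dt)
  g <- rowSums(sapply(spikes, function(s)
    ifelse(tt > s, synaptic_kernel(pmax(tt - s, 0)), 0))) * 45e-6
  single <- run_single_neuron(net$neuron_params, g_exc = g, time_step = dt)

  vnet <- sim$voltage_traces[, "1"]
  away <- rep(TRUE, length(tt))
  for (s in c(sim$output_raster$time, single$spike_times))
    away <- away & abs(tt - s) > 3
  expect_lt(max(abs(vnet[seq_along(tt)][away] - single$voltage[away])), 0.5)
  expect_equal(length(sim$output_raster$time), length(single$spike_times))
  if (length(single$spike_times))
    expect_lt(max(abs(sim$output_raster$time - single$spike_times)), 0.2)
})
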