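# Measurement battery: rates, spectra, ISI, correlograms, response
# statistics, unpaired selection, gamma phase and phase efficacy.

test_that("population rate counts spikes per bin per neuron", {
  r0 <- spike_raster(integer(), numeric(), 10, 1000)
  expect_true(all(population_rate(r0, 10)$rate == 0))

  # 3 neurons, one spike each in the first 10 ms bin
  r <- spike_raster(1:3, c(1, 5, 9), 3, 100)
  rs <- population_rate(r, 10)
  expect_equal(rs$rate[1], 3 / 0.01 / 3)
  expect_equal(sum(rs$rate[-1]), 0)

  d <- drive_spec(40, 0, duration = 5, seed = 13)
  rp <- generate_poisson_raster(d, 50)
  m <- mean(population_rate(rp, 10)$rate)
  expect_lt(abs(m - 40), 3 * sqrt(40 / (5 * 50)))
})

test_that("power spectrum finds known sinusoids and ignores white noise", {
  set.seed(1)
  t <- seq(0.001, 10, by = 0.001)  # 1 ms sampling, 10 s
  x <- 5 * sin(2 * pi * 38 * t) + rnorm(length(t), 0, 0.5)
  sp <- power_spectrum(x, bin_width = 1)
  expect_lt(abs(sp$dominant - 38), 0.5)
  expect_equal(sp$classification, "resonant")

  x2 <- 3 * sin(2 * pi * 30 * t) + 3 * sin(2 * pi * 50 * t) +
    rnorm(length(t), 0, 0.5)
  sp2 <- power_spectrum(x2, bin_width = 1)
  expect_equal(sp2$classification, "coexisting")
  expect_setequal(round(sort(sp2$peak_frequencies$frequency)), c(30, 50))

  noise <- rnorm(length(t))
  sp3 <- power_spectrum(noise, bin_width = 1)
  expect_equal(sp3$classification, "none")
})

test_that("harmonics of a strong peak are not reported as coexistence", {
  t <- seq(0.001, 10, by = 0.001)
  # spiky periodic signal: strong energy at 40, 80, 120 Hz
  set.seed(2)
  x <- exp(3 * cos(2 * pi * 40 * t)) + rnorm(length(t), 0, 0.1)
  sp <- power_spectrum(x, bin_width = 1)
  expect_lt(abs(sp$dominant - 40), 0.5)
  expect_equal(sp$classification, "resonant")
})

test_that("ISI distribution: periodic trains are maximally sharp, Poisson CV ~ 1", {
  per <- periodic_raster(n_neurons = 5, period = 20, duration = 2000)
  h <- isi_distribution(per)
  expect_equal(h$stats$cv, 0, tolerance = 1e-9)
  expect_equal(h$stats$sharpness, 100)  # capped

  d <- drive_spec(40, 0, duration = 10, seed = 21)
  rp <- generate_poisson_raster(d, 30)  # ~12000 ISIs
  hp <- isi_distribution(rp, max_isi = 400)
  expect_equal(hp$stats$cv, 1, tolerance = 0.05)
  expect_error(isi_distribution(spike_raster(1L, 5, 1, 10)), "two spikes")
})

test_that("correlogram baseline is 1 for independent trains", {
  d1 <- drive_spec(40, 0, duration = 5, seed = 31)
  d2 <- drive_spec(40, 0, duration = 5, seed = 32)
  ra <- generate_poisson_raster(d1, 60)
  rb <- generate_poisson_raster(d2, 60)
  cg <- spike_correlogram(ra, rb, max_lag = 50, bin = 1)
  expect_lt(max(abs(cg$normalized_coincidence - 1)), 0.05)
  expect_equal(mean(cg$normalized_coincidence), 1, tolerance = 0.005)

  # auto-population correlogram excludes same-neuron pairs: a raster of
  # identical periodic neurons still has baseline-1 structure at lag 0
  # rather than a self-coincidence spike
  per <- periodic_raster(n_neurons = 6, period = 25, duration = 3000,
                         jitter = 0)
  cga <- spike_correlogram(per, per, max_lag = 50, bin = 1)
  expect_true(all(is.finite(cga$normalized_coincidence)))
  # symmetric in lag for the auto case
  nc <- cga$normalized_coincidence
  expect_equal(nc, rev(nc), tolerance = 1e-9)
})

test_that("unpaired-spike selection applies the isolation rule exactly", {
  r <- spike_raster(rep(1L, 3), c(100, 110, 200), 1, 300)
  u <- select_unpaired_spikes(r, 20)
  expect_equal(u$time, 200)

  # all gaps > 2x window: unchanged; and idempotent
  r2 <- spike_raster(rep(1L, 4), c(10, 60, 110, 160), 1, 300)
  u2 <- select_unpaired_spikes(r2, 20)
  expect_equal(u2$time, r2$time)
  expect_equal(select_unpaired_spikes(u2, 20)$time, u2$time)

  # analytic retention for a homogeneous Poisson train: exp(-2 r w)
  d <- drive_spec(40, 0, duration = 10, seed = 41)
  rp <- generate_poisson_raster(d, 40)
  frac <- length(select_unpaired_spikes(rp, 20)$time) / length(rp$time)
  p0 <- exp(-2 * 40 * 0.02)
  se <- sqrt(p0 * (1 - p0) / length(rp$time))
  expect_lt(abs(frac - p0), 3 * se + 0.01)
})

test_that("response probability and delay follow the constructed correspondence", {
  inp <- spike_raster(rep(1:2, each = 5),
                      c(seq(100, 900, 200), seq(150, 950, 200)), 2, 1000)
  out <- spike_raster(inp$id, inp$time + 3, 2, 1000)
  st <- response_probability(inp, out, response_window = 10)
  expect_equal(st$response_probability, 1)
  expect_equal(st$response_delay, 3)
  expect_equal(st$n_input_spikes, 10)

  none <- spike_raster(integer(), numeric(), 2, 1000)
  st0 <- response_probability(inp, none)
  expect_equal(st0$response_probability, 0)
  expect_true(is.na(st0$response_delay))

  # outputs beyond the window do not count
  late <- spike_raster(inp$id, inp$time + 15, 2, 1000)
  expect_equal(response_probability(inp, late,
                                    response_window = 10)$response_probability,
               0)

  # afferent map redirects the attribution
  out1 <- spike_raster(rep(2L, 5), seq(100, 900, 200) + 2, 2, 1000)
  inp1 <- spike_raster(rep(1L, 5), seq(100, 900, 200), 2, 1000)
  stm <- response_probability(inp1, out1, afferent_map = c(2L, 1L))
  expect_equal(stm$response_probability, 1)
  expect_equal(stm$response_delay, 2)
})

test_that("response enhancement is the plain difference of matched stats", {
  a <- structure(list(response_probability = 0.30, response_delay = 8),
                 class = "response_stats")
  b <- structure(list(response_probability = 0.22, response_delay = 6),
                 class = "response_stats")
  enh <- response_enhancement(a, b)
  expect_equal(enh$probability_enhancement, 0.08)
  expect_equal(enh$delay_decrement, -2)  # negative: delay increased
  expect_equal(response_enhancement(a, a)$probability_enhancement, 0)
})

test_that("gamma phase is 0 at cycle peaks and advances linearly", {
  t <- seq(0.001, 5, by = 0.001)
  x <- sin(2 * pi * 40 * t)
  rs <- structure(list(time = t * 1000, rate = x + 2, bin_width = 1,
                       n_neurons = 1), class = "rate_series")
  ph <- gamma_phase(rs, band = c(30, 50))
  # phase at the sinusoid maxima is ~0 degrees
  peaks_ms <- (which(diff(sign(diff(x))) < 0) + 1)
  mid <- peaks_ms[peaks_ms > 500 & peaks_ms < 4500]
  expect_lt(max(abs(ph$phase[mid])), 10)
  # linear advance: unwrapped phase slope = 360 * f deg/s
  inner <- ph$time > 500 & ph$time < 4500
  slope <- coef(lm(ph$unwrapped[inner] ~ ph$time[inner]))[2] * 1000
  expect_equal(unname(slope), 360 * 40, tolerance = 0.01)
})

test_that("phase efficacy normalizes to a weighted mean of exactly 1", {
  # synthetic phase series: 40 Hz, 5 s
  t <- seq(0.001, 5, by = 0.001)
  rs <- structure(list(time = t * 1000, rate = sin(2 * pi * 40 * t) + 2,
                       bin_width = 1, n_neurons = 1), class = "rate_series")
  ph <- gamma_phase(rs, band = c(30, 50))

  set.seed(5)
  n <- 4000
  tin <- sort(runif(n, 10, 4990))
  # one afferent per neuron so responses attribute unambiguously
  ids <- seq_len(n)
  inp <- spike_raster(ids, tin, n, 5000)

  # phase-independent responder: every input answered 2 ms later
  out_all <- spike_raster(ids, tin + 2, n, 5000)
  eff <- phase_efficacy(inp, out_all, NULL, ph, n_bins = 12)
  wm <- sum(eff$normalized_efficacy * eff$n_spikes, na.rm = TRUE) /
    sum(eff$n_spikes[!is.na(eff$normalized_efficacy)])
  expect_equal(wm, 1, tolerance = 1e-12)
  expect_lt(max(abs(eff$normalized_efficacy - 1), na.rm = TRUE), 0.05)

  # responder active in a single bin: efficacy 12 there, 0 elsewhere
  phases <- gammares:::phase_at_times(ph, tin)
  sel <- phases > 30 & phases <= 60
  out_one <- spike_raster(ids[sel], tin[sel] + 2, n, 5000)
  eff1 <- phase_efficacy(inp, out_one, NULL, ph, n_bins = 12)
  hit <- which.max(eff1$normalized_efficacy)
  expect_equal(eff1$phase_bin_centers[hit], 45)
  expect_equal(eff1$max_efficacy,
               sum(eff1$n_spikes) / eff1$n_spikes[hit], tolerance = 0.05)
  expect_true(all(eff1$normalized_efficacy[-hit] < 0.2, na.rm = TRUE))
  wm1 <- sum(eff1$normalized_efficacy * eff1$n_spikes, na.rm = TRUE) /
    sum(eff1$n_spikes[!is.na(eff1$normalized_efficacy)])
  expect_equal(wm1, 1, tolerance = 1e-12)

  expect_error(phase_efficacy(inp, out_all, NULL, ph, n_bins = 4), "n_bins")
})
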