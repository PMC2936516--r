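# Experiment drivers: weight calibration, the input-frequency sweep, the
# gmax -> spontaneous-frequency curve, and the gmax resonance sweep.

#' Run one drive condition and its analysis battery
#'
#' Generates the Poisson afferent raster for `drive`, integrates the
#' network, and computes the full set of measurements.
#'
#' @param network a `"cortical_network"`.
#' @param drive a [drive_spec()].
#' @param sim_config a [simulation_config()].
#' @param analysis analysis settings (section `analysis` of
#'   [default_config()]).
#' @param full compute the complete battery (ISI, gamma phase, phase
#'   efficacy); `FALSE` restricts to spectrum and response statistics,
#'   which is what the parameter sweeps report.
#' @return list with `sim`, `rate` (population rate series), `spectrum`,
#'   `isi`, `stats_all`, `stats_unpaired`, `phase`, `efficacy`.
#' @export
run_condition <- function(network, drive, sim_config,
                          analysis = default_config()$analysis,
                          full = TRUE) {
  drive$duration <- sim_config$duration
  input <- generate_poisson_raster(drive, network$geometry$neuron_count)
  sim <- run_simulation(network, input, sim_config)
  analyze_simulation(sim, network$types, analysis, full = full)
}

#' Analysis battery for a finished simulation
#'
#' @param sim a [run_simulation()] result.
#' @param types per-neuron type labels.
#' @param analysis analysis settings.
#' @param full see [run_condition()].
#' @return see [run_condition()].
#' @export
analyze_simulation <- function(sim, types,
                               analysis = default_config()$analysis,
                               full = TRUE) {
  an <- analysis
  out <- sim$output_raster
  empty <- length(out$time) < 10
  rate <- population_rate(out, bin_width = an$rate_bin_ms)
  spectrum <- tryCatch(
    power_spectrum(rate, segment_length = an$segment_ms,
                   overlap = an$overlap,
                   band = c(an$band_low_Hz, an$band_high_Hz),
                   baseline_factor = an$baseline_factor),
    error = function(e) NULL)
  isi <- if (full && !empty) tryCatch(isi_distribution(out, types),
                                      error = function(e) NULL) else NULL
  stats_all <- response_probability(sim$input_raster, out,
                                    response_window = an$response_window_ms)
  unpaired <- select_unpaired_spikes(sim$input_raster,
                                     an$isolation_window_ms)
  stats_unp <- response_probability(unpaired, out,
                                    response_window = an$response_window_ms,
                                    condition = "unpaired")
  phase <- efficacy <- NULL
  if (full && !empty && !is.null(spectrum) && !is.na(spectrum$dominant)) {
    rate1 <- population_rate(out, bin_width = 1)
    phase <- tryCatch(
      gamma_phase(rate1, band = c(max(spectrum$dominant - 10, 1),
                                  spectrum$dominant + 10)),
      error = function(e) NULL)
    if (!is.null(phase))
      efficacy <- phase_efficacy(unpaired, out, NULL, phase,
                                 n_bins = an$n_phase_bins,
                                 response_window = an$response_window_ms)
  }
  list(sim = sim, rate = rate, spectrum = spectrum, isi = isi,
       stats_all = stats_all, stats_unpaired = stats_unp,
       phase = phase, efficacy = efficacy)
}

condition_row <- function(cond, label, value, amplitude, seed, types) {
  sp <- cond$spectrum
  peaks <- if (!is.null(sp)) sp$peak_frequencies else NULL
  out <- cond$sim$output_raster
  dur_s <- out$duration / 1000
  rate_of <- function(ty) {
    n <- sum(types == ty)
    sum(types[out$id] == ty) / n / dur_s
  }
  data.frame(
    condition = label, value = value, amplitude = amplitude, seed = seed,
    dominant_Hz = if (!is.null(sp)) sp$dominant else NA_real_,
    classification = if (!is.null(sp)) sp$classification else "none",
    n_peaks = if (is.null(peaks)) 0L else nrow(peaks),
    rate_E = rate_of("E"), rate_I = rate_of("I"),
    response_probability = cond$stats_all$response_probability,
    response_delay_ms = cond$stats_all$response_delay,
    response_probability_unpaired = cond$stats_unpaired$response_probability,
    response_delay_unpaired_ms = cond$stats_unpaired$response_delay,
    max_efficacy = if (is.null(cond$efficacy)) NA_real_
                   else cond$efficacy$max_efficacy,
    peak_phase_deg = if (is.null(cond$efficacy)) NA_real_
                     else cond$efficacy$peak_phase,
    isi_sharpness_E = isi_sharp(cond$isi, "E"),
    isi_sharpness_I = isi_sharp(cond$isi, "I"))
}

isi_sharp <- function(isi, ty) {
  if (is.null(isi)) return(NA_real_)
  s <- isi$stats
  if (!ty %in% s$type) return(NA_real_)
  s$sharpness[s$type == ty]
}

set_gmax <- function(network, gmax) {
  network$feedforward_gmax <- gmax
  network
}

#' Calibrate the recurrent coupling weights
#'
#' Multiplicative coordinate search over the four coupling weights until the
#' static-drive spontaneous oscillation peak lies within `tolerance` of
#' `target_frequency` with the feedforward conductance at the low end of the
#' plasticity range, subject to the population-structure constraints
#' (inhibitory cells fire about once per gamma cycle, excitatory cells less
#' than once per cycle). Deterministic for fixed seeds.
#'
#' @param target_frequency target spontaneous peak, Hz (within 30-70).
#' @param base_config configuration supplying everything but the weights.
#' @param gmax feedforward conductance (uS/cm2) at which to calibrate.
#' @param duration run length per evaluation, s.
#' @param tolerance acceptable |peak - target|, Hz.
#' @param budget maximum number of simulation evaluations.
#' @param seed drive seed for the evaluation runs.
#' @param quiet suppress progress output.
#' @return list with `weights` (named vector, uS/cm2), `config` (base config
#'   with the weights installed), `achieved_Hz`, `report` (data frame of all
#'   evaluations). Raises an error with the best-found report attached if
#'   the budget is exhausted without meeting the tolerance.
#' @export
calibrate_weights <- function(target_frequency = 38,
                              base_config = default_config(),
                              gmax = 30, duration = 4, tolerance = 1,
                              budget = 60, seed = 1, quiet = TRUE) {
  if (target_frequency < 30 || target_frequency > 70)
    stop_config("target_frequency", "must lie within 30-70 Hz")
  cfg <- merge_config(default_config(), base_config)
  cfg$simulation$duration_s <- duration
  w <- c(EE = cfg$connectivity$weight_EE, EI = cfg$connectivity$weight_EI,
         IE = cfg$connectivity$weight_IE, II = cfg$connectivity$weight_II)
  report <- NULL
  evals <- 0

  eval_w <- function(w) {
    cfg$connectivity$weight_EE <- unname(w["EE"])
    cfg$connectivity$weight_EI <- unname(w["EI"])
    cfg$connectivity$weight_IE <- unname(w["IE"])
    cfg$connectivity$weight_II <- unname(w["II"])
    ob <- config_objects(cfg)
    net <- network_from_config(cfg, gmax = gmax)
    drive <- ob$drive
    drive$modulation_amplitude <- 0
    drive$seed <- as.integer(seed)
    cond <- run_condition(net, drive, ob$sim_config, ob$analysis)
    row <- condition_row(cond, "calibration", gmax, 0, seed, net$types)
    f <- row$dominant_Hz
    ratio_i <- if (is.na(f) || f <= 0) NA_real_ else row$rate_I / f
    ratio_e <- if (is.na(f) || f <= 0) NA_real_ else row$rate_E / f
    score <- if (is.na(f)) 1e3 else abs(f - target_frequency)
    if (!is.na(ratio_i))
      score <- score + 20 * max(0, 0.8 - ratio_i) + 20 * max(0, ratio_i - 1.2)
    if (!is.na(ratio_e)) score <- score + 20 * max(0, ratio_e - 1)
    evals <<- evals + 1
    report <<- rbind(report,
                     cbind(data.frame(eval = evals, t(w), score = score,
                                      ratio_I = ratio_i, ratio_E = ratio_e),
                           row[c("dominant_Hz", "classification",
                                 "rate_E", "rate_I")]))
    if (!quiet)
      message(sprintf(
        "eval %d: w=(%.3g,%.3g,%.3g,%.3g) f=%.1f Hz score=%.2f",
        evals, w[1], w[2], w[3], w[4],
        if (is.na(f)) NA else f, score))
    score
  }

  best <- eval_w(w)
  steps <- c(1.35, 1.15, 1.07)
  done <- function(s) s <= tolerance
  for (stepf in steps) {
    improved <- TRUE
    while (improved && evals < budget && !done(best)) {
      improved <- FALSE
      for (k in names(w)) {
        for (fac in c(stepf, 1 / stepf)) {
          if (evals >= budget || done(best)) break
          w2 <- w
          w2[k] <- w2[k] * fac
          s2 <- eval_w(w2)
          if (s2 < best - 1e-9) {
            best <- s2
            w <- w2
            improved <- TRUE
            break
          }
        }
      }
    }
    if (done(best)) break
  }

  ib <- which.min(report$score)
  w_best <- unlist(report[ib, c("EE", "EI", "IE", "II")])
  achieved <- report$dominant_Hz[ib]
  cfg$connectivity$weight_EE <- unname(w_best["EE"])
  cfg$connectivity$weight_EI <- unname(w_best["EI"])
  cfg$connectivity$weight_IE <- unname(w_best["IE"])
  cfg$connectivity$weight_II <- unname(w_best["II"])
  if (!done(report$score[ib])) {
    e <- simpleError(sprintf(
      "calibration failed: best |peak - target| score %.2f after %d evaluations",
      report$score[ib], evals))
    e$report <- report
    stop(e)
  }
  list(weights = w_best, config = cfg, achieved_Hz = achieved,
       report = report)
}

#' Spontaneous-frequency curve over the thalamocortical strength sweep
#'
#' Static drive only: for each feedforward `gmax` value, the dominant
#' spectral peak of the spontaneous population oscillation.
#'
#' @param gmax_values feedforward conductances, uS/cm2.
#' @param config configuration (calibrated weights).
#' @param seed drive seed.
#' @param duration run length, s (`NULL` keeps the configured value).
#' @param network optional prebuilt network (rebuilt from config otherwise).
#' @return data frame with `gmax`, `peak_frequency_Hz`, `rate_E`, `rate_I`;
#'   attribute `"monotone"` flags a non-decreasing curve.
#' @export
run_gmax_frequency_curve <- function(gmax_values = seq(30, 70, by = 5),
                                     config = default_config(), seed = 1,
                                     duration = NULL, network = NULL) {
  ob <- config_objects(config)
  if (!is.null(duration)) ob$sim_config$duration <- duration
  if (is.null(network)) network <- network_from_config(config)
  drive <- ob$drive
  drive$modulation_amplitude <- 0
  drive$seed <- as.integer(seed)
  rows <- lapply(gmax_values, function(g) {
    cond <- run_condition(set_gmax(network, g), drive, ob$sim_config,
                          ob$analysis, full = FALSE)
    condition_row(cond, "static", g, 0, seed, network$types)
  })
  tab <- do.call(rbind, rows)
  out <- data.frame(gmax = gmax_values, peak_frequency_Hz = tab$dominant_Hz,
                    rate_E = tab$rate_E, rate_I = tab$rate_I)
  attr(out, "monotone") <-
    !anyNA(out$peak_frequency_Hz) &&
    all(diff(out$peak_frequency_Hz) >= 0)
  out
}

#' Input-frequency sweep
#'
#' For each modulation frequency and amplitude (plus one static reference
#' per repeat) runs a simulation and the full analysis battery; enhancement
#' columns compare each oscillating condition with the matched static
#' reference.
#'
#' @param frequencies modulation frequencies, Hz.
#' @param amplitudes modulation amplitudes, spikes/s (10 = weak, 20 =
#'   strong).
#' @param config configuration (calibrated weights).
#' @param seeds one run per seed per condition.
#' @param duration run length, s (`NULL` keeps the configured value).
#' @param network optional prebuilt network.
#' @return data frame, one row per condition x seed, including the static
#'   rows (`amplitude == 0`).
#' @export
run_frequency_sweep <- function(frequencies = seq(25, 55, by = 5),
                                amplitudes = c(10, 20),
                                config = default_config(), seeds = 1,
                                duration = NULL, network = NULL) {
  ob <- config_objects(config)
  if (!is.null(duration)) ob$sim_config$duration <- duration
  if (is.null(network)) network <- network_from_config(config)
  rows <- list()
  for (sd in seeds) {
    drive0 <- ob$drive
    drive0$modulation_amplitude <- 0
    drive0$seed <- as.integer(sd)
    static <- run_condition(network, drive0, ob$sim_config, ob$analysis)
    srow <- condition_row(static, "static", NA_real_, 0, sd, network$types)
    srow$probability_enhancement <- 0
    srow$delay_decrement_ms <- 0
    rows[[length(rows) + 1]] <- srow
    for (a in amplitudes) {
      for (f in frequencies) {
        drv <- drive0
        drv$modulation_amplitude <- a
        drv$modulation_frequency <- f
        cond <- run_condition(network, drv, ob$sim_config, ob$analysis)
        row <- condition_row(cond, "oscillating", f, a, sd, network$types)
        enh <- response_enhancement(cond$stats_all, static$stats_all)
        row$probability_enhancement <- enh$probability_enhancement
        row$delay_decrement_ms <- enh$delay_decrement
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Resonance sweep over thalamocortical strength
#'
#' For each `gmax` simulates the static reference once (shared by all input
#' frequencies) plus one oscillating run per input frequency, and reports
#' probability enhancement and delay decrement relative to the matched
#' static run. The resonance point per input frequency is the `gmax`
#' maximizing the seed-averaged probability enhancement.
#'
#' @param input_frequencies modulation frequencies, Hz.
#' @param gmax_values feedforward conductances, uS/cm2.
#' @param amplitude modulation amplitude, spikes/s.
#' @param config configuration (calibrated weights).
#' @param seeds one run per seed per condition.
#' @param duration run length, s (`NULL` keeps the configured value).
#' @param network optional prebuilt network.
#' @return data frame of per-condition rows; attribute
#'   `"resonance_points"` holds a data frame `(f_in, gmax)` of argmax
#'   enhancements.
#' @export
run_gmax_resonance_sweep <- function(input_frequencies = c(40, 45, 50),
                                     gmax_values = seq(30, 70, by = 5),
                                     amplitude = 20,
                                     config = default_config(), seeds = 1,
                                     duration = NULL, network = NULL) {
  ob <- config_objects(config)
  if (!is.null(duration)) ob$sim_config$duration <- duration
  if (is.null(network)) network <- network_from_config(config)
  rows <- list()
  for (sd in seeds) {
    for (g in gmax_values) {
      net_g <- set_gmax(network, g)
      drive0 <- ob$drive
      drive0$modulation_amplitude <- 0
      drive0$seed <- as.integer(sd)
      static <- run_condition(net_g, drive0, ob$sim_config, ob$analysis,
                              full = FALSE)
      srow <- condition_row(static, "static", g, 0, sd, network$types)
      srow$f_in <- NA_real_
      srow$probability_enhancement <- 0
      srow$delay_decrement_ms <- 0
      rows[[length(rows) + 1]] <- srow
      for (f in input_frequencies) {
        drv <- drive0
        drv$modulation_amplitude <- amplitude
        drv$modulation_frequency <- f
        cond <- run_condition(net_g, drv, ob$sim_config, ob$analysis,
                              full = FALSE)
        row <- condition_row(cond, "oscillating", g, amplitude, sd,
                             network$types)
        row$f_in <- f
        enh <- response_enhancement(cond$stats_all, static$stats_all)
        row$probability_enhancement <- enh$probability_enhancement
        row$delay_decrement_ms <- enh$delay_decrement
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  osc <- tab[tab$condition == "oscillating", ]
  rp <- do.call(rbind, lapply(split(osc, osc$f_in), function(d) {
    m <- tapply(d$probability_enhancement, d$value, mean)
    data.frame(f_in = d$f_in[1], gmax = as.numeric(names(which.max(m))))
  }))
  rownames(rp) <- NULL
  attr(tab, "resonance_points") <- rp
  tab
}

#' Reduced-scale fixture network
#'
#' Keeps the 1 x 1 mm sheet and the connection geometry but reduces neuron
#' density to `scale_factor` times the default, rescaling the recurrent
#' weights by the inverse neuron-count ratio so the expected per-neuron
#' recurrent drive is conserved. Intended for fast tests.
#'
#' @param scale_factor fraction of the default neuron count, in (0, 1].
#' @param config base configuration.
#' @return list with `network` and the adjusted `config`.
#' @export
make_fixture_network <- function(scale_factor = 0.25,
                                 config = default_config()) {
  if (!is.numeric(scale_factor) || scale_factor <= 0 || scale_factor > 1)
    stop_config("scale_factor", "must lie in (0, 1]")
  cfg <- merge_config(default_config(), config)
  n_full <- cfg$network$neuron_count
  n_fix <- max(20L, as.integer(round(n_full * scale_factor)))
  ratio <- n_full / n_fix
  cfg$network$neuron_count <- n_fix
  for (k in c("weight_EE", "weight_EI", "weight_IE", "weight_II"))
    cfg$connectivity[[k]] <- cfg$connectivity[[k]] * ratio
  list(network = network_from_config(cfg), config = cfg)
}
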