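# Spike-train analysis battery: population rate, power spectra and peak
# classification, ISI distributions, normalized correlograms, response
# probability/delay, unpaired-spike selection, gamma phase, phase efficacy.

#' Population firing rate time series
#'
#' @param raster a [spike_raster()].
#' @param bin_width bin width, ms.
#' @param types optional per-neuron type labels (`"E"`/`"I"`) of the full
#'   population, used with `type_filter`.
#' @param type_filter restrict to one population (`"E"` or `"I"`).
#' @return an object of class `"rate_series"`: `time` (bin centers, ms),
#'   `rate` (spikes/s per neuron), `bin_width`, `n_neurons`.
#' @export
population_rate <- function(raster, bin_width = 2, types = NULL,
                            type_filter = NULL) {
  check_num(bin_width, "bin_width", lower = 1e-9)
  tm <- raster$time
  n_neurons <- raster$population_size
  if (!is.null(type_filter)) {
    if (is.null(types))
      stop("type_filter requires per-neuron types", call. = FALSE)
    sel <- types[raster$id] == type_filter
    tm <- tm[sel]
    n_neurons <- sum(types == type_filter)
  }
  nb <- max(1L, floor(raster$duration / bin_width))
  counts <- tabulate(pmin.int(floor(tm / bin_width) + 1L, nb), nbins = nb)
  structure(list(time = (seq_len(nb) - 0.5) * bin_width,
                 rate = counts / (bin_width / 1000) / n_neurons,
                 bin_width = bin_width, n_neurons = n_neurons),
            class = "rate_series")
}

as_rate_series <- function(x, bin_width) {
  if (inherits(x, "rate_series")) return(x)
  if (is.null(bin_width))
    stop("bin_width is required for a plain numeric series", call. = FALSE)
  structure(list(time = (seq_along(x) - 0.5) * bin_width,
                 rate = as.numeric(x), bin_width = bin_width,
                 n_neurons = NA_integer_),
            class = "rate_series")
}

#' Averaged-periodogram power spectrum of a rate series
#'
#' Welch estimate: Hann-windowed, mean-subtracted segments with overlap.
#' Peaks are detected in the gamma-band search range and attached.
#'
#' @param x a [population_rate()] result or plain numeric series.
#' @param segment_length segment length, ms.
#' @param overlap fractional overlap between segments.
#' @param bin_width sample spacing in ms, required when `x` is numeric.
#' @param band frequency range (Hz) searched for oscillation peaks.
#' @param baseline_factor peak threshold as a multiple of the spectral
#'   baseline (see [detect_oscillation_peaks()]).
#' @return class `"power_spectrum"`: `frequencies` (Hz), `power`,
#'   `peak_frequencies` (data frame, sorted by prominence), `dominant`
#'   (Hz, `NA` if no peak), `classification`.
#' @export
power_spectrum <- function(x, segment_length = 2000, overlap = 0.5,
                           bin_width = NULL, band = c(20, 130),
                           baseline_factor = 3) {
  rs <- as_rate_series(x, bin_width)
  dtms <- rs$bin_width
  nper <- floor(segment_length / dtms)
  nx <- length(rs$rate)
  if (nper < 8 || nper > nx)
    stop("series shorter than one segment", call. = FALSE)
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, nx - nper + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  u <- sum(win^2)
  fs <- 1000 / dtms
  nf <- nper %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- rs$rate[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nf + 1L)]
  }
  power <- acc / length(starts)
  freqs <- (0:nf) * fs / nper
  sp <- structure(list(frequencies = freqs, power = power,
                       n_segments = length(starts)),
                  class = "power_spectrum")
  pk <- detect_oscillation_peaks(sp, baseline_factor = baseline_factor,
                                 band = band)
  sp$peak_frequencies <- pk$peaks
  sp$dominant <- pk$dominant
  sp$classification <- pk$classification
  sp
}

#' Detect oscillation peaks and classify the resonance condition
#'
#' Local spectral maxima within `band` count as oscillation peaks when their
#' power exceeds `baseline_factor` times the local spectral baseline (a
#' ~20 Hz running median, robust to the peaks themselves). The condition
#' is `"coexisting"` (two or more peaks: independent spontaneous and driven
#' oscillations), `"resonant"` (a single peak), or `"none"`.
#'
#' @param spectrum a `"power_spectrum"` object.
#' @param baseline_factor detection threshold multiplier.
#' @param band search range, Hz.
#' @param min_separation maxima closer than this (Hz) are merged, keeping
#'   the stronger (suppresses the spectral skirt of a strong peak).
#' @param harmonic_tol peaks within this distance (Hz) of an integer
#'   multiple of a stronger peak are discarded as harmonics.
#' @param rel_floor secondary peaks weaker than this fraction of the
#'   strongest peak are discarded as noise bumps.
#' @return list with `peaks` (data frame: `frequency`, `power`,
#'   `prominence`, sorted by prominence), `dominant` (Hz), `baseline`,
#'   `classification`.
#' @export
detect_oscillation_peaks <- function(spectrum, baseline_factor = 3,
                                     band = c(20, 130), min_separation = 5,
                                     harmonic_tol = 5, rel_floor = 0.02) {
  f <- spectrum$frequencies
  p <- spectrum$power
  inb <- which(f >= band[1] & f <= band[2])
  if (length(inb) < 5)
    stop("band contains too few frequency bins", call. = FALSE)
  fb <- f[inb]
  # light smoothing stabilizes single-bin noise peaks
  pb <- p[inb]
  if (length(pb) > 4)
    pb <- stats::filter(pb, rep(1 / 3, 3), sides = 2) |> as.numeric()
  pb[is.na(pb)] <- p[inb][is.na(pb)]

  i_max <- which(diff(sign(diff(c(-Inf, pb, -Inf)))) < 0)
  # merge maxima closer than min_separation
  if (length(i_max) > 1) {
    o <- i_max[order(pb[i_max], decreasing = TRUE)]
    kept <- integer()
    for (i in o)
      if (!length(kept) || all(abs(fb[i] - fb[kept]) >= min_separation))
        kept <- c(kept, i)
    i_max <- sort(kept)
  }
  # local spectral baseline: running median over ~20 Hz, robust against the
  # peaks themselves and against the sloping floor of a periodic process
  df <- if (length(fb) > 1) fb[2] - fb[1] else 1
  kmed <- min(max(2 * floor(10 / df) + 1, 3), length(pb))
  if (kmed %% 2 == 0) kmed <- kmed - 1
  base_loc <- stats::runmed(pb, kmed)
  base_loc <- pmax(base_loc, 1e-12 * max(pb))
  baseline <- median(base_loc)
  sel <- i_max[pb[i_max] > baseline_factor * base_loc[i_max]]
  peaks <- data.frame(frequency = fb[sel], power = pb[sel],
                      prominence = pb[sel] / base_loc[sel])
  peaks <- peaks[order(-peaks$power), , drop = FALSE]
  # drop harmonics of stronger peaks
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 1) {
    for (i in 2:nrow(peaks)) {
      f_str <- peaks$frequency[seq_len(i - 1)][keep[seq_len(i - 1)]]
      for (fs in f_str) {
        k <- round(peaks$frequency[i] / fs)
        if (k >= 2 && abs(peaks$frequency[i] - k * fs) <= harmonic_tol)
          keep[i] <- FALSE
      }
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  if (nrow(peaks) > 1)
    peaks <- peaks[peaks$power >= rel_floor * max(peaks$power), ,
                   drop = FALSE]
  peaks <- peaks[order(-peaks$prominence), , drop = FALSE]
  rownames(peaks) <- NULL
  classification <- if (nrow(peaks) >= 2) "coexisting"
                    else if (nrow(peaks) == 1) "resonant" else "none"
  dominant <- if (nrow(peaks)) peaks$frequency[1] else NA_real_
  list(peaks = peaks, dominant = dominant, baseline = baseline,
       classification = classification)
}

#' Inter-spike interval distribution
#'
#' ISIs are computed per neuron and pooled within population type. The
#' sharpness of a distribution is the inverse coefficient of variation,
#' capped at 100 for (near-)periodic trains.
#'
#' @param raster a [spike_raster()].
#' @param types optional per-neuron type labels; if omitted, all neurons are
#'   pooled under type `"all"`.
#' @param bin_width histogram bin width, ms.
#' @param max_isi histogram upper edge, ms.
#' @return class `"isi_histogram"`: `bin_edges`, per-type `counts`, and a
#'   per-type data frame `stats` with `n`, `mean_ms`, `cv`, `sharpness`.
#' @export
isi_distribution <- function(raster, types = NULL, bin_width = 1,
                             max_isi = 100) {
  if (length(raster$time) < 2)
    stop("raster must contain at least two spikes", call. = FALSE)
  grp <- if (is.null(types)) rep("all", raster$population_size) else types
  o <- order(raster$id, raster$time)
  id <- raster$id[o]; tm <- raster$time[o]
  d <- diff(tm)
  same <- diff(id) == 0L
  isi <- d[same]
  isi_type <- grp[id[-1][same]]
  edges <- seq(0, max_isi, by = bin_width)
  utypes <- sort(unique(grp))
  counts <- sapply(utypes, function(ty) {
    v <- isi[isi_type == ty]
    tabulate(pmin.int(floor(v / bin_width) + 1L, length(edges) - 1L),
             nbins = length(edges) - 1L)
  })
  counts <- matrix(counts, ncol = length(utypes),
                   dimnames = list(NULL, utypes))
  stats <- do.call(rbind, lapply(utypes, function(ty) {
    v <- isi[isi_type == ty]
    cv <- if (length(v) > 1 && mean(v) > 0) sd(v) / mean(v) else NA_real_
    data.frame(type = ty, n = length(v),
               mean_ms = if (length(v)) mean(v) else NA_real_,
               cv = cv,
               sharpness = if (is.na(cv)) NA_real_
                           else min(1 / max(cv, 1e-12), 100))
  }))
  structure(list(bin_edges = edges, counts = counts, stats = stats),
            class = "isi_histogram")
}

#' Normalized spike correlogram
#'
#' Cross-neuron coincidence counts versus lag, divided by the expectation
#' under independent homogeneous trains of the same rates, so that
#' uncorrelated activity has baseline 1. When the two rasters describe the
#' same population (same `population_size`), same-neuron pairs are excluded.
#'
#' @param raster_a,raster_b [spike_raster()] objects of equal duration.
#' @param max_lag maximum lag, ms.
#' @param bin lag bin width, ms.
#' @return class `"correlogram"`: `lags` (bin centers, ms),
#'   `normalized_coincidence`.
#' @export
spike_correlogram <- function(raster_a, raster_b, max_lag = 50, bin = 1) {
  if (!length(raster_a$time) || !length(raster_b$time))
    stop("rasters must be nonempty", call. = FALSE)
  Tms <- min(raster_a$duration, raster_b$duration)
  nb <- floor(Tms / bin)
  L <- floor(max_lag / bin)
  binned <- function(r) tabulate(
    pmin.int(floor(r$time[r$time < nb * bin] / bin) + 1L, nb), nbins = nb)
  sa <- binned(raster_a)
  sb <- binned(raster_b)
  # cross-correlation via FFT with zero padding
  npad <- stats::nextn(nb + L + 1L, 2)
  fa <- fft(c(sa, numeric(npad - nb)))
  fb <- fft(c(sb, numeric(npad - nb)))
  cc_all <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / npad
  # cc_all[1 + k mod npad] = sum_t sa(t) sb(t + k)
  lag_idx <- c(npad + 1 - (L:1), 1, 1 + seq_len(L))
  cc <- cc_all[lag_idx]

  shared <- raster_a$population_size == raster_b$population_size
  same <- numeric(2 * L + 1)
  S <- 0
  if (shared) {
    cut_a <- raster_a$time < nb * bin
    cut_b <- raster_b$time < nb * bin
    ta <- split(floor(raster_a$time[cut_a] / bin), raster_a$id[cut_a])
    tb <- split(floor(raster_b$time[cut_b] / bin), raster_b$id[cut_b])
    for (idc in intersect(names(ta), names(tb))) {
      va <- ta[[idc]]; vb <- sort(tb[[idc]])
      S <- S + length(va) * length(vb)
      lo <- findInterval(va - L - 0.5, vb)
      hi <- findInterval(va + L + 0.5, vb)
      cnt <- hi - lo
      pos <- cnt > 0
      if (!any(pos)) next
      idx <- sequence(cnt[pos], from = lo[pos] + 1L)
      dd <- vb[idx] - rep(va[pos], cnt[pos])  # lag in bins
      same <- same + tabulate(dd + L + 1L, nbins = 2 * L + 1)
    }
  }
  na <- sum(sa)
  nbt <- sum(sb)
  lags_bins <- (-L):L
  expected <- (as.double(na) * nbt - S) * bin *
    pmax(Tms - abs(lags_bins) * bin, 0) / Tms^2
  norm <- (cc - same) / expected
  norm[!is.finite(norm)] <- NA_real_
  structure(list(lags = lags_bins * bin, normalized_coincidence = norm),
            class = "correlogram")
}

#' Select temporally unpaired input spikes
#'
#' Retains exactly those spikes with no other spike of the same neuron
#' within `isolation_window` ms before or after; used to remove input
#' autocorrelation confounds from response measurements. Idempotent.
#'
#' @param input_raster a [spike_raster()].
#' @param isolation_window half-width of the isolation window, ms.
#' @return a [spike_raster()] containing the retained spikes.
#' @export
select_unpaired_spikes <- function(input_raster, isolation_window = 20) {
  check_num(isolation_window, "isolation_window", lower = 1e-9)
  o <- order(input_raster$id, input_raster$time)
  id <- input_raster$id[o]; tm <- input_raster$time[o]
  n <- length(tm)
  if (!n) return(input_raster)
  gap_prev <- c(Inf, tm[-1] - tm[-n])
  gap_prev[c(TRUE, id[-1] != id[-n])] <- Inf
  gap_next <- c(gap_prev[-1], Inf)
  gap_next[c(id[-1] != id[-n], TRUE)] <- Inf
  keep <- gap_prev > isolation_window & gap_next > isolation_window
  spike_raster(id[keep], tm[keep], input_raster$population_size,
               input_raster$duration)
}

respond_latency <- function(input_raster, output_raster, afferent_map,
                            response_window) {
  n_in <- input_raster$population_size
  if (is.null(afferent_map)) afferent_map <- seq_len(n_in)
  out_by <- split(output_raster$time, output_raster$id)
  lat <- rep(NA_real_, length(input_raster$time))
  o <- order(input_raster$id)
  idx_by <- split(seq_along(input_raster$id)[o], input_raster$id[o])
  for (idc in names(idx_by)) {
    tgt <- as.character(afferent_map[as.integer(idc)])
    to <- out_by[[tgt]]
    if (is.null(to)) next
    ii <- idx_by[[idc]]
    ti <- input_raster$time[ii]
    pos <- findInterval(ti, to)
    nxt <- ifelse(pos + 1 <= length(to), to[pmin(pos + 1, length(to))],
                  NA_real_)
    l <- nxt - ti
    l[is.na(l) | l <= 0 | l > response_window] <- NA_real_
    lat[ii] <- l
  }
  lat
}

#' Response probability and delay
#'
#' Fraction of input spikes followed by at least one output spike of the
#' target neuron within `(0, response_window]` ms, and the mean latency to
#' that first output spike. With no responses the delay is reported as `NA`,
#' never 0.
#'
#' @param input_raster,output_raster [spike_raster()] objects.
#' @param afferent_map integer vector mapping input train id to target
#'   neuron id; `NULL` for the identity (afferent i drives neuron i).
#' @param response_window response window, ms.
#' @param condition label stored in the result (e.g. `"all"`, `"unpaired"`).
#' @return class `"response_stats"`: `response_probability`,
#'   `response_delay` (ms), `n_input_spikes`, `condition`.
#' @export
response_probability <- function(input_raster, output_raster,
                                 afferent_map = NULL, response_window = 10,
                                 condition = "all") {
  check_num(response_window, "response_window", lower = 1e-9)
  lat <- respond_latency(input_raster, output_raster, afferent_map,
                         response_window)
  n <- length(lat)
  resp <- !is.na(lat)
  structure(list(
    response_probability = if (n) mean(resp) else NA_real_,
    response_delay = if (any(resp)) mean(lat[resp]) else NA_real_,
    n_input_spikes = n, condition = condition),
    class = "response_stats")
}

#' Response enhancement relative to static drive
#'
#' @param stats_condition,stats_static [response_probability()] results from
#'   matched networks and durations.
#' @return list with `probability_enhancement` (condition minus static) and
#'   `delay_decrement` (static minus condition, ms; negative values mean the
#'   delay increased).
#' @export
response_enhancement <- function(stats_condition, stats_static) {
  list(probability_enhancement =
         stats_condition$response_probability -
         stats_static$response_probability,
       delay_decrement =
         stats_static$response_delay - stats_condition$response_delay)
}

#' Instantaneous gamma phase of the population rate
#'
#' Band-passes the rate series around the dominant oscillation (second-order
#' Butterworth, zero-phase), takes the analytic-signal phase, and rotates it
#' so that oscillation cycle maxima map to 0 degrees. Phase is negative on
#' the rising flank before a population-rate peak.
#'
#' @param rate_series a [population_rate()] result.
#' @param band two-element band (Hz); `NULL` selects the dominant spectral
#'   peak +/- 10 Hz.
#' @return class `"phase_series"`: `time` (ms), `phase` (degrees in
#'   (-180, 180]), `unwrapped` (degrees), `filtered`, `band`.
#' @export
gamma_phase <- function(rate_series, band = NULL) {
  x <- rate_series$rate - mean(rate_series$rate)
  fs <- 1000 / rate_series$bin_width
  if (is.null(band)) {
    sp <- power_spectrum(rate_series,
                         segment_length = min(2000, rate_series$bin_width *
                                                length(x) / 2))
    f0 <- sp$dominant
    if (is.na(f0)) f0 <- sp$frequencies[which.max(
      sp$power * (sp$frequencies >= 20 & sp$frequencies <= 130))]
    band <- c(max(f0 - 10, 1), min(f0 + 10, fs / 2 * 0.95))
  }
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie within the spectral support", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  # analytic signal via FFT
  n <- length(xf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  xa <- fft(fft(xf) * h, inverse = TRUE) / n
  ph <- Arg(xa)  # radians, 0 at cycle maxima of the band-passed signal
  # anchor: rotate so detected cycle maxima sit exactly at 0 degrees
  pk <- which(diff(sign(diff(xf))) < 0) + 1L
  pk <- pk[xf[pk] > 0]
  if (length(pk) >= 3) {
    offset <- Arg(mean(exp(1i * ph[pk])))
    ph <- ph - offset
  }
  unwrapped <- cumsum(c(ph[1], wrap_pi(diff(ph)))) * 180 / pi
  structure(list(time = rate_series$time,
                 phase = wrap_deg(unwrapped),
                 unwrapped = unwrapped,
                 filtered = xf, band = band),
            class = "phase_series")
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

# wrap degrees into (-180, 180]
wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

phase_at_times <- function(phase_series, times) {
  u <- approx(phase_series$time, phase_series$unwrapped, xout = times,
              rule = 2)$y
  wrap_deg(u)
}

#' Phase-binned efficacy of unpaired input spikes
#'
#' The efficacy of an input spike is its relative probability of evoking a
#' cortical spike, measured as a function of the gamma phase at which it
#' arrives. Per-bin response probabilities are normalized by their
#' spike-count-weighted mean, which is exactly 1 by construction; efficacy
#' above 1 marks the pass band of the gamma cycle, below 1 the block band.
#'
#' @param unpaired_inputs a [select_unpaired_spikes()] raster.
#' @param output_raster the simulation output raster.
#' @param afferent_map as in [response_probability()].
#' @param phase_series a [gamma_phase()] result on the same time base.
#' @param n_bins number of phase bins covering (-180, 180] (>= 8).
#' @param response_window response window, ms.
#' @return class `"phase_efficacy_curve"`: `phase_bin_centers` (degrees),
#'   `normalized_efficacy`, `n_spikes`, `max_efficacy`, `peak_phase`.
#' @export
phase_efficacy <- function(unpaired_inputs, output_raster,
                           afferent_map = NULL, phase_series,
                           n_bins = 12, response_window = 10) {
  if (n_bins < 8) stop_config("n_bins", "must be >= 8")
  lat <- respond_latency(unpaired_inputs, output_raster, afferent_map,
                         response_window)
  resp <- !is.na(lat)
  ph <- phase_at_times(phase_series, unpaired_inputs$time)
  edges <- seq(-180, 180, length.out = n_bins + 1)
  bin <- pmin.int(pmax.int(findInterval(ph, edges, left.open = TRUE), 1L),
                  n_bins)
  n_b <- tabulate(bin, nbins = n_bins)
  r_b <- tabulate(bin[resp], nbins = n_bins)
  p_tot <- sum(r_b) / sum(n_b)
  eff <- ifelse(n_b > 0, (r_b / pmax(n_b, 1)) / p_tot, NA_real_)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  imax <- which.max(eff)
  structure(list(phase_bin_centers = centers, normalized_efficacy = eff,
                 n_spikes = n_b,
                 max_efficacy = eff[imax], peak_phase = centers[imax]),
            class = "phase_efficacy_curve")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.3g-%.4g Hz, %d segment(s)\n",
              length(x$frequencies), min(x$frequencies),
              max(x$frequencies), x$n_segments))
  if (!is.null(x$classification))
    cat(sprintf("  %s; dominant peak %s Hz\n", x$classification,
                format(x$dominant)))
  invisible(x)
}

#' @export
print.response_stats <- function(x, ...) {
  cat(sprintf(
    "<response_stats> [%s] P(response) = %.4f, delay = %s ms (n = %d)\n",
    x$condition, x$response_probability,
    ifelse(is.na(x$response_delay), "NA",
           sprintf("%.2f", x$response_delay)), x$n_input_spikes))
  invisible(x)
}

#' @export
print.phase_efficacy_curve <- function(x, ...) {
  cat(sprintf(
    "<phase_efficacy_curve> %d bins; max efficacy %.3g at %g deg\n",
    length(x$phase_bin_centers), x$max_efficacy, x$peak_phase))
  invisible(x)
}
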