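# Thalamocortical drive: independent inhomogeneous Poisson spike trains with
# a shared (possibly sinusoidally modulated) rate function, one afferent per
# cortical neuron.

#' Feedforward drive specification
#'
#' Rate function `r(t) = mean_rate + modulation_amplitude *
#' sin(2*pi*modulation_frequency*t + phase)` shared by all afferents.
#'
#' @param mean_rate mean input firing rate, spikes/s.
#' @param modulation_amplitude sinusoidal modulation amplitude, spikes/s;
#'   0 gives static drive. Must not exceed `mean_rate`.
#' @param modulation_frequency modulation frequency, Hz.
#' @param modulation_phase phase offset, degrees.
#' @param duration drive duration, s.
#' @param seed integer seed; each afferent uses an independent substream
#'   derived from `(seed, neuron id)`.
#' @return an object of class `"drive_spec"`.
#' @export
drive_spec <- function(mean_rate = 40, modulation_amplitude = 0,
                       modulation_frequency = 38, modulation_phase = 0,
                       duration = 10, seed = 1) {
  check_num(mean_rate, "mean_rate", lower = 0)
  check_num(modulation_amplitude, "modulation_amplitude", lower = 0)
  if (modulation_amplitude > mean_rate)
    stop_config("modulation_amplitude",
                "must not exceed mean_rate (rate would go negative)")
  check_num(modulation_frequency, "modulation_frequency", lower = 0)
  check_num(modulation_phase, "modulation_phase")
  check_num(duration, "duration", lower = 1e-9)
  structure(list(mean_rate = mean_rate,
                 modulation_amplitude = modulation_amplitude,
                 modulation_frequency = modulation_frequency,
                 modulation_phase = modulation_phase,
                 duration = duration, seed = as.integer(seed)),
            class = "drive_spec")
}

#' Instantaneous drive rate
#'
#' @param t time, seconds (vectorized).
#' @param drive a [drive_spec()].
#' @return rate(s) in spikes/s.
#' @export
instantaneous_rate <- function(t, drive) {
  drive$mean_rate + drive$modulation_amplitude *
    sin(2 * pi * drive$modulation_frequency * t +
          drive$modulation_phase * pi / 180)
}

#' Spike raster container
#'
#' @param id integer neuron ids (1-based).
#' @param time spike times, ms.
#' @param population_size number of neurons the raster refers to.
#' @param duration raster duration, ms.
#' @return an object of class `"spike_raster"` with a time-sorted stable
#'   event order.
#' @export
spike_raster <- function(id, time, population_size, duration) {
  if (length(id) != length(time))
    stop("id and time must have equal length", call. = FALSE)
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stop("spike times must lie in [0, duration]", call. = FALSE)
  if (length(id) && (min(id) < 1 || max(id) > population_size))
    stop("neuron ids must lie in [1, population_size]", call. = FALSE)
  o <- order(time, id)
  structure(list(id = as.integer(id[o]), time = as.numeric(time[o]),
                 population_size = as.integer(population_size),
                 duration = as.numeric(duration)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %d spikes, %d neurons, %.4g s (%.3g spikes/s/neuron)\n",
    length(x$time), x$population_size, x$duration / 1000,
    length(x$time) / x$population_size / (x$duration / 1000)))
  invisible(x)
}

# per-afferent substream seed, kept within the 32-bit integer range
afferent_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 69621) %% 2147483647)
}

#' Generate the thalamocortical Poisson raster
#'
#' One independent inhomogeneous Poisson train per neuron, sampled by
#' thinning: candidate spikes are drawn from a homogeneous process at the
#' peak rate and kept with probability `r(t) / r_max`, which is exact for
#' any modulation. Each afferent's stream depends only on
#' `(drive$seed, neuron id)`, so rasters are reproducible and extendable.
#'
#' @param drive a [drive_spec()].
#' @param population_size number of afferents (= cortical neurons).
#' @return a [spike_raster()] with times in ms.
#' @export
generate_poisson_raster <- function(drive, population_size) {
  stopifnot(inherits(drive, "drive_spec"))
  if (population_size < 1)
    stop_config("population_size", "must be >= 1")
  rmax <- drive$mean_rate + drive$modulation_amplitude
  Tsec <- drive$duration
  old <- local_seed(0L)
  on.exit(restore_seed(old))
  ids <- times <- vector("list", population_size)
  for (i in seq_len(population_size)) {
    set.seed(afferent_seed(drive$seed, i))
    n <- rpois(1, rmax * Tsec)
    if (n == 0) next
    tt <- runif(n, 0, Tsec)
    if (drive$modulation_amplitude > 0) {
      keep <- runif(n) < instantaneous_rate(tt, drive) / rmax
      tt <- tt[keep]
    }
    if (length(tt)) {
      ids[[i]] <- rep.int(i, length(tt))
      times[[i]] <- tt * 1000
    }
  }
  spike_raster(unlist(ids), unlist(times), population_size,
               drive$duration * 1000)
}

#' Flatness check of the input correlogram
#'
#' Computes the cross-neuron normalized correlogram of a raster over +/-50 ms
#' lags and returns its maximum absolute deviation from the independence
#' baseline of 1. For static Poisson drive the deviation is only sampling
#' noise; sinusoidally modulated drive produces a periodic correlogram.
#'
#' @param raster a [spike_raster()].
#' @param max_lag maximum lag, ms.
#' @param bin lag bin width, ms.
#' @return the maximum absolute deviation from 1; the full correlogram is
#'   attached as attribute `"correlogram"`.
#' @export
input_correlogram_check <- function(raster, max_lag = 50, bin = 1) {
  if (length(raster$time) < 2) {
    out <- 0
    attr(out, "correlogram") <- NULL
    return(out)
  }
  cg <- spike_correlogram(raster, raster, max_lag = max_lag, bin = bin)
  dev <- max(abs(cg$normalized_coincidence - 1))
  attr(dev, "correlogram") <- cg
  dev
}

#' Write / read a spike raster as a tab-separated table
#'
#' Two columns (`neuron_id`, `time_ms`) preceded by a `#`-prefixed header
#' block carrying the population size, duration and (for input rasters) the
#' drive specification.
#'
#' @param raster a [spike_raster()].
#' @param file path.
#' @param drive optional [drive_spec()] stored in the header.
#' @return `write_raster` returns `file` invisibly; `read_raster` returns a
#'   [spike_raster()] with any stored drive attached as attribute `"drive"`.
#' @export
write_raster <- function(raster, file, drive = NULL) {
  hdr <- c(sprintf("# population_size: %d", raster$population_size),
           sprintf("# duration_ms: %.10g", raster$duration))
  if (!is.null(drive))
    hdr <- c(hdr, sprintf("# drive_%s: %.10g",
                          c("mean_rate", "modulation_amplitude",
                            "modulation_frequency", "modulation_phase",
                            "duration", "seed"),
                          unlist(drive[1:6])))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(hdr, "neuron_id\ttime_ms"), con)
  if (length(raster$id))
    writeLines(sprintf("%d\t%.10g", raster$id, raster$time), con)
  invisible(file)
}

#' @rdname write_raster
#' @export
read_raster <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(sub(".*: *", "", ln[1]))
  }
  body <- lines[!grepl("^#", lines)][-1]  # drop column header
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    id <- as.integer(vapply(parts, `[`, "", 1L))
    tm <- as.numeric(vapply(parts, `[`, "", 2L))
  } else {
    id <- integer(); tm <- numeric()
  }
  r <- spike_raster(id, tm, get_hdr("population_size"), get_hdr("duration_ms"))
  if (!is.na(get_hdr("drive_mean_rate")))
    attr(r, "drive") <- drive_spec(
      mean_rate = get_hdr("drive_mean_rate"),
      modulation_amplitude = get_hdr("drive_modulation_amplitude"),
      modulation_frequency = get_hdr("drive_modulation_frequency"),
      modulation_phase = get_hdr("drive_modulation_phase"),
      duration = get_hdr("drive_duration"),
      seed = get_hdr("drive_seed"))
  r
}
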