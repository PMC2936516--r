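# Network construction: neuron placement, type assignment, and the
# distance-decayed recurrent weight matrix.

#' Spatial connection factor
#'
#' Dimensionless factor in `[0, 1]` by which a recurrent weight decays with
#' cortical distance. Decay length is indexed by the presynaptic population:
#' `decay_length_exc` for E sources, `decay_length_inh` for I sources.
#'
#' @param distance cortical distance, um (vectorized, must be >= 0).
#' @param source_type `"E"` or `"I"`.
#' @param connectivity a [connectivity_spec()].
#' @return numeric vector of factors; 1 at zero distance, strictly
#'   decreasing with distance.
#' @export
spatial_factor <- function(distance, source_type = c("E", "I"),
                           connectivity = connectivity_spec()) {
  source_type <- match.arg(source_type)
  if (any(distance < 0)) stop("distance must be non-negative", call. = FALSE)
  lambda <- if (source_type == "E") connectivity$decay_length_exc
            else connectivity$decay_length_inh
  switch(connectivity$spatial_form,
         exponential = exp(-distance / lambda),
         gaussian = exp(-(distance / lambda)^2))
}

#' Peak-normalized difference-of-exponentials synaptic kernel
#'
#' Conductance waveform `exp(-t/tau_decay) - exp(-t/tau_rise)` scaled so its
#' peak value is exactly 1. The kernel is zero at `t = 0` and peaks at
#' `tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param t time since the presynaptic spike, ms (vectorized, >= 0).
#' @param kernel a [kernel_parameters()].
#' @return kernel values (dimensionless, peak 1).
#' @export
synaptic_kernel <- function(t, kernel = kernel_parameters()) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  td <- kernel$decay_time_constant
  tr <- kernel$rise_time_constant
  (exp(-t / td) - exp(-t / tr)) / kernel_peak_value(td, tr)
}

kernel_peak_time <- function(td, tr) td * tr / (td - tr) * log(td / tr)

kernel_peak_value <- function(td, tr) {
  if (td <= tr) stop("degenerate kernel: decay must exceed rise",
                     call. = FALSE)
  ts <- kernel_peak_time(td, tr)
  exp(-ts / td) - exp(-ts / tr)
}

#' Build the model cortical network
#'
#' Places neurons on a jittered regular grid filling the sheet, assigns E/I
#' type labels by a seeded shuffle hitting the excitatory fraction to the
#' nearest neuron, and computes the dense recurrent weight matrix
#' `W[target, source] = weight[target_type, source_type] *
#' spatial_factor(distance, source_type)`, zero on the diagonal and beyond
#' the cutoff radius.
#'
#' @param geometry a [network_geometry()].
#' @param connectivity a [connectivity_spec()].
#' @param neuron_params an [neuron_parameters()] object shared by all cells.
#' @param kernels list with elements `E`, `I`, `F`: [kernel_parameters()]
#'   for recurrent excitatory, recurrent inhibitory and feedforward synapses.
#' @param feedforward_gmax peak excitatory conductance (uS/cm2) evoked by one
#'   thalamocortical input spike; the synaptic-plasticity knob of the model.
#' @param seed integer seed for placement jitter and type shuffling.
#' @return an object of class `"cortical_network"` with fields `geometry`,
#'   `positions` (um), `types` (`"E"`/`"I"`), `W` (uS/cm2, target x source),
#'   `connectivity`, `neuron_params`, `kernels`, `feedforward_gmax`, `seed`.
#' @export
build_network <- function(geometry = network_geometry(),
                          connectivity = connectivity_spec(),
                          neuron_params = neuron_parameters(),
                          kernels = default_kernels(),
                          feedforward_gmax = 30,
                          seed = 0) {
  stopifnot(inherits(geometry, "network_geometry"),
            inherits(connectivity, "connectivity_spec"),
            inherits(neuron_params, "hh_parameters"))
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0)
    stop_config("seed", "must be a non-negative integer")
  check_num(feedforward_gmax, "feedforward_gmax", lower = 0)

  n <- geometry$neuron_count
  wx <- geometry$sheet_width * 1000   # um
  wy <- geometry$sheet_height * 1000

  # jittered grid with exactly n cells; surplus grid cells dropped evenly
  nx <- ceiling(sqrt(n * wx / wy))
  ny <- ceiling(n / nx)
  px <- wx / nx
  py <- wy / ny
  gx <- rep(seq_len(nx) - 0.5, times = ny) * px
  gy <- rep(seq_len(ny) - 0.5, each = nx) * py
  keep <- round(seq(1, nx * ny, length.out = n))
  gx <- gx[keep]; gy <- gy[keep]

  old <- local_seed(as.integer(seed))
  on.exit(restore_seed(old))
  j <- geometry$placement_jitter
  x <- gx + runif(n, -j, j) * px
  y <- gy + runif(n, -j, j) * py
  x <- pmin(pmax(x, 0), wx)
  y <- pmin(pmax(y, 0), wy)

  n_e <- round(n * geometry$excitatory_fraction)
  types <- rep("I", n)
  types[sample.int(n, n_e)] <- "E"

  W <- weight_matrix(x, y, types, connectivity)

  structure(list(geometry = geometry, positions = cbind(x = x, y = y),
                 types = types, W = W, connectivity = connectivity,
                 neuron_params = neuron_params, kernels = kernels,
                 feedforward_gmax = feedforward_gmax, seed = as.integer(seed)),
            class = "cortical_network")
}

# dense target x source weight matrix in uS/cm2
weight_matrix <- function(x, y, types, cs) {
  n <- length(x)
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  is_i <- types == "I"
  lambda <- ifelse(is_i, cs$decay_length_inh, cs$decay_length_exc)
  # spatial factor, decay length by source (column)
  sf <- if (cs$spatial_form == "exponential") {
    exp(-sweep(d, 2, lambda, "/"))
  } else {
    exp(-sweep(d, 2, lambda, "/")^2)
  }
  sf[d > cs$connection_radius_cutoff] <- 0
  wblock <- matrix(c(cs$weight_EE, cs$weight_IE, cs$weight_EI, cs$weight_II),
                   2, 2, dimnames = list(c("E", "I"), c("E", "I")))
  wpair <- wblock[cbind(rep(match(types, c("E", "I")), n),
                        rep(match(types, c("E", "I")), each = n))]
  W <- sf * matrix(wpair, n, n)
  diag(W) <- 0
  W
}

#' Default synaptic kernel set
#'
#' Recurrent excitatory (3, 1) ms, recurrent inhibitory (7, 1) ms, and a
#' feedforward kernel sharing the excitatory shape.
#' @return list with elements `E`, `I`, `F`.
#' @export
default_kernels <- function() {
  list(E = kernel_parameters(3, 1, "E"),
       I = kernel_parameters(7, 1, "I"),
       F = kernel_parameters(3, 1, "E"))
}

#' @export
print.cortical_network <- function(x, ...) {
  n <- x$geometry$neuron_count
  cat(sprintf("<cortical_network> %d neurons (%d E / %d I) on %.2g x %.2g mm\n",
              n, sum(x$types == "E"), sum(x$types == "I"),
              x$geometry$sheet_width, x$geometry$sheet_height))
  cat(sprintf("  recurrent synapses: %d; feedforward gmax %.3g uS/cm2\n",
              sum(x$W > 0), x$feedforward_gmax))
  invisible(x)
}

#' Export the connectivity as a three-column table
#'
#' @param network a `"cortical_network"`.
#' @param file optional path to write a CSV; if `NULL` the data frame is
#'   returned only.
#' @return data frame with columns `source`, `target`, `weight` (uS/cm2),
#'   nonzero weights only.
#' @export
connectivity_table <- function(network, file = NULL) {
  idx <- which(network$W != 0, arr.ind = TRUE)
  out <- data.frame(source = idx[, 2], target = idx[, 1],
                    weight = network$W[idx])
  out <- out[order(out$source, out$target), ]
  rownames(out) <- NULL
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Hodgkin-Huxley gating rates
#'
#' Classic squid-axon alpha/beta rate functions (1/ms) evaluated at
#' `V - gate_shift`, as used by the integrator.
#'
#' @param V membrane potential(s), mV.
#' @param params an [neuron_parameters()].
#' @return matrix with columns `am, bm, ah, bh, an, bn`.
#' @export
hh_rates <- function(V, params = neuron_parameters()) {
  hh_rates_cpp(as.numeric(V), params$gate_shift)
}

hh_steady_gates <- function(V, params = neuron_parameters()) {
  r <- hh_rates(V, params)
  cbind(m = r[, "am"] / (r[, "am"] + r[, "bm"]),
        h = r[, "ah"] / (r[, "ah"] + r[, "bh"]),
        n = r[, "an"] / (r[, "an"] + r[, "bn"]))
}

#' Membrane right-hand side
#'
#' Time derivatives of the membrane potential and gating variables for given
#' synaptic conductances; the analytic form integrated by the simulation
#' engine, exposed for inspection and testing.
#'
#' @param state list with numeric vectors `V` (mV), `m`, `h`, `n`.
#' @param params an [neuron_parameters()].
#' @param g_exc,g_inh excitatory / inhibitory synaptic conductance, S/cm2
#'   (vectors recycled against `V`).
#' @return list with `dV` (mV/ms), `dm`, `dh`, `dn` (1/ms).
#' @export
membrane_derivatives <- function(state, params = neuron_parameters(),
                                 g_exc = 0, g_inh = 0) {
  V <- state$V
  if (any(!is.finite(V)))
    stop(sprintf("non-finite membrane state at neuron index %d",
                 which(!is.finite(V))[1]), call. = FALSE)
  if (any(g_exc < 0) || any(g_inh < 0))
    stop("synaptic conductances must be non-negative", call. = FALSE)
  p <- params
  r <- hh_rates(V, p)
  gna <- p$na_max_conductance * state$m^3 * state$h
  gk <- p$k_max_conductance * state$n^4
  i_total <- p$leak_conductance * (V - p$leak_reversal) +
    gna * (V - p$na_reversal) + gk * (V - p$k_reversal) +
    g_exc * (V - p$exc_reversal) + g_inh * (V - p$inh_reversal)
  list(dV = unname(-i_total / p$membrane_capacitance / 1000),  # mV/ms
       dm = unname(r[, "am"] * (1 - state$m) - r[, "bm"] * state$m),
       dh = unname(r[, "ah"] * (1 - state$h) - r[, "bh"] * state$h),
       dn = unname(r[, "an"] * (1 - state$n) - r[, "bn"] * state$n))
}

# seed handling: temporarily install a seed, restore the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
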