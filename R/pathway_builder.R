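# Pathway construction: supraspinal drive, membrane noise, probabilistic
# layer-to-layer connectivity and leak-potential heterogeneity.

#' Epoched signal container
#'
#' A real-valued signal organized as independent analysis epochs.
#'
#' @param values Numeric matrix, epochs x samples.
#' @param fs Sampling rate (Hz).
#' @param epoch_length Epoch duration (s).
#' @return An `epoched_signal` object.
#' @export
epoched_signal <- function(values, fs = 1000, epoch_length = 1) {
  values <- as.matrix(values)
  if (ncol(values) != round(fs * epoch_length)) {
    stop("samples per epoch must equal fs * epoch_length")
  }
  if (!all(is.finite(values))) stop("epoched signal contains non-finite values")
  structure(list(values = values, fs = fs, epoch_length = epoch_length),
            class = "epoched_signal")
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("<epoched_signal> %d epochs x %d samples @ %g Hz (var %.4g)\n",
              nrow(x$values), ncol(x$values), x$fs, stats::var(as.vector(x$values))))
  invisible(x)
}

# Band-limited Gaussian noise, built per epoch by frequency-domain masking:
# independent complex-Gaussian coefficients on the integer-frequency bins
# inside the band, zero elsewhere, inverse FFT, then one global rescale to the
# requested variance.  Exact band edges, no filter transients, zero mean per
# epoch by construction.
band_gaussian <- function(fs, epochs, epoch_length, band, seed, variance = 1) {
  if (band[1] <= 0 || band[2] >= fs / 2) {
    stop("band must lie strictly inside (0, fs/2)")
  }
  if (band[1] > band[2]) stop("band must be increasing")
  n <- round(fs * epoch_length)
  k <- seq(ceiling(band[1] * epoch_length), floor(band[2] * epoch_length))
  if (length(k) == 0) stop("band contains no resolvable frequency bin")
  set.seed(seed)
  coef <- matrix(0 + 0i, n, epochs)
  nk <- length(k)
  coef[k + 1, ] <- matrix(complex(real = rnorm(nk * epochs),
                                  imaginary = rnorm(nk * epochs)), nk, epochs)
  coef[n + 1 - k, ] <- Conj(coef[k + 1, ])
  x <- Re(stats::mvfft(coef, inverse = TRUE)) / n
  x <- t(x)
  x * sqrt(variance / mean(x^2))
}

#' Common beta-band supraspinal drive
#'
#' The supraspinal input shared by all first-layer neurons: a zero-mean
#' Gaussian signal band-limited to the beta band (15-35 Hz by default),
#' generated independently per 1-s epoch at exact 1 Hz frequency resolution
#' and normalized to unit variance.
#'
#' @param fs Sampling rate (Hz).
#' @param epochs Number of epochs.
#' @param epoch_length Epoch duration (s).
#' @param band Frequency band (Hz), within (0, fs/2).
#' @param seed RNG seed (same seed gives a bit-identical signal).
#' @return An [epoched_signal()] with unit variance.
#' @export
generate_supraspinal_input <- function(fs = 1000, epochs = 200, epoch_length = 1,
                                       band = c(15, 35), seed = 1) {
  epoched_signal(band_gaussian(fs, epochs, epoch_length, band, seed, 1),
                 fs, epoch_length)
}

#' Per-neuron membrane noise
#'
#' Band-limited (1-100 Hz by default) Gaussian noise, independent across
#' neurons: the realization is keyed by `neuron_id`, so different ids give
#' independent draws while the same `(seed, neuron_id)` is reproducible.
#'
#' @inheritParams generate_supraspinal_input
#' @param variance Noise variance.
#' @param neuron_id Integer id selecting the independent realization.
#' @return An [epoched_signal()].
#' @export
generate_membrane_noise <- function(fs = 1000, epochs = 200, epoch_length = 1,
                                    band = c(1, 100), variance = 1, seed = 1,
                                    neuron_id = 1) {
  s <- derive_seed(seed, paste0("membrane-noise-", neuron_id))
  epoched_signal(band_gaussian(fs, epochs, epoch_length, band, s, variance),
                 fs, epoch_length)
}

#' Compose the injected drive
#'
#' Builds the first-layer injected current `dc_level + signal + noise`,
#' rescaling the components so that the signal-to-noise ratio equals `snr_db`
#' and (optionally) the total stochastic standard deviation equals `total_sd`.
#'
#' @param common The shared signal component ([epoched_signal()]).
#' @param noise The independent noise component ([epoched_signal()]).
#' @param dc_level Constant current offset.
#' @param snr_db Signal-to-noise ratio, `10 log10(P_signal / P_noise)` (dB).
#' @param total_sd If non-`NULL`, the composed stochastic part (signal +
#'   noise) is scaled to this standard deviation.
#' @return An [epoched_signal()] with attributes `signal` and `noise` holding
#'   the scaled components.
#' @export
compose_injected_drive <- function(common, noise, dc_level, snr_db = -7.5,
                                   total_sd = NULL) {
  stopifnot(inherits(common, "epoched_signal"), inherits(noise, "epoched_signal"))
  if (common$fs != noise$fs || !all(dim(common$values) == dim(noise$values))) {
    stop("signal and noise must have matching sampling rate and epoch layout")
  }
  p_s <- mean(common$values^2)
  p_n <- mean(noise$values^2)
  if (p_s <= 0 || p_n <= 0) stop("zero-power drive component")
  ratio <- 10^(snr_db / 10)
  s <- common$values
  n <- noise$values * sqrt(p_s / (ratio * p_n))
  if (!is.null(total_sd)) {
    k <- total_sd / sqrt(mean(s^2) + mean(n^2))
    s <- s * k
    n <- n * k
  }
  out <- epoched_signal(dc_level + s + n, common$fs, common$epoch_length)
  attr(out, "signal") <- s
  attr(out, "noise") <- n
  attr(out, "dc_level") <- dc_level
  out
}

# Shipped two-exponential leak-potential mixture for interneuron layers:
# each component is a downward shifted exponential (E_L = offset - Exp(scale)),
# so no draw exceeds its component offset.  Weights/offsets/scales are
# calibration constants chosen so that (a) the sample mean is about -64 mV,
# (b) the bulk component's mode sits where neurons fire ~20 spikes/s under
# the calibrated drive (the deep tail is nearly silent and carries the mean
# down to -64), and (c) the second component's mode sits where neurons fire
# ~50 spikes/s, producing the secondary firing-rate histogram mode.  The cap
# is a safety bound below the zero-drive spontaneous-firing boundary.
EL_MIX_IN <- list(w = c(0.6, 0.4), offset = c(-65.5, -59.6),
                  scale = c(1.6, 0.5), cap = -58)

# Motoneuron leak-potential distribution: uniform just below the zero-drive
# silence cap; the spread is set by the firing-rate calibration.
EL_MN_CAP <- -53
EL_MN_SPREAD <- 8

#' Sample leak reversal potentials for one layer
#'
#' Interneuron layers draw from a two-component shifted-exponential mixture
#' (each component pointing downward from its offset) whose mean is
#' approximately -64 mV; motoneurons draw from a uniform distribution
#' spanning `spread` mV below a fixed cap.  Both distributions lie entirely
#' below the zero-drive spontaneous-firing boundary of the respective model,
#' so an undriven pathway is silent.
#'
#' @param layer_kind `"interneuron"` or `"motoneuron"`.
#' @param n Number of neurons.
#' @param seed RNG seed.
#' @param mix Mixture constants (interneurons); see `EL_MIX_IN`.
#' @param cap,spread Upper bound and range (motoneurons).
#' @return Numeric vector of E_L values (mV).
#' @export
sample_leak_potentials <- function(layer_kind = c("interneuron", "motoneuron"),
                                   n, seed,
                                   mix = EL_MIX_IN,
                                   cap = EL_MN_CAP, spread = EL_MN_SPREAD) {
  layer_kind <- match.arg(layer_kind)
  stopifnot(n >= 1)
  set.seed(seed)
  if (layer_kind == "motoneuron") {
    return(runif(n, cap - spread, cap))
  }
  comp <- sample.int(length(mix$w), n, replace = TRUE, prob = mix$w)
  el <- mix$offset[comp] - stats::rexp(n, rate = 1 / mix$scale[comp])
  # component offsets already sit below the zero-drive firing boundary; the
  # cap is a safety clamp only
  el[el > mix$cap] <- mix$cap
  el
}

#' Pathway configuration
#'
#' Describes one simulated descending pathway: the number of interneuron
#' layers between the supraspinal drive and the motoneuron pool, layer sizes,
#' synaptic fan-in, EPSP targets, the dual-drive mixing weight and the drive
#' statistics.  Defaults follow the reference configuration: 100 neurons per
#' layer, 100 inputs per motoneuron, EPSP peaks of 100 uV (motoneuron) and
#' 500 uV (interneuron), supraspinal signal-to-noise ratio -7.5 dB, 200
#' epochs of 1 s at 1 kHz.
#'
#' When `neurons_per_layer` differs from the reference size of 100, all
#' synaptic peak conductances are scaled by `100 / neurons_per_layer` so that
#' the mean synaptic drive per neuron is preserved (standard network
#' down-scaling); the EPSP calibration targets refer to the unscaled
#' reference synapse.
#'
#' @param n_interneuron_layers Number of interneuron layers (>= 0; 0 is the
#'   mono-synaptic pathway).
#' @param neurons_per_layer Neurons per interneuron layer and motoneurons in
#'   the pool.
#' @param inputs_per_motoneuron Synaptic inputs per motoneuron (defaults to
#'   the whole terminal layer).
#' @param inputs_per_interneuron Fan-in of interneuron layers >= 2; `NULL`
#'   until set by [calibrate_pathway()].
#' @param epsp_peak_mn,epsp_peak_in Single-EPSP somatic peak targets (uV).
#' @param indirect_weight Fraction (in signal power) of the indirect drive in
#'   the dual-drive configuration: the motoneuron pool receives
#'   `sqrt(1 - w)` times the direct injected drive plus `sqrt(w)` times the
#'   synaptic drive from the terminal interneuron layer.  Defaults to 1 when
#'   interneuron layers are present (plain multi-synaptic pathway) and is
#'   ignored for the 0-layer pathway.
#' @param seed Master RNG seed (topology and common drive derive from it).
#' @param snr_db Supraspinal drive signal-to-noise ratio (dB).
#' @param fs Output sampling rate (Hz).
#' @param epochs Number of 1-s analysis epochs.
#' @param epoch_length Epoch duration (s).
#' @param warmup_s Discarded warm-up (s) before the analysis epochs.
#' @param dt Internal integration step (ms); 1/dt must be an integer.
#' @return A `pathway_config` object.
#' @export
pathway_config <- function(n_interneuron_layers = 0,
                           neurons_per_layer = 100,
                           inputs_per_motoneuron = neurons_per_layer,
                           inputs_per_interneuron = NULL,
                           epsp_peak_mn = 100,
                           epsp_peak_in = 500,
                           indirect_weight = if (n_interneuron_layers >= 1) 1 else 0,
                           seed = 1,
                           snr_db = -7.5,
                           fs = 1000,
                           epochs = 200,
                           epoch_length = 1,
                           warmup_s = 1,
                           dt = 0.025) {
  stopifnot(n_interneuron_layers >= 0,
            neurons_per_layer >= 1,
            inputs_per_motoneuron >= 1,
            inputs_per_motoneuron <= neurons_per_layer,
            indirect_weight >= 0, indirect_weight <= 1,
            epsp_peak_mn > 0, epsp_peak_in > 0,
            epochs >= 1, fs > 0, dt > 0)
  if (!is.null(inputs_per_interneuron) &&
      inputs_per_interneuron > neurons_per_layer) {
    stop("inputs_per_interneuron must not exceed neurons_per_layer")
  }
  structure(list(
    n_interneuron_layers = as.integer(n_interneuron_layers),
    neurons_per_layer = as.integer(neurons_per_layer),
    inputs_per_motoneuron = as.integer(inputs_per_motoneuron),
    inputs_per_interneuron = if (is.null(inputs_per_interneuron)) NULL
                             else as.integer(inputs_per_interneuron),
    epsp_peak_mn = epsp_peak_mn,
    epsp_peak_in = epsp_peak_in,
    indirect_weight = indirect_weight,
    seed = as.integer(seed),
    snr_db = snr_db,
    fs = fs,
    epochs = as.integer(epochs),
    epoch_length = epoch_length,
    warmup_s = warmup_s,
    dt = dt,
    synaptic_scale = 100 / neurons_per_layer
  ), class = "pathway_config")
}

#' @export
print.pathway_config <- function(x, ...) {
  cat(sprintf(paste0("<pathway_config> %d interneuron layer(s), %d neurons/layer, ",
                     "%d inputs/motoneuron\n  epochs: %d x %g s @ %g Hz, snr %g dB, ",
                     "indirect weight %g, seed %d\n"),
              x$n_interneuron_layers, x$neurons_per_layer, x$inputs_per_motoneuron,
              x$epochs, x$epoch_length, x$fs, x$snr_db, x$indirect_weight, x$seed))
  invisible(x)
}

#' Sample the probabilistic layer-to-layer connectivity
#'
#' Interneurons of layer `l >= 2` draw `inputs_per_interneuron` distinct
#' sources uniformly without replacement from layer `l - 1`; each motoneuron
#' draws `inputs_per_motoneuron` distinct sources from the terminal
#' interneuron layer (all of it, at the default).  A 0-layer pathway has no
#' synaptic connectivity: the motoneuron pool is driven by injected current.
#'
#' @param config A [pathway_config()].
#' @param seed RNG seed (defaults to the topology seed derived from the
#'   config master seed).
#' @return A `connectivity_map`: list with one element per interneuron layer
#'   (`NULL` for layer 1) plus `mn`, each an `k x n` integer matrix of source
#'   indices (columns = targets), or `NULL` for the 0-layer pathway; the
#'   `direct_drive` attribute marks the latter.
#' @export
sample_connectivity <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pathway_config"))
  if (is.null(seed)) seed <- derive_seed(config$seed, "topology")
  set.seed(seed)
  L <- config$n_interneuron_layers
  N <- config$neurons_per_layer
  out <- list(layers = vector("list", L), mn = NULL)
  if (L == 0) {
    attr(out, "direct_drive") <- TRUE
    class(out) <- "connectivity_map"
    return(out)
  }
  if (L >= 2) {
    k <- config$inputs_per_interneuron
    if (is.null(k)) stop("inputs_per_interneuron not set; run calibrate_pathway() first")
    if (k > N) stop("inputs_per_interneuron exceeds layer size")
    for (l in 2:L) {
      out$layers[[l]] <- vapply(seq_len(N), function(i) sort(sample.int(N, k)),
                                integer(k))
    }
  }
  km <- config$inputs_per_motoneuron
  out$mn <- vapply(seq_len(N), function(i) sort(sample.int(N, km)), integer(km))
  attr(out, "direct_drive") <- FALSE
  class(out) <- "connectivity_map"
  out
}

#' @export
print.connectivity_map <- function(x, ...) {
  if (isTRUE(attr(x, "direct_drive"))) {
    cat("<connectivity_map> direct drive (0 interneuron layers)\n")
  } else {
    cat(sprintf("<connectivity_map> %d interneuron layer(s); motoneuron fan-in %d\n",
                length(x$layers), nrow(x$mn)))
  }
  invisible(x)
}

#' Export a connectivity map as an edge list
#'
#' @param x A `connectivity_map`.
#' @param weights Named list with per-edge conductances `w_in` (interneuron
#'   targets) and `w_mn` (motoneuron targets); optional.
#' @param ... Unused.
#' @return `data.frame(source, target, layer, weight)` where `layer` is the
#'   target layer index (`Inf`... the motoneuron pool is labelled `"mn"`).
#' @export
as.data.frame.connectivity_map <- function(x, ..., weights = NULL) {
  rows <- list()
  for (l in seq_along(x$layers)) {
    m <- x$layers[[l]]
    if (is.null(m)) next
    rows[[length(rows) + 1]] <- data.frame(
      source = as.vector(m),
      target = rep(seq_len(ncol(m)), each = nrow(m)),
      layer = as.character(l),
      weight = if (is.null(weights)) NA_real_ else weights$w_in)
  }
  if (!is.null(x$mn)) {
    rows[[length(rows) + 1]] <- data.frame(
      source = as.vector(x$mn),
      target = rep(seq_len(ncol(x$mn)), each = nrow(x$mn)),
      layer = "mn",
      weight = if (is.null(weights)) NA_real_ else weights$w_mn)
  }
  if (length(rows) == 0) {
    return(data.frame(source = integer(0), target = integer(0),
                      layer = character(0), weight = numeric(0)))
  }
  do.call(rbind, rows)
}
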