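# Experiment protocols: layer sweep, per-layer propagation and dual-drive
# mixing, plus synthetic coupling fixtures with known ground truth.

#' Experiment specification
#'
#' Bundles the protocol choice with its scale.  The `reduced` tier (50
#' epochs, 10 repetitions, 50 neurons/layer, depth <= 4) preserves the
#' sign/ordering structure of the full-scale protocols (200 epochs, 100
#' repetitions, 100 neurons/layer) at a cost compatible with routine testing;
#' full-scale runs only tighten the error bars.
#'
#' @param protocol `"layer_sweep"`, `"per_layer"` or `"dual_drive"`.
#' @param tier `"reduced"` or `"full"`.
#' @param layers Layer counts (layer_sweep) or chain depth (per_layer).
#' @param proportions Indirect-drive power fractions (dual_drive).
#' @param repetitions Noise repetitions per condition.
#' @param epochs,neurons_per_layer Scale overrides (default by tier).
#' @param n_surrogates Surrogates per pair for significance thresholds.
#' @param seed Master seed.
#' @param out_dir Output directory for [write_experiment()] (optional).
#' @return An `experiment_spec`.
#' @export
experiment_spec <- function(protocol = c("layer_sweep", "per_layer", "dual_drive"),
                            tier = c("reduced", "full"),
                            layers = NULL,
                            proportions = seq(0, 1, by = 0.2),
                            repetitions = NULL,
                            epochs = NULL,
                            neurons_per_layer = NULL,
                            n_surrogates = NULL,
                            seed = 1,
                            out_dir = NULL) {
  protocol <- match.arg(protocol)
  tier <- match.arg(tier)
  reduced <- tier == "reduced"
  if (is.null(layers)) {
    layers <- if (protocol == "per_layer") 4L else if (reduced) 0:3 else 0:6
  }
  if (protocol == "layer_sweep" && layers[1] != 0) {
    stop("layer sweep must start at 0 layers")
  }
  if (protocol == "dual_drive" &&
      !all(proportions %in% seq(0, 1, by = 0.2))) {
    stop("dual-drive proportions must be multiples of 20%")
  }
  structure(list(
    protocol = protocol, tier = tier,
    layers = as.integer(layers), proportions = proportions,
    repetitions = if (is.null(repetitions)) (if (reduced) 10L else 100L)
                  else as.integer(repetitions),
    epochs = if (is.null(epochs)) (if (reduced) 50L else 200L) else as.integer(epochs),
    neurons_per_layer = if (is.null(neurons_per_layer)) (if (reduced) 50L else 100L)
                        else as.integer(neurons_per_layer),
    n_surrogates = if (is.null(n_surrogates)) (if (reduced) 400L else 1000L)
                   else as.integer(n_surrogates),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "experiment_spec")
}

base_config <- function(spec, n_layers, indirect_weight = NULL) {
  if (is.null(indirect_weight)) indirect_weight <- if (n_layers >= 1) 1 else 0
  pathway_config(n_interneuron_layers = n_layers,
                 neurons_per_layer = spec$neurons_per_layer,
                 indirect_weight = indirect_weight,
                 seed = spec$seed,
                 epochs = spec$epochs)
}

couple_against_input <- function(chain, Y, spec, rep, tag) {
  X <- analysis_input(chain$common_unit[-seq_len(chain$warm_epochs), , drop = FALSE],
                      chain$config, noise_rep = rep)
  nmc_map(X, Y, n_surrogates = spec$n_surrogates,
          seed = derive_seed(spec$seed, paste0("surr-", tag, "-", rep)))
}

cst_from_raw <- function(spikes, config, warm_epochs, dt) {
  epoch_ms <- config$epoch_length * 1000
  warm_ms <- warm_epochs * epoch_ms
  t <- spikes$step * dt
  keep <- t >= warm_ms
  t <- t[keep] - warm_ms
  ev <- data.frame(neuron_id = spikes$neuron[keep],
                   epoch = floor(t / epoch_ms) + 1L,
                   time_ms = t %% epoch_ms)
  cumulative_spike_train(ev, n_epochs = config$epochs, fs = config$fs,
                         epoch_length = config$epoch_length)
}

#' Layer-count sweep
#'
#' For every layer count in `spec$layers`, computes the coupling (IFC, CFC,
#' COI) between the supraspinal input and the motoneuron-pool cumulative
#' spike train, over `spec$repetitions` independent noise realizations.  One
#' deep interneuron chain per repetition is shared across depths (the first
#' `l` layers of a deep chain are identical to an `l`-layer chain under the
#' per-layer seed scheme), so each depth's results equal a standalone
#' [simulate_pathway()] run of that depth.
#'
#' @param spec An [experiment_spec()].
#' @param calibration Optional `pathway_calibration`.
#' @param verbose Print progress?
#' @return `data.frame(layers, repetition, ifc, cfc, coi, n_sig)` with
#'   attribute `summary` (per-layer mean and +/- 2 SD).
#' @export
run_layer_sweep <- function(spec, calibration = NULL, verbose = FALSE) {
  stopifnot(spec$protocol %in% c("layer_sweep", "per_layer"))
  max_l <- max(spec$layers)
  cfg_deep <- base_config(spec, max_l)
  if (is.null(calibration)) calibration <- calibrate_pathway(cfg_deep)
  rows <- list()
  for (rep in seq_len(spec$repetitions)) {
    chain <- simulate_chain(cfg_deep, calibration, noise_rep = rep)
    for (l in spec$layers) {
      cfg <- base_config(spec, l)
      mn <- simulate_mn_pool(cfg, calibration, chain, noise_rep = rep)
      Y <- cst_from_raw(mn$spikes, cfg, chain$warm_epochs, chain$dt)
      cr <- couple_against_input(chain, Y, spec, rep, paste0("sweep-", l))
      rows[[length(rows) + 1]] <- data.frame(
        layers = l, repetition = rep, ifc = unname(cr$ifc),
        cfc = unname(cr$cfc), coi = unname(cr$coi),
        n_sig = sum(cr$mask, na.rm = TRUE))
      if (verbose) message(sprintf("rep %d, %d layers: IFC %.3f CFC %.3f COI %.3f",
                                   rep, l, cr$ifc, cr$cfc, cr$coi))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_experiment(out, "layers")
  out
}

#' Per-layer propagation
#'
#' Couples the supraspinal input against the cumulative spike train of every
#' successive interneuron layer of one deep pathway (depth `spec$layers`),
#' plus the motoneuron pool attached to the terminal layer.
#'
#' @inheritParams run_layer_sweep
#' @return `data.frame(layer, repetition, ifc, cfc, coi, n_sig)` where
#'   `layer` is `"1" ... "D"` or `"mn"`, with attribute `summary`.
#' @export
run_per_layer <- function(spec, calibration = NULL, verbose = FALSE) {
  depth <- max(spec$layers)
  cfg <- base_config(spec, depth)
  if (is.null(calibration)) calibration <- calibrate_pathway(cfg)
  rows <- list()
  for (rep in seq_len(spec$repetitions)) {
    chain <- simulate_chain(cfg, calibration, noise_rep = rep)
    for (l in seq_len(depth)) {
      Y <- cst_from_raw(chain$spikes[[l]], cfg, chain$warm_epochs, chain$dt)
      cr <- couple_against_input(chain, Y, spec, rep, paste0("perlayer-", l))
      rows[[length(rows) + 1]] <- data.frame(
        layer = as.character(l), repetition = rep, ifc = unname(cr$ifc),
        cfc = unname(cr$cfc), coi = unname(cr$coi),
        n_sig = sum(cr$mask, na.rm = TRUE))
    }
    mn <- simulate_mn_pool(cfg, calibration, chain, noise_rep = rep)
    Y <- cst_from_raw(mn$spikes, cfg, chain$warm_epochs, chain$dt)
    cr <- couple_against_input(chain, Y, spec, rep, paste0("sweep-", depth))
    rows[[length(rows) + 1]] <- data.frame(
      layer = "mn", repetition = rep, ifc = unname(cr$ifc),
      cfc = unname(cr$cfc), coi = unname(cr$coi),
      n_sig = sum(cr$mask, na.rm = TRUE))
    if (verbose) message(sprintf("rep %d done", rep))
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_experiment(out, "layer")
  out
}

#' Dual-drive mixing
#'
#' The motoneuron pool receives a direct supraspinal drive and an indirect
#' drive from the same supraspinal input relayed through two interneuron
#' layers; the indirect fraction of the drive power is stepped over
#' `spec$proportions`.  The two-layer chain is simulated once per repetition
#' and shared across proportions (mixing only rescales the motoneuron
#' inputs).
#'
#' @inheritParams run_layer_sweep
#' @return `data.frame(indirect, repetition, ifc, cfc, coi, n_sig)` with
#'   attribute `summary`.
#' @export
run_dual_drive <- function(spec, calibration = NULL, verbose = FALSE) {
  cfg2 <- base_config(spec, 2)
  if (is.null(calibration)) calibration <- calibrate_pathway(cfg2)
  rows <- list()
  for (rep in seq_len(spec$repetitions)) {
    chain <- simulate_chain(cfg2, calibration, noise_rep = rep)
    for (w in spec$proportions) {
      cfg <- base_config(spec, 2, indirect_weight = w)
      mn <- simulate_mn_pool(cfg, calibration, chain, noise_rep = rep)
      Y <- cst_from_raw(mn$spikes, cfg, chain$warm_epochs, chain$dt)
      cr <- couple_against_input(chain, Y, spec, rep,
                                 paste0("dual-", round(100 * w)))
      rows[[length(rows) + 1]] <- data.frame(
        indirect = w, repetition = rep, ifc = unname(cr$ifc),
        cfc = unname(cr$cfc), coi = unname(cr$coi),
        n_sig = sum(cr$mask, na.rm = TRUE))
      if (verbose) message(sprintf("rep %d, indirect %.0f%%: COI %.3f",
                                   rep, 100 * w, cr$coi))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_experiment(out, "indirect")
  out
}

summarize_experiment <- function(df, by) {
  agg <- function(v, f) stats::aggregate(df[[v]], list(df[[by]]), f, simplify = TRUE)$x
  lv <- stats::aggregate(df$ifc, list(df[[by]]), mean)$Group.1
  data.frame(
    condition = lv,
    ifc_mean = agg("ifc", mean), ifc_2sd = 2 * agg("ifc", stats::sd),
    cfc_mean = agg("cfc", mean), cfc_2sd = 2 * agg("cfc", stats::sd),
    coi_mean = agg("coi", function(x) mean(x, na.rm = TRUE)),
    coi_2sd = 2 * agg("coi", function(x) stats::sd(x, na.rm = TRUE)))
}

#' Write experiment results with a reproducibility manifest
#'
#' @param result Long-format result table from a protocol runner.
#' @param spec The [experiment_spec()] that produced it.
#' @param dir Output directory (created if missing).
#' @param name Base file name (defaults to the protocol).
#' @return Paths of the written files, invisibly.
#' @export
write_experiment <- function(result, spec, dir = spec$out_dir, name = spec$protocol) {
  if (is.null(dir)) stop("no output directory given")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_file <- file.path(dir, paste0(name, ".csv"))
  summary_file <- file.path(dir, paste0(name, "_summary.csv"))
  manifest_file <- file.path(dir, paste0(name, "_manifest.json"))
  utils::write.csv(result, data_file, row.names = FALSE)
  utils::write.csv(attr(result, "summary"), summary_file, row.names = FALSE)
  params <- default_model_params()
  manifest <- list(
    package_version = as.character(utils::packageVersion("nmcoupling")),
    spec = unclass(spec),
    spec_hash = object_hash(unclass(spec)),
    params_hash = object_hash(lapply(params, unclass)),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(data = data_file, summary = summary_file, manifest = manifest_file))
}

#' Synthetic coupling fixtures with known ground truth
#'
#' Epoched signal pairs whose NMC at chosen pairs is known analytically:
#' `"identical"` (iso-diagonal NMC 1), `"phase_locked"` (NMC 1 at the chosen
#' `(f0, f1)` pair: the epoch phases are `m * theta` in X and `n * theta` in
#' Y, so the powered bins align exactly), `"independent"` (NMC at the null
#' level everywhere) and `"mixture"` (phase-locked pair diluted with an
#' independent component of relative power `1 - strength`).
#'
#' @param kind Fixture type.
#' @param f0,f1 Input/output frequencies of the constructed coupling (Hz).
#' @param epochs Number of epochs.
#' @param strength Coupled fraction of the output power (mixture only).
#' @param seed RNG seed.
#' @param fs,epoch_length Sampling layout.
#' @return List `x`, `y` ([epoched_signal()]s) plus `target` (data frame of
#'   pair(s) with the analytic NMC value).
#' @export
make_coupling_fixtures <- function(kind = c("identical", "phase_locked",
                                            "independent", "mixture"),
                                   f0 = 10, f1 = 20, epochs = 100,
                                   strength = 0.5, seed = 1,
                                   fs = 1000, epoch_length = 1) {
  kind <- match.arg(kind)
  n <- round(fs * epoch_length)
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  if (kind == "identical") {
    x <- band_gaussian(fs, epochs, epoch_length, c(5, 45), seed, 1)
    return(list(x = epoched_signal(x, fs, epoch_length),
                y = epoched_signal(x, fs, epoch_length),
                target = data.frame(f_x = f0, f_y = f0, nmc = 1)))
  }
  if (kind == "independent") {
    x <- band_gaussian(fs, epochs, epoch_length, c(5, 45), derive_seed(seed, "x"), 1)
    y <- band_gaussian(fs, epochs, epoch_length, c(5, 45), derive_seed(seed, "y"), 1)
    return(list(x = epoched_signal(x, fs, epoch_length),
                y = epoched_signal(y, fs, epoch_length),
                target = data.frame(f_x = f0, f_y = f1, nmc = 0)))
  }
  k <- reduce_ratio(f0, f1)
  theta <- runif(epochs, 0, 2 * pi)
  x <- t(vapply(theta, function(th) cos(2 * pi * f0 * t + k["m"] * th), numeric(n)))
  y_c <- t(vapply(theta, function(th) cos(2 * pi * f1 * t + k["n"] * th), numeric(n)))
  if (kind == "phase_locked") {
    return(list(x = epoched_signal(x, fs, epoch_length),
                y = epoched_signal(y_c, fs, epoch_length),
                target = data.frame(f_x = f0, f_y = f1, nmc = 1)))
  }
  # mixture: add an independent same-frequency component; with coupled power
  # fraction s at the output bin, NMC = ... the coupled fraction of the
  # amplitude, sqrt(s), in the n = m = 1 case; for general (n, m) the target
  # is computed by the moment definition below and recorded.
  phi <- runif(epochs, 0, 2 * pi)
  y <- sqrt(strength) * y_c +
    sqrt(1 - strength) * t(vapply(phi, function(ph) cos(2 * pi * f1 * t + ph),
                                  numeric(n)))
  xs <- epoched_signal(x, fs, epoch_length)
  ys <- epoched_signal(y, fs, epoch_length)
  list(x = xs, y = ys,
       target = data.frame(f_x = f0, f_y = f1, nmc = nmc(xs, ys, f0, f1)))
}
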