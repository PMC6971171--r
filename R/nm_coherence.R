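# Generalized n:m coherence (NMC) between epoched signals, with
# permutation-surrogate significance at a Bonferroni-corrected family-wise
# error rate, and the IFC / CFC / COI summaries.

#' Reduce a frequency pair to its coprime ratio
#'
#' For integer frequencies, returns the reduced integers `(n, m)` with
#' `f_X / f_Y = m / n` and `gcd(n, m) = 1`; the NMC at this pair compares the
#' n-th power of the input bin with the m-th power of the output bin (both
#' land on the common frequency `n f_X = m f_Y`).
#'
#' @param f_X,f_Y Positive integer frequencies (Hz).
#' @return Named integer vector `c(n, m)`.
#' @examples
#' reduce_ratio(8, 16)   # n = 2, m = 1
#' reduce_ratio(20, 20)  # n = 1, m = 1
#' @export
reduce_ratio <- function(f_X, f_Y) {
  stopifnot(f_X >= 1, f_Y >= 1, f_X == round(f_X), f_Y == round(f_Y))
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(f_X, f_Y)
  c(n = as.integer(f_Y / d), m = as.integer(f_X / d))
}

#' The input x output frequency-pair grid
#'
#' 21 input frequencies (15-35 Hz) by 100 output frequencies (1-100 Hz) at
#' 1 Hz resolution: 2,100 pairs, each with its reduced `(n, m)`.
#'
#' @param fx,fy Integer frequency vectors (Hz).
#' @return `data.frame(f_x, f_y, n, m, iso, high_order)`.
#' @export
frequency_pair_grid <- function(fx = 15:35, fy = 1:100) {
  grid <- expand.grid(f_x = as.integer(fx), f_y = as.integer(fy))
  nm <- mapply(function(a, b) reduce_ratio(a, b), grid$f_x, grid$f_y)
  grid$n <- nm["n", ]
  grid$m <- nm["m", ]
  grid$iso <- grid$f_x == grid$f_y
  grid$high_order <- grid$n > 12 | grid$m > 12
  grid
}

#' Per-epoch Fourier spectra
#'
#' Discrete Fourier transform of each epoch after demeaning, with a
#' rectangular window (the 1-s epochs at 1 Hz resolution make integer
#' frequencies exactly resolvable).
#'
#' @param signal An [epoched_signal()].
#' @param freqs Frequencies (Hz) to retain; defaults to all positive bins
#'   below Nyquist.
#' @return Complex matrix (epochs x frequencies) with attribute `freqs`.
#' @export
epoch_spectra <- function(signal, freqs = NULL) {
  stopifnot(inherits(signal, "epoched_signal"))
  x <- signal$values
  n <- ncol(x)
  if (abs(n - signal$fs * signal$epoch_length) > 1e-9) {
    stop("epoch length does not match fs x epoch_length samples")
  }
  x <- x - rowMeans(x)
  sp <- t(stats::mvfft(t(x)))
  df <- 1 / signal$epoch_length
  all_freqs <- (seq_len(n) - 1) * df
  if (is.null(freqs)) freqs <- all_freqs[all_freqs > 0 & all_freqs < signal$fs / 2]
  idx <- match(freqs, all_freqs)
  if (anyNA(idx)) stop("requested frequencies are not resolvable bins")
  out <- sp[, idx, drop = FALSE]
  attr(out, "freqs") <- freqs
  out
}

# Raise per-epoch complex bins to an integer power after RMS normalization
# (the NMC is exactly invariant to per-bin rescaling; powering the normalized
# values keeps high moment orders within double range).
power_bins <- function(z, k) {
  s <- sqrt(mean(Mod(z)^2))
  if (s > 0) z <- z / s
  z^k
}

#' n:m coherence at one frequency pair
#'
#' `NMC(f_X, f_Y) = |<X^n (Y^m)*>| / sqrt(<|X^n|^2> <|Y^m|^2>)` with
#' averaging over epochs, where `(n, m)` is the reduced ratio of the two
#' frequencies.  Values lie in `[0, 1]` (Cauchy-Schwarz); 1 indicates perfect
#' coupling at the tested pair, and for `f_X = f_Y` the NMC equals the square
#' root of classical magnitude-squared coherence.
#'
#' @param X,Y [epoched_signal()] objects with matching epoch counts.
#' @param f_X,f_Y Integer frequencies (Hz).
#' @return NMC value in `[0, 1]`, or `NA` for a degenerate (all-zero bin)
#'   pair.
#' @export
nmc <- function(X, Y, f_X, f_Y) {
  sx <- epoch_spectra(X, f_X)[, 1]
  sy <- epoch_spectra(Y, f_Y)[, 1]
  if (length(sx) < 2 || length(sx) != length(sy)) {
    stop("need >= 2 epochs with matching counts")
  }
  k <- reduce_ratio(f_X, f_Y)
  u <- power_bins(sx, k["n"])
  v <- power_bins(sy, k["m"])
  den <- sqrt(mean(Mod(u)^2) * mean(Mod(v)^2))
  if (!is.finite(den) || den == 0) return(NA_real_)
  Mod(mean(u * Conj(v))) / den
}

#' Per-pair significance threshold from epoch-permutation surrogates
#'
#' Builds the null distribution of the NMC statistic for one pair by randomly
#' permuting the epoch pairing of the two (already powered) bin vectors, and
#' returns the `1 - alpha` quantile.  When the quantile is directly estimable
#' from the surrogate count (`n_surrogates * alpha >= 20`) the empirical
#' quantile is used; otherwise the upper tail of the squared statistic is
#' fitted with a Weibull survival model over the top quintile and
#' extrapolated (never below the largest surrogate value).
#'
#' @param u,v Complex per-epoch vectors (the powered, normalized bins).
#' @param alpha Per-test level (e.g. `fwer / n_pairs`).
#' @param n_surrogates Number of epoch permutations.
#' @param seed RNG seed for the permutations.
#' @return Threshold in `[0, 1]` (possibly `Inf` for degenerate input).
#' @export
significance_threshold <- function(u, v, alpha, n_surrogates = 800, seed = 1) {
  L <- length(u)
  stopifnot(length(v) == L, L >= 2)
  nu <- sqrt(sum(Mod(u)^2))
  nv <- sqrt(sum(Mod(v)^2))
  if (nu == 0 || nv == 0) return(Inf)
  u <- u / nu
  vc <- Conj(v / nv)
  set.seed(seed)
  t2 <- vapply(seq_len(n_surrogates), function(k) {
    Mod(sum(u[sample.int(L)] * vc))^2
  }, numeric(1))
  t2 <- sort(t2)
  K <- length(t2)
  if (K * alpha >= 20) {
    return(sqrt(stats::quantile(t2, 1 - alpha, names = FALSE)))
  }
  top <- t2[seq.int(floor(0.8 * K) + 1, K)]
  surv <- 1 - (seq.int(floor(0.8 * K) + 1, K)) / (K + 1)
  ok <- top > 0
  if (sum(ok) < 5) return(Inf)
  fit <- stats::lm(log(-log(surv[ok])) ~ log(top[ok]))
  g <- stats::coef(fit)[2]
  if (!is.finite(g) || g <= 0.05) return(Inf)
  ln_s <- -stats::coef(fit)[1] / g
  thr2 <- exp(ln_s) * (-log(alpha))^(1 / g)
  sqrt(min(max(thr2, max(t2)), 1))
}

#' NMC map over the frequency-pair grid with significance
#'
#' Computes the NMC and its per-pair surrogate threshold for every pair of
#' the (f_X, f_Y) grid, with the per-test level `fwer / n_pairs` (Bonferroni).
#'
#' @param X Input [epoched_signal()] (e.g. the supraspinal drive).
#' @param Y Output [epoched_signal()] (e.g. a cumulative spike train).
#' @param fx,fy Integer frequency grids (Hz).
#' @param fwer Family-wise error rate across the grid.
#' @param n_pairs Number of tests for the Bonferroni correction (defaults to
#'   the grid size).
#' @param threshold Significance scheme. `"analytic"` (default) applies the
#'   classical coherence null quantile `sqrt(1 - alpha^(1/(L-1)))` uniformly
#'   (the practice of the coherence literature this analysis follows; exact
#'   for `n = m = 1`, anticonservative at high moment orders, hence the
#'   high-order exclusion below).  `"permutation"` builds a per-pair null
#'   from epoch-permutation surrogates, which controls the FWER for every
#'   pair.  See the methods vignette for the trade-off.
#' @param n_surrogates Epoch permutations per pair (permutation mode).
#' @param seed RNG seed for the surrogate permutations.
#' @param include_high_order Keep pairs with reduced order n or m > 12 in the
#'   IFC/CFC sums?  Default `FALSE`: under the analytic threshold such pairs
#'   are dominated by moment-concentration artifacts.
#' @return A `coupling_result`: matrices `nmc`, `threshold`, `mask`, `n`,
#'   `m`, `high_order` (input frequencies x output frequencies), the summary
#'   `ifc`, `cfc`, `coi`, and bookkeeping fields.
#' @export
nmc_map <- function(X, Y, fx = 15:35, fy = 1:100, fwer = 0.05,
                    n_pairs = length(fx) * length(fy),
                    threshold = c("analytic", "permutation"),
                    n_surrogates = 800, seed = 1, include_high_order = FALSE) {
  stopifnot(inherits(X, "epoched_signal"), inherits(Y, "epoched_signal"))
  threshold <- match.arg(threshold)
  L <- nrow(X$values)
  if (nrow(Y$values) != L) stop("X and Y must have the same number of epochs")
  if (L < 2) stop("need >= 2 epochs")
  alpha <- fwer / n_pairs
  sx <- epoch_spectra(X, fx)
  sy <- epoch_spectra(Y, fy)
  if (threshold == "permutation") {
    set.seed(seed)
    perms <- vapply(seq_len(n_surrogates), function(k) sample.int(L) - 1L,
                    integer(L))
  } else {
    perms <- matrix(integer(0), nrow = L, ncol = 0)
  }
  res <- .nmc_map_cpp(sx, sy, as.integer(fx), as.integer(fy), perms, alpha)
  if (threshold == "analytic") {
    res$threshold[] <- sqrt(1 - alpha^(1 / (L - 1)))
    res$threshold[res$undefined] <- Inf
  }
  dimnames(res$nmc) <- dimnames(res$threshold) <- list(fx, fy)
  mask <- !res$undefined & is.finite(res$threshold) & res$nmc > res$threshold
  high <- res$n > 12 | res$m > 12
  out <- structure(list(
    nmc = res$nmc, threshold = res$threshold, mask = mask,
    n = res$n, m = res$m, high_order = high, undefined = res$undefined,
    fx = fx, fy = fy, n_epochs = L, fwer = fwer, alpha = alpha,
    threshold_mode = threshold,
    n_surrogates = if (threshold == "permutation") n_surrogates else 0L,
    seed = seed,
    include_high_order = include_high_order
  ), class = "coupling_result")
  s <- coupling_summary(out)
  out$ifc <- s["ifc"]
  out$cfc <- s["cfc"]
  out$coi <- s["coi"]
  out
}

#' IFC, CFC and the cross-over-iso index
#'
#' `IFC` is the sum of significant NMC values at iso-frequency pairs
#' (`f_X = f_Y`), `CFC` the sum at cross-frequency pairs, and
#' `COI = (CFC - IFC) / (CFC + IFC)` in `[-1, 1]` (positive = cross-frequency
#' coupling dominates).  COI is `NA` when no pair is significant.
#'
#' @param result A `coupling_result`, or an NMC matrix.
#' @param mask Significance mask (when `result` is a plain matrix).
#' @param fx,fy Grid frequencies (when `result` is a plain matrix).
#' @param include_high_order Include pairs of reduced order > 12?  `NULL`
#'   (default) keeps the setting stored in `result`.
#' @return Named vector `c(ifc, cfc, coi)`.
#' @export
coupling_summary <- function(result, mask = NULL, fx = NULL, fy = NULL,
                             include_high_order = NULL) {
  if (inherits(result, "coupling_result")) {
    mask <- result$mask
    fx <- result$fx
    fy <- result$fy
    nmcv <- result$nmc
    if (is.null(include_high_order)) include_high_order <- result$include_high_order
    if (!include_high_order) {
      mask <- mask & !result$high_order
    }
  } else {
    if (is.null(include_high_order)) include_high_order <- TRUE
    nmcv <- result
    if (is.null(mask) || is.null(fx) || is.null(fy)) {
      stop("mask, fx, fy are required with a plain NMC matrix")
    }
  }
  iso <- outer(fx, fy, "==")
  sig <- mask & !is.na(nmcv)
  ifc <- sum(nmcv[sig & iso])
  cfc <- sum(nmcv[sig & !iso])
  coi <- if (ifc + cfc > 0) (cfc - ifc) / (cfc + ifc) else NA_real_
  c(ifc = ifc, cfc = cfc, coi = coi)
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %d x %d pairs, %d epochs, FWER %.2f (alpha %.2e)\n",
              length(x$fx), length(x$fy), x$n_epochs, x$fwer, x$alpha))
  cat(sprintf("  significant pairs: %d (iso %d) | IFC %.3f CFC %.3f COI %s\n",
              sum(x$mask, na.rm = TRUE),
              sum(x$mask & outer(x$fx, x$fy, "=="), na.rm = TRUE),
              x$ifc, x$cfc,
              if (is.na(x$coi)) "undefined" else sprintf("%.3f", x$coi)))
  invisible(x)
}

#' Coupling analysis of a simulated pathway
#'
#' Computes the NMC map between the supraspinal input and the cumulative
#' spike train of a layer of a [simulate_pathway()] result.  The analysis-side
#' input is the noisy supraspinal signal: the common beta-band drive plus an
#' independent band-limited (1-100 Hz) noise realization at the configured
#' signal-to-noise ratio, regenerated per repetition (set
#' `x_noise = FALSE` for the clean common drive).
#'
#' @param sim A `pathway_sim`.
#' @param layer Layer selector (`"mn"` or an interneuron layer index).
#' @param x_noise Add the analysis-side noise realization to the input?
#' @param x_noise_seed Seed of that realization; defaults to a seed derived
#'   from the config seed and the simulation's noise repetition index.
#' @param ... Passed to [nmc_map()].
#' @return A `coupling_result`.
#' @export
coupling_analysis <- function(sim, layer = "mn", x_noise = TRUE,
                              x_noise_seed = NULL, ...) {
  X <- analysis_input(sim$input, sim$config, sim$noise_rep, x_noise, x_noise_seed)
  Y <- cumulative_spike_train(sim, layer = layer)
  nmc_map(X, Y, ...)
}

# The analysis-side X: clean common drive epochs, optionally diluted with an
# independent noise realization at the configured SNR.
analysis_input <- function(input_values, config, noise_rep = 1,
                           x_noise = TRUE, x_noise_seed = NULL) {
  X <- epoched_signal(input_values, config$fs, config$epoch_length)
  if (!x_noise) return(X)
  if (is.null(x_noise_seed)) {
    x_noise_seed <- derive_seed(config$seed, paste0("xnoise-", noise_rep))
  }
  nu <- generate_membrane_noise(config$fs, nrow(input_values),
                                config$epoch_length, seed = x_noise_seed,
                                neuron_id = 0)
  compose_injected_drive(X, nu, dc_level = 0, snr_db = config$snr_db)
}

#' Repeat the coupling analysis over independent noise realizations
#'
#' Re-runs the full simulate-couple chain `n_repetitions` times with a fresh
#' realization of every neuron's membrane noise (the common beta-band drive
#' and the topology stay fixed), and collects the per-repetition IFC, CFC and
#' COI.
#'
#' @param config A [pathway_config()].
#' @param calibration A `pathway_calibration`; computed on demand if `NULL`.
#' @param n_repetitions Number of noise realizations.
#' @param layer Output layer for the coupling (default: motoneuron pool).
#' @param n_surrogates Surrogates per pair for the thresholds.
#' @param seed Base seed for the surrogate permutations.
#' @param verbose Print progress?
#' @return `data.frame(repetition, ifc, cfc, coi, n_sig)` with attribute
#'   `summary` (mean and +/- 2 SD of each quantity).
#' @export
repeated_coupling_analysis <- function(config, calibration = NULL,
                                       n_repetitions = 100, layer = "mn",
                                       n_surrogates = 800, seed = NULL,
                                       verbose = FALSE) {
  if (is.null(calibration)) calibration <- calibrate_pathway(config)
  if (is.null(seed)) seed <- config$seed
  rows <- vector("list", n_repetitions)
  for (rep in seq_len(n_repetitions)) {
    sim <- simulate_pathway(config, calibration, noise_rep = rep)
    cr <- coupling_analysis(sim, layer = layer,
                            n_surrogates = n_surrogates,
                            seed = derive_seed(seed, paste0("surr-", rep)))
    rows[[rep]] <- data.frame(repetition = rep, ifc = unname(cr$ifc),
                              cfc = unname(cr$cfc), coi = unname(cr$coi),
                              n_sig = sum(cr$mask, na.rm = TRUE))
    if (verbose) {
      message(sprintf("rep %d: IFC %.3f CFC %.3f COI %s", rep,
                      cr$ifc, cr$cfc,
                      if (is.na(cr$coi)) "NA" else sprintf("%.3f", cr$coi)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    quantity = c("ifc", "cfc", "coi"),
    mean = c(mean(out$ifc), mean(out$cfc), mean(out$coi, na.rm = TRUE)),
    two_sd = c(2 * sd(out$ifc), 2 * sd(out$cfc), 2 * sd(out$coi, na.rm = TRUE)))
  out
}
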