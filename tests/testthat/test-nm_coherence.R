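# The generalized n:m coherence, its significance machinery and the
# IFC/CFC/COI summaries.

test_that("frequency ratios reduce to coprime (n, m) with f_X/f_Y = m/n", {
  expect_equal(reduce_ratio(8, 16), c(n = 2L, m = 1L))
  expect_equal(reduce_ratio(20, 20), c(n = 1L, m = 1L))
  expect_equal(reduce_ratio(15, 33), c(n = 11L, m = 5L))
  set.seed(1)
  for (i in 1:50) {
    fx <- sample(15:35, 1)
    fy <- sample(1:100, 1)
    k <- reduce_ratio(fx, fy)
    expect_equal(fx * k["n"], fy * k["m"], ignore_attr = TRUE)
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    expect_equal(g(k["n"], k["m"]), 1, ignore_attr = TRUE)
  }
})

test_that("the frequency-pair grid has exactly 2,100 coprime pairs", {
  grid <- frequency_pair_grid()
  expect_equal(nrow(grid), 2100)
  expect_true(all(grid$n >= 1 & grid$m >= 1))
  expect_equal(sum(grid$iso), 21)
  g <- mapply(function(a, b) { r <- function(x, y) if (y == 0) x else r(y, x %% y); r(a, b) },
              grid$n, grid$m)
  expect_true(all(g == 1))
})

test_that("epoch spectra: integer-cycle cosine, Parseval, linearity", {
  t <- (0:999) / 1000
  x <- epoched_signal(matrix(cos(2 * pi * 20 * t), 1, 1000, byrow = TRUE))
  sp <- epoch_spectra(x)
  f <- attr(sp, "freqs")
  expect_equal(Mod(sp[1, f == 20]), 500)  # n/2 for a unit cosine
  expect_lt(max(Mod(sp[1, f != 20])), 1e-10)
  set.seed(5)
  y <- matrix(rnorm(3 * 1000), 3)
  ys <- epoched_signal(y)
  spy <- epoch_spectra(ys)
  # Parseval on the demeaned signal (all bins including Nyquist and >fs/2
  # are needed for exact equality; compare over the full fft instead)
  yd <- y - rowMeans(y)
  full <- stats::mvfft(t(yd))
  expect_equal(colSums(Mod(full)^2) / 1000, rowSums(yd^2),
               tolerance = 1e-8)
  # linearity
  z <- matrix(rnorm(3 * 1000), 3)
  both <- epoch_spectra(epoched_signal(2.5 * y + 4 * z))
  expect_equal(both, 2.5 * epoch_spectra(ys) + 4 * epoch_spectra(epoched_signal(z)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(epoch_spectra(epoched_signal(y, fs = 500, epoch_length = 2)),
               NA)  # consistent layout is fine
})

test_that("NMC is 1 for identical signals and constructed phase-locked pairs", {
  fx <- make_coupling_fixtures("identical", epochs = 60, seed = 2)
  expect_equal(nmc(fx$x, fx$y, 20, 20), 1, tolerance = 1e-12)
  expect_equal(nmc(fx$x, fx$y, 31, 31), 1, tolerance = 1e-12)
  # phase-locked (n, m) = (2, 1) at f0 = 10, f1 = 20
  fb <- make_coupling_fixtures("phase_locked", f0 = 10, f1 = 20, epochs = 80, seed = 3)
  expect_equal(nmc(fb$x, fb$y, 10, 20), 1, tolerance = 1e-10)
  # also at a non-harmonic pair: f0 = 10, f1 = 15 -> (n, m) = (3, 2)
  fc <- make_coupling_fixtures("phase_locked", f0 = 10, f1 = 15, epochs = 80, seed = 4)
  expect_equal(nmc(fc$x, fc$y, 10, 15), 1, tolerance = 1e-10)
})

test_that("NMC agrees with a brute-force moment computation", {
  set.seed(9)
  x <- epoched_signal(matrix(rnorm(40 * 1000), 40))
  y <- epoched_signal(matrix(rnorm(40 * 1000), 40))
  for (pair in list(c(20, 20), c(10, 20), c(15, 33))) {
    fx <- pair[1]; fy <- pair[2]
    # independent path: raw fft, no shared helpers
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    d <- g(fx, fy)
    n <- fy / d; m <- fx / d
    xb <- apply(x$values - rowMeans(x$values), 1, function(r) fft(r)[fx + 1])
    yb <- apply(y$values - rowMeans(y$values), 1, function(r) fft(r)[fy + 1])
    u <- (xb / sqrt(mean(Mod(xb)^2)))^n
    v <- (yb / sqrt(mean(Mod(yb)^2)))^m
    want <- Mod(mean(u * Conj(v))) / sqrt(mean(Mod(u)^2) * mean(Mod(v)^2))
    expect_equal(nmc(x, y, fx, fy), want, tolerance = 1e-10)
  }
})

test_that("NMC is invariant to global amplitude scaling and bounded by 1", {
  set.seed(12)
  x <- epoched_signal(matrix(rnorm(30 * 1000), 30))
  y <- epoched_signal(matrix(rnorm(30 * 1000), 30))
  base <- nmc(x, y, 20, 40)
  y2 <- epoched_signal(y$values * 3.7)
  expect_equal(nmc(x, y2, 20, 40), base, tolerance = 1e-10)
  x2 <- epoched_signal(x$values * 0.037)
  expect_equal(nmc(x2, y, 20, 40), base, tolerance = 1e-10)
  # Cauchy-Schwarz bound over many random pairs and the full grid
  m <- nmc_map(x, y, n_surrogates = 0)
  expect_true(all(m$nmc <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(m$nmc >= 0, na.rm = TRUE))
})

test_that("iso-frequency NMC equals the square root of classical coherence", {
  set.seed(20)
  L <- 50
  s <- matrix(rnorm(L * 1000), L)
  y <- 0.5 * s + matrix(rnorm(L * 1000), L)
  X <- epoched_signal(s)
  Y <- epoched_signal(y)
  for (f in c(10, 20, 35)) {
    # independent classical magnitude-squared coherence over epochs
    xb <- apply(s - rowMeans(s), 1, function(r) fft(r)[f + 1])
    yb <- apply(y - rowMeans(y), 1, function(r) fft(r)[f + 1])
    msc <- Mod(mean(xb * Conj(yb)))^2 / (mean(Mod(xb)^2) * mean(Mod(yb)^2))
    expect_equal(nmc(X, Y, f, f), sqrt(msc), tolerance = 1e-8)
  }
})

test_that("independent signals: null level and dispersion of iso NMC", {
  set.seed(30)
  L <- 200
  vals <- replicate(40, {
    x <- epoched_signal(matrix(rnorm(L * 1000), L))
    y <- epoched_signal(matrix(rnorm(L * 1000), L))
    nmc(x, y, sample(15:35, 1), sample(15:35, 1))
  })
  # complex-Gaussian null: E|z| = sqrt(pi / (4 L))
  expect_equal(mean(vals), sqrt(pi / (4 * L)), tolerance = 0.25)
  expect_lt(quantile(vals, 0.95), 0.2)
})

test_that("per-pair thresholds: level, epoch monotonicity, R/C++ agreement", {
  alpha <- 0.05 / 2100
  expect_equal(alpha, 2.380952e-05, tolerance = 1e-6)
  set.seed(40)
  thr_by_L <- sapply(c(50, 100, 200), function(L) {
    u <- complex(real = rnorm(L), imaginary = rnorm(L))
    v <- complex(real = rnorm(L), imaginary = rnorm(L))
    significance_threshold(u, v, alpha, n_surrogates = 600, seed = 1)
  })
  expect_true(all(diff(thr_by_L) < 0))
  # same tail model as the compiled path: compare on one pair
  set.seed(41)
  x <- epoched_signal(matrix(rnorm(60 * 1000), 60))
  y <- epoched_signal(matrix(rnorm(60 * 1000), 60))
  m <- nmc_map(x, y, fx = 20L, fy = 20L, n_pairs = 2100,
               threshold = "permutation", n_surrogates = 500, seed = 7)
  xb <- epoch_spectra(x, 20)[, 1]
  yb <- epoch_spectra(y, 20)[, 1]
  # same permutations cannot be reproduced across implementations (different
  # RNG streams), so compare at coarse tolerance
  thr_r <- significance_threshold(xb / sqrt(mean(Mod(xb)^2)),
                                  yb / sqrt(mean(Mod(yb)^2)),
                                  0.05 / 2100, n_surrogates = 500, seed = 8)
  expect_equal(unname(m$threshold[1, 1]), unname(thr_r), tolerance = 0.15)
})

# The family-wise error-rate calibration on synthetic null runs lives in
# test-acceptance.R (it implements that acceptance criterion directly).

test_that("coupling summaries follow the COI arithmetic", {
  nmcv <- matrix(0, 2, 3, dimnames = list(c(10, 20), c(10, 20, 30)))
  fx <- c(10L, 20L)
  fy <- c(10L, 20L, 30L)
  nmcv[1, 1] <- 0.4            # iso 10-10
  nmcv[1, 2] <- 0.1            # cross
  nmcv[2, 3] <- 0.2            # cross
  mask <- nmcv > 0
  s <- coupling_summary(nmcv, mask, fx, fy)
  expect_equal(unname(s["ifc"]), 0.4)
  expect_equal(unname(s["cfc"]), 0.3)
  expect_equal(unname(s["coi"]), -1 / 7)
  # bounds
  mask_iso_only <- mask & outer(fx, fy, "==")
  expect_equal(unname(coupling_summary(nmcv, mask_iso_only, fx, fy)["coi"]), -1)
  mask_cross_only <- mask & !outer(fx, fy, "==")
  expect_equal(unname(coupling_summary(nmcv, mask_cross_only, fx, fy)["coi"]), 1)
  # CFC = IFC > 0 gives 0
  nm2 <- nmcv
  nm2[2, 2] <- 0.3
  nm2[1, 2] <- 0.3
  mk <- matrix(FALSE, 2, 3)
  mk[2, 2] <- TRUE
  mk[1, 2] <- TRUE
  expect_equal(unname(coupling_summary(nm2, mk, fx, fy)["coi"]), 0)
  # nothing significant: undefined, never zero
  expect_true(is.na(coupling_summary(nmcv, nmcv > 1, fx, fy)["coi"]))
})

test_that("high-order pairs are flagged and excludable from the sums", {
  set.seed(60)
  x <- epoched_signal(matrix(rnorm(30 * 1000), 30))
  y <- epoched_signal(matrix(rnorm(30 * 1000), 30))
  m <- nmc_map(x, y, fx = c(15L, 20L), fy = c(33L, 40L), n_surrogates = 100, seed = 2)
  expect_false(m$high_order[1, 1])   # 15 vs 33 -> (n, m) = (11, 5)
  expect_true(m$high_order[2, 1])    # 20 vs 33 -> (n, m) = (33, 20)
  m2 <- nmc_map(x, y, fx = 15L, fy = 34L, n_surrogates = 50, seed = 2)
  expect_true(m2$n[1, 1] == 34 && m2$high_order[1, 1])
  # excluding high-order pairs changes only the cross sums
  s_in <- coupling_summary(m, include_high_order = TRUE)
  s_ex <- coupling_summary(m, include_high_order = FALSE)
  expect_lte(s_ex["cfc"], s_in["cfc"])
})
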