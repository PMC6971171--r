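# Biophysics of the two neuron classes: current equations, gating kinetics,
# calcium dynamics, compartment coupling, synaptic conductances.

mn_par <- neuron_params("motoneuron")
in_par <- neuron_params("interneuron")

test_that("K(Ca) activation follows the saturating form", {
  expect_identical(kca_activation(0, 0.2), 0)
  expect_identical(kca_activation(0.2, 0.2), 0.5)
  expect_equal(kca_activation(999 * 0.2, 0.2), 0.999)
  expect_error(kca_activation(-1, 0.2), "negative Ca")
  expect_error(kca_activation(0.1, 0), "K_d")
})

test_that("calcium kinetics: fixed points and closed-form decay", {
  expect_identical(calcium_derivative(0, 0, mn_par), 0)
  # steady state at clamped current: Ca* = -alpha I / k_Ca
  I <- -2.5
  ca_star <- -mn_par$alpha_ca * I / mn_par$k_Ca
  expect_equal(calcium_derivative(ca_star, I, mn_par), 0, tolerance = 1e-12)
  # zero-current decay matches Ca0 exp(-f k t) (exact update of a linear ODE)
  ca0 <- 1.3
  dt <- 0.01
  ca <- ca0
  for (i in 1:5000) ca <- ca + dt * calcium_derivative(ca, 0, mn_par)
  t_end <- 5000 * dt
  # forward Euler at dt = 0.01 carries O(dt * rate) relative error
  expect_equal(ca, ca0 * exp(-mn_par$f_ca * mn_par$k_Ca * t_end), tolerance = 5e-3)
})

test_that("gating kinetics stay within bounds over the physiological range", {
  v <- seq(-100, 60, by = 0.5)
  for (par in list(mn_par, in_par)) {
    kin <- gating_kinetics(par)
    for (g in names(kin)) {
      inf <- kin[[g]]$inf(v)
      tau <- kin[[g]]$tau(v)
      expect_true(all(inf >= 0 & inf <= 1), info = g)
      expect_true(all(tau > 0), info = g)
    }
  }
})

test_that("gating derivative: fixed point, monotone approach, closed form", {
  kin <- gating_kinetics(mn_par)
  for (g in c("h_Na", "m_K", "m_CaN")) {
    v <- -48
    x_inf <- kin[[g]]$inf(v)
    expect_equal(gating_derivative(x_inf, v, kin, g), 0, tolerance = 1e-14)
    # sign of dx/dt equals sign of (x_inf - x)
    for (x in c(0.05, 0.5, 0.95)) {
      expect_equal(sign(gating_derivative(x, v, kin, g)), sign(x_inf - x))
    }
  }
  # clamped-V relaxation matches x_inf + (x0 - x_inf) exp(-t / tau)
  g <- "h_Na"
  v <- -50
  x0 <- 0.1
  tau <- kin[[g]]$tau(v)
  x_inf <- kin[[g]]$inf(v)
  dt <- 0.01
  a <- 1 - exp(-dt / tau)
  x <- x0
  for (i in 1:2000) x <- x + (x_inf - x) * a
  expect_equal(x, x_inf + (x0 - x_inf) * exp(-2000 * dt / tau), tolerance = 1e-6)
  expect_error(gating_derivative(0.5, -50, kin, "no_such_gate"), "unknown")
})

test_that("compartment coupling conserves charge and decouples at g_C = 0", {
  expect_equal(coupling_currents(-60, -60, 0.1, 0.1)$I_C_soma, 0)
  expect_equal(coupling_currents(-60, -60, 0.1, 0.1)$I_C_dendrite, 0)
  set.seed(11)
  for (i in 1:50) {
    vs <- runif(1, -90, 40)
    vd <- runif(1, -90, 40)
    p <- runif(1, 0.05, 0.95)
    cc <- coupling_currents(vs, vd, 0.1, p)
    expect_equal(p * cc$I_C_soma + (1 - p) * cc$I_C_dendrite, 0, tolerance = 1e-12)
  }
  cc0 <- coupling_currents(-40, -70, 0, 0.1)
  expect_equal(unlist(cc0), c(I_C_soma = 0, I_C_dendrite = 0))
  expect_error(coupling_currents(-60, -60, 0.1, 1.2), "p must be in")
})

test_that("synaptic conductance decays exponentially and superposes", {
  expect_equal(synaptic_current(0.01, mn_par$E_SynE, mn_par$E_SynE), 0)
  g0 <- 0.02
  expect_equal(synaptic_update(g0, 5, 5), g0 / exp(1), tolerance = 1e-12)
  # two spikes at t = 0 and t = 5 ms: value at 5 ms (after the second spike)
  # equals the brute-force sum of two shifted exponentials
  g <- synaptic_update(synaptic_update(0, 0, 5, g0), 5, 5, g0)
  brute <- g0 * exp(-5 / 5) + g0 * exp(0)
  expect_equal(g, brute, tolerance = 1e-12)
  # linear superposition at arbitrary offsets
  times <- c(0, 1.7, 3.2)
  t_eval <- 7.5
  brute <- sum(g0 * exp(-(t_eval - times) / 5))
  g <- 0
  prev <- 0
  for (tt in times) {
    g <- synaptic_update(g, tt - prev, 5, g0)
    prev <- tt
  }
  g <- synaptic_update(g, t_eval - prev, 5)
  expect_equal(g, brute, tolerance = 1e-12)
  expect_error(synaptic_current(-0.1, -60, 0), ">= 0")
})

test_that("ionic currents vanish at their reversal potentials and with closed gates", {
  st <- neuron_state(mn_par)
  st$V_S <- mn_par$E_Na
  cur <- ionic_currents(st, mn_par, "soma")
  expect_equal(cur$I_Na, 0)
  st$V_D <- mn_par$E_Na
  expect_equal(ionic_currents(st, mn_par, "dendrite")$I_NaP, 0)
  # all gating variables zero (and no residual calcium): only the leak survives
  st0 <- neuron_state(mn_par, V = -55)
  for (g in c("m_Na", "h_Na", "m_K", "m_CaN", "h_CaN", "m_CaN_D", "h_CaN_D",
              "m_CaL", "m_NaP", "h_NaP")) st0[[g]] <- 0
  st0$Ca_S <- 0
  st0$Ca_D <- 0
  cur <- ionic_currents(st0, mn_par, "soma")
  expect_equal(cur$I_Na, 0)
  expect_equal(cur$I_K, 0)
  expect_equal(cur$I_CaN, 0)
  expect_equal(cur$I_KCa, 0)  # Ca = 0
  expect_equal(cur$I_L, mn_par$g_L * (-55 - mn_par$E_L))
  expect_error(ionic_currents(neuron_state(in_par), in_par, "dendrite"),
               "no dendritic compartment")
})

# Independent formula transcription: every current and state derivative of the
# motoneuron written out directly, sharing no code with the package.
oracle_mn_deriv <- function(s, p, I_inject = 0) {
  sig <- function(V, v12, k) 1 / (1 + exp((V - v12) / k))
  tau_biexp <- function(V, sc, v0, k1, k2) sc / (exp((V - v0) / k1) + exp(-(V - v0) / k2))
  VS <- s$V_S; VD <- s$V_D
  INa <- p$g_Na * s$m_Na^3 * s$h_Na * (VS - p$E_Na)
  IK <- p$g_K * s$m_K^4 * (VS - p$E_K)
  ICaN_S <- p$g_CaN_S * s$m_CaN^2 * s$h_CaN * (VS - p$E_Ca)
  IKCa_S <- p$g_KCa_S * (s$Ca_S / (s$Ca_S + p$K_d)) * (VS - p$E_K)
  IL_S <- p$g_L * (VS - p$E_L)
  ICS <- p$g_C / p$p * (VD - VS)
  ISyn <- s$g_syn * (VS - p$E_SynE)
  INaP <- p$g_NaP * s$m_NaP * s$h_NaP * (VD - p$E_Na)
  ICaN_D <- p$g_CaN_D * s$m_CaN_D^2 * s$h_CaN_D * (VD - p$E_Ca)
  ICaL <- p$g_CaL * s$m_CaL * (VD - p$E_Ca)
  IKCa_D <- p$g_KCa_D * (s$Ca_D / (s$Ca_D + p$K_d)) * (VD - p$E_K)
  IL_D <- p$g_L * (VD - p$E_L)
  ICD <- p$g_C / (1 - p$p) * (VS - VD)
  list(
    V_S = (-INa - IK - ICaN_S - IKCa_S - IL_S + ICS - ISyn + I_inject) / p$C,
    V_D = (-INaP - ICaN_D - ICaL - IKCa_D - IL_D + ICD) / p$C,
    m_Na = (sig(VS, p$mNa_V12, p$mNa_k) - s$m_Na) / p$mNa_tau,
    h_Na = (sig(VS, p$hNa_V12, p$hNa_k) - s$h_Na) /
      tau_biexp(VS, p$hNa_tau_scale, p$hNa_tau_V, p$hNa_tau_k1, p$hNa_tau_k2),
    m_K = (sig(VS, p$mK_V12, p$mK_k) - s$m_K) /
      tau_biexp(VS, p$mK_tau_scale, p$mK_tau_V, p$mK_tau_k1, p$mK_tau_k2),
    m_CaN = (sig(VS, p$mCaN_V12, p$mCaN_k) - s$m_CaN) / p$mCaN_tau,
    h_CaN = (sig(VS, p$hCaN_V12, p$hCaN_k) - s$h_CaN) / p$hCaN_tau,
    m_CaN_D = (sig(VD, p$mCaN_V12, p$mCaN_k) - s$m_CaN_D) / p$mCaN_tau,
    h_CaN_D = (sig(VD, p$hCaN_V12, p$hCaN_k) - s$h_CaN_D) / p$hCaN_tau,
    m_CaL = (sig(VD, p$mCaL_V12, p$mCaL_k) - s$m_CaL) / p$mCaL_tau,
    m_NaP = (sig(VD, p$mNaP_V12, p$mNaP_k) - s$m_NaP) / p$mNaP_tau,
    h_NaP = (sig(VD, p$hNaP_V12, p$hNaP_k) - s$h_NaP) /
      (p$hNaP_tau_max / cosh((VD - p$hNaP_tau_V) / p$hNaP_tau_k)),
    Ca_S = -p$f_ca * (p$alpha_ca * ICaN_S + p$k_Ca * s$Ca_S),
    Ca_D = -p$f_ca * (p$alpha_ca * (ICaN_D + ICaL) + p$k_Ca * s$Ca_D),
    g_syn = -s$g_syn / p$tau_synE
  )
}

test_that("motoneuron state derivative matches an independent transcription", {
  set.seed(21)
  for (i in 1:100) {
    st <- neuron_state(mn_par)
    st$V_S <- runif(1, -90, 40)
    st$V_D <- runif(1, -90, 40)
    for (g in c("m_Na", "h_Na", "m_K", "m_CaN", "h_CaN", "m_CaN_D", "h_CaN_D",
                "m_CaL", "m_NaP", "h_NaP")) st[[g]] <- runif(1)
    st$Ca_S <- runif(1, 0, 2)
    st$Ca_D <- runif(1, 0, 2)
    st$g_syn <- runif(1, 0, 0.1)
    I <- runif(1, -5, 15)
    got <- membrane_derivatives(st, mn_par, I)
    want <- oracle_mn_deriv(st, mn_par, I)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, info = f)
    }
  }
})

test_that("interneuron derivative contains only Na, K, leak and synaptic terms", {
  st <- neuron_state(in_par, V = -55)
  st$g_syn <- 0.02
  d <- membrane_derivatives(st, in_par, I_inject = 1.5)
  p <- in_par
  INa <- p$g_Na * st$m_Na^3 * st$h_Na * (st$V_S - p$E_Na)
  IK <- p$g_K * st$m_K^4 * (st$V_S - p$E_K)
  IL <- p$g_L * (st$V_S - p$E_L)
  ISyn <- st$g_syn * (st$V_S - p$E_SynE)
  expect_equal(d$V_S, (-INa - IK - IL - ISyn + 1.5) / p$C, tolerance = 1e-12)
  expect_setequal(names(d), c("V_S", "m_Na", "h_Na", "m_K", "g_syn"))
})

test_that("leak-only limit relaxes exponentially to E_L with tau = C / g_L", {
  par <- neuron_params("interneuron", overrides = list(g_Na = 0, g_K = 0))
  r <- nmcoupling:::simulate_layer(par, E_L = -64, n_ms = 60, dt = 0.025,
                                   record_every = 1L)
  # start the trace from a displaced potential by injecting a brief pulse is
  # unnecessary: start at E_L gives a flat line; instead override E_L of the
  # state via a different resting point
  v <- r$V[, 1]
  expect_true(all(abs(v - (-64)) < 1e-9))
  # displaced start: run with E_L = -64 but a constant injected current, then
  # check the approach to the shifted equilibrium with tau = C / g_L
  tau <- par$C / par$g_L
  r2 <- nmcoupling:::simulate_layer(par, E_L = -64, n_ms = 60, dt = 0.025,
                                    dc = 2, record_every = 1L)
  v2 <- r2$V[, 1]
  v_inf <- -64 + 2 / par$g_L
  t <- (seq_along(v2)) * 0.025
  expect_equal(v2, v_inf + (-64 - v_inf) * exp(-t / tau), tolerance = 1e-3)
})

test_that("interneuron F-I curve is monotone and matches a peak-finding oracle", {
  rates <- sapply(c(4, 6, 10), function(dc) {
    r <- nmcoupling:::simulate_layer(neuron_params("interneuron"), -64, 2000,
                                     dc = dc, record_every = 1L)
    v <- r$V[, 1]
    # oracle: count local maxima above 0 mV
    peaks <- sum(v[2:(length(v) - 1)] > 0 &
                   diff(sign(diff(v))) == -2 & v[2:(length(v) - 1)] ==
                   pmax(v[2:(length(v) - 1)], v[1:(length(v) - 2)]))
    n_det <- length(r$spike_step)
    expect_equal(n_det, sum(v[-1] >= 0 & v[-length(v)] < 0), tolerance = 0)
    n_det / 2
  })
  expect_true(all(diff(rates) > 0))
})

test_that("gating variables and calcium stay bounded along a driven trajectory", {
  # integrate the R-side derivative directly (forward Euler on gates is not
  # used by the engine, so integrate with small dt) for a driven motoneuron
  par <- mn_par
  st <- neuron_state(par, V = -60)
  dt <- 0.01
  gates <- c("m_Na", "h_Na", "m_K", "m_CaN", "h_CaN", "m_CaN_D", "h_CaN_D",
             "m_CaL", "m_NaP", "h_NaP")
  ok <- TRUE
  for (i in 1:20000) {
    d <- membrane_derivatives(st, par, I_inject = 6)
    for (f in names(d)) st[[f]] <- st[[f]] + dt * d[[f]]
    if (any(unlist(st[gates]) < -1e-9) || any(unlist(st[gates]) > 1 + 1e-9) ||
        st$Ca_S < -1e-12 || st$Ca_D < -1e-12) {
      ok <- FALSE
      break
    }
  }
  expect_true(ok)
})

test_that("halving dt changes a subthreshold 1-s trajectory by < 0.5 mV RMS", {
  par <- neuron_params("motoneuron")
  set.seed(3)
  drive <- rnorm(1000, mean = 0.5, sd = 0.6)  # subthreshold noisy drive at 1 kHz
  vs <- lapply(c(0.025, 0.0125), function(dt) {
    r <- nmcoupling:::simulate_layer(par, -60, 1000, dt = dt, dc = 0,
                                     common = drive,
                                     record_every = as.integer(round(1 / dt)))
    r$V[, 1]
  })
  expect_lt(sqrt(mean((vs[[1]] - vs[[2]])^2)), 0.5)
})

test_that("doubling integration substeps changes a 10-s spike count by < 2%", {
  par <- neuron_params("interneuron")
  set.seed(4)
  drive <- rnorm(10000, 0, 1.2)
  # a firmly suprathreshold operating point gives several hundred spikes, so
  # the 2% bound is not dominated by single-spike granularity
  n <- sapply(c(0.025, 0.0125), function(dt) {
    r <- nmcoupling:::simulate_layer(par, -62, 10000, dt = dt, dc = 4,
                                     common = drive)
    length(r$spike_step)
  })
  expect_gt(n[2], 300)
  expect_lt(abs(n[1] - n[2]) / n[2], 0.02)
})

test_that("with PIC and Ca conductances off and strong coupling, the motoneuron
           approaches the single-compartment Na/K/L model", {
  # strong (but numerically integrable) coupling: dt * g_C/p / C stays small
  # enough for the per-compartment exponential update; the true g_C -> Inf
  # limit would need a joint implicit solve of the voltage pair (see the
  # methods vignette)
  par2 <- neuron_params("motoneuron",
                        overrides = list(g_NaP = 0, g_CaN_S = 0, g_CaN_D = 0,
                                         g_CaL = 0, g_KCa_S = 0, g_KCa_D = 0,
                                         g_C = 10, E_L = -64))
  # the fused cell spreads the somatic quantities over the whole surface:
  # the single-compartment equivalent carries area-weighted conductances
  # p * g and receives p * I
  par1 <- neuron_params("interneuron",
                        overrides = list(g_Na = par2$p * par2$g_Na,
                                         g_K = par2$p * par2$g_K,
                                         E_L = -64))
  I <- 100
  r2 <- nmcoupling:::simulate_layer(par2, -64, 3000, dc = I, record_every = 1L)
  r1 <- nmcoupling:::simulate_layer(par1, -64, 3000, dc = par2$p * I)
  # the diluted Na density makes small spikes: detect at -20 mV for both
  sp2 <- detect_spikes(r2$V[, 1], 40000, threshold = -20)
  rate2 <- sum(sp2 * 0.025 > 500) / 2.5
  rate1 <- sum(r1$spike_step * 0.025 > 500) / 2.5
  expect_gt(rate1, 5)  # tonic spiking preserved
  expect_gt(rate2, 5)
  expect_lt(abs(rate2 - rate1) / rate1, 0.15)
})
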