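#' @useDynLib nmcoupling, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile fft mvfft aggregate cor
#' @importFrom utils write.csv modifyList
NULL

# Boltzmann sigmoid; negative slope k yields an increasing (activation) curve.
boltzmann <- function(V, V12, k) 1 / (1 + exp((V - V12) / k))

#' Voltage-dependent gating kinetics for a neuron class
#'
#' Returns, for every gating variable of the class, the steady-state curve
#' `inf(V)` and the time-constant curve `tau(V)` implied by the parameter set.
#' All gates obey first-order relaxation `tau(V) dx/dt = inf(V) - x`.
#'
#' @param params A [neuron_params()] object.
#' @return Named list of gates, each `list(inf = function(V), tau = function(V))`,
#'   with class `gating_kinetics`.
#' @export
gating_kinetics <- function(params) {
  p <- params
  bi_exp_tau <- function(scale, V0, k1, k2) {
    function(V) scale / (exp((V - V0) / k1) + exp(-(V - V0) / k2))
  }
  const_tau <- function(tau) function(V) rep(tau, length.out = length(V))
  gates <- list(
    m_Na = list(inf = function(V) boltzmann(V, p$mNa_V12, p$mNa_k),
                tau = const_tau(p$mNa_tau)),
    h_Na = list(inf = function(V) boltzmann(V, p$hNa_V12, p$hNa_k),
                tau = bi_exp_tau(p$hNa_tau_scale, p$hNa_tau_V,
                                 p$hNa_tau_k1, p$hNa_tau_k2)),
    m_K  = list(inf = function(V) boltzmann(V, p$mK_V12, p$mK_k),
                tau = bi_exp_tau(p$mK_tau_scale, p$mK_tau_V,
                                 p$mK_tau_k1, p$mK_tau_k2))
  )
  if (p$n_compartments == 2) {
    gates <- c(gates, list(
      m_CaN = list(inf = function(V) boltzmann(V, p$mCaN_V12, p$mCaN_k),
                   tau = const_tau(p$mCaN_tau)),
      h_CaN = list(inf = function(V) boltzmann(V, p$hCaN_V12, p$hCaN_k),
                   tau = const_tau(p$hCaN_tau)),
      m_CaL = list(inf = function(V) boltzmann(V, p$mCaL_V12, p$mCaL_k),
                   tau = const_tau(p$mCaL_tau)),
      m_NaP = list(inf = function(V) boltzmann(V, p$mNaP_V12, p$mNaP_k),
                   tau = const_tau(p$mNaP_tau)),
      h_NaP = list(inf = function(V) boltzmann(V, p$hNaP_V12, p$hNaP_k),
                   tau = function(V) p$hNaP_tau_max / cosh((V - p$hNaP_tau_V) / p$hNaP_tau_k))
    ))
  }
  structure(gates, class = "gating_kinetics")
}

#' Instantaneous calcium-dependent potassium activation
#'
#' Saturating activation of the K(Ca) conductance by intracellular calcium,
#' `m = Ca / (Ca + K_d)`.
#'
#' @param Ca Intracellular calcium concentration (uM), `>= 0`.
#' @param K_d Half-saturation concentration (uM), `> 0`.
#' @return Activation in `[0, 1]`.
#' @export
kca_activation <- function(Ca, K_d) {
  if (any(Ca < 0)) stop("negative Ca concentration: corrupted state")
  if (any(K_d <= 0)) stop("K_d must be > 0")
  Ca / (Ca + K_d)
}

#' Intracellular calcium concentration derivative
#'
#' `d[Ca]/dt = -f * (alpha * I_Ca + k_Ca * [Ca])`, where `I_Ca` is the total
#' calcium-carrying current of the compartment (inward currents are negative,
#' so inward flux raises the concentration).
#'
#' @param Ca Calcium concentration (uM), `>= 0`.
#' @param I_Ca_total Sum of Ca currents of the compartment (uA/cm^2).
#' @param params A [neuron_params()] object (uses `f_ca`, `alpha_ca`, `k_Ca`).
#' @return d\[Ca\]/dt in uM/ms.
#' @export
calcium_derivative <- function(Ca, I_Ca_total, params) {
  if (any(Ca < 0)) stop("negative Ca concentration: corrupted state")
  -params$f_ca * (params$alpha_ca * I_Ca_total + params$k_Ca * Ca)
}

#' Gating variable derivative
#'
#' First-order relaxation toward the voltage-dependent steady state:
#' `dx/dt = (x_inf(V) - x) / tau(V)`.
#'
#' @param x Current gating value in `[0, 1]`.
#' @param V Membrane potential (mV).
#' @param kinetics A [gating_kinetics()] object.
#' @param channel Gate name, e.g. `"h_Na"`.
#' @return dx/dt in 1/ms.
#' @export
gating_derivative <- function(x, V, kinetics, channel) {
  g <- kinetics[[channel]]
  if (is.null(g)) stop("unknown gating variable: ", channel)
  (g$inf(V) - x) / g$tau(V)
}

#' Soma-dendrite coupling currents
#'
#' `I_C(S) = g_C/p (V_D - V_S)` and `I_C(D) = g_C/(1-p) (V_S - V_D)`, where
#' `p` is the ratio of somatic to total membrane surface area.  The surface
#' weighting conserves charge: `p I_C(S) + (1-p) I_C(D) = 0`.
#'
#' @param V_S,V_D Somatic and dendritic potentials (mV).
#' @param g_C Coupling conductance (mS/cm^2).
#' @param p Somatic-to-total surface ratio, in `(0, 1)`.
#' @return Named list `I_C_soma`, `I_C_dendrite` (uA/cm^2).
#' @export
coupling_currents <- function(V_S, V_D, g_C, p) {
  if (p <= 0 || p >= 1) stop("somatic surface ratio p must be in (0, 1)")
  list(I_C_soma = g_C / p * (V_D - V_S),
       I_C_dendrite = g_C / (1 - p) * (V_S - V_D))
}

#' Synaptic current and conductance decay
#'
#' Excitatory synapses are conductance-based with instantaneous rise and
#' exponential decay: an arriving spike increments the synaptic conductance by
#' its (calibrated) peak value, between spikes the conductance decays with
#' time constant `tau_synE`, and the current is
#' `I_SynE = g_syn * (V - E_SynE)`.  Multiple inputs superpose linearly.
#'
#' @param g_syn Instantaneous synaptic conductance (mS/cm^2), `>= 0`.
#' @param V Membrane potential (mV).
#' @param E_SynE Excitatory reversal potential (mV).
#' @return Current in uA/cm^2.
#' @export
synaptic_current <- function(g_syn, V, E_SynE) {
  if (any(g_syn < 0)) stop("synaptic conductance must be >= 0")
  g_syn * (V - E_SynE)
}

#' @rdname synaptic_current
#' @param dt Elapsed time (ms).
#' @param tau_synE Synaptic decay time constant (ms).
#' @param incoming_spike_weight Summed peak conductance of spikes arriving at
#'   the end of the interval (mS/cm^2).
#' @return Updated conductance.
#' @export
synaptic_update <- function(g_syn, dt, tau_synE, incoming_spike_weight = 0) {
  g_syn * exp(-dt / tau_synE) + incoming_spike_weight
}

#' Resting neuron state
#'
#' Builds a `neuron_state` with all compartments at the leak potential and all
#' gating variables at their steady state for that potential; calcium and
#' synaptic conductance start at zero.
#'
#' @param params A [neuron_params()] object.
#' @param V Initial potential (mV); defaults to `params$E_L`.
#' @return Named list of state variables with class `neuron_state`.
#' @export
neuron_state <- function(params, V = params$E_L) {
  kin <- gating_kinetics(params)
  st <- list()
  if (params$n_compartments == 2) {
    st$V_S <- V
    st$V_D <- V
  } else {
    st$V_S <- V
  }
  for (g in names(kin)) st[[g]] <- kin[[g]]$inf(V)
  if (params$n_compartments == 2) {
    # the CaN gate pair exists once per compartment, tracking that
    # compartment's voltage
    st$m_CaN_D <- kin$m_CaN$inf(V)
    st$h_CaN_D <- kin$h_CaN$inf(V)
    # calcium starts at the fixed point of its kinetics for the resting Ca
    # currents (keeps the K(Ca) stabilization engaged from the first step)
    p <- params
    i_can_s <- p$g_CaN_S * st$m_CaN^2 * st$h_CaN * (V - p$E_Ca)
    i_ca_d <- p$g_CaN_D * st$m_CaN_D^2 * st$h_CaN_D * (V - p$E_Ca) +
      p$g_CaL * st$m_CaL * (V - p$E_Ca)
    st$Ca_S <- max(0, -p$alpha_ca * i_can_s / p$k_Ca)
    st$Ca_D <- max(0, -p$alpha_ca * i_ca_d / p$k_Ca)
  }
  st$g_syn <- 0
  structure(st, class = "neuron_state")
}

#' Ionic currents of one compartment
#'
#' Evaluates the Hodgkin-Huxley current equations for the requested
#' compartment.  The soma carries `I_Na`, `I_K`, and (motoneurons only)
#' `I_CaN` and `I_KCa`; the motoneuron dendrite carries `I_NaP`, `I_CaN`,
#' `I_CaL` and `I_KCa`; both carry the leak `I_L`.  Interneurons have no
#' dendrite.
#'
#' @param state A [neuron_state()] object.
#' @param params A [neuron_params()] object.
#' @param compartment `"soma"` or `"dendrite"`.
#' @return Named list of currents (uA/cm^2).
#' @export
ionic_currents <- function(state, params, compartment = c("soma", "dendrite")) {
  compartment <- match.arg(compartment)
  p <- params
  if (compartment == "dendrite" && p$n_compartments == 1) {
    stop("interneurons have no dendritic compartment")
  }
  if (compartment == "soma") {
    V <- state$V_S
    out <- list(
      I_Na = p$g_Na * state$m_Na^3 * state$h_Na * (V - p$E_Na),
      I_K  = p$g_K * state$m_K^4 * (V - p$E_K),
      I_L  = p$g_L * (V - p$E_L)
    )
    if (p$n_compartments == 2) {
      out$I_CaN <- p$g_CaN_S * state$m_CaN^2 * state$h_CaN * (V - p$E_Ca)
      out$I_KCa <- p$g_KCa_S * kca_activation(state$Ca_S, p$K_d) * (V - p$E_K)
    }
  } else {
    V <- state$V_D
    out <- list(
      I_NaP = p$g_NaP * state$m_NaP * state$h_NaP * (V - p$E_Na),
      I_CaN = p$g_CaN_D * state$m_CaN^2 * state$h_CaN * (V - p$E_Ca),
      I_CaL = p$g_CaL * state$m_CaL * (V - p$E_Ca),
      I_KCa = p$g_KCa_D * kca_activation(state$Ca_D, p$K_d) * (V - p$E_K),
      I_L   = p$g_L * (V - p$E_L)
    )
  }
  out
}

#' Full state derivative of one neuron
#'
#' Assembles the ionic, coupling and synaptic currents into the complete
#' time derivative of the state.  Injected current and synaptic input enter
#' the soma only.  For the motoneuron the dendritic gates (`m_CaN`, `h_CaN`)
#' follow the somatic voltage in the soma instance and the dendritic voltage
#' in the dendrite instance; this implementation keeps one shared CaN gate
#' pair per compartment voltage, stored as `m_CaN`/`h_CaN` (soma) and
#' `m_CaN_D`/`h_CaN_D` (dendrite).
#'
#' @param state A [neuron_state()] object (for motoneurons, with the dendritic
#'   CaN gates `m_CaN_D`, `h_CaN_D` present; [neuron_state()] is extended
#'   accordingly by [simulate_single_neuron()] helpers).
#' @param params A [neuron_params()] object.
#' @param I_inject Somatic injected current (uA/cm^2).
#' @return Named list of state derivatives (per ms).
#' @export
membrane_derivatives <- function(state, params, I_inject = 0) {
  p <- params
  kin <- gating_kinetics(p)
  d <- list()
  if (p$n_compartments == 1) {
    V <- state$V_S
    cur <- ionic_currents(state, p, "soma")
    I_syn <- synaptic_current(state$g_syn, V, p$E_SynE)
    d$V_S <- (-cur$I_Na - cur$I_K - cur$I_L - I_syn + I_inject) / p$C
    for (g in c("m_Na", "h_Na", "m_K")) {
      d[[g]] <- gating_derivative(state[[g]], V, kin, g)
    }
    d$g_syn <- -state$g_syn / p$tau_synE
    return(d)
  }
  # motoneuron: soma
  VS <- state$V_S
  VD <- state$V_D
  soma <- ionic_currents(state, p, "soma")
  # dendrite currents use the dendritic gate copies
  dend_state <- state
  dend_state$m_CaN <- state$m_CaN_D
  dend_state$h_CaN <- state$h_CaN_D
  dend <- ionic_currents(dend_state, p, "dendrite")
  cc <- coupling_currents(VS, VD, p$g_C, p$p)
  I_syn <- synaptic_current(state$g_syn, VS, p$E_SynE)
  # I_C is the current flowing INTO the compartment through the coupling
  # conductance, so it depolarizes the receiving compartment (positive sign);
  # the ionic and synaptic currents are outward-positive (negative sign)
  d$V_S <- (-soma$I_Na - soma$I_K - soma$I_CaN - soma$I_KCa - soma$I_L +
              cc$I_C_soma - I_syn + I_inject) / p$C
  d$V_D <- (-dend$I_NaP - dend$I_CaN - dend$I_CaL - dend$I_KCa - dend$I_L +
              cc$I_C_dendrite) / p$C
  for (g in c("m_Na", "h_Na", "m_K", "m_CaN", "h_CaN")) {
    d[[g]] <- gating_derivative(state[[g]], VS, kin, g)
  }
  for (g in c("m_NaP", "h_NaP", "m_CaL")) {
    d[[g]] <- gating_derivative(state[[g]], VD, kin, g)
  }
  d$m_CaN_D <- gating_derivative(state$m_CaN_D, VD, kin, "m_CaN")
  d$h_CaN_D <- gating_derivative(state$h_CaN_D, VD, kin, "h_CaN")
  d$Ca_S <- calcium_derivative(state$Ca_S, soma$I_CaN, p)
  d$Ca_D <- calcium_derivative(state$Ca_D, dend$I_CaN + dend$I_CaL, p)
  d$g_syn <- -state$g_syn / p$tau_synE
  d
}
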