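#' Right-hand side of a basal ganglia neuron (STN, GPe or GPi)
#'
#' Time derivatives of the current-balance state
#' `(V, n, h, r, Ca, s)` of one (or a vector of) STN/GPe/GPi neuron(s):
#' \deqn{C dV/dt = -I_{LEAK} - I_K - I_{Na} - I_{Ca} - I_T - I_{AHP}
#'   - I_{syn} + I_{app} + I_{DBS}}
#' with `I_LEAK = g_L (V - E_L)`, `I_K = g_K n^4 (V - E_K)`,
#' `I_Na = g_Na m_inf^3 h (V - E_Na)`, `I_Ca = g_Ca s_inf^2 (V - E_Ca)`,
#' an STN T-current `g_T a_inf^3 b_inf^2 (V - E_Ca)` or a pallidal
#' T-current `g_T a_inf^3 r (V - E_K)`, and
#' `I_AHP = g_AHP (Ca / (k1 + Ca)) (V - E_K)`.  Calcium follows
#' `dCa/dt = k2 (-I_Ca - I_T - k_Ca Ca)` and the synaptic activation
#' follows [synapse_rhs()].
#'
#' This reference implementation is the module surface used by the tests
#' and by single-compartment experiments; the network integrator evaluates
#' the identical expressions in compiled code.
#'
#' @param state named list with numeric vectors `V, n, h, r, Ca, s`
#'   (equal lengths).
#' @param params a [population_params()] set for STN, GPe or GPi.
#' @param I_syn,I_app,I_dbs currents (pA, sign conventions as in the
#'   balance above); scalars or vectors.
#' @return named list of derivatives `V, n, h, r, Ca, s`.
#' @export
membrane_rhs <- function(state, params, I_syn = 0, I_app = 0, I_dbs = 0) {
  if (params$population == "THA")
    stop("use thalamic_rhs() for thalamic neurons")
  need <- c("V", "n", "h", "r", "Ca", "s")
  if (!all(need %in% names(state)))
    stop("state must contain ", paste(need, collapse = ", "))
  V <- state$V
  m_inf <- steady_state(V, params$theta_m, params$sigma_m)
  s_inf <- steady_state(V, params$theta_s, params$sigma_s)
  a_inf <- steady_state(V, params$theta_a, params$sigma_a)
  I_leak <- params$g_leak * (V - params$E_leak)
  I_K <- params$g_K * state$n^4 * (V - params$E_K)
  I_Na <- params$g_Na * m_inf^3 * state$h * (V - params$E_Na)
  I_Ca <- params$g_Ca * s_inf^2 * (V - params$E_Ca)
  I_T <- if (isTRUE(params$stn_type)) {
    b <- b_inf(state$r, params$theta_b, params$sigma_b)
    params$g_T * a_inf^3 * b^2 * (V - params$E_T)
  } else {
    params$g_T * a_inf^3 * state$r * (V - params$E_T)
  }
  I_AHP <- params$g_AHP * (state$Ca / (params$k1 + state$Ca)) * (V - params$E_K)
  list(
    V = (-I_leak - I_K - I_Na - I_Ca - I_T - I_AHP - I_syn + I_app + I_dbs) /
      params$C,
    n = (steady_state(V, params$theta_n, params$sigma_n) - state$n) /
      tau_gate(V, params, "n"),
    h = (steady_state(V, params$theta_h, params$sigma_h) - state$h) /
      tau_gate(V, params, "h"),
    r = (steady_state(V, params$theta_r, params$sigma_r) - state$r) /
      tau_gate(V, params, "r"),
    Ca = params$k2 * (-I_Ca - I_T - params$k_Ca * state$Ca),
    s = synapse_rhs(state$s, V, params$alpha, params$beta,
                    params$theta_0, params$sigma_H))
}

#' Right-hand side of a thalamocortical relay neuron
#'
#' Derivatives of `(V, h, r)` under
#' \deqn{C dV/dt = -I_{LEAK} - I_K - I_{Na} - I_T - I_{GPTH} + I_{SM}}
#' with `I_K = g_K (0.75 (1 - h))^4 (V - E_K)`,
#' `I_Na = g_Na m_inf^3 h (V - E_Na)` and
#' `I_T = g_T p_inf^2 r (V - E_T)`.  `I_GPTH` is the pallido-thalamic
#' GABA current assembled by the caller (see [synaptic_drive()]); `I_SM`
#' is the sensorimotor pulse train.
#'
#' @param state named list with numeric vectors `V, h, r`.
#' @param params a `"THA"` [population_params()] set.
#' @param I_gpth,I_sm currents (pA).
#' @return named list of derivatives `V, h, r`.
#' @export
thalamic_rhs <- function(state, params, I_gpth = 0, I_sm = 0) {
  if (params$population != "THA")
    stop("thalamic_rhs() needs THA parameters")
  if (!all(c("V", "h", "r") %in% names(state)))
    stop("state must contain V, h, r")
  V <- state$V
  m_inf <- steady_state(V, params$theta_m, params$sigma_m)
  p_inf <- steady_state(V, params$theta_p, params$sigma_p)
  I_leak <- params$g_leak * (V - params$E_leak)
  I_K <- params$g_K * (0.75 * (1 - state$h))^4 * (V - params$E_K)
  I_Na <- params$g_Na * m_inf^3 * state$h * (V - params$E_Na)
  I_T <- params$g_T * p_inf^2 * state$r * (V - params$E_T)
  list(
    V = (-I_leak - I_K - I_Na - I_T - I_gpth + I_sm) / params$C,
    h = (steady_state(V, params$theta_h, params$sigma_h) - state$h) /
      tau_gate(V, params, "h"),
    r = (steady_state(V, params$theta_r, params$sigma_r) - state$r) /
      tau_gate(V, params, "r"))
}

#' First-order synaptic activation kinetics
#'
#' `ds/dt = alpha (1 - s) H(V_pre - theta_0) - beta s`, with the smooth
#' Heaviside `H(x) = 1 / (1 + exp(-x / sigma_H))`.  During sustained
#' presynaptic depolarisation s approaches `alpha / (alpha + beta)`;
#' below threshold it decays exponentially at rate `beta`.
#'
#' @param s synaptic activation in \[0, 1\]; vectorised.
#' @param V_pre presynaptic membrane potential (mV).
#' @param alpha,beta opening and closing rates (1/ms).
#' @param theta_0 presynaptic threshold (mV).
#' @param sigma_H smoothness of the threshold (mV).
#' @return ds/dt.
#' @export
synapse_rhs <- function(s, V_pre, alpha, beta, theta_0, sigma_H) {
  H <- 1 / (1 + exp(-(V_pre - theta_0) / sigma_H))
  alpha * (1 - s) * H - beta * s
}

#' Resting state of a population at a given voltage
#'
#' Gating variables at their voltage steady state, calcium at `Ca0` and
#' synaptic activation at `s0`; used to build initial conditions.
#'
#' @param V0 membrane potential(s) (mV).
#' @param params a [population_params()] set.
#' @param Ca0,s0 initial calcium and synaptic activation.
#' @return named list matching the population's state variables.
#' @export
resting_state <- function(V0, params, Ca0 = 0.1, s0 = 0) {
  if (params$population == "THA") {
    list(V = V0,
         h = steady_state(V0, params$theta_h, params$sigma_h),
         r = steady_state(V0, params$theta_r, params$sigma_r))
  } else {
    list(V = V0,
         n = steady_state(V0, params$theta_n, params$sigma_n),
         h = steady_state(V0, params$theta_h, params$sigma_h),
         r = steady_state(V0, params$theta_r, params$sigma_r),
         Ca = rep_len(Ca0, length(V0)), s = rep_len(s0, length(V0)))
  }
}
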