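#' Logistic steady-state activation
#'
#' The voltage-dependent equilibrium of a gating variable,
#' `1 / (1 + exp(-(V - theta) / sigma))`.  Activation gates have
#' `sigma > 0`, inactivation gates `sigma < 0`.
#'
#' @param V membrane potential (mV); vectorised.
#' @param theta half-activation voltage (mV).
#' @param sigma slope factor (mV); must be non-zero.
#' @return values in (0, 1).
#' @examples
#' steady_state(-30, -30, 15)      # 0.5 at the half-activation point
#' @export
steady_state <- function(V, theta, sigma) {
  if (any(!is.finite(V))) stop("V must be finite")
  if (any(sigma == 0)) stop("sigma must be non-zero")
  1 / (1 + exp(-(V - theta) / sigma))
}

#' Equilibrium of the T-current inactivation gate b
#'
#' Unlike the other gates, b equilibrates as a function of the slow gating
#' variable r (not of voltage):
#' `1 / (1 + exp((r - theta_b) / sigma_b)) - 1 / (1 + exp(-theta_b / sigma_b))`,
#' which vanishes at r = 0.
#'
#' @param r_gate value of the r gating variable in \[0, 1\]; vectorised.
#' @param theta_b,sigma_b half-point and slope of the b equilibrium.
#' @export
b_inf <- function(r_gate, theta_b = 0.4, sigma_b = -0.1) {
  if (any(r_gate < 0 | r_gate > 1, na.rm = TRUE))
    stop("r_gate must lie in [0, 1]")
  1 / (1 + exp((r_gate - theta_b) / sigma_b)) -
    1 / (1 + exp(-theta_b / sigma_b))
}

#' Voltage-dependent gating time constant
#'
#' For the basal ganglia populations,
#' `tau_x(V) = (tau_x0 + tau_x1 / (1 + exp(-(V - theta_tau_x) / sigma_tau_x))) / A_x`;
#' when the sigmoid parameters are absent (pallidal r gate) the constant
#' limit `tau_x0 / A_x` applies, and `constant_tau = TRUE` in the
#' parameter set forces that limit for every gate.  For thalamic neurons
#' the closed forms of the relay model are used:
#' `tau_h = 1 / (a_h + b_h)` with `a_h = 0.128 exp(-(V + 46) / 18)`,
#' `b_h = 4 / (1 + exp(-(V + 23) / 5))`, and
#' `tau_r = 28 + exp(-(V + 25) / 10.5)` (ms).
#'
#' @param V membrane potential (mV); vectorised.
#' @param params a [population_params()] set.
#' @param gate one of `"h"`, `"n"`, `"r"` (`"n"` is not a thalamic gate).
#' @return time constant in ms.
#' @export
tau_gate <- function(V, params, gate = c("h", "n", "r")) {
  gate <- match.arg(gate)
  if (params$population == "THA") {
    if (gate == "n") stop("thalamic relay neurons have no n gate")
    if (gate == "h") {
      a_h <- 0.128 * exp(-(V + 46) / 18)
      b_h <- 4 / (1 + exp(-(V + 23) / 5))
      return(1 / (a_h + b_h))
    }
    er <- exp(-(V + 25) / 10.5)
    return(if (isTRUE(params$tau_r_paper)) 28 + (1 + er) else 28 + er)
  }
  t0 <- params[[paste0("tau_", gate, "0")]]
  t1 <- params[[paste0("tau_", gate, "1")]]
  th <- params[[paste0("theta_tau_", gate)]]
  sg <- params[[paste0("sigma_tau_", gate)]]
  A <- params[[paste0("A_", gate)]]
  if (!is.finite(A) || A == 0) stop("A_", gate, " must be non-zero")
  if (isTRUE(params$constant_tau) || !is.finite(th))
    return(rep_len(t0 / A, length(V)))
  (t0 + t1 * steady_state(V, th, sg)) / A
}
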