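#' Rectangular Heaviside pulse train
#'
#' `A * H(sin(2 pi t / T)) * (1 - H(sin(2 pi (t + delta) / T)))` with the
#' exact (discontinuous) Heaviside step: rectangular pulses of width
#' `delta` repeating with period `T`.  This is the waveform of both the
#' sensorimotor drive to the thalamus (A = 5 pA, delta = 5 ms, T = 25 ms)
#' and the DBS current injected into the STN (A = 200, delta = 0.6 ms,
#' T = 1000 / f ms for a stimulation frequency f in Hz).
#'
#' @param t time (ms); vectorised.
#' @param A pulse amplitude (pA).
#' @param delta pulse width (ms); must satisfy `0 < delta < T`.
#' @param period pulse period T (ms).
#' @return current at `t` (pA).
#' @examples
#' pulse_train(c(9, 12.4, 12.6), A = 5, delta = 5, period = 25)
#' @export
pulse_train <- function(t, A, delta, period) {
  if (delta <= 0 || delta >= period)
    stop("pulse width delta must satisfy 0 < delta < period")
  H1 <- as.numeric(sin(2 * pi * t / period) > 0)
  H2 <- as.numeric(sin(2 * pi * (t + delta) / period) > 0)
  A * H1 * (1 - H2)
}

#' Pulse onset times of a Heaviside train
#'
#' With the [pulse_train()] waveform each period's pulse occupies
#' `(k T + T/2 - delta, k T + T/2)`; the onsets returned here are the
#' left edges.  Used to window the thalamic response efficacy.
#'
#' @param delta pulse width (ms).
#' @param period pulse period (ms).
#' @param t_max last time (ms) up to which onsets are listed.
#' @param t_min first time (ms); onsets strictly greater are kept.
#' @return numeric vector of onset times (ms).
#' @export
pulse_onsets <- function(delta, period, t_max, t_min = 0) {
  if (delta <= 0 || delta >= period)
    stop("pulse width delta must satisfy 0 < delta < period")
  k <- 0:ceiling(t_max / period)
  on <- k * period + period / 2 - delta
  on[on > t_min & on < t_max]
}

#' Synaptic current onto postsynaptic neurons
#'
#' Assembles `I_i = g (V_i - E_rev) sum_j A_ij s_j` for one projection:
#' the conductance-weighted sum of presynaptic activations times the
#' postsynaptic driving force.  `adjacency` has one row per postsynaptic
#' and one column per presynaptic neuron (`A_ij = 1` iff j projects
#' to i).
#'
#' @param s_pre presynaptic activations in \[0, 1\] (length = columns of
#'   `adjacency`).
#' @param adjacency 0/1 matrix, rows postsynaptic.
#' @param g synaptic conductance of the projection.
#' @param E_rev reversal potential (mV): -10 for glutamate, -70 for GABA.
#' @param V_post postsynaptic potentials (length = rows of `adjacency`).
#' @return current per postsynaptic neuron (pA).
#' @export
synaptic_drive <- function(s_pre, adjacency, g, E_rev, V_post) {
  adjacency <- as.matrix(adjacency)
  if (length(s_pre) != ncol(adjacency))
    stop("length(s_pre) must equal ncol(adjacency)")
  if (length(V_post) != nrow(adjacency))
    stop("length(V_post) must equal nrow(adjacency)")
  if (any(s_pre < 0 | s_pre > 1)) stop("s_pre must lie in [0, 1]")
  g * (V_post - E_rev) * drop(adjacency %*% s_pre)
}

#' Stimulation protocol for a functional state of the network
#'
#' Bundles every exogenous current of a simulated condition: the constant
#' cortical drive to the STN (4 pA in all conditions), the striatal
#' drives to GPe/GPi (normal: 5/4 pA; parkinsonian and DBS: 3/8 pA,
#' i.e. GPe inhibited, GPi disinhibited), the 40 Hz sensorimotor pulse
#' train to the thalamus, and -- for `condition = "dbs"` -- the
#' high-frequency pulse train injected into every STN neuron.
#'
#' @param condition `"normal"`, `"parkinsonian"` or `"dbs"`.
#' @param dbs_frequency DBS frequency in Hz (sets the pulse period
#'   `T = 1000 / f` ms); only used when `condition = "dbs"`.
#' @param I_app optional named numeric overrides, e.g.
#'   `c(GPe = 4)`.
#' @param dbs_amplitude,dbs_width DBS pulse amplitude (pA) and width (ms).
#' @param sm_amplitude,sm_width,sm_period sensorimotor train parameters.
#' @return object of class `bg_protocol`.
#' @examples
#' stimulus_protocol("dbs", dbs_frequency = 184)
#' @export
stimulus_protocol <- function(condition = c("normal", "parkinsonian", "dbs"),
                              dbs_frequency = 184,
                              I_app = NULL,
                              dbs_amplitude = 200, dbs_width = 0.6,
                              sm_amplitude = 5, sm_width = 5, sm_period = 25) {
  condition <- match.arg(condition)
  app <- if (condition == "normal")
    c(STN = 4, GPe = 5, GPi = 4, THA = 0)
  else
    c(STN = 4, GPe = 3, GPi = 8, THA = 0)
  if (!is.null(I_app)) {
    if (is.null(names(I_app)) || !all(names(I_app) %in% names(app)))
      stop("I_app overrides must be named after populations")
    app[names(I_app)] <- I_app
  }
  dbs_on <- condition == "dbs"
  dbs_T <- 1000 / dbs_frequency
  if (dbs_on && dbs_width >= dbs_T)
    stop("DBS pulse width must be smaller than the pulse period")
  if (sm_width <= 0 || sm_width >= sm_period)
    stop("sensorimotor pulse width must satisfy 0 < delta < period")
  structure(list(
    condition = condition,
    I_app = app,
    sm_A = sm_amplitude, sm_delta = sm_width, sm_T = sm_period,
    dbs_on = dbs_on, dbs_A = dbs_amplitude, dbs_delta = dbs_width,
    dbs_T = dbs_T,
    dbs_frequency = if (dbs_on) dbs_frequency else NA_real_),
    class = "bg_protocol")
}

#' @export
print.bg_protocol <- function(x, ...) {
  cat("<bg_protocol> condition:", x$condition, "\n")
  cat("  I_app (pA):", paste(names(x$I_app), x$I_app, sep = "=",
                             collapse = ", "), "\n")
  cat("  sensorimotor train:", x$sm_A, "pA,", x$sm_delta, "ms @",
      1000 / x$sm_T, "Hz\n")
  if (x$dbs_on)
    cat("  DBS train:", x$dbs_A, "pA,", x$dbs_delta, "ms @",
        x$dbs_frequency, "Hz\n")
  invisible(x)
}
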