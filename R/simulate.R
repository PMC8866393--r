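cpp_params <- function(params) {
  purrr::map(params, unclass)
}

cpp_projections <- function(topology) {
  purrr::imap(topology$projections, function(es, nm) {
    pp <- .proj_pops[[nm]]
    list(pre_pop = pop_id(pp[1]), post_pop = pop_id(pp[2]),
         g = es$g, E_rev = es$E_rev,
         pre = es$pre - 1L, post = es$post - 1L)
  })
}

cpp_protocol <- function(protocol, tha_gaba_g = 0, tha_gaba_E = -70) {
  list(I_app = as.numeric(protocol$I_app),
       sm_A = protocol$sm_A, sm_delta = protocol$sm_delta,
       sm_T = protocol$sm_T,
       dbs_on = isTRUE(protocol$dbs_on), dbs_A = protocol$dbs_A,
       dbs_delta = protocol$dbs_delta, dbs_T = protocol$dbs_T,
       tha_gaba_g = tha_gaba_g, tha_gaba_E = tha_gaba_E)
}

state_vector <- function(states, sizes) {
  # per BG population: V | n | h | r | Ca | s; THA: V | h | r
  out <- numeric(0)
  for (pop in POPULATIONS) {
    n <- sizes[[pop]]
    if (n == 0) next
    st <- states[[pop]]
    vars <- if (pop == "THA") c("V", "h", "r") else
      c("V", "n", "h", "r", "Ca", "s")
    for (v in vars) {
      x <- rep_len(st[[v]], n)
      out <- c(out, x)
    }
  }
  out
}

#' Randomised initial conditions for a network run
#'
#' Per-neuron initial voltages are drawn uniformly from
#' `(-70, -50)` mV (a desynchronised start), gating variables sit at
#' their voltage steady state, calcium starts at 0.1 and synaptic
#' activations at 0.
#'
#' @param sizes named population sizes.
#' @param params network parameter sets.
#' @param seed optional integer seed.
#' @return named list of per-population state lists.
#' @export
initial_state <- function(sizes, params = network_params(), seed = NULL) {
  with_seed(seed, {
    purrr::imap(as.list(sizes), function(n, pop) {
      if (n == 0) return(NULL)
      V0 <- runif(n, -70, -50)
      resting_state(V0, params[[pop]])
    })
  })
}

#' Integrate the coupled basal ganglia-thalamus network
#'
#' Advances all four populations with an adaptive Bogacki-Shampine
#' Runge-Kutta 3(2) pair (the scheme of MATLAB's ode23) at relative and
#' absolute tolerances of 1e-6 by default.  The maximum step is capped at
#' a quarter of the narrowest active pulse width so the discontinuous
#' stimulus trains are never stepped over.  Spike times (upward crossings
#' of `threshold`, 2 ms lockout) are detected online for every neuron;
#' voltage traces are recorded for a configurable subset of neurons and
#' the full synaptic-activation matrix for the populations named in
#' `record_s`.
#'
#' Runs are deterministic given (topology, protocol, seed, tolerances).
#'
#' @param topology a [build_full_network()] topology.
#' @param protocol a [stimulus_protocol()].
#' @param t_span duration (ms), at least 100.
#' @param rtol,atol solver tolerances.
#' @param seed integer seed for the initial conditions (ignored when
#'   `init` is given).
#' @param init optional initial state as from [initial_state()].
#' @param params network parameter sets.
#' @param record_v number of neurons per population whose V is recorded.
#' @param v_dt,s_dt output grids (ms) for voltage and synaptic traces.
#' @param record_s populations whose full s matrix is recorded.
#' @param threshold,lockout spike detection settings (mV, ms).
#' @param method `"adaptive"` (embedded 3(2) pair, tolerance-controlled)
#'   or `"rk4"` (classical fixed-step Runge-Kutta at step `dt`).
#' @param dt fixed step (ms) for `method = "rk4"`.
#' @return object of class `bg_sim`.
#' @export
simulate_network <- function(topology, protocol, t_span = 1500,
                             rtol = 1e-6, atol = 1e-6, seed = NULL,
                             init = NULL, params = network_params(),
                             record_v = 10, v_dt = 0.1,
                             record_s = "GPi", s_dt = 1,
                             threshold = -15, lockout = 2,
                             method = c("adaptive", "rk4"), dt = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(topology, "bg_topology"),
            inherits(protocol, "bg_protocol"))
  if (t_span < 100) stop("t_span must be at least 100 ms")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  sizes <- topology$sizes
  if (is.null(init)) init <- initial_state(sizes, params, seed = seed)
  y0 <- state_vector(init, sizes)
  v_idx <- purrr::map(as.list(sizes), function(n)
    as.integer(seq_len(min(record_v, n)) - 1L))
  if (length(record_s) == 0) stop("record at least one population's s ",
                                  "(the macroscopic analysis needs it)")
  s_pops <- vapply(record_s, pop_id, 0L)
  if (any(s_pops == 3L)) stop("thalamic neurons carry no synaptic activation")
  hmax <- if (isTRUE(protocol$dbs_on)) protocol$dbs_delta / 4 else
    min(1, protocol$sm_delta / 4)
  out <- cpp_integrate(
    cpp_params(params), as.integer(sizes), cpp_projections(topology),
    cpp_protocol(protocol), t_span, y0, rtol, atol, hmax, 1e-10,
    v_dt, v_idx, s_dt, as.integer(s_pops), threshold, lockout,
    fixed_dt = if (method == "rk4") dt else 0)
  spikes <- setNames(out$spikes, POPULATIONS)
  V <- setNames(out$V, POPULATIONS)
  S <- setNames(out$S, record_s)
  structure(list(
    t_span = t_span,
    t_v = seq(0, t_span, by = v_dt)[seq_len(nrow(V$STN))],
    t_s = seq(0, t_span, by = s_dt)[seq_len(nrow(S[[1]]))],
    spikes = spikes, V = V, S = S,
    sizes = sizes, protocol = protocol,
    stn_topology = topology$stn_topology,
    topology_seed = topology$seed,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    solver = list(method = if (method == "rk4") "rk4"
                  else "bogacki-shampine 3(2)",
                  rtol = rtol, atol = atol, dt = if (method == "rk4") dt,
                  hmax = hmax, n_accept = out$n_accept,
                  n_reject = out$n_reject),
    threshold = threshold, lockout = lockout,
    y_final = out$y_final), class = "bg_sim")
}

#' @export
print.bg_sim <- function(x, ...) {
  cat("<bg_sim> ", x$t_span, " ms, condition ", x$protocol$condition,
      if (x$protocol$dbs_on) paste0(" @ ", x$protocol$dbs_frequency, " Hz"),
      "\n", sep = "")
  r <- population_rates(x)
  cat("  mean rates (Hz):",
      paste(r$population, round(r$rate, 1), sep = "=", collapse = ", "), "\n")
  cat("  solver: ", x$solver$n_accept, " steps (+",
      x$solver$n_reject, " rejected)\n", sep = "")
  invisible(x)
}

#' Simulate one uncoupled model neuron
#'
#' Integrates a single STN, GPe/GPi or THA neuron with no synaptic input,
#' under a constant injected current and (optionally, for THA) the
#' sensorimotor pulse train and/or a tonic GABA conductance clamp
#' (`s = 1`), as used to probe pallido-thalamic suppression.
#'
#' @param population population label.
#' @param I_app constant injected current (pA).
#' @param duration run length (ms).
#' @param params optional [population_params()] override.
#' @param sensorimotor logical: apply the `A_SM` pulse train (THA only).
#' @param gaba_g,gaba_E tonic inhibitory clamp conductance and reversal.
#' @param V0 initial voltage (mV) or a full state list via `init`.
#' @param init optional initial state list (overrides `V0`).
#' @param v_dt output grid (ms).
#' @param rtol,atol solver tolerances.
#' @param method,dt solver options as in [simulate_network()].
#' @param threshold,lockout spike detection settings.
#' @return list of class `bg_neuron_sim` with `trace` (tibble `t`, `V`),
#'   `spikes` (ms) and metadata.
#' @export
simulate_neuron <- function(population = c("STN", "GPe", "GPi", "THA"),
                            I_app = 0, duration = 2000, params = NULL,
                            sensorimotor = FALSE, gaba_g = 0, gaba_E = -70,
                            V0 = -62, init = NULL, v_dt = 0.05,
                            rtol = 1e-6, atol = 1e-6,
                            method = c("adaptive", "rk4"), dt = 0.02,
                            threshold = -15, lockout = 2) {
  population <- match.arg(population)
  method <- match.arg(method)
  if (is.null(params)) params <- population_params(population)
  allp <- network_params()
  allp[[population]] <- params
  sizes <- setNames(as.integer(POPULATIONS == population),
                    POPULATIONS)
  app <- c(STN = 0, GPe = 0, GPi = 0, THA = 0)
  app[population] <- I_app
  tha <- allp$THA
  proto <- list(I_app = app,
                sm_A = if (sensorimotor) tha$A_SM else 0,
                sm_delta = tha$delta_SM, sm_T = tha$T_SM,
                dbs_on = FALSE, dbs_A = 0, dbs_delta = 0.1, dbs_T = 1)
  if (is.null(init)) init <- setNames(list(NULL, NULL, NULL, NULL),
                                      POPULATIONS)
  if (is.null(init[[population]]))
    init[[population]] <- resting_state(V0, params)
  y0 <- state_vector(init, sizes)
  v_idx <- purrr::map(as.list(sizes), function(n)
    as.integer(seq_len(n) - 1L))
  hmax <- if (sensorimotor) tha$delta_SM / 4 else 1
  out <- cpp_integrate(
    cpp_params(allp), sizes, list(),
    c(proto[c("I_app", "sm_A", "sm_delta", "sm_T", "dbs_on", "dbs_A",
              "dbs_delta", "dbs_T")],
      list(tha_gaba_g = gaba_g, tha_gaba_E = gaba_E)),
    duration, y0, rtol, atol, hmax, 1e-10,
    v_dt, v_idx, 0, integer(0), threshold, lockout,
    fixed_dt = if (method == "rk4") dt else 0)
  Vm <- out$V[[match(population, POPULATIONS)]]
  tt <- seq(0, duration, by = v_dt)[seq_len(nrow(Vm))]
  nst <- if (population == "THA") 3 else 6
  yf <- matrix(out$y_final, ncol = nst)
  vars <- if (population == "THA") c("V", "h", "r") else
    c("V", "n", "h", "r", "Ca", "s")
  structure(list(
    population = population, I_app = I_app, duration = duration,
    trace = tibble::tibble(t = tt, V = Vm[, 1]),
    spikes = out$spikes[[match(population, POPULATIONS)]][[1]],
    final_state = setNames(as.list(as.data.frame(yf)), vars),
    params = params,
    solver = list(rtol = rtol, atol = atol, n_accept = out$n_accept,
                  n_reject = out$n_reject)),
    class = "bg_neuron_sim")
}

#' Firing rate of a single uncoupled neuron
#'
#' Integrates one neuron under a constant current and reports the spike
#' rate (upward crossings of -15 mV) in the window after an initial
#' transient.
#'
#' @param population population label.
#' @param I_app injected current (pA).
#' @param duration total run length (ms); at least 1000.
#' @param transient discarded initial window (ms).
#' @param ... passed to [simulate_neuron()].
#' @return rate in Hz (0 if no spikes).
#' @examples
#' \donttest{
#' single_neuron_rate("STN", I_app = 10)
#' }
#' @export
single_neuron_rate <- function(population, I_app = 0, duration = 2500,
                               transient = 500, ...) {
  if (duration < 1000) stop("duration must be at least 1000 ms")
  sim <- simulate_neuron(population, I_app = I_app, duration = duration, ...)
  sum(sim$spikes > transient) / (duration - transient) * 1000
}

#' Spike times from a sampled voltage trace
#'
#' Upward crossings of the threshold located by linear interpolation
#' between samples, with a refractory lockout.
#'
#' @param t uniform time grid (ms).
#' @param V voltage samples (mV).
#' @param threshold crossing level (mV).
#' @param lockout minimum inter-spike separation (ms).
#' @return spike times (ms), sorted.
#' @export
detect_spikes <- function(t, V, threshold = -15, lockout = 2) {
  if (length(t) != length(V)) stop("t and V must have equal length")
  if (length(t) < 2) return(numeric(0))
  up <- which(V[-length(V)] <= threshold & V[-1] > threshold)
  if (!length(up)) return(numeric(0))
  ts <- t[up] + (threshold - V[up]) / (V[up + 1] - V[up]) * (t[up + 1] - t[up])
  keep <- logical(length(ts)); last <- -Inf
  for (i in seq_along(ts)) {
    if (ts[i] - last >= lockout) { keep[i] <- TRUE; last <- ts[i] }
  }
  ts[keep]
}

#' Spike raster of one population
#'
#' @param sim a `bg_sim`.
#' @param population population label.
#' @return tibble with columns `neuron` (1-based index) and `time` (ms).
#' @export
raster <- function(sim, population = "GPi") {
  stopifnot(inherits(sim, "bg_sim"))
  sp <- sim$spikes[[match.arg(population, POPULATIONS)]]
  purrr::imap_dfr(sp, function(ts, i)
    tibble::tibble(neuron = as.integer(i), time = as.numeric(ts)))
}

#' Mean firing rate per population
#'
#' @param sim a `bg_sim`.
#' @param window analysis window (ms); default excludes the first 500 ms.
#' @return tibble with `population`, `rate` (Hz, averaged over neurons).
#' @export
population_rates <- function(sim, window = c(500, Inf)) {
  stopifnot(inherits(sim, "bg_sim"))
  window[2] <- min(window[2], sim$t_span)
  w <- diff(window)
  purrr::imap_dfr(sim$spikes, function(sp, pop) {
    counts <- vapply(sp, function(ts)
      sum(ts > window[1] & ts <= window[2]), 0L)
    tibble::tibble(population = pop,
                   rate = mean(counts) / w * 1000)
  })
}
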