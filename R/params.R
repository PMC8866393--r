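#' Ionic, gating and synaptic parameters of one model population
#'
#' Returns the full parameter set of a subthalamic (STN), pallidal
#' (GPe/GPi) or thalamocortical (THA) model neuron.  Conductances are in
#' nS/um^2, potentials in mV, times in ms; the membrane capacitance `C`
#' uses the matching convention and defaults to 1.
#'
#' STN, GPe and GPi neurons carry gating variables n, h, r, an
#' intracellular calcium pool and a synaptic activation s.  The pallidal
#' populations share one parameter column and differ only in their applied
#' striatal current (see [stimulus_protocol()]).  Thalamic relay neurons
#' carry h and r only; their Table entries for calcium and extra time
#' constants are stored but unused by the relay equations.
#'
#' Named values supplied via `...` override the defaults, so sensitivity
#' variants (e.g. a constant-tau pallidum, or alternative gating slopes)
#' are one argument away.
#'
#' @param population one of `"STN"`, `"GPe"`, `"GPi"`, `"THA"`.
#' @param ... named parameter overrides.
#' @param constant_tau force voltage-independent gating time constants
#'   `tau_x0 / A_x` (BG populations only).
#' @return a named list of class `bg_params`.
#' @examples
#' p <- population_params("STN")
#' p$g_Na
#' population_params("GPe", g_AHP = 20)$g_AHP
#' @export
population_params <- function(population = c("STN", "GPe", "GPi", "THA"),
                              ..., constant_tau = FALSE) {
  population <- match.arg(population)
  p <- .bg_defaults[[population]]
  p$population <- population
  p$constant_tau <- isTRUE(constant_tau)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "bg_params")
}

# Defaults: pallidal gating thresholds theta_a / theta_s and the STN slope
# sigma_h follow the conductance-model lineage of this cell family
# (Terman-type STN/GP cells); the remaining entries are the published
# parameter tables of this network.  sigma_s and the smooth-Heaviside
# width sigma_H are not tabulated and also come from the same lineage.
.bg_defaults <- local({
  stn <- list(
    C = 1, g_leak = 2.25, E_leak = -60, g_K = 45, E_K = -80,
    g_Na = 37.5, E_Na = 55, g_Ca = 0.5, E_Ca = 140, g_T = 0.5, E_T = 140,
    g_AHP = 9,
    theta_m = -30, sigma_m = 15, theta_h = -39, sigma_h = -3.1,
    theta_n = -32, sigma_n = 8, theta_r = -67, sigma_r = -2,
    theta_a = -63, sigma_a = 7.8, theta_b = 0.4, sigma_b = -0.1,
    theta_s = -39, sigma_s = 8,
    tau_h0 = 1, tau_h1 = 500, theta_tau_h = -57, sigma_tau_h = -3, A_h = 0.75,
    tau_n0 = 1, tau_n1 = 100, theta_tau_n = -80, sigma_tau_n = -26, A_n = 0.75,
    tau_r0 = 40, tau_r1 = 17.5, theta_tau_r = 68, sigma_tau_r = -2.2, A_r = 0.12,
    k1 = 15, k2 = 3.75e-5, k_Ca = 22.5,
    alpha = 5, beta = 1, theta_0 = -39, sigma_H = 8,
    A_DBS = 200, delta_DBS = 0.6, T_DBS = 6,
    stn_type = TRUE)
  gp <- list(
    C = 1, g_leak = 0.1, E_leak = -55, g_K = 30, E_K = -80,
    g_Na = 120, E_Na = 55, g_Ca = 0.15, E_Ca = 120, g_T = 0.5, E_T = 120,
    g_AHP = 30,
    theta_m = -37, sigma_m = 10, theta_h = -58, sigma_h = -12,
    theta_n = -50, sigma_n = 14, theta_r = -70, sigma_r = -2,
    theta_a = -57, sigma_a = 2, theta_b = 0.4, sigma_b = NA_real_,
    theta_s = -35, sigma_s = 2,
    tau_h0 = 0.05, tau_h1 = 0.27, theta_tau_h = -40, sigma_tau_h = -12,
    A_h = 0.05,
    tau_n0 = 0.05, tau_n1 = 0.27, theta_tau_n = -40, sigma_tau_n = -12,
    A_n = 0.05,
    tau_r0 = 30, tau_r1 = 0.05, theta_tau_r = NA_real_,
    sigma_tau_r = NA_real_, A_r = 2,
    k1 = 30, k2 = 1e-4, k_Ca = 20,
    # sigma_H = 1 keeps pallidal transmitter release spike-gated: the
    # interspike potential sits ~4 mV below theta_0, and a wider smooth
    # step lets silent-but-depolarised neurons hold their synapses open,
    # locking the whole circuit (see the methods vignette)
    alpha = 2, beta = 0.08, theta_0 = -57, sigma_H = 1,
    A_DBS = 0, delta_DBS = 0, T_DBS = 0,
    stn_type = FALSE)
  tha <- list(
    C = 1, g_leak = 0.05, E_leak = -70, g_K = 5, E_K = -90,
    g_Na = 3, E_Na = 50, g_T = 5, E_T = 0,
    theta_m = -37, sigma_m = 7, theta_h = -41, sigma_h = -4,
    theta_r = -84, sigma_r = -4, theta_p = -60, sigma_p = 6.2,
    # tabulated for completeness; unused by the relay current balance
    g_Ca = 0.5, E_Ca = 140, tau_h0 = 1, tau_h1 = 500, tau_n1 = 100,
    tau_r0 = 40, tau_r1 = 17.5, k1 = 15,
    tau_r_paper = FALSE,
    A_SM = 5, delta_SM = 5, T_SM = 25)
  list(STN = stn, GPe = gp, GPi = gp, THA = tha)
})

validate_params <- function(p) {
  pop <- p$population
  gpos <- c("g_leak", "g_K", "g_Na", "g_T")
  gpos <- c(gpos, if (pop == "THA") character() else c("g_Ca", "g_AHP"))
  for (g in gpos)
    if (!is.finite(p[[g]]) || p[[g]] < 0)
      stop(g, " must be a non-negative number")
  if (pop != "THA") {
    if (p$alpha <= 0 || p$beta <= 0) stop("alpha and beta must be positive")
    if (p$sigma_H <= 0) stop("sigma_H must be positive")
    if (pop != "STN" && p$A_DBS != 0)
      stop("only STN neurons receive DBS (A_DBS must be 0 for ", pop, ")")
  }
  invisible(p)
}

#' @export
print.bg_params <- function(x, ...) {
  cat("<bg_params> ", x$population, "\n", sep = "")
  nm <- setdiff(names(x), c("population", "stn_type"))
  v <- vapply(nm, function(n) format(x[[n]]), "")
  cat(paste0("  ", format(nm), " = ", v), sep = "\n")
  invisible(x)
}

#' Parameter sets of all four populations
#'
#' Convenience constructor for the full network: one [population_params()]
#' set per population, with per-population overrides.
#'
#' @param STN,GPe,GPi,THA named lists of overrides for the respective
#'   population.
#' @return named list of `bg_params`.
#' @export
network_params <- function(STN = list(), GPe = list(), GPi = list(),
                           THA = list()) {
  list(
    STN = do.call(population_params, c(list("STN"), STN)),
    GPe = do.call(population_params, c(list("GPe"), GPe)),
    GPi = do.call(population_params, c(list("GPi"), GPi)),
    THA = do.call(population_params, c(list("THA"), THA)))
}

#' Tabulate parameter sets
#'
#' @param params a named list of `bg_params` as from [network_params()].
#' @return a tibble with one row per (population, parameter) pair.
#' @export
params_table <- function(params = network_params()) {
  purrr::map_dfr(params, function(p) {
    nm <- setdiff(names(p), c("population", "stn_type", "constant_tau",
                              "tau_r_paper"))
    tibble::tibble(
      population = p$population, parameter = nm,
      value = vapply(nm, function(n) as.numeric(p[[n]]), 0.0))
  })
}

#' Write / read parameter sets as YAML
#'
#' Serialises the full set of population parameters to a YAML file with
#' one section per population, and reads it back losslessly.
#'
#' @param params named list of `bg_params`.
#' @param path file path.
#' @return `read_params()` returns a named list of `bg_params`.
#' @export
write_params <- function(params, path) {
  stripped <- purrr::map(params, function(p) {
    p <- unclass(p)
    p[setdiff(names(p), c("stn_type"))]
  })
  yaml::write_yaml(stripped, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(p, pop) {
    p$population <- NULL
    ct <- isTRUE(p$constant_tau); p$constant_tau <- NULL
    p <- purrr::map(p, function(v) if (is.null(v)) NA_real_ else v)
    do.call(population_params, c(list(pop), p, list(constant_tau = ct)))
  })
}
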