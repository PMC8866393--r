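test_that("with all conductances off the membrane is a pure capacitor", {
  p <- population_params("STN", g_leak = 0, g_K = 0, g_Na = 0, g_Ca = 0,
                         g_T = 0, g_AHP = 0)
  st <- resting_state(-60, p)
  d <- membrane_rhs(st, p, I_app = 7)
  expect_equal(d$V, 7 / p$C)
  d2 <- membrane_rhs(st, p, I_app = 7, I_syn = 3, I_dbs = 2)
  expect_equal(d2$V, (7 - 3 + 2) / p$C)
})

test_that("derivatives vanish at a numerically located resting point", {
  # root-find V* where dV/dt = 0 with all gates at steady state and the
  # calcium pool equilibrated -- an independent fixed-point oracle
  for (pop in c("STN", "GPe")) {
    p <- population_params(pop)
    # STN: hyperpolarising clamp silences the cell and moves its rest
    # point into (-90, -60); the pallidal cell's (unstable) rest point
    # sits near -70 mV already at zero current
    hold <- if (pop == "STN") -25 else 0
    bracket <- if (pop == "STN") c(-90, -60) else c(-78, -58)
    root <- uniroot(function(V) {
      st <- resting_state(V, p)
      # equilibrate calcium: dCa = 0 => Ca = -(ICa + IT) / k_Ca
      d0 <- membrane_rhs(st, p, I_app = hold)
      st$Ca <- pmax(0, (d0$Ca / p$k2 + p$k_Ca * st$Ca) / p$k_Ca)
      membrane_rhs(st, p, I_app = hold)$V
    }, bracket, tol = 1e-12)$root
    st <- resting_state(root, p)
    d0 <- membrane_rhs(st, p, I_app = hold)
    st$Ca <- pmax(0, (d0$Ca / p$k2 + p$k_Ca * st$Ca) / p$k_Ca)
    d <- membrane_rhs(st, p, I_app = hold)
    expect_lt(abs(d$V), 1e-6)
    expect_lt(abs(d$n), 1e-8)
    expect_lt(abs(d$h), 1e-8)
    expect_lt(abs(d$r), 1e-8)
    expect_lt(abs(d$Ca), 1e-8)
  }
})

test_that("synaptic activation decays exponentially below threshold", {
  p <- population_params("STN")
  s0 <- 0.6
  # far below threshold H ~ 0: ds/dt = -beta s
  expect_equal(synapse_rhs(s0, -200, p$alpha, p$beta, p$theta_0, p$sigma_H),
               -p$beta * s0, tolerance = 1e-8)
  # far above threshold at s = 1: ds/dt = -beta
  expect_equal(synapse_rhs(1, 100, p$alpha, p$beta, p$theta_0, p$sigma_H),
               -p$beta, tolerance = 1e-8)
  # sustained depolarisation fixed point alpha / (alpha + beta)
  s_star <- p$alpha / (p$alpha + p$beta)
  expect_equal(s_star, 5 / 6)
  expect_equal(synapse_rhs(s_star, 100, p$alpha, p$beta, p$theta_0, p$sigma_H),
               0, tolerance = 1e-6)
})

test_that("rhs guards reject mismatched populations and states", {
  expect_error(membrane_rhs(list(V = -60), population_params("THA")),
               "thalamic_rhs")
  expect_error(membrane_rhs(list(V = -60), population_params("STN")),
               "state must contain")
  expect_error(thalamic_rhs(list(V = -60, h = 0, r = 0),
                            population_params("GPe")), "THA")
})

test_that("compiled integrator matches a deSolve integration of the R rhs", {
  skip_if_not_installed("deSolve")
  p <- population_params("STN")
  st0 <- resting_state(-62, p)
  f <- function(t, y, parms) {
    st <- list(V = y[1], n = y[2], h = y[3], r = y[4], Ca = y[5], s = y[6])
    d <- membrane_rhs(st, p, I_app = 4)
    list(c(d$V, d$n, d$h, d$r, d$Ca, d$s))
  }
  y0 <- c(st0$V, st0$n, st0$h, st0$r, st0$Ca, st0$s)
  ref <- deSolve::ode(y0, seq(0, 600, by = 0.05), f, NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-8)
  ref_spikes <- detect_spikes(ref[, 1], ref[, 2])
  sim <- simulate_neuron("STN", I_app = 4, duration = 600, V0 = -62,
                         rtol = 1e-8, atol = 1e-8)
  expect_equal(length(sim$spikes), length(ref_spikes))
  expect_lt(max(abs(sim$spikes - ref_spikes)), 0.5)

  # thalamic cell under constant depolarisation, same cross-check
  pt <- population_params("THA")
  ft <- function(t, y, parms) {
    d <- thalamic_rhs(list(V = y[1], h = y[2], r = y[3]), pt)
    list(c(d$V, d$h, d$r))
  }
  st0 <- resting_state(-70, pt)
  reft <- deSolve::ode(c(st0$V, st0$h, st0$r), seq(0, 400, by = 0.05), ft,
                       NULL, method = "ode45", rtol = 1e-8, atol = 1e-8)
  simt <- simulate_neuron("THA", duration = 400, V0 = -70, rtol = 1e-8,
                          atol = 1e-8)
  # no stimulus: both stay quiescent and end at the same potential
  expect_equal(length(simt$spikes), length(detect_spikes(reft[, 1], reft[, 2])))
})
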