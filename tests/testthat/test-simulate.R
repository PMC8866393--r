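test_that("spike detection locates threshold crossings by interpolation", {
  t <- seq(0, 1000, by = 0.1)
  expect_length(detect_spikes(t, rep(-60, length(t))), 0)
  # 10 Hz sinusoid crossing -15 mV: one upward crossing per cycle
  V <- -20 + 30 * sin(2 * pi * 10 * t / 1000)
  sp <- detect_spikes(t, V)
  expect_length(sp, 10)
  expect_equal(diff(sp), rep(100, 9), tolerance = 1e-3)
  # crossing times agree with an analytic solution
  t_exact <- (asin(5 / 30) / (2 * pi * 10)) * 1000
  expect_equal(sp[1] %% 100, t_exact, tolerance = 0.05)
  # lockout suppresses double counts
  V2 <- rep(-60, length(t)); V2[c(100, 105)] <- 0  # 0.5 ms apart
  expect_length(detect_spikes(t, V2, lockout = 2), 1)
})

test_that("offline detection on a recorded trace matches a finer grid", {
  sim_c <- simulate_neuron("STN", I_app = 10, duration = 1000, v_dt = 0.1)
  sim_f <- simulate_neuron("STN", I_app = 10, duration = 1000, v_dt = 0.01)
  a <- detect_spikes(sim_c$trace$t, sim_c$trace$V)
  b <- detect_spikes(sim_f$trace$t, sim_f$trace$V)
  expect_equal(length(a), length(b))
  expect_lt(max(abs(a - b)), 0.2)
  # and both agree with the online (solver-step) detection
  expect_equal(length(sim_c$spikes), length(a))
  expect_lt(max(abs(sim_c$spikes - a)), 0.2)
})

test_that("network runs are deterministic given seeds", {
  top <- small_topology(seed = 4)
  pro <- stimulus_protocol("normal")
  a <- simulate_network(top, pro, t_span = 300, seed = 9, method = "rk4",
                        dt = 0.05)
  b <- simulate_network(top, pro, t_span = 300, seed = 9, method = "rk4",
                        dt = 0.05)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$S, b$S)
  c <- simulate_network(top, pro, t_span = 300, seed = 10, method = "rk4",
                        dt = 0.05)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("raster conserves events and population rates average counts", {
  top <- small_topology(seed = 4)
  sim <- simulate_network(top, stimulus_protocol("normal"), t_span = 400,
                          seed = 9, method = "rk4", dt = 0.05)
  rs <- raster(sim, "GPe")
  expect_equal(nrow(rs), sum(lengths(sim$spikes$GPe)))
  expect_true(all(rs$neuron %in% seq_len(top$sizes[["GPe"]])))
  pr <- population_rates(sim, window = c(100, 400))
  manual <- mean(vapply(sim$spikes$GPe, function(ts)
    sum(ts > 100 & ts <= 400), 0L)) / 0.3
  expect_equal(pr$rate[pr$population == "GPe"], manual)
  empty <- raster(structure(list(spikes = list(STN = list(), GPe = list(),
    GPi = list(), THA = list())), class = "bg_sim"), "GPi")
  expect_equal(nrow(empty), 0)
})

test_that("fixed-step and adaptive integration agree on population rates", {
  # full-size network: population averages over 500 neurons are the
  # stable observable (small nets amplify trajectory-level chaos)
  top <- build_full_network(seed = 6)
  pro <- stimulus_protocol("normal")
  r1 <- population_rates(simulate_network(top, pro, t_span = 700, seed = 2,
                                          method = "rk4", dt = 0.05),
                         window = c(300, 700))
  r2 <- population_rates(simulate_network(top, pro, t_span = 700, seed = 2,
                                          method = "rk4", dt = 0.025),
                         window = c(300, 700))
  r3 <- population_rates(simulate_network(top, pro, t_span = 700, seed = 2,
                                          method = "adaptive"),
                         window = c(300, 700))
  active <- r1$rate > 5
  expect_true(any(active))
  expect_lt(max(abs(r1$rate[active] - r2$rate[active]) / r1$rate[active]), 0.05)
  expect_lt(max(abs(r1$rate[active] - r3$rate[active]) / r1$rate[active]), 0.05)
})

test_that("tightening tolerances changes population rates by under 5%", {
  top <- small_topology(seed = 6)
  pro <- stimulus_protocol("parkinsonian")
  r1 <- population_rates(simulate_network(top, pro, t_span = 500, seed = 2,
                                          rtol = 1e-6, atol = 1e-6),
                         window = c(200, 500))
  r2 <- population_rates(simulate_network(top, pro, t_span = 500, seed = 2,
                                          rtol = 1e-7, atol = 1e-7),
                         window = c(200, 500))
  active <- r1$rate > 1
  expect_true(any(active))
  expect_lt(max(abs(r1$rate[active] - r2$rate[active]) / r1$rate[active]), 0.05)
})

test_that("permuting neuron labels leaves macroscopic observables unchanged", {
  top <- small_topology(seed = 8)
  n <- top$sizes[["GPi"]]
  perm <- withr::with_seed(5, sample(n))
  top2 <- top
  for (nm in names(top2$projections)) {
    es <- top2$projections[[nm]]
    pp <- bgnet:::.proj_pops[[nm]]
    if (pp[1] == "GPi") es$pre <- perm[es$pre]
    if (pp[2] == "GPi") es$post <- perm[es$post]
    top2$projections[[nm]] <- es
  }
  pro <- stimulus_protocol("parkinsonian")
  params <- network_params()
  init <- initial_state(top$sizes, params, seed = 3)
  init2 <- init
  init2$GPi <- purrr::map(init$GPi, function(x) { x[perm] <- x; x })
  s1 <- simulate_network(top, pro, t_span = 400, init = init,
                         method = "rk4", dt = 0.05)
  s2 <- simulate_network(top2, pro, t_span = 400, init = init2,
                         method = "rk4", dt = 0.05)
  l1 <- mean_synaptic_activity(s1)$l
  l2 <- mean_synaptic_activity(s2)$l
  expect_equal(l1, l2, tolerance = 1e-10)
  expect_equal(sum(lengths(s1$spikes$GPi)), sum(lengths(s2$spikes$GPi)))
  expect_equal(sum(lengths(s1$spikes$THA)), sum(lengths(s2$spikes$THA)))
})

test_that("single-population network reproduces the isolated neuron", {
  # a 1-neuron STN 'network' with no synapses equals simulate_neuron
  top <- structure(list(
    sizes = c(STN = 1L, GPe = 1L, GPi = 1L, THA = 1L),
    stn_topology = "sparse",
    projections = list(),
    E_Glu = -10, E_GABA = -70, seed = NA_integer_), class = "bg_topology")
  pro <- stimulus_protocol("normal", I_app = c(GPe = 0, GPi = 0))
  params <- network_params()
  init <- list(STN = resting_state(-62, params$STN),
               GPe = resting_state(-90, params$GPe),
               GPi = resting_state(-90, params$GPi),
               THA = resting_state(-70, params$THA))
  sim <- simulate_network(top, pro, t_span = 1500, init = init,
                          record_s = "GPi")
  lone <- simulate_neuron("STN", I_app = 4, duration = 1500, V0 = -62)
  expect_equal(length(sim$spikes$STN[[1]]), length(lone$spikes))
  # step sequences differ (error control spans all four cells), so allow
  # a small accumulated phase shift
  expect_lt(max(abs(sim$spikes$STN[[1]] - lone$spikes)), 5)
})

test_that("a run serialises to plain text and reloads", {
  run <- run_scenario("normal", duration = 1000, seed = 1,
                      topology = small_topology(seed = 1))
  dir <- withr::local_tempdir()
  write_run_dir(run, dir)
  expect_true(file.exists(file.path(dir, "spikes.csv")))
  back <- read_run_dir(dir)
  expect_equal(back$manifest$condition, "normal")
  expect_equal(
    sum(lengths(back$spikes$GPi)), sum(lengths(run$sim$spikes$GPi)))
  expect_equal(back$series$l, run$macro$series$l, tolerance = 1e-9)
  got <- unlist(back$spikes$THA)
  want <- unlist(run$sim$spikes$THA)
  expect_equal(got, want, tolerance = 1e-9)
})
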