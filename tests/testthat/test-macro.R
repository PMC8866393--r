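test_that("linear spike phase interpolates 2 pi per interspike interval", {
  expect_equal(linear_phase(c(0, 100), 50), pi)
  expect_equal(linear_phase(c(0, 100, 150), c(0, 100)) %% (2 * pi), c(0, 0))
  # periodic train at rate f: phase slope 2 pi f
  sp <- seq(0, 1000, by = 50)  # 20 Hz
  t <- seq(100, 800, by = 1)
  th <- linear_phase(sp, t)
  expect_equal(diff(th) / diff(t), rep(2 * pi / 50, length(t) - 1),
               tolerance = 1e-10)
  # undefined outside the spiking span or with < 2 spikes
  expect_true(is.na(linear_phase(c(10, 20), 25)))
  expect_true(all(is.na(linear_phase(c(10), c(5, 15)))))
})

test_that("hilbert phase advances linearly for sinusoids", {
  t <- seq(0, 2, by = 1 / 512)[-1]
  f <- 8
  th <- hilbert_phase(sin(2 * pi * f * t))
  mid <- 200:800
  d <- diff(th[mid]) %% (2 * pi)
  expect_equal(median(d), 2 * pi * f / 512, tolerance = 1e-3)
  # cos leads sin by pi/2
  thc <- hilbert_phase(cos(2 * pi * f * t))
  off <- (thc[mid] - th[mid]) %% (2 * pi)
  expect_equal(median(off), pi / 2, tolerance = 1e-2)
  expect_error(hilbert_phase(rep(1, 300)), "constant")
  expect_error(hilbert_phase(sin(1:100)), "256")
})

test_that("synchronisation index has its analytic values and invariances", {
  expect_equal(sync_index(rep(1.3, 50)), 1)
  expect_equal(sync_index(2 * pi * (0:9) / 10), 0, tolerance = 1e-12)
  expect_equal(sync_index(c(0, pi / 2)), sqrt(2) / 2)
  # global phase shift leaves r unchanged
  withr::with_seed(1, {
    th <- runif(40, 0, 2 * pi)
    for (c0 in c(0.3, 2, -1))
      expect_equal(sync_index(th + c0), sync_index(th))
  })
  expect_error(sync_index(0.2), "at least 2")
})

test_that("sync series excludes undefined phases and flags sparse times", {
  spikes <- list(c(100, 200, 300), c(150, 250), c(500, 600))
  rs <- sync_series(spikes, c(50, 220, 550))
  expect_true(is.na(rs$r[1]))          # nobody has a phase yet
  expect_equal(rs$n_defined[2], 2)     # two neurons defined at 220
  expect_true(is.na(rs$r[3]))          # only one defined at 550
  # identical regular trains => perfect synchrony
  sp <- replicate(5, seq(0, 1000, by = 25), simplify = FALSE)
  rs2 <- sync_series(sp, seq(100, 900, by = 10))
  expect_true(all(abs(rs2$r - 1) < 1e-12))
})

test_that("mean synaptic activity averages the activation matrix", {
  S <- cbind(rep(0, 5), rep(1, 5), rep(0.5, 5))
  out <- mean_synaptic_activity(S, t = 1:5)
  expect_equal(out$l, rep(0.5, 5))
  expect_equal(mean_synaptic_activity(matrix(0, 3, 2), t = 1:3)$l, rep(0, 3))
})

test_that("response efficacy counts responding thalamic neurons per pulse", {
  onsets <- pulse_onsets(5, 25, 1500, 500)
  # every neuron spikes in every window
  all_in <- replicate(4, onsets + 2, simplify = FALSE)
  expect_equal(response_efficacy(all_in, onsets), 1)
  # silent thalamus
  expect_equal(response_efficacy(replicate(4, numeric(0), simplify = FALSE),
                                 onsets), 0)
  # half the neurons respond to every pulse
  half <- c(replicate(2, onsets + 2, simplify = FALSE),
            replicate(2, numeric(0), simplify = FALSE))
  expect_equal(response_efficacy(half, onsets), 0.5)
  # invariant under relabelling of neurons
  withr::with_seed(3, {
    sp <- purrr::map(1:6, ~sort(runif(30, 0, 1500)))
    r1 <- response_efficacy(sp, onsets)
    r2 <- response_efficacy(sp[sample(6)], onsets)
    expect_equal(r1, r2)
  })
  expect_error(response_efficacy(all_in, numeric(0)), "onsets")
})

test_that("histogram entropy spans 0 to log(bins)", {
  expect_equal(shannon_entropy(rep(0.37, 200)), 0)
  # exactly uniform over the bins
  u <- rep((seq_len(50) - 0.5) / 50, each = 4)
  expect_equal(shannon_entropy(u, bins = 50), log(50))
  withr::with_seed(9, {
    x <- runif(5000)
    e <- shannon_entropy(x, bins = 50)
    expect_lte(e, log(50))
    expect_gt(e, 0.9 * log(50))
  })
  expect_error(shannon_entropy(runif(10), bins = 50), "shorter")
})

test_that("spectral slope recovers known power laws", {
  t <- seq_len(4096)  # 1 ms grid
  brown <- shaped_noise(4096, -2, seed = 2)
  sp <- spectrum_slope(t, brown, fit_band = c(2, 100), exclude_half_width = 0,
                       min_prominence = 1.1)  # no peak exclusion
  expect_equal(sp$slope, -2, tolerance = 0.25)
  white <- shaped_noise(4096, 0, seed = 3)
  sp0 <- spectrum_slope(t, white, fit_band = c(2, 100), exclude_half_width = 0,
                        min_prominence = 1.1)
  expect_equal(sp0$slope, 0, tolerance = 0.25)
  # a pure tone shows up as the dominant detected peak
  tone <- sin(2 * pi * 11 * t / 1000) + 0.05 * white
  spt <- spectrum_slope(t, tone)
  expect_equal(spt$peaks$frequency[1], 11, tolerance = 0.05)
  expect_error(spectrum_slope(t, white, fit_band = c(1, 1000)), "Nyquist")
})

test_that("response-curve peak detection finds prominent local maxima", {
  f <- seq(50, 250, by = 2)
  y <- 0.05 + 0.2 * exp(-(f - 184)^2 / 40) + 0.15 * exp(-(f - 210)^2 / 40)
  pk <- find_response_peaks(f, y)
  expect_equal(pk$f[1], 184, tolerance = 2)
  expect_true(any(abs(pk$f - 210) <= 2))
  expect_equal(nrow(find_response_peaks(f, rep(0.3, length(f)))), 0)
})

test_that("spike-phase and analytic-signal order parameters agree", {
  # two independent phase definitions (linear interpolation of spike
  # trains vs Hilbert transform of the s traces) must tell the same
  # macroscopic story on a full-size network run
  run <- cached_run("normal", 1)
  m_lin <- macro_analysis(run$sim)
  m_hil <- macro_analysis(run$sim, phase_method = "hilbert")
  d <- abs(m_lin$series$r - m_hil$series$r)
  ok <- m_lin$series$t > 500 & is.finite(d)
  expect_gt(sum(ok), 500)
  expect_lt(mean(d[ok]), 0.25)
  expect_true(all(m_hil$series$r[is.finite(m_hil$series$r)] >= 0 &
                  m_hil$series$r[is.finite(m_hil$series$r)] <= 1 + 1e-12))
})
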