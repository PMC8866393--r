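# Shared fixtures: a scaled-down network for fast structural and solver
# tests, and a memoised set of full-size scenario runs shared by the
# acceptance criteria (each full run integrates 1700 neurons for 1.5 s).

# the sparse-hub STN rule needs more hubs than its mean degree, so the
# scaled-down fixture uses the dense small-world STN variant
small_topology <- function(seed = 1, n = 60, n_tha = 24) {
  build_full_network(n_stn = n, n_gpe = n, n_gpi = n, n_tha = n_tha,
                     stn_topology = "dense", seed = seed)
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(condition, seed, dbs_frequency = 184) {
  key <- paste(condition, seed, dbs_frequency, sep = "_")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_scenario(condition, dbs_frequency = dbs_frequency,
                                      seed = seed)
  .run_cache[[key]]
}

acceptance_seeds <- 1:5

scenario_summaries <- function(condition, dbs_frequency = 184) {
  purrr::map_dfr(acceptance_seeds, function(s)
    glance(cached_run(condition, s, dbs_frequency)))
}

# brute-force synaptic current: explicit double loop over (post, pre)
loop_synaptic_drive <- function(s_pre, A, g, E_rev, V_post) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    acc <- 0
    for (j in seq_len(ncol(A))) acc <- acc + A[i, j] * s_pre[j]
    out[i] <- g * (V_post[i] - E_rev) * acc
  }
  out
}

# colored noise with power ~ f^alpha, generated by spectral shaping:
# random-phase hermitian spectrum with amplitude k^(alpha/2), inverse FFT
shaped_noise <- function(n, alpha, seed = 1) {
  stopifnot(n %% 2 == 0)
  withr::with_seed(seed, {
    k <- seq_len(n / 2 - 1)
    ph <- runif(length(k), 0, 2 * pi)
    X <- complex(length.out = n)
    X[k + 1] <- k^(alpha / 2) * exp(1i * ph)
    X[n - k + 1] <- Conj(X[k + 1])
    Re(fft(X, inverse = TRUE)) / n
  })
}
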