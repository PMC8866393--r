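#' Piecewise-linear spike phase
#'
#' Between consecutive spikes `t_n` and `t_(n+1)` the phase grows
#' linearly by 2 pi:
#' `theta(t) = 2 pi (t - t_n) / (t_(n+1) - t_n) + 2 pi n`.
#' Times outside `[first spike, last spike)` have undefined phase and
#' return `NA` (the neuron is then excluded from the order parameter).
#'
#' @param spike_times sorted spike times of one neuron (ms); at least 2.
#' @param t evaluation times (ms); vectorised.
#' @return unwrapped phase in radians (`NA` where undefined).
#' @export
linear_phase <- function(spike_times, t) {
  if (length(spike_times) < 2) return(rep(NA_real_, length(t)))
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  n <- findInterval(t, spike_times)
  ok <- n >= 1 & t < spike_times[length(spike_times)]
  th <- rep(NA_real_, length(t))
  tn <- spike_times[n[ok]]
  tn1 <- spike_times[n[ok] + 1]
  th[ok] <- 2 * pi * (t[ok] - tn) / (tn1 - tn) + 2 * pi * (n[ok] - 1)
  th
}

#' Instantaneous phase via the analytic signal
#'
#' The discrete Hilbert transform (FFT construction of the analytic
#' signal) of a mean-removed uniformly sampled signal; the returned phase
#' is `atan2(X(t), x(t))` wrapped to `[0, 2 pi)`.
#'
#' @param x signal on a uniform grid; at least 256 samples.
#' @return phase in `[0, 2 pi)`.
#' @export
hilbert_phase <- function(x) {
  n <- length(x)
  if (n < 256) stop("need at least 256 samples")
  x <- x - mean(x)
  if (max(abs(x)) == 0) stop("phase of a constant signal is undefined")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  th <- atan2(Im(z), Re(z))
  th %% (2 * pi)
}

#' Kuramoto synchronisation index
#'
#' Modulus of the population-mean unit phasor
#' \eqn{r = | N^{-1} \sum_k e^{i \theta_k} |}: 1 for identical phases, 0 for
#' incoherent (e.g. uniformly spread) phases.
#'
#' @param phases numeric vector of phases (radians); at least 2 finite
#'   values.
#' @return r in \[0, 1\].
#' @examples
#' sync_index(c(0, pi / 2))      # sqrt(2) / 2
#' @export
sync_index <- function(phases) {
  phases <- phases[is.finite(phases)]
  if (length(phases) < 2)
    stop("need at least 2 neurons with a defined phase")
  Mod(mean(exp(1i * phases)))
}

#' Synchronisation index over time from spike trains
#'
#' Evaluates [linear_phase()] for every neuron on a uniform grid and
#' takes the [sync_index()] across neurons at each time; neurons whose
#' phase is undefined at a time (outside their spiking span, or with
#' fewer than 2 spikes) are excluded there, and times with fewer than 2
#' defined phases give `NA`.
#'
#' @param spikes list of per-neuron spike time vectors.
#' @param t_grid evaluation times (ms).
#' @return tibble with columns `t`, `r`, `n_defined`.
#' @export
sync_series <- function(spikes, t_grid) {
  ph <- vapply(spikes, linear_phase, numeric(length(t_grid)), t = t_grid)
  if (is.null(dim(ph))) ph <- matrix(ph, nrow = length(t_grid))
  r <- apply(ph, 1, function(row) {
    row <- row[is.finite(row)]
    if (length(row) < 2) NA_real_ else Mod(mean(exp(1i * row)))
  })
  tibble::tibble(t = t_grid, r = r,
                 n_defined = apply(ph, 1, function(row) sum(is.finite(row))))
}

#' Mean synaptic activity l(t)
#'
#' The arithmetic mean across neurons of the synaptic activation
#' variables, `l(t) = mean_i s_i(t)` -- the model's proxy for the
#' inhibitory drive a population projects (for GPi: onto the thalamus),
#' and its stand-in for a local field potential.
#'
#' @param sim a `bg_sim` with a recorded s matrix, or a plain matrix
#'   (rows = times) with `t` supplied.
#' @param population population whose s matrix is used.
#' @param t time grid when `sim` is a matrix.
#' @return tibble with columns `t`, `l`.
#' @export
mean_synaptic_activity <- function(sim, population = "GPi", t = NULL) {
  if (inherits(sim, "bg_sim")) {
    S <- sim$S[[population]]
    if (is.null(S)) stop("population ", population, " was not recorded")
    t <- sim$t_s
  } else {
    S <- as.matrix(sim)
    if (is.null(t)) stop("supply t for a plain matrix")
  }
  tibble::tibble(t = t, l = rowMeans(S))
}

#' Thalamic response efficacy R
#'
#' For each sensorimotor pulse onset `t_i` in the analysis window, the
#' fraction `a_i` of thalamic neurons that fire at least one spike within
#' `[t_i, t_i + 2 delta]`; R is the mean of `a_i` over pulses.  R = 1
#' means every thalamic neuron answers every pulse, R = 0 a silent
#' thalamus.
#'
#' @param tha_spikes list of per-neuron thalamic spike time vectors.
#' @param onsets sensorimotor pulse onset times (ms); defaults via
#'   [pulse_onsets()] for the 40 Hz train in `window`.
#' @param delta pulse width (ms); the response window is `2 * delta`.
#' @param window analysis window (ms).
#' @return R in \[0, 1\].
#' @export
response_efficacy <- function(tha_spikes, onsets = NULL, delta = 5,
                              window = c(500, 1500)) {
  if (is.null(onsets))
    onsets <- pulse_onsets(delta, 25, window[2], window[1])
  onsets <- onsets[onsets > window[1] & onsets < window[2]]
  if (!length(onsets)) stop("no pulse onsets inside the window")
  n_tha <- length(tha_spikes)
  a <- vapply(onsets, function(t0) {
    responded <- vapply(tha_spikes, function(ts)
      any(ts >= t0 & ts <= t0 + 2 * delta), logical(1))
    sum(responded) / n_tha
  }, 0.0)
  mean(a)
}

#' Shannon entropy of a bounded macroscopic series
#'
#' Histogram estimate over `bins` equal cells spanning `support`
#' (default \[0, 1\], the range of the order parameters), with the
#' convention `0 log 0 = 0`.  A constant series has entropy 0; a series
#' uniform over the bins attains the maximum `log(bins)`.
#'
#' @param x numeric series (NAs dropped).
#' @param bins number of histogram bins.
#' @param support fixed support of the histogram.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(x, bins = 50, support = c(0, 1)) {
  x <- x[is.finite(x)]
  if (length(x) < bins) stop("series shorter than the number of bins")
  cuts <- seq(support[1], support[2], length.out = bins + 1)
  x <- pmin(pmax(x, support[1]), support[2])
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Power spectrum, peaks and log-log slope of a macroscopic series
#'
#' Periodogram of the mean-removed series, spectral peaks (local maxima
#' above a prominence threshold relative to the strongest peak), and the
#' least-squares slope of log10 power against log10 frequency over
#' `fit_band`, excluding `exclude_half_width` Hz around each detected
#' peak so that narrow rhythmic peaks do not dominate the broadband
#' power-law fit.
#'
#' @param t uniform time grid (ms).
#' @param x series values.
#' @param fit_band frequency band (Hz) of the slope fit.
#' @param exclude_half_width half-width (Hz) removed around each peak.
#' @param peak_band band (Hz) within which peaks are reported.
#' @param min_prominence peak height relative to the maximum power in
#'   `peak_band`.
#' @return list with `spectrum` (tibble `frequency`, `power`), `peaks`
#'   (tibble, strongest first) and `slope`.
#' @export
spectrum_slope <- function(t, x, fit_band = c(1, 100),
                           exclude_half_width = 2,
                           peak_band = c(1, 30), min_prominence = 0.05) {
  if (length(t) != length(x)) stop("t and x must have equal length")
  dt <- diff(t[1:2]) / 1000  # s
  nyq <- 1 / (2 * dt)
  if (fit_band[2] > nyq) stop("fit band exceeds the Nyquist frequency")
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  nf <- floor(n / 2)
  freq <- (1:nf) / (n * dt)
  P <- P[2:(nf + 1)]
  spec <- tibble::tibble(frequency = freq, power = P)

  inb <- freq >= peak_band[1] & freq <= peak_band[2]
  pk <- integer(0)
  if (any(inb)) {
    idx <- which(inb)
    top <- max(P[idx])
    # a peak needs both neighbours present and below it, so the first
    # and last frequency bins never qualify by default
    idx <- idx[idx > 1 & idx < length(P)]
    for (i in idx) {
      if (P[i] >= P[i - 1] && P[i] >= P[i + 1] && P[i] >= min_prominence * top)
        pk <- c(pk, i)
    }
    pk <- pk[order(P[pk], decreasing = TRUE)]
  }
  peaks <- tibble::tibble(frequency = freq[pk], power = P[pk])

  keep <- freq >= fit_band[1] & freq <= fit_band[2] & P > 0
  for (f0 in peaks$frequency)
    keep <- keep & abs(freq - f0) > exclude_half_width
  slope <- if (sum(keep) >= 10) {
    unname(coef(lm(log10(P[keep]) ~ log10(freq[keep])))[2])
  } else NA_real_
  list(spectrum = spec, peaks = peaks, slope = slope)
}

#' Macroscopic observables of a network run
#'
#' Computes the full macroscopic description of a simulation: the
#' synchronisation index r(t) of GPi spiking (linear spike phases by
#' default, Hilbert phases of the s traces optionally), the mean GPi
#' synaptic activity l(t), the thalamic response efficacy R, Shannon
#' entropies of r and l over the full run (transient included) and the
#' spectral peaks and log-log slope of l(t) in the post-transient
#' window.
#'
#' @param sim a `bg_sim` with GPi s recorded.
#' @param window post-transient analysis window (ms) for R and the
#'   spectrum.
#' @param entropy_window window (ms) for the entropies.
#' @param entropy_bins histogram bins on \[0, 1\].
#' @param r_dt grid step (ms) of the r(t) series.
#' @param phase_method `"linear"` (spike trains) or `"hilbert"`
#'   (s traces).
#' @return object of class `bg_macro`: list with `series` (tibble `t`,
#'   `r`, `l`), `R`, `E_r`, `E_l`, `slope`, `peaks`, `spectrum`.
#' @export
macro_analysis <- function(sim, window = c(500, 1500),
                           entropy_window = c(0, 1500), entropy_bins = 50,
                           r_dt = 1, phase_method = c("linear", "hilbert")) {
  stopifnot(inherits(sim, "bg_sim"))
  phase_method <- match.arg(phase_method)
  window[2] <- min(window[2], sim$t_span)
  entropy_window[2] <- min(entropy_window[2], sim$t_span)
  t_grid <- seq(0, sim$t_span, by = r_dt)
  if (phase_method == "linear") {
    rs <- sync_series(sim$spikes$GPi, t_grid)
  } else {
    S <- sim$S$GPi
    ph <- apply(S, 2, function(s) {
      s <- s - mean(s)
      if (max(abs(s)) == 0) return(rep(NA_real_, length(s)))
      hilbert_phase(s)
    })
    r <- apply(ph, 1, function(row) {
      row <- row[is.finite(row)]
      if (length(row) < 2) NA_real_ else Mod(mean(exp(1i * row)))
    })
    rs <- tibble::tibble(t = sim$t_s, r = r)
    rs <- rs[rs$t %in% t_grid, ]
  }
  ll <- mean_synaptic_activity(sim)
  l_on_grid <- approx(ll$t, ll$l, xout = t_grid, rule = 2)$y
  series <- tibble::tibble(t = t_grid, r = rs$r[match(t_grid, rs$t)],
                           l = l_on_grid)
  R <- response_efficacy(sim$spikes$THA, delta = sim$protocol$sm_delta,
                         window = window)
  ew <- series$t >= entropy_window[1] & series$t <= entropy_window[2]
  E_r <- shannon_entropy(series$r[ew], bins = entropy_bins)
  E_l <- shannon_entropy(series$l[ew], bins = entropy_bins)
  sw <- ll$t > window[1] & ll$t <= window[2]
  sp <- spectrum_slope(ll$t[sw], ll$l[sw])
  structure(list(
    series = series, R = R, E_r = E_r, E_l = E_l,
    slope = sp$slope, peaks = sp$peaks, spectrum = sp$spectrum,
    window = window, entropy_window = entropy_window,
    phase_method = phase_method,
    condition = sim$protocol$condition,
    dbs_frequency = sim$protocol$dbs_frequency), class = "bg_macro")
}

#' @export
print.bg_macro <- function(x, ...) {
  cat("<bg_macro> condition ", x$condition,
      if (!is.na(x$dbs_frequency)) paste0(" @ ", x$dbs_frequency, " Hz"),
      "\n", sep = "")
  cat(sprintf("  R = %.3f, E_r = %.2f, E_l = %.2f, slope = %.2f\n",
              x$R, x$E_r, x$E_l, x$slope))
  if (nrow(x$peaks))
    cat("  peaks (Hz):", paste(round(x$peaks$frequency, 1), collapse = ", "),
        "\n")
  invisible(x)
}
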