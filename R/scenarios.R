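#' Run one functional-state scenario end to end
#'
#' Builds (or reuses) a network topology, simulates the chosen condition
#' and computes all macroscopic observables.  The topology seed and the
#' initial-state seed are derived deterministically from `seed` unless
#' explicit seeds are given, so a scenario is reproducible from its
#' manifest alone.
#'
#' @param condition `"normal"`, `"parkinsonian"` or `"dbs"`.
#' @param dbs_frequency DBS frequency (Hz), used when `condition = "dbs"`.
#' @param duration run length (ms); at least 1000 so the response
#'   efficacy window is populated.
#' @param seed master seed; topology and initial-state seeds default to
#'   `seed` and `seed + 1`.
#' @param topology optional prebuilt [build_full_network()] topology
#'   (shared across the runs of a sweep).
#' @param topology_seed,init_seed explicit seeds.
#' @param stn_topology `"sparse"` or `"dense"`.
#' @param params network parameter sets.
#' @param rtol,atol solver tolerances.
#' @param method,dt solver choice; scenario runs default to the fixed-step
#'   RK4 integrator at 0.05 ms, which matches the adaptive reference to
#'   well under a percent on population rates (see the methods vignette
#'   for the comparison).
#' @param ... further arguments to [simulate_network()].
#' @return object of class `bg_run`: list with `sim` (`bg_sim`), `macro`
#'   (`bg_macro`) and `manifest`.
#' @export
run_scenario <- function(condition = c("normal", "parkinsonian", "dbs"),
                         dbs_frequency = 184, duration = 1500, seed = 1,
                         topology = NULL, topology_seed = NULL,
                         init_seed = NULL,
                         stn_topology = c("sparse", "dense"),
                         params = network_params(),
                         rtol = 1e-6, atol = 1e-6,
                         method = "rk4", dt = 0.05, ...) {
  condition <- match.arg(condition)
  stn_topology <- match.arg(stn_topology)
  if (duration < 1000) stop("duration must be at least 1000 ms")
  if (is.null(topology_seed)) topology_seed <- seed
  if (is.null(init_seed)) init_seed <- seed + 1
  if (is.null(topology))
    topology <- build_full_network(stn_topology = stn_topology,
                                   seed = topology_seed)
  protocol <- stimulus_protocol(condition, dbs_frequency = dbs_frequency)
  sim <- simulate_network(topology, protocol, t_span = duration,
                          rtol = rtol, atol = atol, seed = init_seed,
                          params = params, method = method, dt = dt, ...)
  macro <- macro_analysis(sim, window = c(500, min(1500, duration)),
                          entropy_window = c(0, min(1500, duration)))
  manifest <- list(
    condition = condition,
    dbs_frequency = if (condition == "dbs") dbs_frequency else NA_real_,
    duration = duration,
    topology_seed = topology$seed, init_seed = init_seed,
    stn_topology = topology$stn_topology,
    rtol = rtol, atol = atol, method = method,
    package_version = as.character(utils::packageVersion("bgnet")))
  structure(list(sim = sim, macro = macro, manifest = manifest),
            class = "bg_run")
}

#' @export
print.bg_run <- function(x, ...) {
  cat("<bg_run>\n")
  print(x$sim)
  print(x$macro)
  invisible(x)
}

#' @export
tidy.bg_run <- function(x, ...) {
  x$macro$series
}

#' @export
glance.bg_run <- function(x, ...) {
  m <- x$macro
  tibble::tibble(
    condition = m$condition,
    dbs_frequency = m$dbs_frequency,
    R = m$R, E_r = m$E_r, E_l = m$E_l, slope = m$slope,
    peak1 = if (nrow(m$peaks) >= 1) m$peaks$frequency[1] else NA_real_,
    peak2 = if (nrow(m$peaks) >= 2) m$peaks$frequency[2] else NA_real_,
    mean_l = mean(m$series$l[m$series$t > m$window[1]]),
    mean_r = mean(m$series$r[m$series$t > m$window[1]], na.rm = TRUE))
}

#' Sweep the DBS frequency
#'
#' Runs one DBS scenario per frequency with a shared topology and shared
#' initial-state seed (so only the stimulation differs), and aggregates
#' the macroscopic summaries.  Runs are independent: the result does not
#' depend on execution order.
#'
#' @param frequencies DBS frequencies (Hz); at least 2.
#' @param seed master seed shared by all runs.
#' @param duration run length (ms).
#' @param topology optional shared topology.
#' @param ... further arguments to [run_scenario()].
#' @return tibble with one row per frequency: `f`, `R`, `E_r`, `E_l`,
#'   `slope`, `mean_l`.
#' @export
frequency_sweep <- function(frequencies, seed = 1, duration = 1500,
                            topology = NULL, ...) {
  if (length(frequencies) < 2) stop("supply at least 2 frequencies")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (is.null(topology)) topology <- build_full_network(seed = seed)
  purrr::map_dfr(frequencies, function(f) {
    run <- run_scenario("dbs", dbs_frequency = f, duration = duration,
                        seed = seed, topology = topology, ...)
    g <- glance(run)
    tibble::tibble(f = f, R = g$R, E_r = g$E_r, E_l = g$E_l,
                   slope = g$slope, mean_l = g$mean_l)
  })
}

#' Local maxima of a response curve
#'
#' Peak detection used on sweep outputs: 3-point median smoothing
#' followed by local-maximum search with a minimum prominence.
#'
#' @param f,y curve samples (e.g. frequency and response efficacy).
#' @param min_prominence minimum height above the higher neighbouring
#'   minimum.
#' @return tibble of peak locations and heights, strongest first.
#' @export
find_response_peaks <- function(f, y, min_prominence = 0.05) {
  stopifnot(length(f) == length(y))
  n <- length(y)
  if (n < 3) return(tibble::tibble(f = numeric(0), y = numeric(0)))
  ys <- y
  ys[2:(n - 1)] <- vapply(2:(n - 1), function(i) median(y[(i - 1):(i + 1)]),
                          0.0)
  pk <- integer(0)
  for (i in 2:(n - 1)) {
    if (ys[i] > ys[i - 1] && ys[i] >= ys[i + 1]) {
      left_min <- min(ys[1:i]); right_min <- min(ys[i:n])
      if (ys[i] - max(left_min, right_min) >= min_prominence)
        pk <- c(pk, i)
    }
  }
  pk <- pk[order(ys[pk], decreasing = TRUE)]
  tibble::tibble(f = f[pk], y = ys[pk])
}

#' Serialise a run to a directory of plain-text files
#'
#' Writes spike lists, recorded voltage and synaptic-activation traces,
#' the macroscopic series and a JSON manifest (summary scalars included)
#' into `dir`.  [read_run_dir()] restores the spike lists, macro series
#' and manifest.
#'
#' @param run a `bg_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_dir <- function(run, dir) {
  stopifnot(inherits(run, "bg_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- run$sim
  sp <- purrr::imap_dfr(sim$spikes, function(sl, pop)
    purrr::imap_dfr(sl, function(ts, i)
      tibble::tibble(population = pop, neuron = as.integer(i),
                     time = as.numeric(ts))))
  readr::write_csv(sp, file.path(dir, "spikes.csv"))
  readr::write_csv(run$macro$series, file.path(dir, "macro_series.csv"))
  readr::write_csv(run$macro$spectrum, file.path(dir, "spectrum.csv"))
  for (pop in names(sim$S)) {
    S <- tibble::as_tibble(as.data.frame(sim$S[[pop]]), .name_repair = "minimal")
    names(S) <- paste0("s", seq_len(ncol(S)))
    readr::write_csv(dplyr::bind_cols(tibble::tibble(t = sim$t_s), S),
                     file.path(dir, paste0("s_", pop, ".csv")))
  }
  g <- glance(run)
  manifest <- c(run$manifest, list(
    sizes = as.list(sim$sizes),
    summary = as.list(g)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_run_dir
#' @export
read_run_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sp <- readr::read_csv(file.path(dir, "spikes.csv"),
                        col_types = readr::cols(
                          population = readr::col_character(),
                          neuron = readr::col_integer(),
                          time = readr::col_double()))
  spikes <- purrr::map(setNames(nm = POPULATIONS), function(pop) {
    n <- manifest$sizes[[pop]]
    sub <- sp[sp$population == pop, ]
    purrr::map(seq_len(n), function(i) sub$time[sub$neuron == i])
  })
  series <- readr::read_csv(file.path(dir, "macro_series.csv"),
                            col_types = readr::cols())
  list(manifest = manifest, spikes = spikes, series = series)
}
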