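#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

ring_distance <- function(i, j, N) {
  d <- abs(i - j)
  pmin(d, N - d)
}

edge_set <- function(pre, post, n_pre, n_post, g = NA_real_,
                     E_rev = NA_real_) {
  stopifnot(length(pre) == length(post))
  list(pre = as.integer(pre), post = as.integer(post),
       n_pre = as.integer(n_pre), n_post = as.integer(n_post),
       g = g, E_rev = E_rev)
}

#' Watts-Strogatz small-world ring
#'
#' Ring lattice of `N` nodes, each linked to its `k` nearest neighbours
#' (`k/2` on each side, periodic boundaries), with every lattice edge
#' rewired with probability `p` to a uniformly chosen non-duplicate,
#' non-self target.  The number of undirected edges (`N k / 2`) is
#' conserved exactly; the returned edge set is directed with both
#' directions instantiated.
#'
#' @param N number of nodes.
#' @param k even mean degree, `k < N`.
#' @param p rewiring probability in \[0, 1\].
#' @param seed optional integer for a reproducible graph.
#' @return edge set (list with 1-based `pre`, `post` vectors).
#' @examples
#' ws <- build_ws_ring(100, 10, 0.01, seed = 1)
#' length(ws$pre)   # 100 * 10 directed edges
#' @export
build_ws_ring <- function(N, k, p, seed = NULL) {
  if (k %% 2 != 0) stop("k must be even")
  if (k >= N) stop("k must be smaller than N")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  with_seed(seed, {
    adj <- matrix(FALSE, N, N)
    from <- integer(0); to <- integer(0)
    for (d in seq_len(k / 2)) {
      i <- seq_len(N)
      j <- ((i - 1 + d) %% N) + 1
      from <- c(from, i); to <- c(to, j)
    }
    for (e in seq_along(from)) adj[from[e], to[e]] <- adj[to[e], from[e]] <- TRUE
    rewire <- runif(length(from)) < p
    for (e in which(rewire)) {
      i <- from[e]
      repeat {
        j2 <- sample.int(N, 1)
        if (j2 != i && !adj[i, j2]) break
      }
      adj[i, to[e]] <- adj[to[e], i] <- FALSE
      adj[i, j2] <- adj[j2, i] <- TRUE
      to[e] <- j2
    }
    edge_set(c(from, to), c(to, from), N, N)
  })
}

#' Sparse subthalamic connectivity
#'
#' Only a `hub_fraction` of STN neurons form intra-nuclear synapses; the
#' rest are isolated.  Hubs connect to other hubs with a mean (total)
#' degree of `mean_degree`, drawing partners by ring-distance band:
#' local (`distance <= 10`), intermediate (`10 < distance <= 20`) and
#' remote (`distance > 25`), with weights `bands` summing to 1.  Edges
#' are undirected draws instantiated in both directions; the hub with the
#' currently smallest degree receives the next edge, so the mean hub
#' degree equals `mean_degree` exactly (up to rounding of the edge
#' count).
#'
#' @param N population size.
#' @param hub_fraction fraction of connected neurons; `hub_fraction * N`
#'   must be an integer.
#' @param mean_degree target mean total degree of a hub.
#' @param bands weights of the local / intermediate / remote distance
#'   bands.
#' @param seed optional integer seed.
#' @return edge set with attribute `hubs` (1-based hub indices).
#' @export
build_sparse_stn <- function(N, hub_fraction = 0.2, mean_degree = 25,
                             bands = c(local = 0.30, intermediate = 0.45,
                                       remote = 0.25),
                             seed = NULL) {
  n_hub <- hub_fraction * N
  if (abs(n_hub - round(n_hub)) > 1e-9)
    stop("hub_fraction * N must be an integer")
  n_hub <- as.integer(round(n_hub))
  if (n_hub <= mean_degree)
    stop("need more hubs than mean_degree")
  if (abs(sum(bands) - 1) > 1e-9) stop("band weights must sum to 1")
  with_seed(seed, {
    hubs <- sort(sample.int(N, n_hub))
    n_edges <- round(n_hub * mean_degree / 2)
    deg <- setNames(integer(n_hub), hubs)
    adj <- matrix(FALSE, n_hub, n_hub)
    from <- integer(n_edges); to <- integer(n_edges)
    in_band <- function(d, b) {
      switch(b, local = d <= 10, intermediate = d > 10 & d <= 20,
             remote = d > 25)
    }
    for (e in seq_len(n_edges)) {
      i <- which(deg == min(deg))
      if (length(i) > 1) i <- sample(i, 1)
      d <- ring_distance(hubs[i], hubs, N)
      free <- !adj[i, ] & seq_len(n_hub) != i
      picked <- NA_integer_
      pos <- names(bands)[bands > 0]
      ord <- if (length(pos) > 1) sample(pos, length(pos), prob = bands[pos])
             else pos
      for (b in c(ord, setdiff(names(bands), pos))) {
        cand <- which(free & in_band(d, b))
        if (length(cand)) { picked <- cand[sample.int(length(cand), 1)]; break }
      }
      if (is.na(picked)) {  # saturated in every band: any free hub
        cand <- which(free)
        picked <- cand[sample.int(length(cand), 1)]
      }
      adj[i, picked] <- adj[picked, i] <- TRUE
      deg[i] <- deg[i] + 1L; deg[picked] <- deg[picked] + 1L
      from[e] <- hubs[i]; to[e] <- hubs[picked]
    }
    es <- edge_set(c(from, to), c(to, from), N, N)
    attr(es, "hubs") <- hubs
    es
  })
}

# GPe -> GPi: ring-local fan-out (9 each side around the matching index)
# plus 2 uniform remote targets; mean out-degree 20 exactly
build_gpe_gpi <- function(N, local_halfwidth = 9, n_remote = 2, seed = NULL) {
  with_seed(seed, {
    from <- integer(0); to <- integer(0)
    offs <- c(-(local_halfwidth:1), 1:local_halfwidth)
    for (i in seq_len(N)) {
      loc <- ((i - 1 + offs) %% N) + 1
      far <- setdiff(seq_len(N), c(i, loc))
      rem <- far[sample.int(length(far), n_remote)]
      from <- c(from, rep(i, length(loc) + n_remote))
      to <- c(to, loc, rem)
    }
    edge_set(from, to, N, N)
  })
}

#' Assemble the full basal ganglia-thalamus connectivity
#'
#' Builds all seven projections: intra-GPe and intra-GPi Watts-Strogatz
#' rings (`k = 20`, `p = 0.005`), intra-STN sparse hub connectivity (or a
#' dense `k = 20` small-world variant), reciprocal one-to-one GPe-STN
#' wiring, one-to-one STN to GPi wiring, GPe to GPi small-world fan-out
#' (mean out-degree 20) and GPi to thalamus wiring in which 200 uniformly
#' chosen GPi neurons form a pool from which every thalamic neuron draws
#' 3 distinct afferents.  Synaptic conductances default to
#' `(g_STST, g_GPST, g_GPeGPe, g_STGPe, g_GPiGPi, g_GPeGPi, g_STGPi,
#' g_GPiTha) = (0.5, 4.5, 0.07, 0.56, 0.07, 0.01, 0.2, 0.1)` with
#' glutamate reversal -10 mV and GABA reversal -70 mV.
#'
#' @param n_stn,n_gpe,n_gpi,n_tha population sizes.
#' @param stn_topology `"sparse"` (default) or `"dense"`.
#' @param conductances named vector overriding individual projection
#'   conductances.
#' @param ws_k,ws_p pallidal small-world parameters.
#' @param seed optional integer seed; the build is bit-reproducible given
#'   the seed.
#' @return object of class `bg_topology`: list of named projections, each
#'   an edge set with conductance and reversal potential.
#' @examples
#' top <- build_full_network(seed = 1)
#' connection_census(top)
#' @export
build_full_network <- function(n_stn = 500, n_gpe = 500, n_gpi = 500,
                               n_tha = 200,
                               stn_topology = c("sparse", "dense"),
                               conductances = NULL,
                               ws_k = 20, ws_p = 0.005, seed = NULL) {
  stn_topology <- match.arg(stn_topology)
  if (n_stn != n_gpe || n_stn != n_gpi)
    stop("one-to-one inter-nuclear wiring requires equal STN/GPe/GPi sizes")
  g <- c(STST = 0.5, GPST = 4.5, GPeGPe = 0.07, STGPe = 0.56,
         GPiGPi = 0.07, GPeGPi = 0.01, STGPi = 0.2, GPiTha = 0.1)
  if (!is.null(conductances)) {
    if (is.null(names(conductances)) ||
        !all(names(conductances) %in% names(g)))
      stop("conductance overrides must be named after projections")
    g[names(conductances)] <- conductances
  }
  E_Glu <- -10; E_GABA <- -70
  with_seed(seed, {
    stn <- if (stn_topology == "sparse")
      build_sparse_stn(n_stn) else build_ws_ring(n_stn, ws_k, ws_p)
    gpe <- build_ws_ring(n_gpe, ws_k, ws_p)
    gpi <- build_ws_ring(n_gpi, ws_k, ws_p)
    gpegpi <- build_gpe_gpi(n_gpe)
    idx <- seq_len(n_stn)
    pool <- sort(sample.int(n_gpi, n_tha))
    tha_pre <- integer(0); tha_post <- integer(0)
    for (i in seq_len(n_tha)) {
      tha_pre <- c(tha_pre, pool[sample.int(length(pool), 3)])
      tha_post <- c(tha_post, rep(i, 3))
    }
    proj <- list(
      STST = within_set(stn, g[["STST"]], E_Glu),
      GPST = within_set(edge_set(idx, idx, n_gpe, n_stn), g[["GPST"]], E_GABA),
      GPeGPe = within_set(gpe, g[["GPeGPe"]], E_GABA),
      STGPe = within_set(edge_set(idx, idx, n_stn, n_gpe), g[["STGPe"]], E_Glu),
      GPiGPi = within_set(gpi, g[["GPiGPi"]], E_GABA),
      GPeGPi = within_set(gpegpi, g[["GPeGPi"]], E_GABA),
      STGPi = within_set(edge_set(idx, idx, n_stn, n_gpi), g[["STGPi"]], E_Glu),
      GPiTha = within_set(edge_set(tha_pre, tha_post, n_gpi, n_tha),
                          g[["GPiTha"]], E_GABA))
    structure(list(
      sizes = c(STN = n_stn, GPe = n_gpe, GPi = n_gpi, THA = n_tha),
      stn_topology = stn_topology,
      projections = proj,
      E_Glu = E_Glu, E_GABA = E_GABA,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
      class = "bg_topology")
  })
}

within_set <- function(es, g, E_rev) {
  es$g <- g; es$E_rev <- E_rev
  es
}

# population of origin / target for each canonical projection
.proj_pops <- list(
  STST = c("STN", "STN"), GPST = c("GPe", "STN"),
  GPeGPe = c("GPe", "GPe"), STGPe = c("STN", "GPe"),
  GPiGPi = c("GPi", "GPi"), GPeGPi = c("GPe", "GPi"),
  STGPi = c("STN", "GPi"), GPiTha = c("GPi", "THA"))

#' @export
print.bg_topology <- function(x, ...) {
  cat("<bg_topology> ", sum(x$sizes), " neurons (",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "),
      "), STN ", x$stn_topology, "\n", sep = "")
  print(connection_census(x))
  invisible(x)
}

#' Per-projection connection counts and degree summaries
#'
#' @param topology a [build_full_network()] topology.
#' @return tibble with one row per projection: edge count, conductance,
#'   reversal potential, mean out-degree of presynaptic neurons and mean
#'   in-degree of postsynaptic neurons.
#' @export
connection_census <- function(topology) {
  stopifnot(inherits(topology, "bg_topology"))
  purrr::imap_dfr(topology$projections, function(es, nm) {
    pp <- .proj_pops[[nm]]
    tibble::tibble(
      projection = nm, pre = pp[1], post = pp[2],
      n_edges = length(es$pre), g = es$g, E_rev = es$E_rev,
      mean_out_degree = length(es$pre) / es$n_pre,
      mean_in_degree = length(es$pre) / es$n_post)
  })
}

#' Serialise a topology to a plain-text edge list
#'
#' Writes `projection, pre_index, post_index` rows (0-based indices) plus
#' a YAML sidecar with sizes, conductances and build metadata; reading
#' restores the topology bit-exactly.
#'
#' @param topology a `bg_topology`.
#' @param path CSV file path; the sidecar is `paste0(path, ".meta.yaml")`.
#' @return `read_topology()` returns the restored `bg_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "bg_topology"))
  df <- purrr::imap_dfr(topology$projections, function(es, nm)
    tibble::tibble(projection = nm, pre_index = es$pre - 1L,
                   post_index = es$post - 1L))
  readr::write_csv(df, path)
  meta <- list(
    sizes = as.list(topology$sizes), stn_topology = topology$stn_topology,
    E_Glu = topology$E_Glu, E_GABA = topology$E_GABA,
    seed = topology$seed,
    g = purrr::map(topology$projections, "g"))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15L)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- readr::read_csv(path, col_types = readr::cols(
    projection = readr::col_character(),
    pre_index = readr::col_integer(), post_index = readr::col_integer()))
  sizes <- unlist(meta$sizes)
  proj <- purrr::imap(meta$g, function(g, nm) {
    sub <- df[df$projection == nm, ]
    pp <- .proj_pops[[nm]]
    es <- edge_set(sub$pre_index + 1L, sub$post_index + 1L,
                   sizes[[pp[1]]], sizes[[pp[2]]])
    E <- if (nm %in% c("STST", "STGPe", "STGPi")) meta$E_Glu else meta$E_GABA
    within_set(es, g, E)
  })
  structure(list(
    sizes = sizes, stn_topology = meta$stn_topology,
    projections = proj[names(.proj_pops)],
    E_Glu = meta$E_Glu, E_GABA = meta$E_GABA,
    seed = if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_
           else as.integer(meta$seed)),
    class = "bg_topology")
}

#' Dense adjacency matrix of one projection
#'
#' Rows are postsynaptic, columns presynaptic (`A[i, j] = 1` iff j
#' projects to i), matching [synaptic_drive()].
#'
#' @param topology a `bg_topology`.
#' @param projection projection name, e.g. `"GPiTha"`.
#' @export
adjacency_matrix <- function(topology, projection) {
  es <- topology$projections[[projection]]
  if (is.null(es)) stop("unknown projection: ", projection)
  A <- matrix(0L, es$n_post, es$n_pre)
  A[cbind(es$post, es$pre)] <- 1L
  A
}
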