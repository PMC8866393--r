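ring_dist <- function(i, j, N) pmin(abs(i - j), N - abs(i - j))

test_that("the unrewired ring lattice is exact", {
  ws <- build_ws_ring(500, 20, 0, seed = 1)
  expect_length(ws$pre, 10000)                     # 5000 undirected edges
  expect_true(all(ring_dist(ws$pre, ws$post, 500) <= 10))
  # both directions present
  key <- paste(ws$pre, ws$post)
  rev <- paste(ws$post, ws$pre)
  expect_true(all(rev %in% key))
  # no self loops
  expect_true(all(ws$pre != ws$post))
})

test_that("rewiring conserves edges and creates long-range shortcuts", {
  long_any <- vapply(1:20, function(s) {
    ws <- build_ws_ring(500, 20, 0.005, seed = s)
    expect_length(ws$pre, 10000)
    any(ring_dist(ws$pre, ws$post, 500) > 10)
  }, logical(1))
  expect_gt(mean(long_any), 0.8)  # shortcuts appear for most seeds

  # p = 1: same degree, clustering far below the lattice value
  g_lat <- igraph::graph_from_edgelist(
    cbind(build_ws_ring(200, 10, 0, seed = 1)$pre,
          build_ws_ring(200, 10, 0, seed = 1)$post))
  ws1 <- build_ws_ring(200, 10, 1, seed = 1)
  g_rnd <- igraph::graph_from_edgelist(cbind(ws1$pre, ws1$post))
  expect_equal(length(ws1$pre) / 200, 10)
  c_lat <- igraph::transitivity(igraph::as_undirected(g_lat, mode = "collapse"))
  c_rnd <- igraph::transitivity(igraph::as_undirected(g_rnd, mode = "collapse"))
  expect_lt(c_rnd, c_lat / 3)
  expect_error(build_ws_ring(10, 10, 0.1), "smaller than N")
  expect_error(build_ws_ring(10, 3, 0.1), "even")
})

test_that("sparse subthalamic wiring isolates 80% and gives hubs ~25 links", {
  stn <- build_sparse_stn(500, seed = 3)
  hubs <- attr(stn, "hubs")
  expect_length(hubs, 100)
  touched <- sort(unique(c(stn$pre, stn$post)))
  expect_true(all(touched %in% hubs))
  expect_equal(length(setdiff(1:500, hubs)), 400)  # isolated neurons
  # total (undirected) degree per hub: each undirected edge appears in both
  # directions, so halve the directed incidences
  tot <- (table(factor(stn$pre, levels = hubs)) +
          table(factor(stn$post, levels = hubs))) / 2
  expect_equal(mean(tot), 25, tolerance = 2 / 25)
  expect_error(build_sparse_stn(100, hub_fraction = 0.1, mean_degree = 25),
               "more hubs")
  # degenerate limit: all neurons hubs, purely local
  loc <- build_sparse_stn(100, hub_fraction = 1, mean_degree = 6,
                          bands = c(local = 1, intermediate = 0, remote = 0),
                          seed = 1)
  expect_true(all(ring_dist(loc$pre, loc$post, 100) <= 10))
})

test_that("the assembled network has the published size and wiring counts", {
  top <- build_full_network(seed = 1)
  expect_equal(sum(top$sizes), 1700)
  cen <- connection_census(top)
  expect_setequal(cen$projection,
                  c("STST", "GPST", "GPeGPe", "STGPe", "GPiGPi", "GPeGPi",
                    "STGPi", "GPiTha"))
  # one-to-one inter-nuclear wiring
  expect_equal(cen$n_edges[cen$projection == "GPST"], 500)
  expect_equal(cen$n_edges[cen$projection == "STGPe"], 500)
  expect_equal(cen$n_edges[cen$projection == "STGPi"], 500)
  # pallido-pallidal fan-out 20 +- 1
  expect_equal(cen$mean_out_degree[cen$projection == "GPeGPi"], 20,
               tolerance = 0.05)
  # every thalamic neuron has exactly 3 pallidal afferents
  gt <- top$projections$GPiTha
  expect_true(all(table(gt$post) == 3))
  expect_lte(length(unique(gt$pre)), 200)
  # conductance vector as published
  g <- setNames(cen$g, cen$projection)
  expect_equal(unname(g[c("STST", "GPST", "GPeGPe", "STGPe", "GPiGPi",
                          "GPeGPi", "STGPi", "GPiTha")]),
               c(0.5, 4.5, 0.07, 0.56, 0.07, 0.01, 0.2, 0.1))
  # total synapse count near 30000
  expect_lt(abs(sum(cen$n_edges) - 30000) / 30000, 0.2)
})

test_that("topology builds are reproducible and serialisable bit-exactly", {
  a <- build_full_network(seed = 42)
  b <- build_full_network(seed = 42)
  expect_identical(a$projections, b$projections)
  c <- build_full_network(seed = 43)
  expect_false(identical(a$projections, c$projections))

  path <- withr::local_tempfile(fileext = ".csv")
  write_topology(a, path)
  a2 <- read_topology(path)
  for (nm in names(a$projections)) {
    expect_identical(a2$projections[[nm]]$pre, a$projections[[nm]]$pre)
    expect_identical(a2$projections[[nm]]$post, a$projections[[nm]]$post)
    expect_equal(a2$projections[[nm]]$g, a$projections[[nm]]$g)
  }
  expect_identical(connection_census(a2), connection_census(a))
})

test_that("the dense subthalamic variant is a k = 20 small world", {
  top <- build_full_network(stn_topology = "dense", seed = 5)
  cen <- connection_census(top)
  expect_equal(cen$mean_out_degree[cen$projection == "STST"], 20)
  expect_equal(sum(top$sizes), 1700)
})

test_that("adjacency matrices agree with edge lists", {
  top <- small_topology(seed = 2)
  A <- adjacency_matrix(top, "GPiTha")
  es <- top$projections$GPiTha
  expect_equal(sum(A), length(es$pre))
  expect_true(all(A[cbind(es$post, es$pre)] == 1L))
  expect_true(all(rowSums(A) == 3))
  expect_error(adjacency_matrix(top, "nope"), "unknown projection")
})
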