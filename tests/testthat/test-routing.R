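test_that("link times are length over speed", {
  expect_equal(link_time(1000, 10), 100)
  expect_equal(link_time(250, 10), 25)
  expect_equal(link_time(c(500, 1500), c(10, 20)), c(50, 75))
  expect_error(link_time(1000, 0), "speed")
})

test_that("a fast detour beats a slow direct link", {
  net <- road_network(
    nodes = data.frame(id = 1:3, x = c(0, 1000, 500), y = c(0, 0, 800)),
    links = data.frame(from = c(1, 1, 3), to = c(2, 3, 2),
                       length_m = 1000, speed_mps = c(5, 20, 20)))
  p <- shortest_time_path(net, 1, 2)
  expect_equal(p$node_ids, c(1, 3, 2))
  expect_equal(p$freeflow_time_s, 100)
  expect_equal(p$total_length_m, 2000)
})

test_that("identical origin and destination give an empty path", {
  net <- square_network()
  p <- shortest_time_path(net, 2, 2)
  expect_equal(length(p$node_ids), 1)
  expect_equal(p$freeflow_time_s, 0)
  expect_equal(p$total_length_m, 0)
})

test_that("path free-flow time equals the sum of its link times", {
  net <- square_network(speed = 12.5)
  p <- shortest_time_path(net, 1, 4)
  expect_equal(p$freeflow_time_s,
               sum(link_time(p$links$length_m, p$links$speed_mps)),
               tolerance = 1e-12)
})

test_that("shortest times match exhaustive enumeration on 100 seeded graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:100) {
    net <- random_small_network(seed)
    n <- nrow(net$nodes)
    od <- withr::with_seed(seed + 1000, sample(net$nodes$id, 2))
    p <- shortest_time_path(net, od[1], od[2])
    oracle <- enumerate_shortest_time(net, od[1], od[2])
    expect_equal(p$freeflow_time_s, oracle, tolerance = 1e-9)

    # independent library cross-check
    ig <- igraph::graph_from_data_frame(
      data.frame(from = net$links$from, to = net$links$to),
      directed = FALSE,
      vertices = data.frame(name = net$nodes$id))
    d_ig <- igraph::distances(
      ig, v = as.character(od[1]), to = as.character(od[2]),
      weights = net$links$length_m / net$links$speed_mps)
    expect_equal(p$freeflow_time_s, as.numeric(d_ig), tolerance = 1e-9)
  }
})

test_that("tie-breaking prefers fewer links and is deterministic", {
  # two equal-time two-link routes (via 2 or via 3) plus an equal-time
  # three-link route; expect the two-link route through the smaller node id
  net <- road_network(
    nodes = data.frame(id = 1:5, x = c(0, 1000, 0, 1000, 2000),
                       y = c(0, 0, 1000, 1000, 0)),
    links = data.frame(from = c(1, 2, 1, 3, 1, 5),
                       to = c(2, 4, 3, 4, 5, 4),
                       length_m = c(1000, 1000, 1000, 1000, 1000, 1000),
                       speed_mps = c(10, 10, 10, 10, 20, 20 / 3)))
  p1 <- shortest_time_path(net, 1, 4)
  expect_equal(p1$freeflow_time_s, 200)
  expect_equal(p1$node_ids, c(1, 2, 4))
  p2 <- shortest_time_path(net, 1, 4)
  expect_identical(p1$node_ids, p2$node_ids)
})

test_that("raising a link speed never increases shortest times", {
  for (seed in c(5, 17, 29)) {
    net <- random_small_network(seed)
    base <- shortest_time_path(net, net$nodes$id[1],
                               net$nodes$id[nrow(net$nodes)])$freeflow_time_s
    links2 <- net$links
    k <- withr::with_seed(seed, sample(nrow(links2), 1))
    links2$speed_mps[k] <- links2$speed_mps[k] * 3
    net2 <- road_network(net$nodes, links2)
    faster <- shortest_time_path(net2, net$nodes$id[1],
                                 net$nodes$id[nrow(net$nodes)])$freeflow_time_s
    expect_lte(faster, base + 1e-9)
  }
})

test_that("disconnected endpoints raise a no-route error", {
  net <- road_network(
    nodes = data.frame(id = 1:4, x = c(0, 1000, 5000, 6000),
                       y = 0),
    links = data.frame(from = c(1, 3), to = c(2, 4), length_m = 1000,
                       speed_mps = 10))
  expect_error(shortest_time_path(net, 1, 4), "no route")
})

test_that("points snap to the nearest node, ties to the smallest id", {
  net <- square_network()
  expect_equal(snap_point(net, 1000, 0), 2L)
  expect_equal(snap_point(net, 500, 0), 1L)    # equidistant from 1 and 2
  expect_equal(snap_point(net, 500, 500), 1L)  # equidistant from all four
  # linear-scan oracle over random points
  pts <- withr::with_seed(1, data.frame(x = runif(50, -500, 1500),
                                        y = runif(50, -500, 1500)))
  snapped <- snap_point(net, pts$x, pts$y)
  for (k in seq_len(nrow(pts))) {
    d <- sqrt((net$nodes$x - pts$x[k])^2 + (net$nodes$y - pts$y[k])^2)
    expect_equal(d[net$nodes$id == snapped[k]], min(d))
  }
})

test_that("trip discretization follows the midpoint-span rule", {
  # 250 m at 10 m/s, reported twice the free-flow time: spans [0,50],
  # [50,150], [150,225], [225,250] m at scaled speed 5 m/s
  net <- road_network(
    nodes = data.frame(id = 1:2, x = c(0, 250), y = 0),
    links = data.frame(from = 1, to = 2, length_m = 250, speed_mps = 10))
  p <- shortest_time_path(net, 1, 2)
  pts <- discretize_trip(p, reported_travel_minutes = 50 / 60)
  expect_equal(pts$x, c(0, 100, 200, 250))
  expect_equal(pts$dt * 60, c(10, 20, 15, 5), tolerance = 1e-12)
  expect_equal(sum(pts$dt), 50 / 60, tolerance = 1e-12)
})

test_that("reporting the free-flow time reproduces it exactly", {
  net <- square_network(speed = 10)
  p <- shortest_time_path(net, 1, 4)
  pts <- discretize_trip(p, p$freeflow_time_s / 60)
  expect_equal(sum(pts$dt), p$freeflow_time_s / 60, tolerance = 1e-12)
})

test_that("discretized point times conserve the reported trip time", {
  for (seed in 1:200) {
    net <- random_small_network(seed)
    od <- withr::with_seed(seed + 5000, sample(net$nodes$id, 2))
    p <- shortest_time_path(net, od[1], od[2])
    if (length(p$node_ids) < 2) next
    reported <- withr::with_seed(seed, stats::runif(1, 1, 90))
    pts <- discretize_trip(p, reported)
    expect_equal(sum(pts$dt), reported, tolerance = 1e-9)
    expect_true(all(pts$dt > 0))
  }
})

test_that("zero-length paths place all reported time on the endpoint", {
  net <- square_network()
  p <- shortest_time_path(net, 3, 3)
  pts <- discretize_trip(p, 12)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$dt, 12)
  expect_equal(c(pts$x, pts$y), c(0, 1000))
})

test_that("a zero-trip day traces to a single residence point", {
  net <- square_network()
  pd <- make_person_day(no_trips(), res_x = 0, res_y = 0)
  trace <- build_trace(pd, net)
  expect_equal(nrow(trace), 1)
  expect_equal(trace$dt, 1440)
  expect_equal(trace$kind, "at_residence")
})

test_that("a round-trip day yields a conserved, on-network trace", {
  net <- square_network()
  pd <- make_person_day(round_trip(res_x = 0, res_y = 0,
                                   dest_x = 1000, dest_y = 1000))
  trace <- build_trace(pd, net)
  expect_equal(sum(trace$dt), 1440, tolerance = 1e-9)
  expect_equal(trace$kind[1], "at_residence")
  expect_equal(trace$kind[nrow(trace)], "at_residence")
  expect_true(any(trace$kind == "in_travel"))
  expect_true(any(trace$kind == "nonresidential"))

  # every travel point lies on the network geometry (here: grid edges)
  tp <- trace[trace$kind == "in_travel", ]
  on_edge <- (tp$x %in% c(0, 1000)) | (tp$y %in% c(0, 1000))
  expect_true(all(on_edge))

  # time ordering is contiguous
  ends <- trace$t_start + trace$dt
  expect_equal(trace$t_start[-1], ends[-length(ends)], tolerance = 1e-9)
})

test_that("day-level time is conserved across a generated population", {
  cfg <- tiny_config(seed = 31, n_households = 25)
  net <- generate_network(cfg)
  pop <- generate_population(cfg, net)
  traces <- build_traces(pop, net)
  per_day <- tapply(traces$dt, traces$person_id, sum)
  expect_true(all(abs(per_day - 1440) < 1e-6))
})
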