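test_that("overhead ratios are exact on hand-checkable geometries", {
  # two anchors joined by one straight edge: path equals chord, ratio 1
  net <- line_net(5000, 50)
  og <- overhead_graph(net, net$nodes, c(1, 2))
  expect_equal(og$ratio, matrix(1, 2, 2))
  expect_equal(og$speed[1, 2], 50)

  # L-shaped road, two 1000 m legs; endpoints 1414.2 m apart: the
  # Manhattan-diagonal detour, ratio = 2000 / sqrt(2)/1000 ~ 1.414
  L <- road_network(data.frame(x = c(0, 1000, 1000), y = c(0, 0, 1000)),
                    data.frame(u = c(1, 2), v = c(2, 3), length = 1000,
                               speed = 40))
  og <- overhead_graph(L, L$nodes[c(1, 3), ], c(1, 3))
  expect_equal(og$ratio[1, 2], 2000 / sqrt(2e6), tolerance = 1e-12)
  expect_equal(og$ratio[1, 2], sqrt(2), tolerance = 1e-12)
  expect_true(isSymmetric(og$ratio))
  expect_equal(diag(og$ratio), c(1, 1))
})

test_that("every matrix entry equals an independent Dijkstra/Euclidean recomputation", {
  reg <- generate_region(region_spec(extent = 20000, n_hubs = 3,
                                     hub_sd = 1000, hub_min_sep = 6000,
                                     n_patients = 400, grid_pitch = 2000,
                                     obstacle_fraction = 0.2, seed = 21))
  net <- reg$network
  sel <- select_anchors(reg$patients, net, K = 12, seed = 3, trials = 100)
  og <- overhead_graph(net, sel$anchors, sel$anchor_nodes)
  # independent oracle: igraph all-pairs distance matrix over edge lengths
  un <- unique(sel$anchor_nodes)
  Du <- igraph::distances(net$graph, v = un, to = un,
                          weights = net$edges$length)
  D <- Du[match(sel$anchor_nodes, un), match(sel$anchor_nodes, un)]
  E <- as.matrix(dist(sel$anchors))
  comparable <- E >= og$eps
  expect_equal(og$ratio[comparable], (D / E)[comparable], tolerance = 1e-9)
  expect_equal(og$ratio[!comparable], rep(1, sum(!comparable)))
  expect_true(all(og$ratio[og$reachable] >= 1 - 1e-9))
})

test_that("estimates apply ratio x Euclidean and are exact between anchors", {
  # a stored ratio of 1.4 turns 10 km Euclidean into 14 km travel
  og <- structure(list(anchors = data.frame(x = c(0, 10000), y = c(0, 0)),
                       anchor_nodes = c(1, 2),
                       ratio = matrix(c(1, 1.4, 1.4, 1), 2),
                       speed = matrix(60, 2, 2),
                       reachable = matrix(TRUE, 2, 2), eps = 1),
                  class = "overhead_graph")
  est <- estimate_travel(og, 0, 0, 10000, 0)
  expect_equal(est$distance, 14000)
  expect_equal(est$time, 14)
  expect_equal(estimate_travel(og, 3, 7, 3, 7), list(distance = 0, time = 0))
  # symmetry in the arguments
  expect_equal(estimate_travel(og, 200, 0, 9800, 50),
               estimate_travel(og, 9800, 50, 200, 0))

  # anchor-coincident queries reproduce the exact network distance and time
  sq <- square_net()
  og2 <- overhead_graph(sq, sq$nodes, 1:4)
  sp <- shortest_path(sq, 1, 3)
  est <- estimate_travel(og2, 0, 0, 1000, 1000)
  expect_equal(est$distance, sp$distance, tolerance = 1e-12)
  expect_equal(est$time, sp$time, tolerance = 1e-12)
})

test_that("anchors land one per demand blob and respect K limits", {
  set.seed(5)
  centres <- data.frame(x = c(2000, 18000, 2000, 18000),
                        y = c(2000, 2000, 18000, 18000))
  n <- 240
  cl <- rep(1:4, each = n / 4)
  p <- patients(sprintf("p%d", 1:n), rnorm(n, centres$x[cl], 300),
                rnorm(n, centres$y[cl], 300))
  net <- grid_net(11, pitch = 2000)
  sel <- select_anchors(p, net, K = 4, seed = 2, trials = 200)
  owner <- vapply(1:4, function(j)
    which.min((centres$x - sel$anchors$x[j])^2 +
              (centres$y - sel$anchors$y[j])^2), integer(1))
  expect_setequal(owner, 1:4)  # one anchor per blob
  expect_true(all(sel$anchor_nodes %in% seq_len(nrow(net$nodes))))

  expect_error(select_anchors(p, net, K = n + 1), "distinct")
  expect_error(select_anchors(p, net, K = 1), ">= 2")
})

test_that("overhead graphs persist losslessly through the text format", {
  sq <- square_net()
  og <- overhead_graph(sq, sq$nodes, 1:4)
  prefix <- file.path(withr::local_tempdir(), "og")
  write_overhead_graph(og, prefix)
  og2 <- read_overhead_graph(prefix)
  expect_equal(og2$anchors, og$anchors)
  expect_equal(og2$ratio, og$ratio)
  expect_equal(og2$speed, og$speed)
  expect_equal(og2$reachable, og$reachable)
  expect_equal(og2$eps, og$eps)
})

test_that("unreachable anchor pairs are flagged and propagate as errors", {
  disc <- road_network(data.frame(x = c(0, 1000, 9000, 10000), y = rep(0, 4)),
                       data.frame(u = c(1, 3), v = c(2, 4),
                                  length = c(1000, 1000), speed = 50))
  og <- overhead_graph(disc, disc$nodes, 1:4)
  expect_false(og$reachable[1, 3])
  expect_true(is.na(og$ratio[1, 3]))
  expect_true(og$reachable[1, 2])
  expect_error(estimate_travel(og, 0, 0, 9000, 0), "unreachable")
})
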