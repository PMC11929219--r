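# Shared fixtures, built in code. Heavy objects (the default synthetic
# region and its K = 256 overhead graph) are memoised so several test files
# can share one instance.

.fixtures <- new.env(parent = emptyenv())

# Default-scale synthetic region (generator defaults; fixed fixture seed).
default_region <- function() {
  if (is.null(.fixtures$region))
    .fixtures$region <- generate_region(region_spec(seed = 11))
  .fixtures$region
}

default_og <- function() {
  if (is.null(.fixtures$og)) {
    reg <- default_region()
    .fixtures$og <- build_overhead_graph(reg$patients, reg$network,
                                         K = 256, seed = 12)
  }
  .fixtures$og
}

# Straight one-edge network: two nodes `len` metres apart.
line_net <- function(len = 14000, speed = 60) {
  road_network(data.frame(x = c(0, len), y = c(0, 0)),
               data.frame(u = 1, v = 2, length = len, speed = speed))
}

# 4-node square with two routes of different length between nodes 1 and 3:
# 1-2-3 totals 2000 m, 1-4-3 totals 2600 m (edge 4-3 is a curvy 1600 m).
square_net <- function() {
  road_network(data.frame(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000)),
               data.frame(u = c(1, 2, 1, 4), v = c(2, 3, 4, 3),
                          length = c(1000, 1000, 1000, 1600),
                          speed = c(60, 60, 30, 30)))
}

# Full g x g grid network, straight edges of `pitch` metres.
grid_net <- function(g, pitch = 1000, speed = 50) {
  ids <- seq_len(g * g)
  ix <- (ids - 1L) %% g + 1L
  iy <- (ids - 1L) %/% g + 1L
  ha <- ids[ix < g]
  va <- ids[iy < g]
  road_network(data.frame(x = (ix - 1) * pitch, y = (iy - 1) * pitch),
               data.frame(u = c(ha, va), v = c(ha + 1L, va + g),
                          length = pitch, speed = speed))
}

# Overhead graph whose ratio is identically 1 (anchors on one straight
# road), so estimated distance equals Euclidean distance everywhere.
identity_og <- function(span = 1e6, speed = 60) {
  net <- road_network(data.frame(x = c(0, span), y = c(0, span)),
                      data.frame(u = 1, v = 2, length = sqrt(2) * span,
                                 speed = speed))
  overhead_graph(net, net$nodes, c(1, 2))
}

# Uniform random patients on [0, ext]^2.
random_patients <- function(n, ext = 10000, seed = 1, ages = 60, weights = 1) {
  set.seed(seed)
  patients(sprintf("p%03d", seq_len(n)), runif(n, 0, ext), runif(n, 0, ext),
           age = ages, weight = weights)
}

# Brute-force assignment oracle: slow R argmin over a cost function.
bf_assign <- function(p, s, costfun) {
  vapply(seq_len(nrow(p)), function(i) {
    costs <- vapply(seq_len(nrow(s)), function(j)
      costfun(p[i, , drop = FALSE], s$x[j], s$y[j]), numeric(1))
    which.min(costs)
  }, integer(1))
}
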