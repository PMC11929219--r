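#' Build a road network
#'
#' An undirected embedded graph over planar node coordinates. Each edge
#' carries its road length in metres and an average speed in km/h; travel
#' time along an edge is `length / speed`. The network is the ground-truth
#' travel oracle that the overhead graph approximates. Edge lengths may
#' exceed the straight-line chord between their endpoints (curvy roads) but
#' can never be shorter than it.
#'
#' @param nodes data.frame with numeric columns `x`, `y` (metres).
#' @param edges data.frame with columns `u`, `v` (1-based node indices),
#'   `length` (m, > 0) and `speed` (km/h, > 0).
#' @return An object of class `road_network`: the validated `nodes` and
#'   `edges`, an `igraph` graph used for shortest paths, per-edge travel
#'   times in minutes, and the connected-component count.
#' @export
road_network <- function(nodes, edges) {
  nodes <- data.frame(x = as.numeric(nodes$x), y = as.numeric(nodes$y))
  n <- nrow(nodes)
  stop_if(n == 0, "empty node set")
  stop_if(any(!is.finite(nodes$x) | !is.finite(nodes$y)),
          "non-finite node coordinates")
  edges <- data.frame(u = as.integer(edges$u), v = as.integer(edges$v),
                      length = as.numeric(edges$length),
                      speed = as.numeric(edges$speed))
  stop_if(any(edges$u < 1 | edges$u > n | edges$v < 1 | edges$v > n),
          "edge endpoint index out of range")
  stop_if(any(edges$u == edges$v), "self-loop edges are not allowed")
  stop_if(any(edges$length <= 0), "edge lengths must be > 0")
  stop_if(any(edges$speed <= 0), "edge speeds must be > 0")
  chord <- euclid(nodes$x[edges$u], nodes$y[edges$u],
                  nodes$x[edges$v], nodes$y[edges$v])
  bad <- which(edges$length < chord * (1 - 1e-9))
  stop_if(length(bad) > 0, "edge(s) ", toString(utils::head(bad, 5)),
          " shorter than the straight-line chord between their endpoints ",
          "(corrupt geometry)")
  g <- igraph::make_graph(rbind(edges$u, edges$v), n = n, directed = FALSE)
  net <- list(nodes = nodes, edges = edges, graph = g,
              edge_minutes = edges$length / 1000 / edges$speed * 60,
              n_components = igraph::count_components(g))
  class(net) <- "road_network"
  net
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("road_network: %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), x$n_components))
  invisible(x)
}

#' Shortest road path between two network nodes
#'
#' Dijkstra over edge lengths. Travel time is accumulated along the same
#' length-optimal path (distance is primary; time derives from the segment
#' speeds of that path), not along a separately time-optimal route.
#'
#' @param net a [road_network].
#' @param a,b 1-based node indices.
#' @return list with `distance` (m), `time` (min) and `reachable`; when
#'   unreachable, distance and time are `NA` (never silently infinite).
#' @export
shortest_path <- function(net, a, b) {
  n <- nrow(net$nodes)
  stop_if(a < 1 || a > n || b < 1 || b > n, "node index out of range")
  if (a == b) return(list(distance = 0, time = 0, reachable = TRUE))
  sp <- suppressWarnings(
    igraph::shortest_paths(net$graph, from = a, to = b,
                           weights = net$edges$length, output = "epath"))
  eids <- as.integer(sp$epath[[1]])
  if (length(eids) == 0)
    return(list(distance = NA_real_, time = NA_real_, reachable = FALSE))
  list(distance = sum(net$edges$length[eids]),
       time = sum(net$edge_minutes[eids]),
       reachable = TRUE)
}

#' Snap a point to its nearest network node
#'
#' Off-network locations (patients, stations, anchors) are attached to the
#' graph at the Euclidean-nearest node; ties break to the lowest index.
#'
#' @param net a [road_network].
#' @param x,y planar coordinates, metres.
#' @return 1-based node index.
#' @export
snap_node <- function(net, x, y) {
  stop_if(nrow(net$nodes) == 0, "empty network")
  nearest_index(x, y, net$nodes$x, net$nodes$y)
}

#' Euclidean distance to the nearest point of a layer
#'
#' Used for the bus-stop rule of the travel-cost model ("bus when the
#' nearest stop is within the threshold").
#'
#' @param layer a [point_layer].
#' @param x,y planar coordinates, metres.
#' @return metres.
#' @export
nearest_point_distance <- function(layer, x, y) {
  stop_if(nrow(layer) == 0, "empty point layer")
  min(euclid(x, y, layer$x, layer$y))
}

#' Read a road network from GeoJSON LineStrings or a node/edge CSV pair
#'
#' GeoJSON: every feature must be a LineString with a numeric `speed_kmh`
#' property; consecutive vertices become nodes and straight edges (lengths
#' from the geometry), and vertices with identical coordinates are merged so
#' crossing lines connect. CSV: `node_path` has `node_id,x,y`, `edge_path`
#' has `u,v,length_m,speed_kmh` referring to `node_id`s.
#'
#' @param path GeoJSON file of LineStrings (when `edge_path` is NULL),
#'   otherwise the node CSV.
#' @param edge_path optional edge CSV.
#' @return a [road_network].
#' @export
read_road_network <- function(path, edge_path = NULL) {
  if (!is.null(edge_path)) {
    nd <- read.csv(path, stringsAsFactors = FALSE)
    ed <- read.csv(edge_path, stringsAsFactors = FALSE)
    idx <- setNames(seq_len(nrow(nd)), as.character(nd$node_id))
    return(road_network(data.frame(x = nd$x, y = nd$y),
                        data.frame(u = idx[as.character(ed$u)],
                                   v = idx[as.character(ed$v)],
                                   length = ed$length_m,
                                   speed = ed$speed_kmh)))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stop_if(!identical(gj$type, "FeatureCollection"),
          "expected a GeoJSON FeatureCollection")
  key <- character(0); xs <- numeric(0); ys <- numeric(0)
  uu <- integer(0); vv <- integer(0); ll <- numeric(0); ss <- numeric(0)
  node_of <- new.env(parent = emptyenv())
  get_node <- function(x, y) {
    k <- sprintf("%.3f|%.3f", x, y)
    i <- node_of[[k]]
    if (is.null(i)) {
      i <- length(xs) + 1L
      xs[[i]] <<- x; ys[[i]] <<- y
      node_of[[k]] <- i
    }
    i
  }
  for (f in gj$features) {
    g <- f$geometry
    stop_if(!identical(g$type, "LineString"),
            "expected LineString features, got ", g$type)
    spd <- as.numeric(f$properties$speed_kmh)
    stop_if(!is.finite(spd) || spd <= 0, "missing or invalid speed_kmh")
    cc <- g$coordinates
    for (i in seq_len(length(cc) - 1)) {
      a <- get_node(as.numeric(cc[[i]][[1]]), as.numeric(cc[[i]][[2]]))
      b <- get_node(as.numeric(cc[[i + 1]][[1]]), as.numeric(cc[[i + 1]][[2]]))
      uu <- c(uu, a); vv <- c(vv, b)
      ll <- c(ll, euclid(xs[a], ys[a], xs[b], ys[b]))
      ss <- c(ss, spd)
    }
  }
  road_network(data.frame(x = xs, y = ys),
               data.frame(u = uu, v = vv, length = ll, speed = ss))
}

#' Write a road network as a node/edge CSV pair
#' @param net a [road_network].
#' @param node_path,edge_path output CSV paths.
#' @export
write_road_network <- function(net, node_path, edge_path) {
  write.csv(data.frame(node_id = seq_len(nrow(net$nodes)),
                       x = net$nodes$x, y = net$nodes$y),
            node_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(u = net$edges$u, v = net$edges$v,
                       length_m = net$edges$length,
                       speed_kmh = net$edges$speed),
            edge_path, row.names = FALSE, quote = FALSE)
  invisible(node_path)
}
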