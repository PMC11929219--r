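#' Select overhead-graph anchors from patient locations
#'
#' Anchors are the lookup nodes of the overhead graph. They are placed where
#' demand is: the K centroids of a squared-Euclidean random-swap clustering
#' of the patient locations, each snapped to its nearest road node. The
#' snapped node coordinates are the anchor coordinates, so every anchor lies
#' on the network and overhead ratios are guaranteed `>= 1`.
#'
#' @param p a [patients] table.
#' @param net a [road_network].
#' @param K number of anchors (default 256), `2 <= K <=` number of distinct
#'   patient locations.
#' @param seed integer seed for the clustering.
#' @param trials random-swap trials for the anchor clustering (default 500;
#'   anchor placement needs coverage, not an optimal clustering).
#' @return list with `anchors` (data.frame `x`, `y` of the snapped node
#'   coordinates) and `anchor_nodes` (1-based node indices).
#' @export
select_anchors <- function(p, net, K = 256, seed = 1, trials = 500) {
  stop_if(K < 2, "K must be >= 2")
  ndistinct <- nrow(unique(data.frame(x = p$x, y = p$y)))
  stop_if(K > ndistinct,
          "K exceeds the number of distinct patient locations (", ndistinct, ")")
  fit <- random_swap(p, k = K, obj = station_objective("squared_euclidean"),
                     trials = trials, seed = seed)
  nodes <- vapply(seq_len(K),
                  function(j) snap_node(net, fit$cx[j], fit$cy[j]), integer(1))
  list(anchors = data.frame(x = net$nodes$x[nodes], y = net$nodes$y[nodes]),
       anchor_nodes = nodes)
}

#' Build the overhead-ratio lookup graph
#'
#' For every anchor pair the overhead ratio is the road-network shortest
#' distance divided by the Euclidean distance between the anchors (the
#' locally adapted detour index), and the effective speed is the path
#' distance divided by the travel time accumulated along the same
#' length-optimal path (a harmonic mean of the segment speeds). Anchor pairs
#' closer than `eps` metres get ratio 1 (guards division blow-up for
#' near-coincident anchors); pairs in different road components are flagged
#' unreachable (`NA` entries in both matrices).
#'
#' @param net a [road_network].
#' @param anchors data.frame `x`, `y` of anchor coordinates (snapped).
#' @param anchor_nodes 1-based node indices of the anchors.
#' @param eps near-coincidence threshold in metres (default 1).
#' @return An object of class `overhead_graph`: `anchors`, `anchor_nodes`,
#'   `ratio` and `speed` (K x K matrices), `reachable` (logical K x K),
#'   `eps`.
#' @export
overhead_graph <- function(net, anchors, anchor_nodes, eps = 1) {
  K <- nrow(anchors)
  stop_if(K < 1, "need at least one anchor")
  stop_if(length(anchor_nodes) != K, "anchors and anchor_nodes disagree")
  ratio <- matrix(NA_real_, K, K)
  speed <- matrix(NA_real_, K, K)
  reachable <- matrix(FALSE, K, K)
  # one Dijkstra tree per anchor; distances and times summed over the same
  # length-optimal edge path
  mean_speed <- sum(net$edges$length) / sum(net$edge_minutes) / 1000 * 60
  for (i in seq_len(K)) {
    sp <- suppressWarnings(
      igraph::shortest_paths(net$graph, from = anchor_nodes[i],
                             to = anchor_nodes, weights = net$edges$length,
                             output = "epath"))
    for (j in seq_len(K)) {
      de <- euclid(anchors$x[i], anchors$y[i], anchors$x[j], anchors$y[j])
      eids <- as.integer(sp$epath[[j]])
      if (i == j || de < eps) {
        same_node <- anchor_nodes[i] == anchor_nodes[j]
        if (i == j || same_node || length(eids) > 0) {
          ratio[i, j] <- 1
          sp_eff <- if (length(eids) > 0)
            sum(net$edges$length[eids]) / sum(net$edge_minutes[eids]) / 1000 * 60
          else mean_speed
          speed[i, j] <- sp_eff
          reachable[i, j] <- TRUE
        }
        next
      }
      if (length(eids) == 0) next  # different components
      d <- sum(net$edges$length[eids])
      t <- sum(net$edge_minutes[eids])
      ratio[i, j] <- d / de
      speed[i, j] <- d / 1000 / (t / 60)
      reachable[i, j] <- TRUE
    }
  }
  og <- list(anchors = anchors, anchor_nodes = anchor_nodes, ratio = ratio,
             speed = speed, reachable = reachable, eps = eps)
  class(og) <- "overhead_graph"
  og
}

#' @export
print.overhead_graph <- function(x, ...) {
  K <- nrow(x$anchors)
  ok <- x$reachable & upper.tri(x$ratio)
  cat(sprintf("overhead_graph: K = %d anchors; mean ratio %.3f (range %.3f-%.3f); %d unreachable pair(s)\n",
              K, mean(x$ratio[ok]), min(x$ratio[ok]), max(x$ratio[ok]),
              sum(!x$reachable[upper.tri(x$reachable)])))
  invisible(x)
}

#' Convenience builder: anchors + matrices in one call
#'
#' @inheritParams select_anchors
#' @inheritParams overhead_graph
#' @return an [overhead_graph].
#' @export
build_overhead_graph <- function(p, net, K = 256, seed = 1, trials = 500,
                                 eps = 1) {
  sel <- select_anchors(p, net, K = K, seed = seed, trials = trials)
  overhead_graph(net, sel$anchors, sel$anchor_nodes, eps = eps)
}

#' Index of the anchor nearest to a point (linear scan)
#' @param og an [overhead_graph].
#' @param x,y coordinates, metres.
#' @return 1-based anchor index.
#' @export
nearest_anchor <- function(og, x, y) {
  nearest_index(x, y, og$anchors$x, og$anchors$y)
}

#' Estimate travel distance and time between two points
#'
#' Constant-time travel estimate: Euclidean distance times the stored
#' overhead ratio of the two nearest anchors, time from the stored effective
#' speed of that anchor pair. No shortest-path computation happens at query
#' time.
#'
#' @param og an [overhead_graph].
#' @param x1,y1,x2,y2 point coordinates, metres.
#' @return list with `distance` (m) and `time` (min).
#' @export
estimate_travel <- function(og, x1, y1, x2, y2) {
  if (x1 == x2 && y1 == y2) return(list(distance = 0, time = 0))
  i <- nearest_anchor(og, x1, y1)
  j <- nearest_anchor(og, x2, y2)
  stop_if(!og$reachable[i, j],
          "anchor pair is unreachable in the road network")
  d <- euclid(x1, y1, x2, y2) * og$ratio[i, j]
  list(distance = d, time = d / 1000 / og$speed[i, j] * 60)
}

#' Persist an overhead graph as portable text files
#'
#' Writes `<prefix>_anchors.csv` (anchor coordinates and node indices),
#' `<prefix>_ratio.csv` and `<prefix>_speed.csv` (row-major K x K matrices,
#' empty cells = unreachable) and a `<prefix>.json` sidecar header with K
#' and `eps`.
#'
#' @param og an [overhead_graph].
#' @param prefix path prefix for the output files.
#' @export
write_overhead_graph <- function(og, prefix) {
  write.csv(data.frame(x = og$anchors$x, y = og$anchors$y,
                       node = og$anchor_nodes),
            paste0(prefix, "_anchors.csv"), row.names = FALSE, quote = FALSE)
  utils::write.table(og$ratio, paste0(prefix, "_ratio.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, na = "")
  utils::write.table(og$speed, paste0(prefix, "_speed.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, na = "")
  jsonlite::write_json(list(K = nrow(og$anchors), eps = og$eps,
                            crs = "planar metres (user-supplied projected CRS)"),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an overhead graph written by [write_overhead_graph]
#' @param prefix path prefix used when writing.
#' @return an [overhead_graph].
#' @export
read_overhead_graph <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"))
  an <- read.csv(paste0(prefix, "_anchors.csv"))
  ratio <- as.matrix(read.csv(paste0(prefix, "_ratio.csv"), header = FALSE))
  speed <- as.matrix(read.csv(paste0(prefix, "_speed.csv"), header = FALSE))
  dimnames(ratio) <- NULL
  dimnames(speed) <- NULL
  og <- list(anchors = data.frame(x = an$x, y = an$y),
             anchor_nodes = an$node, ratio = ratio, speed = speed,
             reachable = !is.na(ratio), eps = hdr$eps)
  class(og) <- "overhead_graph"
  og
}
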