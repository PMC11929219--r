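#' Assign patients to their nearest station
#'
#' Nearest under the active objective's own pair cost; ties break to the
#' lowest station index.
#'
#' @param p a [patients] table.
#' @param s a [stations] table.
#' @param obj a [station_objective].
#' @return integer vector of 1-based station indices, one per patient, with
#'   attribute `cost` (the weighted total).
#' @export
assign_patients <- function(p, s, obj = station_objective("euclidean")) {
  stop_if(nrow(s) == 0, "station set must be non-empty")
  res <- cpp_assign(obj_cpp(obj, p), s$x, s$y)
  structure(res$assignment, cost = res$cost)
}

#' Weighted arithmetic-mean centroid update
#'
#' Each station moves to the visit-weight-weighted arithmetic mean of the
#' patients assigned to it (arithmetic means are used for all objectives,
#' including travel cost). A station whose cluster is empty is relocated to
#' the patient farthest from the remaining centroids (without repair the
#' effective number of stations would shrink). Inside the optimizer loop
#' the repair instead reuses the per-patient cost of the preceding
#' assignment: the emptied station jumps to the patient farthest from its
#' own assigned station under the active objective.
#'
#' @param p a [patients] table.
#' @param assignment 1-based station index per patient.
#' @param k number of stations.
#' @return data.frame `x`, `y` of k updated centroids.
#' @export
update_centroids <- function(p, assignment, k) {
  stop_if(any(assignment < 1 | assignment > k), "assignment index out of range")
  cx <- numeric(k); cy <- numeric(k)
  used <- rep(FALSE, nrow(p))
  centx <- tapply(p$weight * p$x, factor(assignment, levels = 1:k), sum)
  centy <- tapply(p$weight * p$y, factor(assignment, levels = 1:k), sum)
  sw <- tapply(p$weight, factor(assignment, levels = 1:k), sum)
  empty <- which(is.na(sw) | sw == 0)
  filled <- setdiff(1:k, empty)
  cx[filled] <- centx[filled] / sw[filled]
  cy[filled] <- centy[filled] / sw[filled]
  if (length(empty) > 0) {
    # distance of each patient to its own (old) station is not available
    # here; repair with the farthest patient from the filled centroids
    mind <- rep(Inf, nrow(p))
    for (j in filled)
      mind <- pmin(mind, euclid(cx[j], cy[j], p$x, p$y))
    for (j in empty) {
      far <- which.max(ifelse(used, -Inf, mind))
      used[far] <- TRUE
      cx[j] <- p$x[far]; cy[j] <- p$y[far]
    }
  }
  data.frame(x = cx, y = cy)
}

#' Two-phase k-means over station locations
#'
#' Alternates patient assignment and arithmetic-mean centroid update
#' `iters` times, then reassigns once and recomputes the cost from scratch.
#' This is the polishing step inside each random-swap trial (two iterations
#' by default).
#'
#' @param p a [patients] table.
#' @param init data.frame `x`, `y` of initial station locations.
#' @param obj a [station_objective].
#' @param iters number of assignment/update rounds, `>= 1`.
#' @return list with `cx`, `cy`, `assignment`, `cost`.
#' @export
kmeans_stations <- function(p, init, obj = station_objective("squared_euclidean"),
                            iters = 2) {
  stop_if(iters < 1, "iters must be >= 1")
  cpp_kmeans(obj_cpp(obj, p), init$x, init$y, as.integer(iters))
}

#' Random-swap optimization of station locations
#'
#' The core optimizer. Starts from k patient locations drawn without
#' replacement, polished by two k-means iterations. Each of the `trials`
#' swap trials copies the current solution, replaces one uniformly chosen
#' station with a uniformly chosen patient location, polishes with two
#' k-means iterations, and keeps the candidate only if it strictly lowers
#' the objective. The trial-and-error swap lets centroids jump across empty
#' regions where plain k-means stalls. Fully deterministic for a given
#' seed; `trials = 0` returns the k-means-polished initial solution.
#'
#' @param p a [patients] table.
#' @param k number of stations, `1 <= k <=` distinct patient locations.
#' @param obj a [station_objective].
#' @param trials number of swap trials T (default 5000).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param iters k-means iterations per trial (default 2).
#' @param init optional data.frame `x`, `y` overriding the random
#'   initialization.
#' @return list with `cx`, `cy` (station coordinates), `assignment`,
#'   `cost`, `pair_cost` (per-patient, unweighted), `initial_cost` and
#'   `history` (one row per trial: trial, candidate cost, accepted).
#' @export
random_swap <- function(p, k, obj = station_objective("squared_euclidean"),
                        trials = 5000, seed = NULL, iters = 2, init = NULL) {
  stop_if(k < 1, "k must be >= 1")
  stop_if(trials < 0, "trials must be >= 0")
  ndistinct <- nrow(unique(data.frame(x = p$x, y = p$y)))
  stop_if(k > ndistinct, "k exceeds the number of distinct patient locations")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    pick <- sample.int(nrow(p), k)
    init <- data.frame(x = p$x[pick], y = p$y[pick])
  }
  res <- cpp_random_swap(obj_cpp(obj, p), init$x, init$y,
                         as.integer(trials), as.integer(iters))
  colnames(res$history) <- c("trial", "cost", "accepted")
  res
}

#' Snap stations to the nearest candidate building
#'
#' Post-processing: each optimized station moves to its Euclidean-nearest
#' existing building, which keeps centroids off lakes and other places
#' without infrastructure. Two stations may snap to the same building (no
#' uniqueness constraint). Applied once, after the optimization.
#'
#' @param s a [stations] table.
#' @param buildings a non-empty building [point_layer].
#' @return the [stations] table with updated coordinates.
#' @export
snap_to_buildings <- function(s, buildings) {
  stop_if(is.null(buildings) || nrow(buildings) == 0, "empty building layer")
  for (i in seq_len(nrow(s))) {
    j <- nearest_index(s$x[i], s$y[i], buildings$x, buildings$y)
    s$x[i] <- buildings$x[j]
    s$y[i] <- buildings$y[j]
  }
  s
}

#' Centroid index between a found and a ground-truth station set
#'
#' Cluster-level error measure: map every found centroid to its
#' Euclidean-nearest ground-truth centroid and count the truth centroids
#' that attract none ("orphans"). 0 means every true cluster is represented;
#' the all-on-one-centroid degenerate solution scores `|truth| - 1`.
#'
#' @param found data.frame (or [stations]) with `x`, `y`.
#' @param truth data.frame with `x`, `y` of the true centres.
#' @return integer, the number of orphaned truth centroids.
#' @export
centroid_index <- function(found, truth) {
  stop_if(nrow(found) == 0 || nrow(truth) == 0, "empty station set")
  mapped <- vapply(seq_len(nrow(found)), function(i)
    nearest_index(found$x[i], found$y[i], truth$x, truth$y), integer(1))
  sum(!(seq_len(nrow(truth)) %in% mapped))
}
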