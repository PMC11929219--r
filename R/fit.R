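#' Optimize health-station locations
#'
#' The main fitting function. Treats facility location as a clustering
#' problem: the k station locations are the centroids, patients the data,
#' and the objective one of Euclidean distance, squared Euclidean distance
#' or per-visit patient travel cost. Optimization uses random swap
#' (trial-and-error centroid replacement with two k-means polishing
#' iterations per trial), which is far more robust than repeated k-means on
#' data with many well-separated population hubs. Optionally snaps the
#' final stations to the nearest existing building.
#'
#' @param p a [patients] table.
#' @param k number of stations to place.
#' @param objective a [station_objective] (default squared Euclidean, the
#'   k-means criterion).
#' @param trials random-swap trials T (default 5000, the standard
#'   recommendation; `0` degenerates to a single seeded k-means run).
#' @param seed integer seed; results are bit-reproducible for a fixed seed.
#' @param buildings optional building [point_layer]; when supplied, the
#'   optimized stations are snapped to the nearest building as
#'   post-processing (the reported cost is recomputed after the snap).
#' @param iters k-means iterations per swap trial (default 2).
#' @param init optional data.frame `x`, `y` initial station locations.
#' @return An object of class `station_fit` with components `stations` (a
#'   [stations] table), `assignment`, `cost`, `initial_cost`, `history`,
#'   `objective`, `k`, `trials`, `seed`, and the patient table used.
#' @seealso [random_swap], [evaluate_stations], [centroid_index]
#' @examples
#' set.seed(1)
#' p <- patients(sprintf("p%d", 1:60),
#'               x = c(rnorm(30, 0, 50), rnorm(30, 5000, 50)),
#'               y = c(rnorm(30, 0, 50), rnorm(30, 0, 50)))
#' fit <- optimize_stations(p, k = 2, trials = 50, seed = 7)
#' fit
#' coef(fit)
#' @export
optimize_stations <- function(p, k,
                              objective = station_objective("squared_euclidean"),
                              trials = 5000, seed = NULL, buildings = NULL,
                              iters = 2, init = NULL) {
  sol <- random_swap(p, k, obj = objective, trials = trials, seed = seed,
                     iters = iters, init = init)
  st <- stations(sprintf("opt%02d", seq_len(k)), sol$cx, sol$cy)
  snapped <- FALSE
  if (!is.null(buildings)) {
    st <- snap_to_buildings(st, buildings)
    snapped <- TRUE
    a <- assign_patients(p, st, objective)
    sol$assignment <- as.integer(a)
    sol$cost <- attr(a, "cost")
  }
  out <- list(stations = st, assignment = sol$assignment, cost = sol$cost,
              pair_cost = sol$pair_cost, initial_cost = sol$initial_cost,
              history = sol$history, objective = objective, k = k,
              trials = trials, iters = iters, seed = seed,
              snapped = snapped, patients = p, call = match.call())
  class(out) <- "station_fit"
  out
}

obj_unit <- function(obj) {
  switch(obj$kind, euclidean = "m", squared_euclidean = "m^2",
         travel_cost = "EUR")
}

#' @export
print.station_fit <- function(x, ...) {
  cat(sprintf("station_fit: k = %d stations, objective = %s\n",
              x$k, x$objective$kind))
  cat(sprintf("  random swap: %d trials, %d accepted; cost %.6g -> %.6g %s\n",
              x$trials, if (x$trials > 0) sum(x$history[, "accepted"]) else 0L,
              x$initial_cost, x$cost, obj_unit(x$objective)))
  if (x$snapped) cat("  stations snapped to nearest building\n")
  invisible(x)
}

#' @export
summary.station_fit <- function(object, ...) {
  a <- object$assignment
  tab <- data.frame(
    station = object$stations$id,
    x = object$stations$x, y = object$stations$y,
    n_patients = as.integer(tabulate(a, object$k)),
    visits = as.numeric(tapply(object$patients$weight,
                               factor(a, levels = seq_len(object$k)), sum,
                               default = 0)),
    subtotal = as.numeric(tapply(object$patients$weight * object$pair_cost,
                                 factor(a, levels = seq_len(object$k)), sum,
                                 default = 0)))
  out <- list(fit = object, stations = tab,
              mean_pair_cost = weighted.mean(object$pair_cost,
                                             object$patients$weight))
  class(out) <- "summary.station_fit"
  out
}

#' @export
print.summary.station_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  weighted mean per-visit cost: %.6g %s\n",
              x$mean_pair_cost, obj_unit(x$fit$objective)))
  print(x$stations, row.names = FALSE)
  invisible(x)
}

#' @export
coef.station_fit <- function(object, ...) {
  m <- cbind(x = object$stations$x, y = object$stations$y)
  rownames(m) <- object$stations$id
  m
}

#' @export
fitted.station_fit <- function(object, ...) {
  object$stations$id[object$assignment]
}

#' Per-patient cost to the assigned station
#' @param object a `station_fit`.
#' @param ... unused.
#' @return numeric vector of unweighted per-patient pair costs.
#' @export
residuals.station_fit <- function(object, ...) {
  object$pair_cost
}

#' Assign new patients to the fitted stations
#' @param object a `station_fit`.
#' @param newdata a [patients] table (default: the training patients).
#' @param ... unused.
#' @return integer station indices with attribute `cost`.
#' @export
predict.station_fit <- function(object, newdata = object$patients, ...) {
  assign_patients(newdata, object$stations, object$objective)
}

#' @export
plot.station_fit <- function(x, ...) {
  p <- x$patients
  plot(p$x, p$y, pch = 16, cex = 0.3,
       col = adjustcolor(x$assignment %% 8 + 1, 0.4),
       xlab = "x (m)", ylab = "y (m)", asp = 1,
       main = sprintf("%d stations, %s objective", x$k, x$objective$kind), ...)
  points(x$stations$x, x$stations$y, pch = 17, cex = 1.4, col = "black")
  invisible(x)
}
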