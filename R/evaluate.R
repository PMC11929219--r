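#' Accessibility report for a station configuration
#'
#' Scores any station set (existing or optimized) against a patient
#' population: patients are assigned to their cheapest station under the
#' travel-cost model, and the report gives the per-visit mean travel time
#' (minutes) and distance (km), the visit-weighted total annual travel cost
#' (EUR/year when weights are visits/year), and per-station patient counts
#' and cost subtotals. Travel distance and time come from the overhead
#' graph. Patients unreachable from every station (anchor pairs in
#' different road components) are listed and excluded from the means.
#'
#' @param p a [patients] table.
#' @param s a [stations] table.
#' @param og an [overhead_graph].
#' @param bus_stops a non-empty bus-stop [point_layer].
#' @param params a [cost_params].
#' @return An object of class `station_eval`: `mean_time_min`,
#'   `mean_dist_km`, `total_cost_eur`, `per_station` (data.frame),
#'   `modes` (visit-weighted mode shares), `unreachable` (patient ids),
#'   `assignment`, `n_patients`, `total_visits`.
#' @export
evaluate_stations <- function(p, s, og, bus_stops, params = cost_params()) {
  stop_if(nrow(s) == 0, "station set must be non-empty")
  stop_if(is.null(bus_stops) || nrow(bus_stops) == 0,
          "bus-stop layer required for the travel-cost model")
  n <- nrow(p)
  k <- nrow(s)
  pa <- vapply(seq_len(n), function(i) nearest_anchor(og, p$x[i], p$y[i]),
               integer(1))
  sa <- vapply(seq_len(k), function(j)
    nearest_anchor(og, s$x[j], s$y[j]), integer(1))
  busd <- vapply(seq_len(n), function(i)
    nearest_point_distance(bus_stops, p$x[i], p$y[i]), numeric(1))

  # n x k matrices of estimated distance (m) and per-visit cost (EUR);
  # NA where the anchor pair is unreachable
  costm <- matrix(NA_real_, n, k)
  distm <- matrix(NA_real_, n, k)
  timem <- matrix(NA_real_, n, k)
  modem <- matrix(NA_character_, n, k)
  for (j in seq_len(k)) {
    de <- euclid(s$x[j], s$y[j], p$x, p$y)
    r <- og$ratio[pa, sa[j]]
    v <- og$speed[pa, sa[j]]
    d <- de * r
    mode <- mode_vec(p$age, de, busd, params)
    km <- d / 1000
    cst <- ifelse(mode == "walk", 0,
           ifelse(mode == "bus", params$trips_per_visit * params$bus_fare,
           ifelse(mode == "car",
                  params$trips_per_visit * params$car_cost_per_km * km,
                  params$trips_per_visit *
                    (params$taxi_base + params$taxi_cost_per_km * km))))
    distm[, j] <- d
    timem[, j] <- ifelse(d == 0, 0, d / 1000 / v * 60)
    costm[, j] <- cst
    modem[, j] <- mode
  }
  ok <- rowSums(!is.na(costm)) > 0
  assignment <- rep(NA_integer_, n)
  assignment[ok] <- apply(costm[ok, , drop = FALSE], 1, which.min)

  idx <- which(ok)
  pick <- cbind(idx, assignment[idx])
  dist_m <- distm[pick]
  time_min <- timem[pick]
  cost <- costm[pick]
  mode <- modem[pick]
  w <- p$weight[idx]

  af <- factor(assignment[idx], levels = seq_len(k))
  visits <- as.numeric(tapply(w, af, sum, default = 0))
  per_station <- data.frame(
    station = s$id,
    n_patients = as.integer(tabulate(assignment[idx], k)),
    visits = visits,
    subtotal_eur = as.numeric(tapply(w * cost, af, sum, default = 0)),
    mean_time_min = ifelse(visits > 0,
      as.numeric(tapply(w * time_min, af, sum, default = 0)) /
        pmax(visits, 1e-300), NA_real_))

  out <- list(mean_time_min = weighted.mean(time_min, w),
              mean_dist_km = weighted.mean(dist_m, w) / 1000,
              total_cost_eur = sum(w * cost),
              per_station = per_station,
              modes = prop.table(tapply(w, factor(mode,
                levels = c("walk", "taxi", "bus", "car")), sum,
                default = 0)),
              unreachable = p$id[!ok],
              assignment = assignment,
              n_patients = n, total_visits = sum(w))
  class(out) <- "station_eval"
  out
}

# vectorized travel_mode over patients (shared rule set)
mode_vec <- function(age, dist_to_station, dist_to_bus_stop, params) {
  n <- length(dist_to_station)
  mode <- rep(NA_character_, n)
  for (m in params$mode_precedence) {
    hit <- switch(m,
      walk = dist_to_station < params$walk_threshold,
      taxi = age >= params$taxi_age,
      bus  = dist_to_bus_stop < params$bus_stop_threshold,
      car  = rep(TRUE, n))
    mode[is.na(mode) & hit] <- m
  }
  mode
}

#' @export
print.station_eval <- function(x, ...) {
  cat(sprintf("station_eval: %d patients, %.0f visits/year, %d station(s)\n",
              x$n_patients, x$total_visits, nrow(x$per_station)))
  cat(sprintf("  mean travel time:     %.1f min/visit\n", x$mean_time_min))
  cat(sprintf("  mean travel distance: %.1f km/visit\n", x$mean_dist_km))
  cat(sprintf("  total travel cost:    %.0f EUR/year (%.2f EUR/visit)\n",
              x$total_cost_eur, x$total_cost_eur / x$total_visits))
  ms <- x$modes
  cat(sprintf("  mode shares (visits): %s\n",
              paste(sprintf("%s %.0f%%", names(ms), 100 * ms),
                    collapse = ", ")))
  if (length(x$unreachable) > 0)
    cat(sprintf("  %d unreachable patient(s) excluded from the means\n",
                length(x$unreachable)))
  invisible(x)
}
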