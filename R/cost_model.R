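#' Travel-cost model parameters
#'
#' Tariffs and thresholds of the rule-based patient travel-cost model.
#' Patients within `walk_threshold` of the station walk at 0 EUR; patients
#' aged `taxi_age` or older take a taxi; patients with a bus stop within
#' `bus_stop_threshold` ride the bus at a flat fare; everyone else drives.
#' `mode_precedence` orders these rules (first match wins; car matches
#' unconditionally). `trips_per_visit` converts per-trip tariffs to
#' per-visit cost (2 = round trip). Bus fares are flat (no fare zones) and
#' the patient's time cost is deliberately excluded from the model.
#'
#' @param walk_threshold metres, default 1000.
#' @param bus_stop_threshold metres, default 200.
#' @param bus_fare EUR per one-way bus trip, default 5.10.
#' @param taxi_age years, default 80.
#' @param car_cost_per_km EUR/km, default 0.25.
#' @param taxi_base EUR per taxi trip, default 5.90.
#' @param taxi_cost_per_km EUR/km, default 1.50.
#' @param trips_per_visit trips per health-station visit, default 2.
#' @param mode_precedence permutation of `c("walk","taxi","bus","car")`.
#' @return a classed list of parameters.
#' @export
cost_params <- function(walk_threshold = 1000, bus_stop_threshold = 200,
                        bus_fare = 5.10, taxi_age = 80,
                        car_cost_per_km = 0.25, taxi_base = 5.90,
                        taxi_cost_per_km = 1.50, trips_per_visit = 2,
                        mode_precedence = c("walk", "taxi", "bus", "car")) {
  stop_if(!setequal(mode_precedence, c("walk", "taxi", "bus", "car")) ||
            length(mode_precedence) != 4,
          "mode_precedence must be a permutation of walk, taxi, bus, car")
  vals <- c(walk_threshold, bus_stop_threshold, bus_fare, taxi_age,
            car_cost_per_km, taxi_base, taxi_cost_per_km)
  stop_if(any(vals < 0), "thresholds and rates must be >= 0")
  stop_if(trips_per_visit < 1, "trips_per_visit must be >= 1")
  out <- list(walk_threshold = walk_threshold,
              bus_stop_threshold = bus_stop_threshold, bus_fare = bus_fare,
              taxi_age = taxi_age, car_cost_per_km = car_cost_per_km,
              taxi_base = taxi_base, taxi_cost_per_km = taxi_cost_per_km,
              trips_per_visit = trips_per_visit,
              mode_precedence = mode_precedence)
  class(out) <- "cost_params"
  out
}

#' @export
print.cost_params <- function(x, ...) {
  cat(jsonlite::toJSON(list(cost_model = unclass(x)), auto_unbox = TRUE,
                       pretty = TRUE), "\n")
  invisible(x)
}

#' Objective function specification
#'
#' The three optimization criteria: straight Euclidean distance (metres),
#' squared Euclidean distance (the k-means criterion, metres^2), or the
#' per-visit patient travel cost in EUR. The travel-cost objective needs an
#' [overhead_graph] for road-distance estimates, a bus-stop [point_layer]
#' for the bus rule and [cost_params] tariffs.
#'
#' @param kind `"euclidean"`, `"squared_euclidean"` or `"travel_cost"`.
#' @param params a [cost_params] (travel cost only).
#' @param og an [overhead_graph] (travel cost only).
#' @param bus_stops a non-empty bus-stop [point_layer] (travel cost only).
#' @return a classed objective specification.
#' @export
station_objective <- function(kind = c("squared_euclidean", "euclidean",
                                       "travel_cost"),
                              params = cost_params(), og = NULL,
                              bus_stops = NULL) {
  kind <- match.arg(kind)
  if (kind == "travel_cost") {
    stop_if(is.null(og), "travel_cost objective needs an overhead graph")
    stop_if(is.null(bus_stops) || nrow(bus_stops) == 0,
            "travel_cost objective needs a non-empty bus-stop layer")
  }
  out <- list(kind = kind, params = params, og = og, bus_stops = bus_stops)
  class(out) <- "station_objective"
  out
}

mode_codes <- c(walk = 0L, taxi = 1L, bus = 2L, car = 3L)

# Pack an objective + patients into the list the C++ core consumes.
# Caches per-patient nearest anchors and bus-stop distances (patients never
# move during the optimization).
obj_cpp <- function(obj, p) {
  code <- match(obj$kind, c("euclidean", "squared_euclidean", "travel_cost")) - 1L
  spec <- list(code = code, px = p$x, py = p$y, w = p$weight)
  if (code == 2L) {
    og <- obj$og
    spec$pa <- vapply(seq_len(nrow(p)),
                      function(i) nearest_anchor(og, p$x[i], p$y[i]),
                      integer(1)) - 1L
    spec$busd <- vapply(seq_len(nrow(p)), function(i)
      nearest_point_distance(obj$bus_stops, p$x[i], p$y[i]), numeric(1))
    spec$age <- as.numeric(p$age)
    spec$ratio <- og$ratio
    spec$ax <- og$anchors$x
    spec$ay <- og$anchors$y
    cp <- obj$params
    spec$params <- c(cp$walk_threshold, cp$bus_stop_threshold, cp$bus_fare,
                     cp$taxi_age, cp$car_cost_per_km, cp$taxi_base,
                     cp$taxi_cost_per_km, cp$trips_per_visit)
    spec$prec <- unname(mode_codes[cp$mode_precedence])
  }
  spec
}

#' Travel mode of a patient
#'
#' First matching rule in the precedence order wins: walk if the patient
#' lives within `walk_threshold` of the station; taxi if aged `taxi_age` or
#' more; bus if the nearest stop is within `bus_stop_threshold`; car
#' otherwise. Both threshold tests use Euclidean distances.
#'
#' @param age years.
#' @param dist_to_station Euclidean patient-to-station distance, metres.
#' @param dist_to_bus_stop Euclidean distance to the nearest bus stop,
#'   metres.
#' @param params a [cost_params].
#' @return one of `"walk"`, `"taxi"`, `"bus"`, `"car"`.
#' @export
travel_mode <- function(age, dist_to_station, dist_to_bus_stop,
                        params = cost_params()) {
  stop_if(dist_to_station < 0 || dist_to_bus_stop < 0, "negative distance")
  for (m in params$mode_precedence) {
    hit <- switch(m,
      walk = dist_to_station < params$walk_threshold,
      taxi = age >= params$taxi_age,
      bus  = dist_to_bus_stop < params$bus_stop_threshold,
      car  = TRUE)
    if (hit) return(m)
  }
  "car"
}

#' Per-visit travel cost of one patient to one station
#'
#' Estimates the road distance with the overhead graph, decides the travel
#' mode, and applies the tariff: walk costs nothing; bus is
#' `trips_per_visit * bus_fare`; car is `trips_per_visit * car_cost_per_km *
#' km`; taxi is `trips_per_visit * (taxi_base + taxi_cost_per_km * km)`.
#'
#' @param p a single-row [patients] table (or a row of one).
#' @param sx,sy station coordinates, metres.
#' @param og an [overhead_graph].
#' @param bus_stops a non-empty bus-stop [point_layer].
#' @param params a [cost_params].
#' @return EUR per visit.
#' @export
visit_cost <- function(p, sx, sy, og, bus_stops, params = cost_params()) {
  stop_if(is.null(bus_stops) || nrow(bus_stops) == 0,
          "bus-stop layer required for the travel-cost model")
  de <- euclid(p$x[1], p$y[1], sx, sy)
  d <- estimate_travel(og, p$x[1], p$y[1], sx, sy)$distance
  busd <- nearest_point_distance(bus_stops, p$x[1], p$y[1])
  mode <- travel_mode(p$age[1], de, busd, params)
  km <- d / 1000
  switch(mode,
         walk = 0,
         bus = params$trips_per_visit * params$bus_fare,
         car = params$trips_per_visit * params$car_cost_per_km * km,
         taxi = params$trips_per_visit *
           (params$taxi_base + params$taxi_cost_per_km * km))
}

#' Per-patient cost to one station under an objective
#'
#' Vectorized over patients: Euclidean distance, its square, or the
#' per-visit travel cost, depending on the objective kind. Always `>= 0`.
#'
#' @param obj a [station_objective].
#' @param p a [patients] table.
#' @param sx,sy station coordinates, metres.
#' @return numeric vector, one (unweighted) cost per patient.
#' @export
pair_cost <- function(obj, p, sx, sy) {
  res <- cpp_assign(obj_cpp(obj, p), sx, sy)
  res$pair_cost
}

#' Total objective value of a station configuration
#'
#' Each patient is served by the station minimizing the objective's own
#' pair cost (the argmin uses the same metric that is summed); the total is
#' the visit-weighted sum of those minima.
#'
#' @param obj a [station_objective].
#' @param p a [patients] table.
#' @param s a [stations] table (non-empty).
#' @return the scalar objective value (m, m^2 or EUR, depending on kind).
#' @export
total_cost <- function(obj, p, s) {
  stop_if(nrow(s) == 0, "station set must be non-empty")
  if (nrow(p) == 0) {
    warning("empty patient set; total cost is 0")
    return(0)
  }
  cpp_assign(obj_cpp(obj, p), s$x, s$y)$cost
}
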