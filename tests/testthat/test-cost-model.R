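test_that("pair costs implement the three objectives", {
  p <- patients("a", 0, 0, age = 50)
  eu <- station_objective("euclidean")
  sq <- station_objective("squared_euclidean")
  expect_equal(pair_cost(eu, p, 3000, 4000), 5000)       # 3-4-5 triangle
  expect_equal(pair_cost(sq, p, 3000, 4000), 2.5e7)
  expect_equal(pair_cost(eu, p, 0, 0), 0)
  expect_equal(pair_cost(sq, p, 0, 0), 0)

  og <- identity_og()
  stops <- point_layer(1e5, 1e5, "bus_stops")
  tc <- station_objective("travel_cost", og = og, bus_stops = stops)
  expect_equal(pair_cost(tc, p, 0, 0), 0)
  expect_true(all(pair_cost(tc, p, 40000, 0) >= 0))
})

test_that("travel mode rules and their boundaries follow the model", {
  cp <- cost_params()
  # stated rule examples
  expect_equal(travel_mode(67, 800, 1000, cp), "walk")
  expect_equal(travel_mode(85, 10000, 50, cp), "taxi")
  expect_equal(travel_mode(50, 5000, 150, cp), "bus")
  expect_equal(travel_mode(50, 5000, 300, cp), "car")
  # boundary semantics: strict < for distances, >= for age
  expect_equal(travel_mode(50, 999, 1000, cp), "walk")
  expect_equal(travel_mode(50, 1000, 1000, cp), "car")
  expect_equal(travel_mode(79, 5000, 1000, cp), "car")
  expect_equal(travel_mode(80, 5000, 1000, cp), "taxi")
  expect_equal(travel_mode(50, 5000, 199, cp), "bus")
  expect_equal(travel_mode(50, 5000, 200, cp), "car")
  # walk precedes taxi: an 85-year-old living next door still walks free
  expect_equal(travel_mode(85, 500, 50, cp), "walk")
  # reordered precedence is honoured
  cp2 <- cost_params(mode_precedence = c("taxi", "walk", "bus", "car"))
  expect_equal(travel_mode(85, 500, 50, cp2), "taxi")
})

test_that("per-visit costs apply the tariffs", {
  og <- identity_og()
  near_stop <- point_layer(10, 0, "bus_stops")
  far_stop <- point_layer(1e5, 1e5, "bus_stops")
  cp <- cost_params()

  walker <- patients("w", 0, 0, age = 67)
  expect_equal(visit_cost(walker, 800, 0, og, far_stop, cp), 0)

  rider <- patients("b", 0, 0, age = 50)
  expect_equal(visit_cost(rider, 5000, 0, og, near_stop, cp), 2 * 5.10)

  # taxi at 10 km: 2 trips x (5 + 1 x 10) with explicit tariffs
  senior <- patients("t", 0, 0, age = 85)
  cp2 <- cost_params(taxi_base = 5, taxi_cost_per_km = 1)
  expect_equal(visit_cost(senior, 10000, 0, og, far_stop, cp2), 30)

  driver <- patients("c", 0, 0, age = 50)
  expect_equal(visit_cost(driver, 8000, 0, og, far_stop, cp),
               2 * 0.25 * 8)
  expect_error(visit_cost(driver, 8000, 0, og,
                          point_layer(numeric(0), numeric(0), "bus_stops"),
                          cp), "bus-stop")
})

test_that("total cost sums weighted minima under each objective's own argmin", {
  p <- patients(c("a", "b"), c(0, 2000), c(0, 0))
  s <- stations("s1", 0, 0)
  expect_equal(total_cost(station_objective("euclidean"), p, s), 2000)
  expect_equal(total_cost(station_objective("squared_euclidean"), p, s), 4e6)

  # stations on the patients, all within walking range: free
  og <- identity_og()
  stops <- point_layer(1e5, 1e5, "bus_stops")
  tc <- station_objective("travel_cost", og = og, bus_stops = stops)
  s2 <- stations(c("s1", "s2"), c(0, 2000), c(0, 0))
  expect_equal(total_cost(tc, p, s2), 0)

  expect_warning(z <- total_cost(station_objective("euclidean"), p[0, ], s),
                 "empty")
  expect_equal(z, 0)
  expect_error(total_cost(station_objective("euclidean"), p, s[0, ]),
               "non-empty")
})

test_that("the all-car travel-cost limit collapses to scaled Euclidean cost", {
  # ratio = 1, nobody walks, no taxis, no bus access:
  # travel cost == trips * car rate * Euclidean total / 1000
  p <- random_patients(60, ext = 30000, seed = 14,
                       ages = sample(20:95, 60, TRUE),
                       weights = sample(1:8, 60, TRUE))
  s <- stations(c("s1", "s2", "s3"), c(5000, 15000, 25000),
                c(22000, 3000, 18000))
  og <- identity_og()
  cp <- cost_params(walk_threshold = 0, taxi_age = Inf,
                    bus_stop_threshold = 0, car_cost_per_km = 0.25,
                    trips_per_visit = 2)
  tc <- station_objective("travel_cost", params = cp, og = og,
                          bus_stops = point_layer(0, 0, "bus_stops"))
  eu <- station_objective("euclidean")
  expect_equal(total_cost(tc, p, s),
               2 * 0.25 * total_cost(eu, p, s) / 1000,
               tolerance = 1e-12)
})

test_that("adding a station never increases any objective", {
  p <- random_patients(80, ext = 20000, seed = 3,
                       ages = sample(20:95, 80, TRUE))
  og <- identity_og()
  stops <- point_layer(c(0, 10000), c(0, 10000), "bus_stops")
  objectives <- list(
    station_objective("euclidean"),
    station_objective("squared_euclidean"),
    station_objective("travel_cost", og = og, bus_stops = stops))
  set.seed(31)
  sx <- runif(5, 0, 20000); sy <- runif(5, 0, 20000)
  for (obj in objectives) {
    for (m in 2:5) {
      before <- total_cost(obj, p, stations(paste0("s", 1:(m - 1)),
                                            sx[1:(m - 1)], sy[1:(m - 1)]))
      after <- total_cost(obj, p, stations(paste0("s", 1:m), sx[1:m], sy[1:m]))
      expect_lte(after, before + 1e-9)
    }
  }
})
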