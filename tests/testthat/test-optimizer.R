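test_that("assignment matches a brute-force argmin with lowest-index ties", {
  p <- patients("a", 500, 0, age = 50)
  s <- stations(c("s1", "s2"), c(0, 1000), c(0, 0))
  expect_equal(as.integer(assign_patients(p, s)), 1)  # equidistant -> lowest

  one <- stations("only", 4000, 4000)
  pp <- random_patients(40, seed = 6)
  expect_equal(as.integer(assign_patients(pp, one)), rep(1, 40))

  ss <- stations(paste0("s", 1:5), runif(5, 0, 10000), runif(5, 0, 10000))
  for (obj in list(station_objective("euclidean"),
                   station_objective("squared_euclidean"))) {
    got <- as.integer(assign_patients(pp, ss, obj))
    pow <- if (obj$kind == "euclidean") 1 else 2
    bf <- bf_assign(pp, ss, function(pi, sx, sy)
      sqrt((pi$x - sx)^2 + (pi$y - sy)^2)^pow)
    expect_identical(got, bf)
  }
})

test_that("centroid updates are weighted means with single-point degeneracy", {
  p <- patients(c("a", "b"), c(0, 2), c(0, 2))
  expect_equal(update_centroids(p, c(1, 1), 1), data.frame(x = 1, y = 1))

  p1 <- patients("a", 123, 456)
  expect_equal(update_centroids(p1, 1, 1), data.frame(x = 123, y = 456))

  # weights 1 and 3 on (0,0) and (4,0): mean at (3, 0)
  pw <- patients(c("a", "b"), c(0, 4), c(0, 0), weight = c(1, 3))
  expect_equal(update_centroids(pw, c(1, 1), 1), data.frame(x = 3, y = 0))

  # an emptied cluster is repaired with a far patient, so k never shrinks
  p3 <- patients(c("a", "b", "c"), c(0, 1, 100), c(0, 0, 0))
  cent <- update_centroids(p3, c(1, 1, 1), 2)
  expect_equal(nrow(cent), 2)
  expect_true(100 %in% cent$x)
})

test_that("k-means recovers the enumerated optimum on a 1-D instance", {
  p <- patients(letters[1:4], c(0, 1, 9, 10), c(0, 0, 0, 0))
  sq <- station_objective("squared_euclidean")
  fit <- kmeans_stations(p, data.frame(x = c(1, 9), y = c(0, 0)), sq,
                         iters = 2)
  expect_equal(sort(fit$cx), c(0.5, 9.5))
  expect_equal(fit$cost, 1.0)

  # oracle: enumerate every 2-partition of the 4 points
  best <- Inf
  for (mask in 1:14) {
    grp <- as.logical(bitwAnd(mask, 2^(0:3)))
    if (all(grp) || !any(grp)) next
    sse <- function(v) sum((v - mean(v))^2)
    best <- min(best, sse(p$x[grp]) + sse(p$x[!grp]))
  }
  expect_equal(fit$cost, best)

  # with k = n and an init covering every point the cost is zero
  fit0 <- kmeans_stations(p, data.frame(x = p$x, y = p$y), sq, iters = 1)
  expect_equal(fit0$cost, 0)
})

test_that("squared-euclidean k-means descends monotonically across iterations", {
  p <- random_patients(300, ext = 50000, seed = 17)
  sq <- station_objective("squared_euclidean")
  set.seed(2)
  init <- data.frame(x = runif(6, 0, 50000), y = runif(6, 0, 50000))
  costs <- vapply(1:6, function(it)
    kmeans_stations(p, init, sq, iters = it)$cost, numeric(1))
  expect_true(all(diff(costs) <= 1e-7))
})

test_that("random swap is seeded, strictly improving and degenerates to k-means at T = 0", {
  p <- random_patients(200, ext = 40000, seed = 23)
  sq <- station_objective("squared_euclidean")

  a <- random_swap(p, k = 5, obj = sq, trials = 150, seed = 42)
  b <- random_swap(p, k = 5, obj = sq, trials = 150, seed = 42)
  expect_identical(a, b)  # bit-identical under the same seed

  acc <- a$history[a$history[, "accepted"] == 1, "cost"]
  expect_true(all(diff(acc) < 0))          # accepted costs strictly decrease
  expect_lte(a$cost, a$initial_cost)
  if (length(acc) > 0) expect_equal(a$cost, min(acc))

  # T = 0: exactly the k-means-polished seeded init
  z <- random_swap(p, k = 5, obj = sq, trials = 0, seed = 7)
  set.seed(7)
  pick <- sample.int(nrow(p), 5)
  km <- kmeans_stations(p, data.frame(x = p$x[pick], y = p$y[pick]), sq,
                        iters = 2)
  expect_equal(z$cx, km$cx)
  expect_equal(z$cy, km$cy)
  expect_equal(z$cost, km$cost)

  # the reported cost always equals a from-scratch recomputation
  st <- stations(sprintf("s%d", 1:5), a$cx, a$cy)
  expect_equal(a$cost, total_cost(sq, p, st), tolerance = 1e-12)
  expect_error(random_swap(p, k = nrow(p) + 1), "distinct")
})

test_that("one Gaussian blob with k = 1 puts the station at the weighted mean", {
  set.seed(12)
  n <- 400
  p <- patients(sprintf("p%d", 1:n), rnorm(n, 5000, 800), rnorm(n, 7000, 800),
                weight = sample(1:9, n, TRUE))
  fit <- random_swap(p, k = 1, trials = 20, seed = 3)
  expect_equal(fit$cx, weighted.mean(p$x, p$weight), tolerance = 1e-8)
  expect_equal(fit$cy, weighted.mean(p$y, p$weight), tolerance = 1e-8)
  # euclidean and travel-cost objectives land near the same centre
  feu <- random_swap(p, k = 1, obj = station_objective("euclidean"),
                     trials = 20, seed = 3)
  expect_lt(abs(feu$cx - fit$cx), 200)
  expect_lt(abs(feu$cy - fit$cy), 200)
})

test_that("station snapping moves each station to its nearest building", {
  b <- point_layer(c(0, 5000, 9000), c(0, 5000, 100), "buildings")
  s <- stations(c("s1", "s2"), c(10, 5100), c(-10, 4900))
  snapped <- snap_to_buildings(s, b)
  expect_equal(snapped$x, c(0, 5000))
  expect_equal(snapped$y, c(0, 5000))
  # station already on a building is unchanged
  s2 <- snap_to_buildings(stations("s", 5000, 5000), b)
  expect_equal(c(s2$x, s2$y), c(5000, 5000))
  # two stations may share one building
  both <- snap_to_buildings(stations(c("a", "b"), c(4900, 5100),
                                     c(5000, 5000)), b)
  expect_equal(both$x, c(5000, 5000))
  # brute-force oracle on random instances
  set.seed(77)
  bb <- point_layer(runif(40, 0, 1000), runif(40, 0, 1000), "buildings")
  ss <- stations(sprintf("s%d", 1:10), runif(10, 0, 1000), runif(10, 0, 1000))
  got <- snap_to_buildings(ss, bb)
  for (i in 1:10) {
    j <- which.min((bb$x - ss$x[i])^2 + (bb$y - ss$y[i])^2)
    expect_equal(c(got$x[i], got$y[i]), c(bb$x[j], bb$y[j]))
  }
  expect_error(snap_to_buildings(ss, point_layer(numeric(0), numeric(0),
                                                 "buildings")), "empty")
})

test_that("centroid index counts orphaned ground-truth centres", {
  truth <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  expect_equal(centroid_index(truth, truth), 0)
  # three corners plus a duplicated corner: one truth centre orphaned
  found <- data.frame(x = c(0, 1, 0, 0.02), y = c(0, 0, 1, 0.02))
  expect_equal(centroid_index(found, truth), 1)
  # everything piled on one centre: m - 1 orphans
  pile <- data.frame(x = rep(0.01, 4), y = rep(0.01, 4))
  expect_equal(centroid_index(pile, truth), 3)
})

test_that("the fitted-model interface is coherent", {
  p <- random_patients(120, ext = 20000, seed = 5,
                       weights = sample(1:5, 120, TRUE))
  fit <- optimize_stations(p, k = 3, trials = 100, seed = 9)
  expect_s3_class(fit, "station_fit")
  expect_equal(nrow(fit$stations), 3)
  expect_equal(dim(coef(fit)), c(3, 2))
  expect_equal(length(fitted(fit)), 120)
  expect_identical(fitted(fit), fit$stations$id[fit$assignment])
  expect_equal(residuals(fit), fit$pair_cost)
  pr <- predict(fit, p[1:10, ])
  expect_identical(as.integer(pr), fit$assignment[1:10])
  expect_output(print(fit), "station_fit")
  expect_output(print(summary(fit)), "n_patients")
  # snapping through the fit interface recomputes cost on snapped stations
  b <- point_layer(runif(30, 0, 20000), runif(30, 0, 20000), "buildings")
  fs <- optimize_stations(p, k = 3, trials = 100, seed = 9, buildings = b)
  expect_true(all(fs$stations$x %in% b$x))
  expect_equal(fs$cost,
               total_cost(fs$objective, p, fs$stations), tolerance = 1e-12)
})
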