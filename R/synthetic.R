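#' Specification of a synthetic study region
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure the optimizer assumes: patients clustered around population
#' hubs of very different densities (one dominant "city" hub), an elderly
#' age profile with a tail above the taxi threshold, visit weights around
#' 4.7 visits/person/year, a grid road network with lake-like obstacles
#' that create locally varying detour ratios, bus stops along major roads,
#' and candidate buildings near the hubs.
#'
#' @param extent side length of the square region, metres (default 120 km).
#' @param n_hubs number of population hubs (default 15).
#' @param hub_weights hub population proportions; default is one dominant
#'   hub holding 40% of patients and geometrically decreasing weights for
#'   the rest.
#' @param hub_sd within-hub Gaussian spread, metres (default 2500).
#' @param hub_min_sep minimum hub separation, metres (default 15000, i.e.
#'   hubs are well separated relative to `hub_sd`).
#' @param n_patients number of patients (default 9333).
#' @param age_mean,age_sd,age_min truncated-normal age parameters
#'   (defaults 67, 12, 18).
#' @param p_over_80 minimum proportion of patients aged 80+ (default 0.15).
#' @param visits_per_year mean annual visits per patient (default 4.7;
#'   weights are `1 + Poisson(visits_per_year - 1)`).
#' @param grid_pitch road-grid spacing, metres (default 2000).
#' @param obstacle_fraction fraction of grid nodes removed as square lakes
#'   (default 0.12).
#' @param major_road_speed,minor_road_speed km/h (defaults 80, 50).
#' @param bus_stop_spacing spacing of stops along major roads, metres
#'   (default 600).
#' @param buildings_per_hub candidate buildings per hub (default 30).
#' @param seed integer seed.
#' @return a classed list of generator settings.
#' @export
region_spec <- function(extent = 120000, n_hubs = 15, hub_weights = NULL,
                        hub_sd = 2500, hub_min_sep = 15000,
                        n_patients = 9333, age_mean = 67, age_sd = 12,
                        age_min = 18, p_over_80 = 0.15,
                        visits_per_year = 4.7, grid_pitch = 2000,
                        obstacle_fraction = 0.12, major_road_speed = 80,
                        minor_road_speed = 50, bus_stop_spacing = 600,
                        buildings_per_hub = 30, seed = 1) {
  if (is.null(hub_weights)) {
    rest <- 0.85^seq_len(n_hubs - 1)
    hub_weights <- c(0.4, 0.6 * rest / sum(rest))
  }
  stop_if(length(hub_weights) != n_hubs, "need one weight per hub")
  stop_if(any(hub_weights < 0) || abs(sum(hub_weights) - 1) > 1e-8,
          "hub_weights must be proportions summing to 1")
  stop_if(n_patients <= 0, "n_patients must be > 0")
  stop_if(p_over_80 < 0 || p_over_80 > 1 || obstacle_fraction < 0 ||
            obstacle_fraction >= 1, "proportions must lie in [0, 1)")
  out <- as.list(environment())
  class(out) <- "region_spec"
  out
}

#' Generate a complete synthetic study region
#'
#' Seed-deterministic generator of every input layer: patients (Gaussian
#' mixture at the hubs, truncated-normal ages with a guaranteed 80+ mass,
#' Poisson-type visit weights), a grid road network with square lake
#' obstacles (re-linked if an obstacle disconnects it), major-road rows and
#' columns through each hub carrying bus stops, candidate buildings around
#' the hubs, and the true hub centres for centroid-index evaluation.
#'
#' @param spec a [region_spec].
#' @return list with `patients`, `network` ([road_network]), `bus_stops`,
#'   `buildings` ([point_layer]s), `truth_hubs` (data.frame `x`, `y`) and
#'   the `spec`.
#' @export
generate_region <- function(spec = region_spec()) {
  set.seed(spec$seed)
  E <- spec$extent

  # hub centres: rejection sampling with a minimum separation, kept away
  # from the border so patient blobs stay inside the extent
  margin <- 3 * spec$hub_sd
  hx <- numeric(0); hy <- numeric(0)
  tries <- 0
  while (length(hx) < spec$n_hubs) {
    cand_x <- runif(1, margin, E - margin)
    cand_y <- runif(1, margin, E - margin)
    if (length(hx) == 0 ||
        min(euclid(cand_x, cand_y, hx, hy)) >= spec$hub_min_sep) {
      hx <- c(hx, cand_x); hy <- c(hy, cand_y)
    }
    tries <- tries + 1
    stop_if(tries > 100000,
            "cannot place hubs with the requested minimum separation")
  }
  truth_hubs <- data.frame(x = hx, y = hy)

  # patients
  n <- spec$n_patients
  hub_of <- sample.int(spec$n_hubs, n, replace = TRUE, prob = spec$hub_weights)
  px <- pmin(pmax(rnorm(n, hx[hub_of], spec$hub_sd), 0), E)
  py <- pmin(pmax(rnorm(n, hy[hub_of], spec$hub_sd), 0), E)
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  while (any(age < spec$age_min))
    age[age < spec$age_min] <- rnorm(sum(age < spec$age_min),
                                     spec$age_mean, spec$age_sd)
  age <- floor(age)
  deficit <- ceiling(spec$p_over_80 * n) - sum(age >= 80)
  if (deficit > 0) {
    young <- which(age < 80)
    lift <- sample(young, deficit)
    age[lift] <- floor(runif(deficit, 80, 96))
  }
  weight <- 1 + rpois(n, max(spec$visits_per_year - 1, 0))
  pat <- patients(sprintf("p%05d", seq_len(n)), px, py, age, weight)

  # grid road network
  g <- floor(E / spec$grid_pitch) + 1
  gx <- rep(seq_len(g) - 1, times = g) * spec$grid_pitch
  gy <- rep(seq_len(g) - 1, each = g) * spec$grid_pitch
  node_id <- function(ix, iy) (iy - 1L) * g + ix  # 1-based grid indices
  keep <- rep(TRUE, g * g)
  if (spec$obstacle_fraction > 0) {
    target <- spec$obstacle_fraction * g * g
    removed <- 0
    guard <- 0
    while (removed < target && guard < 10000) {
      b <- sample(2:4, 1)  # lake block side, in nodes
      ix <- sample.int(g - b + 1, 1)
      iy <- sample.int(g - b + 1, 1)
      cells <- as.vector(outer(ix:(ix + b - 1), (iy:(iy + b - 1)),
                               function(a, bb) node_id(a, bb)))
      cells <- cells[cells >= 1 & cells <= g * g]
      newly <- sum(keep[cells])
      keep[cells] <- FALSE
      removed <- removed + newly
      guard <- guard + 1
    }
  }
  # never drown the hubs: restore the node nearest each hub
  for (h in seq_len(spec$n_hubs))
    keep[nearest_index(hx[h], hy[h], gx, gy)] <- TRUE

  old2new <- cumsum(keep)
  nx <- gx[keep]; ny <- gy[keep]

  # major roads: the full grid row and column through each hub's node
  hub_nodes <- vapply(seq_len(spec$n_hubs),
                      function(h) nearest_index(hx[h], hy[h], gx, gy),
                      integer(1))
  major_rows <- unique(((hub_nodes - 1L) %/% g) + 1L)
  major_cols <- unique(((hub_nodes - 1L) %% g) + 1L)

  ids <- seq_len(g * g)
  ixv <- (ids - 1L) %% g + 1L
  iyv <- (ids - 1L) %/% g + 1L
  ha <- ids[ixv < g]; hb <- ha + 1L              # horizontal edges
  hok <- keep[ha] & keep[hb]
  va <- ids[iyv < g]; vb <- va + g               # vertical edges
  vok <- keep[va] & keep[vb]
  uu <- old2new[c(ha[hok], va[vok])]
  vv <- old2new[c(hb[hok], vb[vok])]
  major <- c(iyv[ha[hok]] %in% major_rows, ixv[va[vok]] %in% major_cols)
  len <- euclid(nx[uu], ny[uu], nx[vv], ny[vv])
  spd <- ifelse(major, spec$major_road_speed, spec$minor_road_speed)

  # re-link disconnected components with straight causeway edges
  gg <- igraph::make_graph(rbind(uu, vv), n = length(nx), directed = FALSE)
  comp <- igraph::components(gg)
  while (comp$no > 1) {
    main_id <- which.max(comp$csize)
    main <- which(comp$membership == main_id)
    other <- which(comp$membership ==
                     setdiff(seq_len(comp$no), main_id)[1])
    best <- c(NA, NA); bd <- Inf
    for (o in other) {
      j <- nearest_index(nx[o], ny[o], nx[main], ny[main])
      d <- euclid(nx[o], ny[o], nx[main[j]], ny[main[j]])
      if (d < bd) { bd <- d; best <- c(o, main[j]) }
    }
    uu <- c(uu, best[1]); vv <- c(vv, best[2])
    len <- c(len, bd)
    spd <- c(spd, spec$minor_road_speed)
    gg <- igraph::add_edges(gg, best)
    comp <- igraph::components(gg)
  }
  net <- road_network(data.frame(x = nx, y = ny),
                      data.frame(u = uu, v = vv, length = len, speed = spd))

  # bus stops along major-road edges
  bx <- numeric(0); by <- numeric(0)
  mi <- which(major)
  for (e in mi) {
    steps <- seq(0, len[e], by = spec$bus_stop_spacing)
    fr <- steps / len[e]
    bx <- c(bx, nx[uu[e]] + fr * (nx[vv[e]] - nx[uu[e]]))
    by <- c(by, ny[uu[e]] + fr * (ny[vv[e]] - ny[uu[e]]))
  }
  # guarantee at least one stop per hub
  bx <- c(bx, nx[old2new[hub_nodes]])
  by <- c(by, ny[old2new[hub_nodes]])
  bus_stops <- point_layer(bx, by, "bus_stops")

  # candidate buildings clustered at the hubs
  nb <- spec$buildings_per_hub * spec$n_hubs
  bh <- rep(seq_len(spec$n_hubs), each = spec$buildings_per_hub)
  buildings <- point_layer(
    pmin(pmax(rnorm(nb, hx[bh], spec$hub_sd), 0), E),
    pmin(pmax(rnorm(nb, hy[bh], spec$hub_sd), 0), E),
    "buildings")

  list(patients = pat, network = net, bus_stops = bus_stops,
       buildings = buildings, truth_hubs = truth_hubs, spec = spec)
}

#' Gaussian-grid clustering benchmark generator
#'
#' A g x g grid of Gaussian clusters (the classic many-separate-clusters
#' benchmark family), for stress-testing clustering robustness: ground
#' truth is the grid of cluster centres, and the centroid index against it
#' measures how many clusters an algorithm failed to find.
#'
#' @param g grid side (`g^2` clusters), `>= 2`.
#' @param n total number of points.
#' @param sd within-cluster standard deviation, metres.
#' @param pitch grid spacing, metres (default 10000).
#' @param seed integer seed.
#' @return list with `points` (a [patients] table, unit weights) and
#'   `truth` (data.frame `x`, `y` of the g^2 centres).
#' @export
generate_grid_clusters <- function(g, n, sd, pitch = 10000, seed = 1) {
  stop_if(g < 2, "g must be >= 2")
  set.seed(seed)
  cx <- rep(seq_len(g), times = g) * pitch
  cy <- rep(seq_len(g), each = g) * pitch
  cl <- sample.int(g * g, n, replace = TRUE)
  pts <- patients(sprintf("b%06d", seq_len(n)),
                  rnorm(n, cx[cl], sd), rnorm(n, cy[cl], sd))
  list(points = pts, truth = data.frame(x = cx, y = cy))
}

#' Write every layer of a generated region to a directory
#'
#' Writes `patients.csv`, `network_nodes.csv` + `network_edges.csv`,
#' `bus_stops.csv`, `buildings.csv` and `truth_hubs.csv` in the formats the
#' readers of this package accept.
#'
#' @param region output of [generate_region].
#' @param dir output directory (created if needed).
#' @export
write_region <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patients(region$patients, file.path(dir, "patients.csv"))
  write_road_network(region$network, file.path(dir, "network_nodes.csv"),
                     file.path(dir, "network_edges.csv"))
  write_point_layer(region$bus_stops, file.path(dir, "bus_stops.csv"))
  write_point_layer(region$buildings, file.path(dir, "buildings.csv"))
  write.csv(region$truth_hubs, file.path(dir, "truth_hubs.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
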