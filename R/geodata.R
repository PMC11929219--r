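#' Construct a patient table
#'
#' Patients are the demand points of the facility-location problem. Each has
#' a planar location in metres (projected CRS; all layers of one problem must
#' share it), an age in years (drives the taxi rule of the travel-cost
#' model) and a visit weight (visits/year; objectives sum
#' `weight * cost(patient, nearest station)`, so `weight = 1` optimizes per
#' visit and `weight = visits/year` gives annualized totals).
#'
#' @param id character vector of unique patient identifiers.
#' @param x,y numeric, planar coordinates in metres.
#' @param age integer years, `>= 0`. Missing values become 0 (never taxi)
#'   with a warning.
#' @param weight positive visit weight, default 1.
#' @return A `data.frame` with columns `id, x, y, age, weight` and class
#'   `c("patients", "data.frame")`.
#' @export
patients <- function(id, x, y, age = 0L, weight = 1) {
  id <- as.character(id)
  stop_if(anyDuplicated(id) > 0, "duplicate patient ids")
  x <- as.numeric(x); y <- as.numeric(y)
  bad <- which(!is.finite(x) | !is.finite(y))
  stop_if(length(bad) > 0,
          "non-finite patient coordinates in row(s) ", toString(bad))
  age <- rep_len(age, length(id))
  if (anyNA(age)) {
    warning("missing patient ages set to 0 (never assigned the taxi mode)")
    age[is.na(age)] <- 0L
  }
  weight <- rep_len(as.numeric(weight), length(id))
  stop_if(any(!is.finite(weight) | weight <= 0), "patient weights must be > 0")
  out <- data.frame(id = id, x = x, y = y, age = as.numeric(age),
                    weight = weight, stringsAsFactors = FALSE)
  class(out) <- c("patients", "data.frame")
  out
}

#' Construct a station table
#'
#' The candidate/fitted health-station locations (the "centroids" of the
#' clustering formulation).
#'
#' @param id character vector of unique station identifiers.
#' @param x,y numeric planar coordinates, metres.
#' @param label optional display label, defaults to `id`.
#' @return A `data.frame` with class `c("stations", "data.frame")`.
#' @export
stations <- function(id, x, y, label = id) {
  id <- as.character(id)
  stop_if(anyDuplicated(id) > 0, "duplicate station ids")
  x <- as.numeric(x); y <- as.numeric(y)
  stop_if(any(!is.finite(x) | !is.finite(y)), "non-finite station coordinates")
  out <- data.frame(id = id, x = x, y = y, label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("stations", "data.frame")
  out
}

#' Construct a point layer (bus stops or candidate buildings)
#'
#' @param x,y numeric planar coordinates, metres.
#' @param kind `"bus_stops"` or `"buildings"`. The travel-cost objective
#'   requires a non-empty bus-stop layer; snapping stations requires a
#'   non-empty building layer.
#' @return A `data.frame` with columns `x, y`, attribute `kind`, class
#'   `c("point_layer", "data.frame")`.
#' @export
point_layer <- function(x, y, kind = c("bus_stops", "buildings")) {
  kind <- match.arg(kind)
  x <- as.numeric(x); y <- as.numeric(y)
  stop_if(any(!is.finite(x) | !is.finite(y)), "non-finite coordinates")
  out <- data.frame(x = x, y = y)
  attr(out, "kind") <- kind
  class(out) <- c("point_layer", "data.frame")
  out
}

#' Read patients from CSV
#'
#' Expects a header `id,x,y` with optional `age` and `weight` columns
#' (UTF-8, "." decimal separator). Missing `age` defaults to 0 with a
#' warning; missing `weight` to 1 visit. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return a [patients] table.
#' @export
read_patients <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("id", "x", "y") %in% names(df)),
          "patients CSV must have columns id, x, y")
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    stop_if(length(bad) > 0, "non-numeric ", col, " in row(s) ",
            toString(bad), " of ", path)
    df[[col]] <- v
  }
  if (is.null(df$age)) {
    warning("no age column in ", path, "; ages set to 0")
    df$age <- 0L
  }
  if (is.null(df$weight)) df$weight <- 1
  patients(df$id, df$x, df$y, df$age, df$weight)
}

#' Write patients to CSV
#' @param p a [patients] table.
#' @param path output path.
#' @export
write_patients <- function(p, path) {
  write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read stations from CSV or GeoJSON
#'
#' CSV needs `id,x,y` (optional `label`); GeoJSON must be a
#' FeatureCollection of Points (properties `id`/`label` used when present).
#'
#' @param path input file; format inferred from the extension unless given.
#' @param format `"csv"` or `"geojson"`.
#' @return a [stations] table.
#' @export
read_stations <- function(path, format = guess_format(path)) {
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    stop_if(!all(c("id", "x", "y") %in% names(df)),
            "stations CSV must have columns id, x, y")
    lab <- if (is.null(df$label)) df$id else df$label
    return(stations(df$id, df$x, df$y, lab))
  }
  feats <- geojson_points(path)
  ids <- vapply(seq_along(feats$props), function(i) {
    p <- feats$props[[i]]
    if (!is.null(p$id)) as.character(p$id) else sprintf("s%d", i)
  }, character(1))
  labs <- vapply(seq_along(feats$props), function(i) {
    p <- feats$props[[i]]
    if (!is.null(p$label)) as.character(p$label) else ids[i]
  }, character(1))
  stations(ids, feats$x, feats$y, labs)
}

#' Write stations to CSV or GeoJSON
#' @param s a [stations] table.
#' @param path output path.
#' @param format `"csv"` or `"geojson"`.
#' @export
write_stations <- function(s, path, format = guess_format(path)) {
  if (format == "csv") {
    write.csv(as.data.frame(s), path, row.names = FALSE, quote = FALSE)
  } else {
    write_geojson_points(path, s$x, s$y,
                         props = Map(function(i, l) list(id = i, label = l),
                                     s$id, s$label))
  }
  invisible(path)
}

#' Read a point layer from CSV or GeoJSON
#'
#' CSV needs `x,y` headers; GeoJSON must contain only Point features.
#' Feature order is preserved.
#'
#' @param path input file.
#' @param kind `"bus_stops"` or `"buildings"`.
#' @param format `"csv"` or `"geojson"`.
#' @return a [point_layer].
#' @export
read_point_layer <- function(path, kind, format = guess_format(path)) {
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    stop_if(!all(c("x", "y") %in% names(df)),
            "point-layer CSV must have columns x, y")
    return(point_layer(df$x, df$y, kind))
  }
  feats <- geojson_points(path)
  point_layer(feats$x, feats$y, kind)
}

#' Write a point layer to CSV or GeoJSON
#' @param layer a [point_layer].
#' @param path output path.
#' @param format `"csv"` or `"geojson"`.
#' @export
write_point_layer <- function(layer, path, format = guess_format(path)) {
  if (format == "csv") {
    write.csv(data.frame(x = layer$x, y = layer$y), path,
              row.names = FALSE, quote = FALSE)
  } else {
    write_geojson_points(path, layer$x, layer$y)
  }
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) "geojson" else "csv"
}

# Parse a GeoJSON FeatureCollection of Points -> list(x, y, props).
geojson_points <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stop_if(!identical(gj$type, "FeatureCollection"),
          "expected a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0)
    return(list(x = numeric(0), y = numeric(0), props = list()))
  x <- numeric(length(feats)); y <- numeric(length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    g <- feats[[i]]$geometry
    stop_if(!identical(g$type, "Point"),
            "feature ", i, " is a ", g$type, ", expected Point")
    x[i] <- as.numeric(g$coordinates[[1]])
    y[i] <- as.numeric(g$coordinates[[2]])
    props[[i]] <- feats[[i]]$properties
  }
  list(x = x, y = y, props = props)
}

write_geojson_points <- function(path, x, y, props = NULL) {
  feats <- lapply(seq_along(x), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x[i], y[i])),
         properties = if (is.null(props)) setNames(list(), character(0))
                      else props[[i]])
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
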