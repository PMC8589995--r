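# File formats: tessellation GeoJSON/CSV, flow CSV, feature CSV + sidecar.

#' Read locations from CSV
#'
#' Flat location table: `id, lat, lon, area_km2, population[, city_label]`.
#'
#' @param path CSV path.
#' @return data frame suitable for [assign_locations()].
#' @export
read_locations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "lat", "lon", "area_km2", "population")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("locations CSV missing columns: ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df
}

#' @rdname read_locations_csv
#' @param locations location data frame (or `tessellation`).
#' @export
write_locations_csv <- function(locations, path) {
  if (inherits(locations, "tessellation")) locations <- locations$locations
  cols <- intersect(c("id", "lat", "lon", "area_km2", "population", "city_label", "roi_id"),
                    names(locations))
  utils::write.csv(locations[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Tessellation GeoJSON I/O
#'
#' Writes a FeatureCollection with one Point feature per location; properties
#' carry `id`, `population`, `area_km2`, and `city_label`/`roi_id` when
#' present. `read_locations_geojson()` reads the same layout back (Polygon
#' features are read via their centroid plus a `polygon` attribute).
#'
#' @param tessellation a `tessellation` or location data frame.
#' @param path file path.
#' @export
write_locations_geojson <- function(tessellation, path) {
  locs <- if (inherits(tessellation, "tessellation")) tessellation$locations else tessellation
  feats <- lapply(seq_len(nrow(locs)), function(i) {
    props <- list(id = locs$id[i],
                  population = locs$population[i],
                  area_km2 = locs$area_km2[i])
    if (!is.null(locs$city_label)) props$city_label <- locs$city_label[i]
    if (!is.null(locs$roi_id)) props$roi_id <- locs$roi_id[i]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(locs$lon[i], locs$lat[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_locations_geojson
#' @export
read_locations_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    geom <- f$geometry
    if (geom$type == "Point") {
      lon <- geom$coordinates[[1]]; lat <- geom$coordinates[[2]]
    } else if (geom$type == "Polygon") {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(v) unlist(v)))
      ring <- open_ring(ring)
      lon <- mean(ring[, 1]); lat <- mean(ring[, 2])
    } else stop("unsupported geometry type: ", geom$type)
    data.frame(id = as.character(p$id), lat = lat, lon = lon,
               area_km2 = as.numeric(p$area_km2),
               population = as.numeric(p$population),
               city_label = if (!is.null(p$city_label)) as.character(p$city_label) else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flow table CSV I/O
#'
#' CSV with header `origin_id,destination_id,flow`; flows nonnegative.
#'
#' @param path CSV path.
#' @return a `flow_table`.
#' @export
read_flows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("origin_id", "destination_id", "flow")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("flow CSV missing columns: ", paste(miss, collapse = ", "))
  flow_table(df$origin_id, df$destination_id, df$flow)
}

#' @rdname read_flows_csv
#' @param flows a `flow_table`.
#' @export
write_flows_csv <- function(flows, path) {
  utils::write.csv(data.frame(origin_id = flows$origin,
                              destination_id = flows$destination,
                              flow = flows$flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' Feature table CSV I/O with schema sidecar
#'
#' The feature table CSV holds `location_id` plus the 19 schema columns in
#' schema order; a JSON sidecar (`<path>.json`) records the schema version and
#' whether values are area-normalized.
#'
#' @param features feature table (see [feature_table()]).
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  df <- cbind(location_id = rownames(features), as.data.frame(features))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(schema_version = feature_schema_version(),
                            normalized = isTRUE(attr(features, "normalized"))),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  schema <- feature_schema()
  miss <- setdiff(schema, names(df))
  if (length(miss)) stop("feature CSV missing schema columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, schema])
  rownames(m) <- df$location_id
  sidecar <- paste0(path, ".json")
  normalized <- FALSE
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$schema_version) && meta$schema_version != feature_schema_version())
      stop("feature schema version mismatch: ", meta$schema_version)
    normalized <- isTRUE(meta$normalized)
  }
  attr(m, "normalized") <- normalized
  m
}
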