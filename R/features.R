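# The 19-value location feature schema (population + 18 geographic features
# in 7 categories), aggregation of tagged geometries, area normalization, and
# construction of model input vectors.

FEATURE_SCHEMA_VERSION <- "1.0"

POI_CATEGORIES <- c("transport", "food", "health", "education", "retail")
LANDUSE_CLASSES <- c("residential", "commercial", "industrial", "retail", "natural")
ROAD_CLASSES <- c("residential", "main", "other")

#' The location feature schema
#'
#' Ordered names of the 19 per-location values: population, five land-use
#' areas (km2), three road-length classes (km), and point-of-interest and
#' building counts for the transport, food, health, education and retail
#' categories.
#'
#' @return character vector of 19 feature names.
#' @export
feature_schema <- function() {
  c("population",
    paste0("land_use_", LANDUSE_CLASSES),
    paste0("roads_", ROAD_CLASSES),
    as.vector(t(outer(POI_CATEGORIES, c("pois", "buildings"), paste, sep = "_"))))
}

#' @rdname feature_schema
#' @export
feature_schema_version <- function() FEATURE_SCHEMA_VERSION

# Names of the ten POI/building count features.
poi_count_features <- function() {
  as.vector(t(outer(POI_CATEGORIES, c("pois", "buildings"), paste, sep = "_")))
}

#' Build an empty or populated feature table
#'
#' @param location_ids character vector of location ids (rownames).
#' @param values optional numeric matrix (locations x 19) in schema order.
#' @return numeric matrix with schema colnames and a `normalized` attribute
#'   (FALSE).
#' @export
feature_table <- function(location_ids, values = NULL) {
  schema <- feature_schema()
  if (is.null(values)) {
    values <- matrix(0, nrow = length(location_ids), ncol = length(schema))
  }
  stopifnot(ncol(values) == length(schema), nrow(values) == length(location_ids))
  dimnames(values) <- list(as.character(location_ids), schema)
  attr(values, "normalized") <- FALSE
  values
}

#' Default OSM-style tag-to-category mapping
#'
#' Reads the editable mapping shipped with the package (a CSV with columns
#' `tag`, `category`), which resolves tags like `amenity=restaurant` to the
#' schema categories (`food`, `roads_main`, `land_use_residential`, ...).
#' The mapping is data, not code: pass your own data frame of the same shape
#' to [aggregate_osm_features()] to change it.
#'
#' @param path optional path to an alternative mapping CSV.
#' @return data frame with columns `tag`, `category`.
#' @export
default_tag_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "osm_tag_mapping.csv", package = "gravityflows")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate tagged geometries into the raw feature table
#'
#' Points, lines and polygons carrying a tag are resolved through the mapping
#' into schema categories and aggregated per location: polygon areas (km2) sum
#' into the land-use features, line lengths (km) into the road features, and
#' point counts / building-polygon counts into the ten POI/building features.
#' Lines and polygons crossing location boundaries are split by exact
#' geometric clipping (convex location polygons) so pieces sum to the whole.
#' Geometries with no resolvable tag are skipped and tallied in the
#' `unmatched` attribute of the result.
#'
#' @param geometries list of geometry records, each a list with `type` (one of
#'   `"point"`, `"line"`, `"polygon"`), `tag` (e.g. `"amenity=restaurant"`),
#'   and `coords` (lon/lat: length-2 vector for points, two-column matrix
#'   otherwise). Alternatively a data frame of tagged points with columns
#'   `lon`, `lat`, `tag`.
#' @param tessellation a `tessellation` whose `polygons` list gives each
#'   location's convex boundary ring (lon/lat).
#' @param mapping tag mapping data frame; defaults to the shipped one.
#' @return raw (unnormalized) feature table; attribute `unmatched` counts
#'   skipped geometries by tag.
#' @export
aggregate_osm_features <- function(geometries, tessellation,
                                   mapping = default_tag_mapping()) {
  if (is.data.frame(geometries)) {
    geometries <- lapply(seq_len(nrow(geometries)), function(i)
      list(type = "point", tag = geometries$tag[i],
           coords = c(geometries$lon[i], geometries$lat[i])))
  }
  locs <- tessellation$locations
  polys <- tessellation$polygons
  if (is.null(polys)) stop("tessellation carries no location polygons; clipping-based aggregation needs them")
  ref <- tessellation$proj_ref
  proj <- local_projection(ref["lon"], ref["lat"])

  # precompute projected polygons + half-planes per location
  loc_ids <- locs$id
  proj_polys <- lapply(loc_ids, function(id) {
    ring <- polys[[id]]
    if (is.null(ring)) stop("no polygon for location ", id)
    pxy <- proj$fwd(ring[, 1], ring[, 2])
    if (!is_convex_ring(pxy)) stop("location polygon not convex: ", id)
    list(ring = pxy, hp = convex_halfplanes(pxy))
  })
  names(proj_polys) <- loc_ids

  ft <- feature_table(loc_ids)
  unmatched <- integer(0)
  cat_of <- stats::setNames(mapping$category, mapping$tag)

  for (g in geometries) {
    cat <- unname(cat_of[g$tag])
    if (is.null(cat) || is.na(cat)) {
      unmatched[g$tag] <- sum(unmatched[g$tag], 1L, na.rm = TRUE)
      next
    }
    if (g$type == "point") {
      pxy <- proj$fwd(g$coords[1], g$coords[2])
      if (!cat %in% POI_CATEGORIES) {
        unmatched[g$tag] <- sum(unmatched[g$tag], 1L, na.rm = TRUE); next
      }
      col <- paste0(cat, "_pois")
      for (id in loc_ids) {
        if (point_in_polygon(pxy[1, 1], pxy[1, 2], proj_polys[[id]]$ring)) {
          ft[id, col] <- ft[id, col] + 1
          break
        }
      }
    } else if (g$type == "line") {
      if (!startsWith(cat, "roads_")) {
        unmatched[g$tag] <- sum(unmatched[g$tag], 1L, na.rm = TRUE); next
      }
      xy <- proj$fwd(g$coords[, 1], g$coords[, 2])
      for (id in loc_ids) {
        len <- clip_polyline_length(xy, proj_polys[[id]]$hp)
        if (len > 0) ft[id, cat] <- ft[id, cat] + len
      }
    } else if (g$type == "polygon") {
      xy <- proj$fwd(g$coords[, 1], g$coords[, 2])
      if (startsWith(cat, "land_use_")) {
        for (id in loc_ids) {
          a <- clip_polygon_area(xy, proj_polys[[id]]$ring)
          if (a > 0) ft[id, cat] <- ft[id, cat] + a
        }
      } else if (cat %in% POI_CATEGORIES) {
        # building polygon: counted once, in the location containing its centroid
        cx <- mean(open_ring(xy)[, 1]); cy <- mean(open_ring(xy)[, 2])
        col <- paste0(cat, "_buildings")
        for (id in loc_ids) {
          if (point_in_polygon(cx, cy, proj_polys[[id]]$ring)) {
            ft[id, col] <- ft[id, col] + 1
            break
          }
        }
      } else {
        unmatched[g$tag] <- sum(unmatched[g$tag], 1L, na.rm = TRUE)
      }
    } else stop("unknown geometry type: ", g$type)
  }
  ft[, "population"] <- locs$population
  attr(ft, "normalized") <- FALSE
  attr(ft, "unmatched") <- unmatched
  ft
}

#' Area-normalize a feature table
#'
#' Divides every per-location value (population included; distance is not a
#' location feature) by the location's area in km2. Refuses input that is
#' already normalized.
#'
#' @param features raw feature table.
#' @param tessellation a `tessellation` supplying `area_km2` per location.
#' @param include_population normalize population too (default TRUE, matching
#'   the full-schema convention); set FALSE to keep raw population for
#'   sensitivity checks.
#' @return normalized feature table (attribute `normalized = TRUE`).
#' @export
normalize_by_area <- function(features, tessellation, include_population = TRUE) {
  if (isTRUE(attr(features, "normalized")))
    stop("feature table is already area-normalized")
  locs <- tessellation$locations
  areas <- stats::setNames(locs$area_km2, locs$id)
  ids <- rownames(features)
  if (any(!ids %in% names(areas))) stop("locations missing from tessellation: ",
                                        paste(setdiff(ids, names(areas)), collapse = ", "))
  a <- areas[ids]
  if (any(a <= 0)) stop("nonpositive area for location(s): ",
                        paste(ids[a <= 0], collapse = ", "))
  out <- features / a
  if (!include_population) out[, "population"] <- features[, "population"]
  attr(out, "normalized") <- TRUE
  attr(out, "unmatched") <- attr(features, "unmatched")
  out
}

#' Build model input vectors for one origin and its candidate destinations
#'
#' Full variant: 39 values per candidate — the 19 origin features, the 19
#' destination features, and the origin-destination distance (km, not
#' area-normalized). Light variant: 5 values — origin population, destination
#' population, distance, and the total POI/building count of origin and
#' destination (sum of the ten count features).
#'
#' @param origin_id origin location id.
#' @param candidate_ids candidate destination ids.
#' @param features feature table covering all ids.
#' @param distances distance matrix (km) with ids as dimnames.
#' @param variant `"full_39"` or `"light_5"`.
#' @return numeric matrix, one row per candidate (rownames = candidate ids).
#' @export
build_input_vectors <- function(origin_id, candidate_ids, features, distances,
                                variant = c("full_39", "light_5")) {
  variant <- match.arg(variant)
  ids <- c(origin_id, candidate_ids)
  miss <- setdiff(ids, rownames(features))
  if (length(miss)) stop("missing feature rows: ", paste(miss, collapse = ", "))
  r <- distances[origin_id, candidate_ids]
  if (any(!is.finite(r))) stop("missing distances for origin ", origin_id)
  xi <- features[origin_id, , drop = TRUE]
  Xj <- features[candidate_ids, , drop = FALSE]
  n <- length(candidate_ids)
  if (variant == "full_39") {
    out <- cbind(matrix(xi, nrow = n, ncol = length(xi), byrow = TRUE), Xj, r)
    colnames(out) <- c(paste0("O:", feature_schema()),
                       paste0("D:", feature_schema()), "distance")
  } else {
    poi_cols <- poi_count_features()
    out <- cbind(xi[["population"]],
                 Xj[, "population"],
                 r,
                 sum(xi[poi_cols]),
                 rowSums(Xj[, poi_cols, drop = FALSE]))
    colnames(out) <- c("O:population", "D:population", "distance",
                       "O:total_pois", "D:total_pois")
  }
  rownames(out) <- candidate_ids
  out
}

# Input vectors for the gravity/NG families. gravity_2d: [ln m_j, ln r | r];
# pop_dist: [pop_o, pop_d, r] (3 inputs) or [pop_d, r] (2 inputs).
build_gravity_inputs <- function(masses, r, deterrence_kind, r_floor) {
  r <- pmax(r, r_floor)
  cbind(log_mass = log(masses), dist = if (deterrence_kind == "power") log(r) else r)
}
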