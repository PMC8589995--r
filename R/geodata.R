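# Tessellation construction, region-of-interest bookkeeping, distances,
# flow tables, and train/test splitting schemes.

#' Build a square grid of regions of interest over a boundary
#'
#' Tiles the bounding box of `boundary` with square cells of side
#' `cell_km` kilometres, constructed in a local equirectangular projection
#' centred on the boundary, and retains the cells that intersect the boundary
#' polygon. Cell bounds are stored back in lon/lat.
#'
#' @param boundary two-column matrix or data frame of boundary ring vertices,
#'   columns lon then lat (degrees, WGS84). The ring need not be closed.
#' @param cell_km cell side length in km (> 0).
#' @return a data frame of class `roi_grid` with one row per retained cell:
#'   `roi_id`, `row`, `col`, `min_lon`, `min_lat`, `max_lon`, `max_lat`.
#'   Attributes: `cell_km`, `proj_ref` (reference lon/lat of the projection),
#'   `n_rows`, `n_cols`.
#' @examples
#' b <- square_boundary(0, 0, 100)
#' g <- build_square_grid(b, 25)
#' nrow(g)  # 16
#' @export
build_square_grid <- function(boundary, cell_km) {
  boundary <- as.matrix(boundary)
  if (!is.numeric(boundary) || ncol(boundary) < 2)
    stop("boundary must be a numeric two-column (lon, lat) ring")
  boundary <- open_ring(boundary[, 1:2, drop = FALSE])
  if (nrow(unique(boundary)) < 3)
    stop("boundary is degenerate: fewer than 3 distinct vertices")
  if (!is.numeric(cell_km) || length(cell_km) != 1 || cell_km <= 0)
    stop("cell_km must be a single positive number")
  check_lonlat(boundary[, 1], boundary[, 2])

  ref_lon <- mean(range(boundary[, 1]))
  ref_lat <- mean(range(boundary[, 2]))
  proj <- local_projection(ref_lon, ref_lat)
  bxy <- proj$fwd(boundary[, 1], boundary[, 2])
  if (polygon_area(bxy) <= 0)
    stop("boundary is degenerate: zero area")

  x0 <- min(bxy[, 1]); y0 <- min(bxy[, 2])
  nx <- max(1L, ceiling((max(bxy[, 1]) - x0) / cell_km - 1e-9))
  ny <- max(1L, ceiling((max(bxy[, 2]) - y0) / cell_km - 1e-9))

  cells <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  keep <- logical(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cx0 <- x0 + (cells$col[k] - 1) * cell_km
    cy0 <- y0 + (cells$row[k] - 1) * cell_km
    rect <- rbind(c(cx0, cy0), c(cx0 + cell_km, cy0),
                  c(cx0 + cell_km, cy0 + cell_km), c(cx0, cy0 + cell_km))
    keep[k] <- rect_intersects_polygon(rect, bxy)
  }
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) stop("no grid cell intersects the boundary")

  ll_min <- proj$inv(x0 + (cells$col - 1) * cell_km, y0 + (cells$row - 1) * cell_km)
  ll_max <- proj$inv(x0 + cells$col * cell_km, y0 + cells$row * cell_km)
  grid <- data.frame(
    roi_id = sprintf("r%02dc%02d", cells$row, cells$col),
    row = cells$row, col = cells$col,
    min_lon = ll_min[, 1], min_lat = ll_min[, 2],
    max_lon = ll_max[, 1], max_lat = ll_max[, 2],
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$row, grid$col), ]
  rownames(grid) <- NULL
  attr(grid, "cell_km") <- cell_km
  attr(grid, "proj_ref") <- c(lon = ref_lon, lat = ref_lat)
  attr(grid, "n_rows") <- ny
  attr(grid, "n_cols") <- nx
  class(grid) <- c("roi_grid", "data.frame")
  grid
}

# Rectangle/polygon intersection test (both in projected km coordinates):
# true only for overlap of positive area, so cells that merely touch the
# boundary at an edge or corner are not retained.
rect_intersects_polygon <- function(rect, poly) {
  clip_polygon_area(poly, rect) > 1e-9
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates must be finite with lat in [-90, 90], lon in [-180, 180]")
  invisible(TRUE)
}

#' Square boundary helper
#'
#' Convenience constructor of a rectangular lon/lat boundary ring whose sides
#' measure `width_km` by `height_km` in the local metric projection anchored
#' at the south-west corner. Used throughout for synthetic study regions.
#'
#' @param lon,lat south-west corner (degrees).
#' @param width_km,height_km side lengths in km (`height_km` defaults to
#'   `width_km`).
#' @return four-row matrix of (lon, lat) ring vertices.
#' @export
square_boundary <- function(lon, lat, width_km, height_km = width_km) {
  proj <- local_projection(lon, lat)
  ll <- proj$inv(c(0, width_km, width_km, 0), c(0, 0, height_km, height_km))
  unname(ll)
}

#' Assign locations to grid cells by centroid containment
#'
#' Each location is attached to the unique cell whose half-open bounds
#' `[min, max)` (on both axes; the global maximum edge is closed) contain its
#' centroid. Locations whose centroid falls in no retained cell are excluded
#' and reported via the `excluded` attribute and a message.
#'
#' @param locations data frame with columns `id`, `lon`, `lat`, `area_km2`,
#'   `population`, and optionally `city_label`.
#' @param grid a `roi_grid` from [build_square_grid()].
#' @param polygons optional named list (by location id) of convex lon/lat
#'   polygon rings; required only by geometry-clipping feature aggregation.
#' @return object of class `tessellation`: list with `locations` (the input
#'   plus a `roi_id` column), `grid` (with `n_locations` and
#'   `total_population` columns added), `cell_km`, `proj_ref`, `polygons`.
#' @export
assign_locations <- function(locations, grid, polygons = NULL) {
  stopifnot(inherits(grid, "roi_grid"))
  locations <- as.data.frame(locations)
  req <- c("id", "lon", "lat", "area_km2", "population")
  miss <- setdiff(req, names(locations))
  if (length(miss)) stop("locations missing columns: ", paste(miss, collapse = ", "))
  locations$id <- as.character(locations$id)
  if (anyDuplicated(locations$id))
    stop("duplicate location ids: ",
         paste(unique(locations$id[duplicated(locations$id)]), collapse = ", "))
  if (any(locations$area_km2 <= 0)) stop("location areas must be > 0")
  if (any(locations$population < 0)) stop("location populations must be >= 0")
  check_lonlat(locations$lon, locations$lat)

  ref <- attr(grid, "proj_ref")
  cell_km <- attr(grid, "cell_km")
  proj <- local_projection(ref["lon"], ref["lat"])
  # grid origin in projected space from the (row=1, col=1) cell position
  g1 <- grid[1, ]
  oxy <- proj$fwd(g1$min_lon, g1$min_lat)
  x0 <- oxy[1, 1] - (g1$col - 1) * cell_km
  y0 <- oxy[1, 2] - (g1$row - 1) * cell_km
  nx <- attr(grid, "n_cols"); ny <- attr(grid, "n_rows")

  lxy <- proj$fwd(locations$lon, locations$lat)
  col <- floor((lxy[, 1] - x0) / cell_km) + 1L
  row <- floor((lxy[, 2] - y0) / cell_km) + 1L
  # closed global max edge
  on_max_x <- abs(lxy[, 1] - (x0 + nx * cell_km)) < 1e-9
  on_max_y <- abs(lxy[, 2] - (y0 + ny * cell_km)) < 1e-9
  col[on_max_x] <- nx
  row[on_max_y] <- ny

  key <- sprintf("r%02dc%02d", row, col)
  key[col < 1 | col > nx | row < 1 | row > ny] <- NA_character_
  roi_id <- ifelse(key %in% grid$roi_id, key, NA_character_)

  excluded <- locations$id[is.na(roi_id)]
  if (length(excluded))
    message(length(excluded), " location(s) fall outside every grid cell and were excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
  locations$roi_id <- roi_id
  kept <- locations[!is.na(roi_id), , drop = FALSE]
  rownames(kept) <- NULL

  grid$n_locations <- as.integer(table(factor(kept$roi_id, levels = grid$roi_id)))
  pops <- tapply(kept$population, factor(kept$roi_id, levels = grid$roi_id), sum)
  grid$total_population <- ifelse(is.na(pops), 0, pops)

  structure(
    list(locations = kept, grid = grid, cell_km = cell_km,
         proj_ref = ref, polygons = polygons, excluded = excluded),
    class = "tessellation"
  )
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Tessellation:", nrow(x$locations), "locations in", nrow(x$grid),
      sprintf("regions of interest (%g km cells)\n", x$cell_km))
  invisible(x)
}

#' Great-circle distance matrix between location centroids
#'
#' Haversine distances in km (Earth radius 6371.0088 km) between all pairs of
#' location centroids.
#'
#' @param locations data frame with `id`, `lon`, `lat` columns, or a
#'   `tessellation`.
#' @return symmetric matrix of km with dimnames set to location ids.
#' @export
pairwise_distance <- function(locations) {
  if (inherits(locations, "tessellation")) locations <- locations$locations
  check_lonlat(locations$lon, locations$lat)
  pts <- cbind(locations$lon, locations$lat)
  d <- geosphere::distm(pts, fun = function(a, b)
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000)) / 1000
  dimnames(d) <- list(locations$id, locations$id)
  d
}

#' Flow table constructor
#'
#' A sparse origin-destination flow table: one row per observed pair.
#'
#' @param origin,destination character vectors of location ids.
#' @param flow nonnegative flows (people per unit time).
#' @return data frame of class `flow_table` with columns `origin`,
#'   `destination`, `flow`.
#' @export
flow_table <- function(origin = character(), destination = character(),
                       flow = numeric()) {
  stopifnot(length(origin) == length(destination),
            length(origin) == length(flow))
  if (any(flow < 0)) stop("flows must be nonnegative")
  out <- data.frame(origin = as.character(origin),
                    destination = as.character(destination),
                    flow = as.numeric(flow), stringsAsFactors = FALSE)
  class(out) <- c("flow_table", "data.frame")
  out
}

as_flow_table <- function(df) {
  flow_table(df$origin, df$destination, df$flow)
}

#' Total outflow per origin
#'
#' Row sums of the flow table: O_i = sum_j y(l_i, l_j). Origins listed in
#' `ids` but absent from the table get 0.
#'
#' @param flows a `flow_table`.
#' @param ids optional character vector of origin ids the result must cover.
#' @return named numeric vector of outflows.
#' @export
total_outflows <- function(flows, ids = NULL) {
  sums <- tapply(flows$flow, flows$origin, sum)
  if (is.null(ids)) ids <- sort(unique(flows$origin))
  out <- stats::setNames(rep(0, length(ids)), ids)
  present <- intersect(names(sums), ids)
  out[present] <- sums[present]
  out
}

#' Restrict a flow table to within-ROI pairs
#'
#' Keeps exactly the entries whose origin and destination are assigned to the
#' same region of interest. Entries touching unassigned locations are dropped.
#' Idempotent.
#'
#' @param flows a `flow_table`.
#' @param tessellation a `tessellation`.
#' @return filtered `flow_table`.
#' @export
restrict_flows_within_rois <- function(flows, tessellation) {
  roi <- stats::setNames(tessellation$locations$roi_id, tessellation$locations$id)
  ro <- roi[flows$origin]
  rd <- roi[flows$destination]
  keep <- !is.na(ro) & !is.na(rd) & ro == rd
  out <- flows[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flow_table", "data.frame")
  out
}

# Decile assignment: rank by population, ties broken by id, cut into 10
# groups; when n is not a multiple of 10 the extra members go to the lowest
# deciles first.
population_deciles <- function(ids, populations, n_groups = 10L) {
  ord <- order(populations, ids)
  n <- length(ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  dec <- rep(seq_len(n_groups), times = sizes)
  out <- integer(n)
  out[ord] <- dec
  stats::setNames(out, ids)
}

#' Stratified train/test split of regions of interest
#'
#' Regions are ranked by total population and cut into ten equal-sized deciles
#' (ties broken by ROI id; remainders spread from the lowest decile up);
#' within each decile `round(train_fraction * k)` regions go to the training
#' set, drawn at random. Deterministic given `seed`. With fewer regions than
#' deciles the split degrades to a plain random split with a warning.
#'
#' @param tessellation a `tessellation` (or a grid with `roi_id` and
#'   `total_population` columns).
#' @param train_fraction fraction of ROIs per decile assigned to training.
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `train_roi_ids`,
#'   `test_roi_ids`, `seed`, `scheme`.
#' @export
stratified_split <- function(tessellation, train_fraction = 0.5, seed = 1L) {
  grid <- if (inherits(tessellation, "tessellation")) tessellation$grid else tessellation
  stopifnot(train_fraction > 0, train_fraction < 1)
  ids <- grid$roi_id
  pops <- grid$total_population
  n <- length(ids)
  withr::with_seed(seed, {
    if (n < 10) {
      warning("fewer ROIs than deciles; falling back to a plain random split")
      n_train <- max(1L, min(n - 1L, floor(train_fraction * n + 0.5)))
      train <- sample(ids, n_train)
    } else {
      dec <- population_deciles(ids, pops)
      train <- character(0)
      # cumulative-target rounding: per decile |n_train - n_test| <= 1 and
      # the global train fraction is met even when deciles hold one ROI each
      cum_target <- 0
      assigned <- 0L
      for (d in sort(unique(dec))) {
        members <- ids[dec == d]
        k <- length(members)
        cum_target <- cum_target + train_fraction * k
        n_train <- max(0L, min(k, as.integer(floor(cum_target + 0.5)) - assigned))
        assigned <- assigned + n_train
        train <- c(train, sample(members, n_train))
      }
    }
  })
  structure(list(train_roi_ids = sort(train),
                 test_roi_ids = sort(setdiff(ids, train)),
                 seed = seed, scheme = "stratified_half"),
            class = "split_plan")
}

#' Leave-one-city-out split plans
#'
#' One plan per labelled city: its regions of interest form the test set and
#' every other labelled region forms the training set. ROI city labels are
#' derived from member locations' `city_label` (majority label; a mixed ROI
#' raises a warning). Unlabelled ROIs take part in neither side.
#'
#' @param tessellation a `tessellation` whose locations carry `city_label`.
#' @return named list of `split_plan` objects, one per city.
#' @export
leave_one_city_out_splits <- function(tessellation) {
  locs <- tessellation$locations
  if (is.null(locs$city_label)) stop("locations carry no city_label")
  lab <- locs$city_label
  roi_city <- vapply(split(lab, locs$roi_id), function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    if (!length(v)) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1)
      warning("ROI with mixed city labels; using majority label ", names(tab)[1])
    names(tab)[1]
  }, character(1))
  roi_city <- roi_city[!is.na(roi_city)]
  cities <- unique(unname(roi_city))
  if (length(cities) < 2) stop("leave-one-city-out needs at least 2 labelled cities")
  plans <- list()
  for (city in cities) {
    test <- names(roi_city)[roi_city == city]
    if (!length(test)) { warning("city ", city, " has no ROIs; skipped"); next }
    plans[[city]] <- structure(
      list(train_roi_ids = sort(names(roi_city)[roi_city != city]),
           test_roi_ids = sort(test),
           seed = NA_integer_, scheme = paste0("leave_one_city_out(", city, ")")),
      class = "split_plan")
  }
  plans
}
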