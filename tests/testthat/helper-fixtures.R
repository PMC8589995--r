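# Shared fixtures: tiny geographies built in code.

# A rectangle ring (lon/lat) spanning the given km extents from a corner.
km_rect <- function(lon0, lat0, w_km, h_km = w_km) {
  square_boundary(lon0, lat0, w_km, h_km)
}

# Tessellation of `n_cells` 25-km cells in a row, each with locations on a
# deterministic layout. Returns the assign_locations() result.
toy_tessellation <- function(n_cells = 2, per_cell = 3, cell_km = 25,
                             pops = NULL) {
  boundary <- square_boundary(0, 45, n_cells * cell_km, cell_km)
  grid <- build_square_grid(boundary, cell_km)
  rows <- list()
  for (k in seq_len(nrow(grid))) {
    fr <- seq(0.2, 0.8, length.out = per_cell)
    rows[[k]] <- data.frame(
      id = sprintf("c%d_%d", k, seq_len(per_cell)),
      lon = grid$min_lon[k] + fr * (grid$max_lon[k] - grid$min_lon[k]),
      lat = grid$min_lat[k] + fr * (grid$max_lat[k] - grid$min_lat[k]),
      area_km2 = 2 + seq_len(per_cell),
      population = if (is.null(pops)) 100 * seq_len(per_cell) else pops,
      stringsAsFactors = FALSE)
  }
  assign_locations(do.call(rbind, rows), grid)
}

# A one-cell tessellation whose locations are adjacent convex rectangles,
# with polygons attached (needed by feature aggregation).
rect_location_tessellation <- function() {
  cell_km <- 25
  boundary <- square_boundary(0, 45, cell_km, cell_km)
  grid <- build_square_grid(boundary, cell_km)
  proj <- gravityflows:::local_projection(attr(grid, "proj_ref")["lon"],
                                          attr(grid, "proj_ref")["lat"])
  # two 10x10 km rectangles side by side, inside the cell
  mk_rect <- function(x0, y0, w, h) {
    xy <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
    # local_projection is centred mid-boundary; shift to cell frame
    proj$inv(xy[, 1] - cell_km / 2, xy[, 2] - cell_km / 2)
  }
  pa <- mk_rect(1, 1, 10, 10)
  pb <- mk_rect(11, 1, 10, 10)
  locs <- data.frame(
    id = c("A", "B"),
    lon = c(mean(pa[, 1]), mean(pb[, 1])),
    lat = c(mean(pa[, 2]), mean(pb[, 2])),
    area_km2 = c(100, 100), population = c(200, 300),
    stringsAsFactors = FALSE)
  assign_locations(locs, grid, polygons = list(A = pa, B = pb))
}

# Random flow table over the given ids with matched per-origin totals.
random_matched_flows <- function(ids, n_origins = 4, total = 50) {
  gen <- list(); real <- list()
  for (k in seq_len(n_origins)) {
    oi <- sample(ids, 1)
    dests <- sample(ids, min(4, length(ids)))
    yg <- as.vector(stats::rmultinom(1, total, rep(1, length(dests))))
    yr <- as.vector(stats::rmultinom(1, total, rep(1, length(dests))))
    gen[[k]] <- data.frame(origin = oi, destination = dests, flow = yg)
    real[[k]] <- data.frame(origin = oi, destination = dests, flow = yr)
  }
  agg <- function(df) {
    df <- do.call(rbind, df)
    df <- stats::aggregate(flow ~ origin + destination, df, sum)
    flow_table(df$origin, df$destination, df$flow)
  }
  list(generated = agg(gen), real = agg(real))
}
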