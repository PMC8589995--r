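test_that("square grid tiles the boundary with the expected cell counts", {
  expect_equal(nrow(build_square_grid(km_rect(0, 45, 100), 25)), 16)
  expect_equal(nrow(build_square_grid(km_rect(0, 45, 10), 25)), 1)

  # L-shaped boundary occupying 3 of 4 quadrants of a 50x50 km square
  proj <- gravityflows:::local_projection(0, 45)
  xy <- rbind(c(0, 0), c(50, 0), c(50, 25), c(25, 25), c(25, 50), c(0, 50))
  ring <- proj$inv(xy[, 1], xy[, 2])
  gL <- build_square_grid(ring, 25)
  expect_equal(nrow(gL), 3)

  expect_error(build_square_grid(cbind(c(0, 0, 0), c(1, 2, 3)), 25),
               "degenerate")
  expect_error(build_square_grid(km_rect(0, 45, 100), -1), "positive")
})

test_that("centroid assignment matches a point-in-box brute force and uses the half-open rule", {
  grid <- build_square_grid(km_rect(0, 45, 50), 25)  # 2 x 2 cells
  set.seed(42)
  n <- 100
  lon <- runif(n, min(grid$min_lon), max(grid$max_lon))
  lat <- runif(n, min(grid$min_lat), max(grid$max_lat))
  locs <- data.frame(id = sprintf("p%03d", 1:n), lon = lon, lat = lat,
                     area_km2 = 1, population = 10)
  tess <- assign_locations(locs, grid)
  # brute force: first cell whose half-open lon/lat box contains the point
  brute <- vapply(seq_len(n), function(i) {
    hit <- which(lon[i] >= grid$min_lon & lon[i] < grid$max_lon &
                   lat[i] >= grid$min_lat & lat[i] < grid$max_lat)
    if (length(hit)) grid$roi_id[hit[1]] else NA_character_
  }, character(1))
  expect_equal(stats::setNames(tess$locations$roi_id, NULL),
               brute[match(tess$locations$id, locs$id)])

  # a centroid exactly on the shared edge belongs to exactly one cell (the
  # half-open rule assigns it to the cell on the upper side)
  edge <- data.frame(id = "edge", lon = grid$max_lon[1], lat = grid$min_lat[1] + 1e-3,
                     area_km2 = 1, population = 1)
  t2 <- assign_locations(edge, grid)
  expect_equal(nrow(t2$locations), 1)
  expect_equal(sum(t2$grid$n_locations), 1L)

  # all locations in one cell
  one <- data.frame(id = letters[1:5],
                    lon = grid$min_lon[1] + 1e-3 * (1:5),
                    lat = grid$min_lat[1] + 1e-3, area_km2 = 1, population = 1)
  t3 <- assign_locations(one, grid)
  counts <- t3$grid$n_locations
  expect_equal(sort(counts, decreasing = TRUE), c(5L, 0L, 0L, 0L))

  expect_error(assign_locations(rbind(one, one), grid), "duplicate")
})

test_that("locations outside every cell are excluded and reported", {
  grid <- build_square_grid(km_rect(0, 45, 25), 25)
  locs <- data.frame(id = c("in", "out"),
                     lon = c(mean(grid$min_lon + grid$max_lon) / 1, 50),
                     lat = c(mean(grid$min_lat + grid$max_lat) / 2 * 1, 80),
                     area_km2 = 1, population = 1)
  locs$lon[1] <- (grid$min_lon + grid$max_lon) / 2
  locs$lat[1] <- (grid$min_lat + grid$max_lat) / 2
  expect_message(tess <- assign_locations(locs, grid), "excluded")
  expect_equal(tess$locations$id, "in")
  expect_equal(tess$excluded, "out")
})

test_that("haversine distances use the IUGG radius, are symmetric and satisfy the triangle inequality", {
  d <- pairwise_distance(data.frame(id = c("a", "b", "c"),
                                    lon = c(0, 1, 0), lat = c(0, 0, 0)))
  expect_equal(d["a", "b"], 111.1951, tolerance = 1e-6)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d["a", "c"], 0)

  set.seed(7)
  pts <- data.frame(id = sprintf("x%d", 1:12),
                    lon = runif(12, -10, 10), lat = runif(12, 30, 60))
  D <- pairwise_distance(pts)
  expect_equal(D, t(D))
  for (k in 1:30) {
    ijk <- sample(12, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("total outflows are exact row sums with zeros for absent origins", {
  ft <- flow_table(c("A", "A"), c("B", "C"), c(2, 3))
  expect_equal(total_outflows(ft), c(A = 5))
  expect_equal(total_outflows(flow_table(), ids = c("A", "B")), c(A = 0, B = 0))

  set.seed(3)
  ids <- sprintf("l%02d", 1:8)
  df <- expand.grid(origin = ids, destination = ids, stringsAsFactors = FALSE)
  df <- df[runif(nrow(df)) < 0.4, ]
  df$flow <- rpois(nrow(df), 4)
  ft <- flow_table(df$origin, df$destination, df$flow)
  M <- matrix(0, 8, 8, dimnames = list(ids, ids))
  M[cbind(df$origin, df$destination)] <- df$flow
  expect_equal(total_outflows(ft, ids), rowSums(M))
})

test_that("flow restriction keeps exactly the within-ROI pairs and is idempotent", {
  tess <- toy_tessellation(n_cells = 2, per_cell = 3)
  ids <- tess$locations$id   # c1_* in ROI 1, c2_* in ROI 2
  ft <- flow_table(c("c1_1", "c1_1", "c1_2", "c2_1", "c1_3", "c2_2"),
                   c("c1_2", "c1_3", "c2_1", "c2_2", "c1_1", "c1_1"),
                   1:6)
  kept <- restrict_flows_within_rois(ft, tess)
  expect_equal(nrow(kept), 4)
  expect_setequal(kept$flow, c(1, 2, 4, 5))
  expect_equal(restrict_flows_within_rois(kept, tess), kept)

  within <- ft[c(1, 2), ]
  class(within) <- c("flow_table", "data.frame")
  again <- restrict_flows_within_rois(within, tess)
  expect_equal(again$flow, within$flow)
})

test_that("stratified splits balance population deciles and are deterministic", {
  tess <- toy_tessellation(n_cells = 20, per_cell = 2,
                           pops = NULL)
  # distinct ROI populations via distinct location populations
  tess$grid$total_population <- 100 * seq_len(20)
  plan <- stratified_split(tess, 0.5, seed = 9)
  expect_equal(length(plan$train_roi_ids), 10)
  expect_equal(length(plan$test_roi_ids), 10)
  expect_length(intersect(plan$train_roi_ids, plan$test_roi_ids), 0)
  expect_setequal(c(plan$train_roi_ids, plan$test_roi_ids), tess$grid$roi_id)
  # each decile (2 ROIs) split 1/1
  dec <- gravityflows:::population_deciles(tess$grid$roi_id,
                                           tess$grid$total_population)
  for (d in 1:10) {
    members <- names(dec)[dec == d]
    expect_equal(sum(members %in% plan$train_roi_ids), 1)
  }
  expect_identical(stratified_split(tess, 0.5, seed = 9), plan)
  expect_false(identical(stratified_split(tess, 0.5, seed = 10), plan))
})

test_that("per-decile train counts are balanced for 100 ROIs and tiny grids degrade with a warning", {
  ids <- sprintf("r%03d", 1:100)
  grid <- data.frame(roi_id = ids, total_population = sample(1:1e6, 100))
  plan <- stratified_split(grid, 0.5, seed = 2)
  dec <- gravityflows:::population_deciles(ids, grid$total_population)
  counts <- vapply(1:10, function(d)
    sum(ids[dec == d] %in% plan$train_roi_ids), numeric(1))
  expect_equal(counts, rep(5, 10))

  small <- data.frame(roi_id = c("a", "b", "c"), total_population = 1:3)
  expect_warning(p <- stratified_split(small, 0.5, seed = 1), "plain random")
  expect_length(intersect(p$train_roi_ids, p$test_roi_ids), 0)
})

test_that("leave-one-city-out builds one complementary plan per city", {
  tess <- toy_tessellation(n_cells = 9, per_cell = 2)
  city <- rep(c("alpha", "beta", "gamma"), times = c(2, 3, 4))
  tess$locations$city_label <- city[match(tess$locations$roi_id,
                                          tess$grid$roi_id)]
  plans <- leave_one_city_out_splits(tess)
  expect_named(plans, c("alpha", "beta", "gamma"))
  expect_equal(vapply(plans, function(p) length(p$test_roi_ids), numeric(1)),
               c(alpha = 2, beta = 3, gamma = 4))
  all_test <- sort(unlist(lapply(plans, `[[`, "test_roi_ids"), use.names = FALSE))
  expect_equal(all_test, sort(tess$grid$roi_id))
  for (p in plans)
    expect_length(intersect(p$train_roi_ids, p$test_roi_ids), 0)
  tess$locations$city_label <- "only_one"
  expect_error(leave_one_city_out_splits(tess), "at least 2")
})
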