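# Seeded generator of synthetic geographies, feature tables, and flows with
# known ground truth. Emulates the study setting: a square study region cut
# into 25 x 25 km regions of interest, each holding a handful of census-like
# locations with heterogeneous populations and geographic features, and
# commuting flows sampled multinomially from a known generative process.

#' Synthetic study configuration
#'
#' Defaults describe the study conditions all bundled experiments run under:
#' 40 regions of interest of 25 km, 8-15 locations each, log-normal
#' populations (median ~300 residents, like small census output areas),
#' negative-binomial POI/building counts partly tied to population, gamma
#' land-use areas and road lengths, a gravity flow process with beta1 = 1 and
#' power-law deterrence beta2 = -2, and per-origin outflows averaging ~40% of
#' residents.
#'
#' @param n_rois number of regions of interest.
#' @param locations_per_roi length-2 range of locations per ROI.
#' @param cell_km ROI side length (km).
#' @param pop_meanlog,pop_sdlog log-normal population parameters.
#' @param poi_size negative-binomial dispersion of count features.
#' @param poi_mu base mean of count features.
#' @param process flow process: `"gravity"` or `"nonlinear"`.
#' @param beta1,beta2,deterrence gravity-process parameters.
#' @param nonlinear_spec coefficients of the nonlinear ground-truth score,
#'   see [nonlinear_flow_spec()].
#' @param trips_rate expected trips per resident (per-origin outflows are
#'   Poisson with mean `trips_rate * population`).
#' @param n_cities if > 0, ROIs are labelled with this many synthetic city
#'   labels (contiguous row-major blocks) for leave-one-city-out protocols.
#' @param seed mandatory integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rois = 40L, locations_per_roi = c(8L, 15L),
                             cell_km = 25, pop_meanlog = log(300),
                             pop_sdlog = 0.8, poi_size = 1.5, poi_mu = 20,
                             process = c("gravity", "nonlinear"),
                             beta1 = 1.0, beta2 = -2.0, deterrence = "power",
                             nonlinear_spec = nonlinear_flow_spec(),
                             trips_rate = 0.4, n_cities = 0L, seed) {
  process <- match.arg(process)
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  stopifnot(n_rois >= 1, all(locations_per_roi >= 1), cell_km > 0,
            trips_rate > 0)
  structure(list(n_rois = as.integer(n_rois),
                 locations_per_roi = as.integer(locations_per_roi),
                 cell_km = cell_km, pop_meanlog = pop_meanlog,
                 pop_sdlog = pop_sdlog, poi_size = poi_size, poi_mu = poi_mu,
                 process = process, beta1 = beta1, beta2 = beta2,
                 deterrence = deterrence, nonlinear_spec = nonlinear_spec,
                 trips_rate = trips_rate, n_cities = as.integer(n_cities),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Nonlinear ground-truth flow score
#'
#' Coefficients of the score g(x_i, x_j, r_ij) used by the nonlinear flow
#' process. The default combines (i) a distance-POI interaction — the pull of
#' a destination's points of interest decays with distance — and (ii) a
#' non-monotone (saturating then declining) destination-population term, so
#' a linear model on \[ln m, ln r\] is misspecified while a flexible function
#' of the full feature vector is not.
#'
#' @param poi_pull coefficient of ln(1 + total POIs of destination) /
#'   (1 + r / poi_range).
#' @param poi_range distance scale (km) of the POI pull.
#' @param pop_lin,pop_quad linear and quadratic coefficients of
#'   z = ln(1 + destination population); `pop_quad < 0` makes the term
#'   non-monotone.
#' @param dist_decay plain linear distance decay per km.
#' @return list of class `nonlinear_flow_spec`.
#' @export
nonlinear_flow_spec <- function(poi_pull = 3.0, poi_range = 5,
                                pop_lin = 22.8, pop_quad = -2.0,
                                dist_decay = 0.08) {
  structure(list(poi_pull = poi_pull, poi_range = poi_range,
                 pop_lin = pop_lin, pop_quad = pop_quad,
                 dist_decay = dist_decay),
            class = "nonlinear_flow_spec")
}

# ground-truth score of the nonlinear process on raw features
nonlinear_score <- function(spec, features_raw, origin_id, cand, r) {
  poi <- rowSums(features_raw[cand, poi_count_features(), drop = FALSE])
  zp <- log1p(features_raw[cand, "population"])
  spec$poi_pull * log1p(poi) / (1 + r / spec$poi_range) +
    spec$pop_lin * zp + spec$pop_quad * zp^2 -
    spec$dist_decay * r
}

#' Generate a synthetic geography and feature table
#'
#' Builds a square-grid tessellation with `n_rois` regions of interest, each
#' holding a random number of locations with uniformly scattered centroids,
#' gamma-distributed areas (rescaled to cover 60% of the cell), log-normal
#' populations (minimum 1 resident), and the 18 geographic features drawn per
#' the configuration: land-use areas as random fractions of the location
#' area, road lengths gamma, POI/building counts negative binomial with means
#' partly proportional to population^0.7. Deterministic given the seed.
#'
#' @param config a `synthetic_config`.
#' @return list with `tessellation`, `features_raw` (unnormalized feature
#'   table), `config`.
#' @export
gen_geography <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nx <- ceiling(sqrt(config$n_rois))
  ny <- ceiling(config$n_rois / nx)
  boundary <- square_boundary(0, 45, nx * config$cell_km, ny * config$cell_km)
  grid <- build_square_grid(boundary, config$cell_km)
  keep_attrs <- attributes(grid)[c("cell_km", "proj_ref", "n_rows", "n_cols")]
  grid <- grid[seq_len(config$n_rois), ]  # row-major subset
  attributes(grid)[names(keep_attrs)] <- keep_attrs
  rownames(grid) <- NULL

  withr::with_seed(config$seed, {
    lo <- config$locations_per_roi[1]
    hi <- config$locations_per_roi[length(config$locations_per_roi)]
    rows <- list()
    for (k in seq_len(nrow(grid))) {
      n_loc <- if (hi > lo) sample(lo:hi, 1) else lo
      # scatter centroids with a small margin from the cell edges
      u <- stats::runif(n_loc, 0.03, 0.97)
      v <- stats::runif(n_loc, 0.03, 0.97)
      lon <- grid$min_lon[k] + u * (grid$max_lon[k] - grid$min_lon[k])
      lat <- grid$min_lat[k] + v * (grid$max_lat[k] - grid$min_lat[k])
      g <- stats::rgamma(n_loc, shape = 2, rate = 1)
      areas <- g / sum(g) * 0.6 * config$cell_km^2
      pop <- pmax(1, round(stats::rlnorm(n_loc, config$pop_meanlog, config$pop_sdlog)))
      rows[[k]] <- data.frame(
        id = sprintf("%s_l%02d", grid$roi_id[k], seq_len(n_loc)),
        lat = lat, lon = lon, area_km2 = areas, population = pop,
        city_label = if (config$n_cities > 0)
          sprintf("city_%d", ((k - 1L) %% config$n_cities) + 1L)
        else NA_character_,
        stringsAsFactors = FALSE)
    }
    locs <- do.call(rbind, rows)
    tess <- assign_locations(locs, grid)

    n <- nrow(tess$locations)
    ft <- feature_table(tess$locations$id)
    ft[, "population"] <- tess$locations$population
    area <- tess$locations$area_km2
    # land use: random fractions of the location area per class
    frac <- matrix(stats::rgamma(n * 5, shape = 0.8), nrow = n)
    frac <- frac / rowSums(frac) * stats::runif(n, 0.3, 0.9)
    ft[, paste0("land_use_", LANDUSE_CLASSES)] <- frac * area
    # roads: km, loosely scaling with area
    for (cl in ROAD_CLASSES)
      ft[, paste0("roads_", cl)] <- stats::rgamma(n, shape = 1.2,
                                                  rate = 1.2 / (2 * sqrt(area)))
    # POI/building counts: over-dispersed, partly tied to population
    popfac <- (tess$locations$population / 300)^0.7
    for (col in poi_count_features()) {
      mu <- config$poi_mu * popfac * stats::runif(1, 0.3, 1.2)
      ft[, col] <- stats::rnbinom(n, size = config$poi_size, mu = mu)
    }
  })
  attr(ft, "normalized") <- FALSE
  list(tessellation = tess, features_raw = ft, config = config)
}

#' Sample synthetic flows from a known process
#'
#' Per-origin outflows O_i are Poisson with mean `trips_rate * population`
#' (at least 1 trip); each origin's O_i trips are assigned to within-ROI
#' destinations by a multinomial draw from the process's softmax
#' probabilities — the gravity process of the configuration, or the
#' nonlinear ground-truth score. Deterministic given the seed.
#'
#' @param geography output of [gen_geography()].
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @param include_self whether a location may send trips to itself.
#' @return list with `flows` (a `flow_table`), `probabilities` (per-origin
#'   named list of true destination probabilities), `outflows`.
#' @export
gen_flows <- function(geography, seed = NULL, include_self = TRUE) {
  config <- geography$config
  if (is.null(seed)) seed <- config$seed + 1L
  tess <- geography$tessellation
  ftr <- geography$features_raw
  locs <- tess$locations
  D <- pairwise_distance(locs)
  members <- split(locs$id, locs$roi_id)
  areas <- stats::setNames(locs$area_km2, locs$id)
  pops <- stats::setNames(locs$population, locs$id)

  probs <- list()
  flows_list <- list()
  outflows <- stats::setNames(numeric(nrow(locs)), locs$id)
  withr::with_seed(seed, {
    for (roi in names(members)) {
      ids <- members[[roi]]
      for (oi in ids) {
        cand <- if (include_self) ids else setdiff(ids, oi)
        if (!length(cand)) next
        r <- D[oi, cand]
        if (config$process == "gravity") {
          params <- gravity_params(config$beta1, config$beta2, config$deterrence)
          p <- gravity_probabilities(params, pops[cand], r,
                                     r_floor = self_distance_floor(areas[oi]))
        } else {
          s <- nonlinear_score(config$nonlinear_spec, ftr, oi, cand,
                               pmax(r, self_distance_floor(areas[oi])))
          p <- softmax(s)
        }
        probs[[oi]] <- stats::setNames(p, cand)
        Oi <- max(1L, stats::rpois(1, config$trips_rate * pops[oi]))
        outflows[oi] <- Oi
        draws <- stats::rmultinom(1, Oi, p)[, 1]
        pos <- draws > 0
        flows_list[[oi]] <- data.frame(origin = oi, destination = cand[pos],
                                       flow = as.numeric(draws[pos]),
                                       stringsAsFactors = FALSE)
      }
    }
  })
  flows <- do.call(rbind, flows_list)
  rownames(flows) <- NULL
  class(flows) <- c("flow_table", "data.frame")
  list(flows = flows, probabilities = probs, outflows = outflows,
       seed = seed)
}
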