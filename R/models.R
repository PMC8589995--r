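# The four flow models — gravity (G), nonlinear gravity (NG), multi-feature
# gravity (MFG) and the deep model (DG) — behind one interface: scores,
# softmax destination probabilities, cross-entropy training with negative
# sampling, and expected-flow generation.

MODEL_VARIANTS <- c(G = "gravity_2d", NG = "pop_dist", MFG = "full_39", DG = "full_39")

#' Training configuration
#'
#' Defaults follow the reference training recipe: 20 epochs of RMSprop with
#' momentum 0.9 and learning rate 5e-6, batches of 64 origin locations, and
#' negative sampling of up to 512 destinations per origin.
#'
#' @param epochs number of passes over the training origins.
#' @param learning_rate RMSprop learning rate.
#' @param momentum RMSprop momentum.
#' @param batch_origins origins per mini-batch.
#' @param max_sampled_destinations cap on candidate destinations per origin
#'   during training (observed destinations are always kept).
#' @param seed master seed for initialization, shuffling and sampling.
#' @param weight_decay decoupled L2 penalty coefficient on the network
#'   weights (default 0; useful against overfitting when training origins
#'   are few).
#' @param average_tail fraction of final epochs over which network weights
#'   are averaged (Polyak averaging; 0 disables). Averaging the tail of the
#'   optimization path damps gradient noise on small training sets.
#' @param standardize input conditioning for the network model kinds:
#'   `FALSE` (raw, the default), `TRUE` (z-score with training-set
#'   statistics), or `"log1p_zscore"` (log1p then z-score, suited to
#'   nonnegative heavy-tailed features).
#' @param include_self treat a location as a candidate destination of itself.
#' @return object of class `training_config`.
#' @export
training_config <- function(epochs = 20L, learning_rate = 5e-6, momentum = 0.9,
                            batch_origins = 64L, max_sampled_destinations = 512L,
                            seed = 1L, standardize = FALSE, include_self = TRUE,
                            weight_decay = 0, average_tail = 0) {
  stopifnot(epochs >= 1, learning_rate > 0, momentum >= 0, batch_origins >= 1,
            max_sampled_destinations >= 1, weight_decay >= 0,
            average_tail >= 0, average_tail < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, batch_origins = as.integer(batch_origins),
                 max_sampled_destinations = as.integer(max_sampled_destinations),
                 seed = as.integer(seed),
                 standardize = if (is.character(standardize))
                   match.arg(standardize, "log1p_zscore") else isTRUE(standardize),
                 include_self = isTRUE(include_self),
                 weight_decay = weight_decay, average_tail = average_tail),
            class = "training_config")
}

#' Softmax over destination scores
#'
#' p_j = exp(s_j) / sum_k exp(s_k), stabilized by subtracting the maximum
#' score. Invariant under adding a constant to all scores.
#'
#' @param scores finite numeric score vector.
#' @return probability vector summing to 1.
#' @export
softmax_probabilities <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  softmax(scores)
}

#' Cross-entropy between observed flows and model probabilities
#'
#' H = -sum_i sum_j (y_ij / O_i) ln p_ij over origins with positive outflow.
#' A zero probability where y > 0 yields an infinite loss, reported as `Inf`.
#'
#' @param flows a `flow_table`.
#' @param probabilities named list: for each origin id, a named probability
#'   vector over its candidate destinations.
#' @return scalar loss (sum over origins).
#' @export
cross_entropy_loss <- function(flows, probabilities) {
  H <- 0
  O <- total_outflows(flows)
  for (oi in names(probabilities)) {
    if (is.na(O[oi]) || O[oi] <= 0) next
    p <- probabilities[[oi]]
    rows <- flows[flows$origin == oi & flows$flow > 0, ]
    if (!nrow(rows)) next
    pj <- p[rows$destination]
    if (any(is.na(pj))) stop("probability vector for origin ", oi,
                             " misses observed destinations")
    if (any(pj == 0)) return(Inf)
    H <- H - sum(rows$flow / O[oi] * log(pj))
  }
  H
}

#' Negative sampling of candidate destinations
#'
#' All observed (positive-flow) destinations are always retained; the set is
#' padded with uniformly sampled zero-flow candidates up to
#' `min(max_n, number of candidates)`. Deterministic given `seed`.
#'
#' @param candidates character vector of all candidate destination ids.
#' @param observed ids of destinations with positive flow from the origin.
#' @param max_n cap on the sampled set size.
#' @param seed optional integer seed.
#' @return character vector of sampled candidate ids (original order).
#' @export
negative_sample <- function(candidates, observed, max_n, seed = NULL) {
  stopifnot(max_n >= 1)
  observed <- intersect(observed, candidates)
  if (length(candidates) <= max_n) return(candidates)
  n_fill <- max_n - length(observed)
  pool <- setdiff(candidates, observed)
  pick <- if (n_fill <= 0) character(0) else {
    if (!is.null(seed)) withr::with_seed(seed, sample(pool, min(n_fill, length(pool))))
    else sample(pool, min(n_fill, length(pool)))
  }
  keep <- union(observed, pick)
  candidates[candidates %in% keep]
}

# Input conditioning for the network kinds: optional log compression
# (log1p for the nonnegative heavy-tailed feature columns; floored plain log
# for the distance column, whose effect is log-linear in spatial interaction
# models) followed by z-scoring with training-set statistics.
apply_transform <- function(X, transform) {
  if (isTRUE(transform$log1p)) {
    lc <- transform$log_cols
    Xl <- log1p(pmax(X, 0))
    if (length(lc)) Xl[, lc] <- log(pmax(X[, lc, drop = FALSE], 1e-2))
    X <- Xl
  }
  sweep(sweep(X, 2, transform$mean), 2, transform$sd, "/")
}

distance_columns <- function(nms) which(nms %in% c("distance", "dist", "r"))

# ---- model object ------------------------------------------------------

new_flow_model <- function(kind, variant, layers = NULL, spec = NULL,
                           params = NULL, transform = NULL,
                           include_self = TRUE, history = NULL) {
  structure(list(kind = kind, variant = variant, layers = layers, spec = spec,
                 params = params, transform = transform,
                 include_self = include_self, history = history,
                 schema_version = feature_schema_version()),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat("Flow model", x$kind, sprintf("(variant %s)", x$variant), "\n")
  if (x$kind == "G")
    cat(sprintf("  beta1 = %.4f, beta2 = %.4f (%s deterrence)\n",
                x$params$beta1, x$params$beta2, x$params$deterrence))
  else
    cat(sprintf("  %d layer(s), input dim %d\n", length(x$layers),
                ncol(x$layers[[1]]$W)))
  invisible(x)
}

input_dim_of <- function(variant, ng_inputs = 3L) {
  switch(variant,
         gravity_2d = 2L, pop_dist = as.integer(ng_inputs),
         full_39 = 39L, light_5 = 5L,
         stop("unknown variant: ", variant))
}

#' Model scores for a matrix of input vectors
#'
#' One finite real score per row (candidate destination). Linear model kinds
#' compute beta . x; network kinds run the forward pass.
#'
#' @param model a `flow_model`.
#' @param X input matrix, rows = candidates, columns matching the model's
#'   input variant dimension.
#' @return numeric score vector.
#' @export
score <- function(model, X) {
  X <- as.matrix(X)
  d_expect <- if (model$kind == "G") 2L else ncol(model$layers[[1]]$W)
  if (ncol(X) != d_expect)
    stop("input dimension ", ncol(X), " does not match model variant (", d_expect, ")")
  if (model$kind == "G")
    return(drop(X %*% c(model$params$beta1, model$params$beta2)))
  if (!is.null(model$transform))
    X <- apply_transform(X, model$transform)
  s <- mlp_forward(model$layers, X,
                   if (!is.null(model$spec)) model$spec$leaky_slope else 0.01)
  if (any(!is.finite(s))) stop("non-finite model scores")
  s
}

# Build the per-origin input matrix appropriate for a model kind. Distances
# are floored at the origin's within-location characteristic length so that
# self-pairs carry a meaningful (nonzero) travel distance.
model_inputs <- function(kind, variant, origin_id, cand, features, distances,
                         masses, areas, deterrence = "power", ng_inputs = 3L) {
  r_floor <- self_distance_floor(areas[origin_id])
  if (kind == "G") {
    r <- distances[origin_id, cand]
    build_gravity_inputs(masses[cand], r, deterrence, r_floor)
  } else if (kind == "NG") {
    r <- pmax(distances[origin_id, cand], r_floor)
    if (ng_inputs == 3L)
      cbind(o_pop = unname(features[origin_id, "population"]),
            d_pop = unname(features[cand, "population"]), dist = r)
    else
      cbind(d_pop = unname(features[cand, "population"]), dist = r)
  } else {
    X <- build_input_vectors(origin_id, cand, features, distances,
                             if (variant == "light_5") "light_5" else "full_39")
    dc <- distance_columns(colnames(X))
    X[, dc] <- pmax(X[, dc], r_floor)
    X
  }
}

# ---- training ----------------------------------------------------------

#' Train a flow model
#'
#' G is fitted by gravity maximum likelihood (its softmax-linear form). The
#' network kinds (NG, MFG, DG) minimize the cross-entropy of per-origin
#' softmax probabilities over negative-sampled candidate sets by mini-batch
#' RMSprop with momentum. All randomness (initialization, shuffling,
#' sampling) derives from `config$seed`. Per-epoch mean training loss is
#' recorded in the returned model's `history`.
#'
#' @param kind `"G"`, `"NG"`, `"MFG"` or `"DG"`.
#' @param data training data list: `tessellation`, `features` (normalized
#'   feature table), `flows` (within-ROI `flow_table`), `distances`,
#'   `roi_ids` (the training ROIs).
#' @param config a `training_config`.
#' @param variant input variant for DG: `"full_39"` (default) or `"light_5"`.
#' @param spec `mlp_spec` for the network kinds; default the 15-hidden-layer
#'   256/128 architecture (ignored for G; MFG always uses a single linear
#'   layer).
#' @param deterrence deterrence family for G.
#' @param ng_inputs 3 (origin population, destination population, distance)
#'   or 2 (destination population, distance) for NG.
#' @return trained `flow_model`.
#' @export
train_flow_model <- function(kind = c("DG", "G", "NG", "MFG"), data, config,
                             variant = "full_39", spec = NULL,
                             deterrence = "power", ng_inputs = 3L) {
  kind <- match.arg(kind)
  locs <- data$tessellation$locations
  roi_ids <- data$roi_ids
  train_locs <- locs[locs$roi_id %in% roi_ids, ]
  flows <- data$flows
  flows <- flows[flows$origin %in% train_locs$id & flows$destination %in% train_locs$id, ]
  masses <- stats::setNames(train_locs$population, train_locs$id)
  areas <- stats::setNames(train_locs$area_km2, train_locs$id)
  variant <- if (kind %in% c("G")) "gravity_2d"
             else if (kind == "NG") "pop_dist"
             else if (kind == "MFG") "full_39" else variant

  roi_members <- split(train_locs$id, train_locs$roi_id)
  cand_of <- function(oi, roi) {
    cand <- roi_members[[roi]]
    if (!config$include_self) cand <- setdiff(cand, oi)
    cand
  }

  if (kind == "G") {
    if (any(masses <= 0)) stop("gravity masses (populations) must be > 0")
    origins <- unique(flows$origin)
    cands <- lapply(origins, function(oi)
      cand_of(oi, train_locs$roi_id[match(oi, train_locs$id)]))
    names(cands) <- origins
    floors <- stats::setNames(self_distance_floor(areas[origins]), origins)
    params <- fit_gravity_mle(flows, masses, data$distances, deterrence,
                              candidates = cands, r_floor = floors)
    return(new_flow_model("G", "gravity_2d", params = params,
                          include_self = config$include_self))
  }

  # per-origin precomputed training structures
  O <- total_outflows(flows)
  origins <- names(O)[O > 0]
  if (!length(origins)) stop("no training origin with positive outflow")
  prep <- lapply(origins, function(oi) {
    roi <- train_locs$roi_id[match(oi, train_locs$id)]
    cand <- cand_of(oi, roi)
    X <- model_inputs(kind, variant, oi, cand, data$features, data$distances,
                      masses, areas, deterrence, ng_inputs)
    rows <- flows[flows$origin == oi & flows$flow > 0, ]
    y <- stats::setNames(rep(0, length(cand)), cand)
    hit <- rows$destination %in% cand
    y[rows$destination[hit]] <- y[rows$destination[hit]] + rows$flow[hit]
    list(X = X, y = y, O = sum(y), cand = cand,
         observed = rows$destination[hit])
  })
  names(prep) <- origins
  prep <- prep[vapply(prep, function(p) p$O > 0 && length(p$cand) >= 2, logical(1))]
  origins <- names(prep)

  transform <- NULL
  if (!identical(config$standardize, FALSE)) {
    use_log1p <- identical(config$standardize, "log1p_zscore")
    allX <- do.call(rbind, lapply(prep, `[[`, "X"))
    log_cols <- if (use_log1p) distance_columns(colnames(allX)) else integer(0)
    pre <- list(log1p = use_log1p, log_cols = log_cols,
                mean = rep(0, ncol(allX)), sd = rep(1, ncol(allX)))
    allX <- apply_transform(allX, pre)
    mu <- colMeans(allX)
    sd <- apply(allX, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    transform <- list(log1p = use_log1p, log_cols = log_cols, mean = mu, sd = sd)
    prep <- lapply(prep, function(p) {
      p$X <- apply_transform(p$X, transform); p
    })
  }

  if (is.null(spec)) spec <- mlp_spec()
  if (kind == "MFG") spec <- mlp_spec(hidden_dims = integer(0),
                                      leaky_slope = spec$leaky_slope,
                                      init_seed = spec$init_seed)
  d_in <- ncol(prep[[1]]$X)
  history <- numeric(config$epochs)

  # stack all per-origin blocks once; batches address rows by index
  X_all <- do.call(rbind, lapply(prep, `[[`, "X"))
  t_all <- unlist(lapply(prep, function(p) unname(p$y) / p$O), use.names = FALSE)
  n_cand <- vapply(prep, function(p) length(p$cand), integer(1))
  row_end <- cumsum(n_cand)
  row_span <- lapply(seq_along(prep), function(k)
    seq.int(row_end[k] - n_cand[k] + 1L, row_end[k]))
  needs_sampling <- n_cand > config$max_sampled_destinations

  avg_layers <- NULL
  n_avg <- 0L
  withr::with_seed(config$seed, {
    spec$init_seed <- sample.int(2^30, 1)
    layers <- mlp_init(spec, d_in)
    state <- rmsprop_state(layers)
    n_or <- length(origins)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n_or)
      epoch_loss <- 0
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_origins))
      for (bi in batches) {
        spans <- lapply(bi, function(k) {
          if (!needs_sampling[k]) return(row_span[[k]])
          p <- prep[[k]]
          samp <- negative_sample(p$cand, p$observed,
                                  config$max_sampled_destinations)
          row_span[[k]][match(samp, p$cand)]
        })
        idx <- unlist(spans, use.names = FALSE)
        gid <- rep.int(seq_along(bi), lengths(spans))
        X <- X_all[idx, , drop = FALSE]
        t_vec <- t_all[idx]
        # renormalize targets in case sampling dropped mass (it keeps all
        # observed destinations, so this is the identity in practice)
        fwd <- mlp_forward(layers, X, spec$leaky_slope, keep = TRUE)
        s <- fwd$score
        # per-origin softmax over the sampled candidate block (gid is
        # contiguous 1..n_groups, so positional indexing is safe here)
        mx <- vapply(split(s, gid), max, numeric(1))[gid]
        e <- exp(s - mx)
        denom <- rowsum(e, gid, reorder = FALSE)[gid, 1]
        pvec <- e / denom
        loss <- -sum(t_vec * log(pmax(pvec, 1e-300)))
        if (!is.finite(loss)) stop("training loss is not finite at epoch ", epoch)
        epoch_loss <- epoch_loss + loss
        g_s <- pvec - t_vec
        grads <- mlp_backward(layers, fwd, g_s, spec$leaky_slope)
        upd <- rmsprop_step(layers, grads, state, config$learning_rate,
                            config$momentum,
                            weight_decay = if (is.null(config$weight_decay)) 0
                                           else config$weight_decay)
        layers <- upd$layers
        state <- upd$state
      }
      history[epoch] <- epoch_loss / n_or
      if (!is.null(config$average_tail) && config$average_tail > 0 &&
          epoch > (1 - config$average_tail) * config$epochs) {
        n_avg <- n_avg + 1L
        if (is.null(avg_layers)) avg_layers <- layers
        else for (h in seq_along(layers)) {
          avg_layers[[h]]$W <- avg_layers[[h]]$W +
            (layers[[h]]$W - avg_layers[[h]]$W) / n_avg
          avg_layers[[h]]$b <- avg_layers[[h]]$b +
            (layers[[h]]$b - avg_layers[[h]]$b) / n_avg
        }
      }
    }
  })
  if (!is.null(avg_layers)) layers <- avg_layers
  new_flow_model(kind, variant, layers = layers, spec = spec,
                 transform = transform, include_self = config$include_self,
                 history = history)
}

#' Destination probabilities of a trained model for one origin
#'
#' Softmax over all candidate destinations of the origin's region of
#' interest (no negative sampling at evaluation time).
#'
#' @param model a `flow_model`.
#' @param origin_id origin location id.
#' @param cand candidate destination ids.
#' @param data data list as in [train_flow_model()] (features, distances,
#'   tessellation).
#' @return named probability vector over `cand`.
#' @export
predict_probabilities <- function(model, origin_id, cand, data) {
  locs <- data$tessellation$locations
  masses <- stats::setNames(locs$population, locs$id)
  areas <- stats::setNames(locs$area_km2, locs$id)
  ng_inputs <- if (model$kind == "NG") ncol(model$layers[[1]]$W) else 3L
  X <- model_inputs(model$kind, model$variant, origin_id, cand, data$features,
                    data$distances, masses, areas,
                    if (model$kind == "G") model$params$deterrence else "power",
                    ng_inputs)
  # model$transform is applied inside score() for network kinds
  p <- softmax_probabilities(score(model, X))
  stats::setNames(p, cand)
}

#' Generate expected flows on a region of interest
#'
#' For every origin of the ROI with positive outflow, expected flows are the
#' model's destination probabilities times the origin's total outflow:
#' yhat(l_i, l_j) = O_i p_ij. Per-origin generated totals equal O_i.
#'
#' @param model trained `flow_model`.
#' @param data data list (`tessellation`, `features`, `distances`).
#' @param outflows named vector of per-origin total outflows O_i.
#' @param roi_id region of interest to generate on.
#' @return `flow_table` of expected flows.
#' @export
generate_flows <- function(model, data, outflows, roi_id) {
  locs <- data$tessellation$locations
  members <- locs$id[locs$roi_id == roi_id]
  if (!length(members)) stop("unknown or empty ROI: ", roi_id)
  unknown <- setdiff(names(outflows), locs$id)
  if (length(unknown)) stop("outflows name unknown locations: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  out <- list()
  for (oi in members) {
    Oi <- if (oi %in% names(outflows)) outflows[[oi]] else 0
    if (Oi <= 0) next
    cand <- if (model$include_self) members else setdiff(members, oi)
    p <- predict_probabilities(model, oi, cand, data)
    out[[oi]] <- data.frame(origin = oi, destination = cand,
                            flow = Oi * unname(p), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(flow_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("flow_table", "data.frame")
  res
}

# ---- serialization -----------------------------------------------------

#' Flow model serialization
#'
#' Writes the model (kind, variant, schema version, hyperparameters, flat
#' weight arrays) to a single JSON archive; `read_flow_model()` restores it
#' exactly.
#'
#' @param model a `flow_model`.
#' @param path file path.
#' @export
write_flow_model <- function(model, path) {
  obj <- list(kind = model$kind, variant = model$variant,
              schema_version = model$schema_version,
              include_self = model$include_self)
  if (model$kind == "G") {
    obj$params <- list(beta1 = model$params$beta1, beta2 = model$params$beta2,
                       deterrence = model$params$deterrence)
  } else {
    obj$spec <- unclass(model$spec)
    obj$layers <- lapply(model$layers, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b))
    if (!is.null(model$transform))
      obj$transform <- list(log1p = isTRUE(model$transform$log1p),
                            log_cols = as.integer(model$transform$log_cols),
                            mean = unname(model$transform$mean),
                            sd = unname(model$transform$sd))
  }
  # digits = I(17): shortest representation that restores doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_flow_model
#' @export
read_flow_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (obj$kind == "G") {
    params <- gravity_params(obj$params$beta1, obj$params$beta2,
                             obj$params$deterrence)
    return(new_flow_model("G", obj$variant, params = params,
                          include_self = isTRUE(obj$include_self)))
  }
  spec <- mlp_spec(hidden_dims = as.integer(unlist(obj$spec$hidden_dims)),
                   leaky_slope = obj$spec$leaky_slope,
                   init_seed = as.integer(obj$spec$init_seed))
  layers <- lapply(obj$layers, function(l) {
    d <- as.integer(unlist(l$dim))
    list(W = matrix(as.numeric(unlist(l$W)), nrow = d[1], ncol = d[2]),
         b = as.numeric(unlist(l$b)))
  })
  transform <- if (!is.null(obj$transform))
    list(log1p = isTRUE(obj$transform$log1p),
         log_cols = as.integer(unlist(obj$transform$log_cols)),
         mean = as.numeric(unlist(obj$transform$mean)),
         sd = as.numeric(unlist(obj$transform$sd))) else NULL
  new_flow_model(obj$kind, obj$variant, layers = layers, spec = spec,
                 transform = transform, include_self = isTRUE(obj$include_self))
}
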