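# Shapley-value attribution of model scores to input features: exact
# coalition enumeration for small numbers of feature groups, and a seeded
# permutation-sampling estimator for larger ones. Feature "absence" means
# interventional substitution from a background set of input vectors.

#' Exact Shapley attribution
#'
#' Enumerates all 2^k coalitions of the k feature groups. The value of a
#' coalition S is the mean of `f` over hybrid inputs taking the groups in S
#' from `instance` and the remaining groups from each background row; the
#' baseline is the coalition value of the empty set (the mean background
#' prediction). Local accuracy — baseline + sum(phi) = f(instance) — holds
#' exactly.
#'
#' @param f score function mapping an input matrix (rows = instances) to a
#'   numeric vector; typically `function(X) score(model, X)`.
#' @param instance single input vector (length = input dimension).
#' @param background matrix of background input vectors (same columns).
#' @param feature_groups optional named list of column-index vectors defining
#'   feature groups attributed jointly; default one group per column.
#' @return object of class `attribution`: list with `phi` (named), `baseline`,
#'   `prediction`, `method`.
#' @export
exact_shapley <- function(f, instance, background, feature_groups = NULL) {
  background <- as.matrix(background)
  d <- length(instance)
  stopifnot(ncol(background) == d)
  if (is.null(feature_groups)) {
    nm <- names(instance)
    if (is.null(nm)) nm <- colnames(background)
    if (is.null(nm)) nm <- paste0("x", seq_len(d))
    feature_groups <- stats::setNames(as.list(seq_len(d)), nm)
  }
  k <- length(feature_groups)
  if (k > 12) stop("more than 12 feature groups: use sampled_shapley()")
  nb <- nrow(background)

  # coalition values: v[mask + 1] for every subset mask of the k groups
  n_coal <- 2^k
  v <- numeric(n_coal)
  for (mask in 0:(n_coal - 1)) {
    X <- background
    for (g in seq_len(k)) {
      if (bitwAnd(mask, bitwShiftL(1L, g - 1L)) != 0) {
        cols <- feature_groups[[g]]
        X[, cols] <- matrix(instance[cols], nrow = nb, ncol = length(cols),
                            byrow = TRUE)
      }
    }
    v[mask + 1] <- mean(f(X))
  }

  fact <- factorial(0:k)
  phi <- numeric(k)
  for (g in seq_len(k)) {
    bit <- bitwShiftL(1L, g - 1L)
    for (mask in 0:(n_coal - 1)) {
      if (bitwAnd(mask, bit) != 0) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) != 0)
      w <- fact[s + 1] * fact[k - s] / fact[k + 1]
      phi[g] <- phi[g] + w * (v[bitwOr(mask, bit) + 1] - v[mask + 1])
    }
  }
  names(phi) <- names(feature_groups)
  structure(list(phi = phi, baseline = v[1],
                 prediction = v[n_coal],
                 method = "exact"),
            class = "attribution")
}

#' Permutation-sampling Shapley attribution
#'
#' Samples random permutations of the feature groups; for each permutation a
#' background row is drawn and features are switched one at a time from the
#' background value to the instance value, accumulating marginal
#' contributions. Deterministic given `seed`; per-feature Monte-Carlo
#' standard errors are reported. The identity
#' baseline + sum(phi) = f(instance) holds exactly by construction (the
#' baseline being the mean prediction of the sampled background rows).
#'
#' @inheritParams exact_shapley
#' @param n_permutations number of sampled permutations (>= 1).
#' @param seed integer seed.
#' @return `attribution` with additional element `se` (standard errors).
#' @export
sampled_shapley <- function(f, instance, background, n_permutations = 200L,
                            feature_groups = NULL, seed = 1L) {
  background <- as.matrix(background)
  d <- length(instance)
  stopifnot(ncol(background) == d, n_permutations >= 1)
  if (is.null(feature_groups)) {
    nm <- names(instance)
    if (is.null(nm)) nm <- colnames(background)
    if (is.null(nm)) nm <- paste0("x", seq_len(d))
    feature_groups <- stats::setNames(as.list(seq_len(d)), nm)
  }
  k <- length(feature_groups)
  contrib <- matrix(0, nrow = n_permutations, ncol = k)
  base_vals <- numeric(n_permutations)
  withr::with_seed(seed, {
    for (it in seq_len(n_permutations)) {
      b <- background[sample(nrow(background), 1), ]
      perm <- sample(k)
      # evaluate the k+1 points along the permutation path in one batch
      X <- matrix(b, nrow = k + 1, ncol = d, byrow = TRUE)
      cur <- b
      for (step in seq_len(k)) {
        cols <- feature_groups[[perm[step]]]
        cur[cols] <- instance[cols]
        X[step + 1, ] <- cur
      }
      vals <- f(X)
      base_vals[it] <- vals[1]
      contrib[it, perm] <- diff(vals)
    }
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  names(phi) <- names(se) <- names(feature_groups)
  structure(list(phi = phi, baseline = mean(base_vals),
                 prediction = mean(base_vals) + sum(phi),
                 se = se, method = "sampled",
                 n_permutations = as.integer(n_permutations)),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s): baseline %.4f, prediction %.4f\n",
              x$method, x$baseline, x$prediction))
  ord <- order(abs(x$phi), decreasing = TRUE)
  print(round(x$phi[ord], 4))
  invisible(x)
}

#' Global attribution summary
#'
#' Pools local attributions over many origin-destination pairs into the
#' beeswarm-style export: per feature, the list of (feature value, phi)
#' points across pairs, and a ranking by mean absolute attribution.
#'
#' @param attributions list of `attribution` objects.
#' @param instances matrix of the corresponding input vectors (rows aligned
#'   with `attributions`).
#' @return list with `points` (data frame: `feature`, `value`, `phi`) and
#'   `ranking` (data frame: `feature`, `mean_abs_phi`, sorted decreasing).
#' @export
global_summary <- function(attributions, instances) {
  stopifnot(length(attributions) >= 1,
            nrow(instances) == length(attributions))
  feat <- names(attributions[[1]]$phi)
  pts <- do.call(rbind, lapply(seq_along(attributions), function(i) {
    phi <- attributions[[i]]$phi
    data.frame(pair = i, feature = feat,
               value = as.numeric(instances[i, seq_along(feat)]),
               phi = as.numeric(phi), stringsAsFactors = FALSE)
  }))
  agg <- tapply(abs(pts$phi), pts$feature, mean)
  ranking <- data.frame(feature = names(agg), mean_abs_phi = as.numeric(agg),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_phi), ]
  rownames(ranking) <- NULL
  list(points = pts, ranking = ranking)
}

#' Attribution export
#'
#' Writes local attributions as CSV rows `(origin, destination, feature,
#' value, phi)` using the `O:`/`D:` feature-name prefixes of the full input
#' schema.
#'
#' @param attribution an `attribution`.
#' @param instance the attributed input vector.
#' @param origin_id,destination_id pair identifiers.
#' @param path CSV path.
#' @export
write_attribution_csv <- function(attribution, instance, origin_id,
                                  destination_id, path) {
  df <- data.frame(origin = origin_id, destination = destination_id,
                   feature = names(attribution$phi),
                   value = as.numeric(instance[seq_along(attribution$phi)]),
                   phi = as.numeric(attribution$phi))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
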