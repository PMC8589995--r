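# Singly constrained gravity model: closed-form destination probabilities and
# maximum-likelihood fitting through the multinomial-logit (softmax-linear)
# formulation.

#' Gravity parameter container
#'
#' @param beta1 mass exponent.
#' @param beta2 deterrence parameter (exponent of the power law, or rate of
#'   the exponential).
#' @param deterrence `"power"` (f(r) = r^beta2) or `"exponential"`
#'   (f(r) = exp(beta2 r)).
#' @return object of class `gravity_params`.
#' @export
gravity_params <- function(beta1, beta2, deterrence = c("power", "exponential")) {
  deterrence <- match.arg(deterrence)
  stopifnot(is.finite(beta1), is.finite(beta2))
  structure(list(beta1 = beta1, beta2 = beta2, deterrence = deterrence),
            class = "gravity_params")
}

#' Within-location characteristic distance floor
#'
#' Distance used for self-pairs (and any pair closer than it) under power-law
#' deterrence, where r = 0 is undefined: half the radius of the circle with
#' the origin's area, 0.5 * sqrt(area / pi).
#'
#' @param area_km2 origin location area(s), km2.
#' @return floor distance(s) in km.
#' @export
self_distance_floor <- function(area_km2) 0.5 * sqrt(area_km2 / pi)

#' Destination probabilities of the singly constrained gravity model
#'
#' p_ij = m_j^beta1 f(r_ij) / sum_k m_k^beta1 f(r_ik), computed in log space
#' for numerical stability.
#'
#' @param params a `gravity_params`.
#' @param masses positive destination masses (resident populations), one per
#'   candidate.
#' @param distances origin-to-candidate distances in km.
#' @param r_floor minimum distance substituted for smaller (e.g. self-pair)
#'   distances under power deterrence; default the smallest positive distance
#'   present, or 1e-6 km if none.
#' @return probability vector over candidates (sums to 1).
#' @export
gravity_probabilities <- function(params, masses, distances, r_floor = NULL) {
  stopifnot(inherits(params, "gravity_params"),
            length(masses) == length(distances))
  if (any(masses <= 0)) stop("masses must be > 0")
  if (any(distances < 0)) stop("distances must be >= 0")
  if (params$deterrence == "power") {
    if (is.null(r_floor)) {
      pos <- distances[distances > 0]
      r_floor <- if (length(pos)) min(pos) else 1e-6
    }
    r <- pmax(distances, r_floor)
    s <- params$beta1 * log(masses) + params$beta2 * log(r)
  } else {
    s <- params$beta1 * log(masses) + params$beta2 * distances
  }
  if (all(!is.finite(s))) stop("all gravity numerators are degenerate")
  softmax(s)
}

softmax <- function(s) {
  m <- max(s)
  e <- exp(s - m)
  e / sum(e)
}

#' Fit gravity parameters by maximum likelihood
#'
#' Maximizes the multinomial loglikelihood of the singly constrained gravity
#' model using its softmax-linear form: per origin i the destination scores
#' are beta1 * ln m_j + beta2 * g(r_ij) with g = ln for power deterrence and
#' identity for exponential. The per-trip-normalized negative loglikelihood
#' is minimized by BFGS with analytic gradient; convergence requires the
#' gradient max-norm (per trip) below `grad_tol`.
#'
#' @param flows a `flow_table` of observed flows.
#' @param masses named vector of location masses (populations), covering every
#'   candidate destination.
#' @param distances distance matrix (km) with location ids as dimnames.
#' @param deterrence `"power"` or `"exponential"`.
#' @param candidates optional named list mapping each origin id to its
#'   candidate destination ids; default: all locations in `masses`.
#' @param r_floor named vector of per-origin distance floors (km) for
#'   self-pairs; default [self_distance_floor()] is not applied here — pass
#'   floors explicitly, otherwise the smallest positive distance per origin
#'   is used under power deterrence.
#' @param grad_tol gradient tolerance (default 1e-8).
#' @return fitted `gravity_params` with attributes `loglik` and `n_trips`.
#' @export
fit_gravity_mle <- function(flows, masses, distances,
                            deterrence = c("power", "exponential"),
                            candidates = NULL, r_floor = NULL,
                            grad_tol = 1e-8) {
  deterrence <- match.arg(deterrence)
  origins <- unique(flows$origin)
  O <- total_outflows(flows, origins)
  origins <- origins[O[origins] > 0]
  if (!length(origins)) stop("no origin with positive outflow")

  # per-origin: feature matrix X (n_cand x 2) and observed counts y
  per_origin <- lapply(origins, function(oi) {
    cand <- if (!is.null(candidates)) candidates[[oi]] else names(masses)
    if (length(cand) < 2) stop("origin ", oi, " has fewer than 2 candidate destinations")
    r <- distances[oi, cand]
    fl <- if (!is.null(r_floor)) r_floor[[oi]] else {
      pos <- r[r > 0]; if (length(pos)) min(pos) else 1e-6
    }
    X <- build_gravity_inputs(masses[cand], r, deterrence, fl)
    yrow <- flows[flows$origin == oi, ]
    y <- stats::setNames(rep(0, length(cand)), cand)
    hit <- yrow$destination %in% cand
    y[yrow$destination[hit]] <- y[yrow$destination[hit]] + yrow$flow[hit]
    list(X = X, y = y, O = sum(y))
  })
  total_trips <- sum(vapply(per_origin, `[[`, numeric(1), "O"))

  nll <- function(beta) {
    val <- 0
    for (po in per_origin) {
      s <- drop(po$X %*% beta)
      val <- val - sum(po$y * (s - logsumexp(s)))
    }
    val / total_trips
  }
  grad <- function(beta) {
    g <- c(0, 0)
    for (po in per_origin) {
      s <- drop(po$X %*% beta)
      p <- softmax(s)
      g <- g - drop((po$y - po$O * p) %*% po$X)
    }
    g / total_trips
  }
  hess <- function(beta) {
    H <- matrix(0, 2, 2)
    for (po in per_origin) {
      s <- drop(po$X %*% beta)
      p <- softmax(s)
      Xp <- drop(p %*% po$X)
      H <- H + po$O * (t(po$X) %*% (p * po$X) - tcrossprod(Xp))
    }
    H / total_trips
  }
  fit <- stats::optim(c(0, 0), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # Newton polish to drive the gradient below tolerance
  beta <- fit$par
  for (it in seq_len(50)) {
    g <- grad(beta)
    if (max(abs(g)) <= grad_tol) break
    step <- tryCatch(solve(hess(beta), g), error = function(e) g)
    beta_new <- beta - step
    if (nll(beta_new) <= nll(beta) + 1e-12) beta <- beta_new else break
  }
  fit$par <- beta
  gn <- max(abs(grad(fit$par)))
  if (gn > grad_tol)
    stop(sprintf("gravity MLE did not converge: per-trip gradient max-norm %.3g > %.3g (optim code %d, nll %.6g)",
                 gn, grad_tol, fit$convergence, fit$value))
  out <- gravity_params(fit$par[1], fit$par[2], deterrence)
  attr(out, "loglik") <- -fit$value * total_trips
  attr(out, "n_trips") <- total_trips
  out
}

logsumexp <- function(s) {
  m <- max(s)
  m + log(sum(exp(s - m)))
}
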