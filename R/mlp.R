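# Feed-forward scoring network: leaky-rectifier MLP with a scalar linear
# output, trained by backpropagation with RMSprop-with-momentum. Written in
# plain R matrix code; there is no deep-learning framework dependency.

#' MLP architecture specification
#'
#' Default architecture: 15 hidden layers, the bottom six of width 256 and
#' the remaining nine of width 128, leaky-rectifier activations (negative
#' slope 0.01), scalar linear output.
#'
#' @param hidden_dims integer vector of hidden-layer widths.
#' @param leaky_slope negative slope of the leaky rectifier.
#' @param init_seed seed for weight initialization.
#' @return object of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden_dims = c(rep(256L, 6), rep(128L, 9)),
                     leaky_slope = 0.01, init_seed = 1L) {
  stopifnot(all(hidden_dims >= 1), leaky_slope >= 0)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 leaky_slope = leaky_slope,
                 init_seed = as.integer(init_seed)),
            class = "mlp_spec")
}

# Fan-in-scaled uniform initialization, seeded.
mlp_init <- function(spec, input_dim) {
  dims <- c(input_dim, spec$hidden_dims, 1L)
  withr::with_seed(spec$init_seed, {
    layers <- lapply(seq_len(length(dims) - 1L), function(h) {
      fan_in <- dims[h]
      lim <- sqrt(1 / fan_in)
      list(W = matrix(stats::runif(dims[h + 1L] * fan_in, -lim, lim),
                      nrow = dims[h + 1L], ncol = fan_in),
           b = stats::runif(dims[h + 1L], -lim, lim))
    })
    layers
  })
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Forward pass over a row-matrix X; returns scores and (optionally) the
# per-layer pre-activations and activations for backprop.
mlp_forward <- function(layers, X, slope, keep = FALSE) {
  H <- length(layers)
  A <- X
  acts <- if (keep) vector("list", H) else NULL
  pres <- if (keep) vector("list", H) else NULL
  for (h in seq_len(H - 1L)) {
    Z <- A %*% t(layers[[h]]$W)
    Z <- sweep(Z, 2, layers[[h]]$b, "+")
    if (keep) { pres[[h]] <- Z; acts[[h]] <- A }
    A <- leaky(Z, slope)
  }
  s <- drop(A %*% t(layers[[H]]$W) + layers[[H]]$b)
  if (keep) list(score = s, acts = acts, pres = pres, last = A) else s
}

# Backward pass: g_s is dLoss/dscore per row. Returns gradients shaped like
# the layer list.
mlp_backward <- function(layers, fwd, g_s, slope) {
  H <- length(layers)
  grads <- vector("list", H)
  delta <- matrix(g_s, ncol = 1)
  grads[[H]] <- list(W = t(delta) %*% fwd$last,
                     b = sum(delta))
  if (H == 1L) return(grads)
  back <- delta %*% layers[[H]]$W  # n x d_{H-1}
  for (h in seq(H - 1L, 1L)) {
    delta <- back * leaky_grad(fwd$pres[[h]], slope)
    grads[[h]] <- list(W = t(delta) %*% fwd$acts[[h]],
                       b = colSums(delta))
    if (h > 1L) back <- delta %*% layers[[h]]$W
  }
  grads
}

# RMSprop with momentum (square-average smoothing `alpha`, epsilon for
# numerical stability): one optimizer state and update step per weight array.
rmsprop_state <- function(layers) {
  lapply(layers, function(l) list(
    vW = matrix(0, nrow(l$W), ncol(l$W)), vb = rep(0, length(l$b)),
    mW = matrix(0, nrow(l$W), ncol(l$W)), mb = rep(0, length(l$b))))
}

# Weight decay is decoupled (applied directly to the weights, outside the
# gradient normalization), so it cannot overwhelm small data gradients.
rmsprop_step <- function(layers, grads, state, lr, momentum, alpha = 0.99,
                         eps = 1e-8, weight_decay = 0) {
  for (h in seq_along(layers)) {
    g <- grads[[h]]
    if (weight_decay > 0)
      layers[[h]]$W <- layers[[h]]$W * (1 - lr * weight_decay)
    st <- state[[h]]
    st$vW <- alpha * st$vW + (1 - alpha) * g$W^2
    st$vb <- alpha * st$vb + (1 - alpha) * g$b^2
    st$mW <- momentum * st$mW + g$W / (sqrt(st$vW) + eps)
    st$mb <- momentum * st$mb + g$b / (sqrt(st$vb) + eps)
    layers[[h]]$W <- layers[[h]]$W - lr * st$mW
    layers[[h]]$b <- layers[[h]]$b - lr * st$mb
    state[[h]] <- st
  }
  list(layers = layers, state = state)
}
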