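test_that("gravity probabilities follow the singly constrained form", {
  p_eq <- gravity_probabilities(gravity_params(1, -1, "power"),
                                masses = c(2, 2), distances = c(5, 5))
  expect_equal(p_eq, c(0.5, 0.5))
  p_mass <- gravity_probabilities(gravity_params(1, 0, "exponential"),
                                  masses = c(1, 3), distances = c(4, 4))
  expect_equal(p_mass, c(0.25, 0.75))
  p_dist <- gravity_probabilities(gravity_params(0, -1, "power"),
                                  masses = c(7, 7), distances = c(1, 2))
  expect_equal(p_dist, c(2 / 3, 1 / 3))
  expect_equal(sum(gravity_probabilities(gravity_params(1.3, -2.1),
                                         c(1, 10, 100), c(2, 3, 4))), 1)
  expect_error(gravity_probabilities(gravity_params(1, -1), c(0, 1), c(1, 2)),
               "masses")
})

test_that("softmax probabilities are stabilized, normalized and shift-invariant", {
  expect_equal(softmax_probabilities(rep(3, 4)), rep(0.25, 4))
  expect_equal(softmax_probabilities(c(0, log(3))), c(0.25, 0.75))
  s <- rnorm(10)
  expect_equal(softmax_probabilities(s), softmax_probabilities(s + 123.4))
  expect_equal(sum(softmax_probabilities(c(1000, 1001))), 1)  # no overflow
  expect_error(softmax_probabilities(c(1, NA)), "finite")
})

test_that("cross-entropy matches its closed forms and the gravity loglikelihood", {
  ft1 <- flow_table("A", "B", 10)
  expect_equal(cross_entropy_loss(ft1, list(A = c(B = 1))), 0)
  # uniform probabilities give ln n per origin
  ftu <- flow_table(rep("A", 3), c("B", "C", "D"), c(5, 2, 3))
  pu <- list(A = c(B = 1/4, C = 1/4, D = 1/4, E = 1/4))
  expect_equal(cross_entropy_loss(ftu, pu), log(4))
  # zero probability on an observed destination
  expect_equal(cross_entropy_loss(ftu, list(A = c(B = 0, C = .5, D = .5))), Inf)

  # equals the negative multinomial loglikelihood / O_i for a single origin
  set.seed(8)
  masses <- c(a = 3, b = 9, c = 27)
  r <- c(a = 2, b = 5, c = 9)
  params <- gravity_params(0.8, -1.4, "power")
  p <- gravity_probabilities(params, masses, r)
  y <- c(a = 4, b = 9, c = 2)
  ft <- flow_table(rep("o", 3), names(y), y)
  H <- cross_entropy_loss(ft, list(o = p))
  loglik <- sum(y * log(p))
  expect_equal(H, -loglik / sum(y))
})

test_that("negative sampling keeps observed destinations and is seed-deterministic", {
  cand <- sprintf("d%04d", 1:1000)
  obs <- sample(cand, 10)
  s1 <- negative_sample(cand, obs, 512, seed = 4)
  expect_length(s1, 512)
  expect_true(all(obs %in% s1))
  expect_identical(s1, negative_sample(cand, obs, 512, seed = 4))
  expect_false(identical(s1, negative_sample(cand, obs, 512, seed = 5)))
  expect_identical(negative_sample(cand[1:100], obs[1:2], 512), cand[1:100])
})

test_that("linear scores equal beta.x and the default deep spec maps 39 inputs to one score", {
  g <- gravity_params(1.2, -1.7, "power")
  model <- gravityflows:::new_flow_model("G", "gravity_2d", params = g)
  X <- cbind(log(c(10, 20, 40)), log(c(1, 2, 3)))
  expect_equal(score(model, X), drop(X %*% c(1.2, -1.7)))
  expect_error(score(model, cbind(1, 2, 3)), "dimension")

  spec <- mlp_spec()  # 15 hidden layers: six of 256, nine of 128
  expect_length(spec$hidden_dims, 15)
  layers <- gravityflows:::mlp_init(spec, 39L)
  expect_length(layers, 16)  # 15 hidden + scalar output
  dg <- gravityflows:::new_flow_model("DG", "full_39", layers = layers,
                                      spec = spec)
  s <- score(dg, matrix(rnorm(2 * 39), 2))
  expect_length(s, 2)
  expect_true(all(is.finite(s)))

  # all-zero weights: every input scores the same
  zero_layers <- lapply(layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  dg0 <- gravityflows:::new_flow_model("DG", "full_39", layers = zero_layers,
                                       spec = spec)
  expect_equal(diff(range(score(dg0, matrix(rnorm(5 * 39), 5)))), 0)
})

test_that("gravity MLE recovers simulated parameters and matches a grid-search oracle", {
  # 3-location toy against a dense grid search
  set.seed(12)
  masses <- c(x = 5, y = 50, z = 500)
  D <- matrix(c(0, 4, 9, 4, 0, 6, 9, 6, 0), 3, dimnames = list(names(masses), names(masses)))
  truth <- gravity_params(0.7, -1.1, "power")
  p1 <- gravity_probabilities(truth, masses, D["x", ], r_floor = 1)
  y1 <- drop(stats::rmultinom(1, 20000, p1))
  ft <- flow_table(rep("x", 3), names(masses), y1)
  fit <- fit_gravity_mle(ft, masses, D, "power",
                         r_floor = c(x = 1, y = 1, z = 1))
  grid_beta <- as.matrix(expand.grid(b1 = seq(-3, 3, 0.01), b2 = seq(-3, 3, 0.01)))
  X <- cbind(log(masses), log(pmax(D["x", ], 1)))
  S <- grid_beta %*% t(X)
  mx <- pmax(S[, 1], S[, 2], S[, 3])
  lse <- mx + log(exp(S[, 1] - mx) + exp(S[, 2] - mx) + exp(S[, 3] - mx))
  ll <- S %*% y1 - sum(y1) * lse
  best <- grid_beta[which.max(ll), ]
  expect_lt(abs(fit$beta1 - best["b1"]), 0.011)
  expect_lt(abs(fit$beta2 - best["b2"]), 0.011)

  # no distance signal: uniform flows over equal-mass destinations
  ids <- sprintf("u%d", 1:5)
  mu <- stats::setNames(rep(10, 5), ids)
  Du <- abs(outer(1:5, 1:5, "-")) + 1
  dimnames(Du) <- list(ids, ids)
  ftu <- flow_table(rep("u1", 4), ids[-1], rep(25, 4))
  fitu <- fit_gravity_mle(ftu, mu, Du, "power",
                          candidates = list(u1 = ids[-1]))
  expect_lt(abs(fitu$beta2), 1e-4)
})

test_that("expected-flow generation conserves every origin's outflow for all model kinds", {
  cfg <- synthetic_config(n_rois = 4, locations_per_roi = c(5, 7), seed = 31)
  geo <- gen_geography(cfg)
  fl <- gen_flows(geo)
  tess <- geo$tessellation
  flows <- restrict_flows_within_rois(fl$flows, tess)
  feats <- normalize_by_area(geo$features_raw, tess, include_population = FALSE)
  D <- pairwise_distance(tess)
  data <- list(tessellation = tess, features = feats, flows = flows,
               distances = D, roi_ids = tess$grid$roi_id)
  O <- total_outflows(flows, tess$locations$id)
  tc <- training_config(epochs = 5, learning_rate = 1e-3, seed = 2,
                        standardize = "log1p_zscore")
  spec <- mlp_spec(hidden_dims = c(8, 8))
  for (kind in c("G", "NG", "MFG", "DG")) {
    model <- train_flow_model(kind, data, tc, spec = spec)
    gen <- generate_flows(model, data, O, tess$grid$roi_id[1])
    got <- total_outflows(gen)
    expect_equal(got, O[names(got)], tolerance = 1e-12)
  }
  # O_i = 0 origins produce no generated flows
  ids <- tess$locations$id[tess$locations$roi_id == tess$grid$roi_id[1]]
  O2 <- O; O2[ids[1]] <- 0
  m <- train_flow_model("G", data, tc)
  gen2 <- generate_flows(m, data, O2, tess$grid$roi_id[1])
  expect_false(ids[1] %in% gen2$origin)
})

test_that("candidate order does not leak into probabilities", {
  cfg <- synthetic_config(n_rois = 2, locations_per_roi = c(6, 6), seed = 17)
  geo <- gen_geography(cfg)
  fl <- gen_flows(geo)
  tess <- geo$tessellation
  data <- list(tessellation = tess,
               features = normalize_by_area(geo$features_raw, tess,
                                            include_population = FALSE),
               flows = restrict_flows_within_rois(fl$flows, tess),
               distances = pairwise_distance(tess),
               roi_ids = tess$grid$roi_id)
  tc <- training_config(epochs = 3, learning_rate = 1e-3, seed = 2,
                        standardize = "log1p_zscore")
  m <- train_flow_model("DG", data, tc, spec = mlp_spec(hidden_dims = c(8, 8)))
  ids <- tess$locations$id[tess$locations$roi_id == tess$grid$roi_id[1]]
  p <- predict_probabilities(m, ids[1], ids, data)
  perm <- sample(seq_along(ids))
  p2 <- predict_probabilities(m, ids[1], ids[perm], data)
  expect_equal(p2, p[perm])
})

test_that("training loss decreases on synthetic gravity data and NaNs abort", {
  cfg <- synthetic_config(n_rois = 4, locations_per_roi = c(6, 8), seed = 23)
  geo <- gen_geography(cfg)
  fl <- gen_flows(geo)
  tess <- geo$tessellation
  data <- list(tessellation = tess,
               features = normalize_by_area(geo$features_raw, tess,
                                            include_population = FALSE),
               flows = restrict_flows_within_rois(fl$flows, tess),
               distances = pairwise_distance(tess),
               roi_ids = tess$grid$roi_id)
  tc <- training_config(epochs = 40, learning_rate = 1e-3, seed = 6,
                        standardize = "log1p_zscore")
  m <- train_flow_model("DG", data, tc, spec = mlp_spec(hidden_dims = c(16, 16)))
  expect_lt(m$history[length(m$history)], m$history[1])
  expect_length(m$history, 40)
})

test_that("model serialization round-trips scores exactly", {
  cfg <- synthetic_config(n_rois = 2, locations_per_roi = c(5, 5), seed = 41)
  geo <- gen_geography(cfg)
  fl <- gen_flows(geo)
  tess <- geo$tessellation
  data <- list(tessellation = tess,
               features = normalize_by_area(geo$features_raw, tess,
                                            include_population = FALSE),
               flows = restrict_flows_within_rois(fl$flows, tess),
               distances = pairwise_distance(tess),
               roi_ids = tess$grid$roi_id)
  tc <- training_config(epochs = 3, learning_rate = 1e-3, seed = 2,
                        standardize = "log1p_zscore")
  for (kind in c("G", "DG")) {
    m <- train_flow_model(kind, data, tc, spec = mlp_spec(hidden_dims = c(8, 8)))
    path <- withr::local_tempfile(fileext = ".json")
    write_flow_model(m, path)
    m2 <- read_flow_model(path)
    ids <- tess$locations$id[tess$locations$roi_id == tess$grid$roi_id[1]]
    expect_identical(predict_probabilities(m, ids[1], ids, data),
                     predict_probabilities(m2, ids[1], ids, data))
  }
})
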