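# End-to-end experiment protocol: stratified split, training, flow
# generation on test regions, metric aggregation over repeated runs, and the
# leave-one-city-out transferability protocol.

#' Experiment configuration
#'
#' @param tessellation a `tessellation`.
#' @param features_raw raw (unnormalized) feature table.
#' @param flows observed `flow_table` (will be restricted to within-ROI
#'   pairs).
#' @param models character subset of `c("G", "NG", "MFG", "DG")`.
#' @param n_runs number of independent split/train/test repetitions.
#' @param train_fraction fraction of ROIs used for training.
#' @param training a `training_config` (seed field is overridden per run).
#' @param mlp `mlp_spec` used for the network models.
#' @param dg_variant `"full_39"` or `"light_5"` for DG.
#' @param normalize_population area-normalize the population feature along
#'   with the rest (TRUE) or keep raw resident counts (FALSE, the default
#'   here): location area is not itself an input feature, so a density-only
#'   population would leave the gravity mass unidentifiable to the feature
#'   models.
#' @param seed master seed; run r uses `seed + r - 1` for the split and
#'   derived seeds for model initialization.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(tessellation, features_raw, flows,
                              models = c("G", "DG"), n_runs = 5L,
                              train_fraction = 0.5,
                              training = training_config(),
                              mlp = mlp_spec(), dg_variant = "full_39",
                              normalize_population = FALSE, seed = 1L) {
  stopifnot(n_runs >= 1, all(models %in% c("G", "NG", "MFG", "DG")))
  structure(list(tessellation = tessellation, features_raw = features_raw,
                 flows = flows, models = models, n_runs = as.integer(n_runs),
                 train_fraction = train_fraction, training = training,
                 mlp = mlp, dg_variant = dg_variant,
                 normalize_population = isTRUE(normalize_population),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic small hash of a model name for per-model seed offsets
model_seed_offset <- function(kind) {
  sum(utf8ToInt(kind) * seq_along(utf8ToInt(kind))) %% 1000L
}

# Assemble the data list handed to train/generate; `roi_ids` scopes training.
prepare_model_data <- function(tessellation, features_norm, flows, distances,
                               roi_ids) {
  locs <- tessellation$locations
  keep <- locs$roi_id %in% roi_ids
  sub <- tessellation
  sub$locations <- locs[keep, , drop = FALSE]
  sub$grid <- tessellation$grid[tessellation$grid$roi_id %in% roi_ids, , drop = FALSE]
  ids <- sub$locations$id
  list(tessellation = sub,
       features = features_norm[ids, , drop = FALSE],
       flows = flows[flows$origin %in% ids & flows$destination %in% ids, , drop = FALSE],
       distances = distances[ids, ids, drop = FALSE],
       roi_ids = roi_ids)
}

# All within-ROI ordered pairs of the given ROIs (the metric universe).
roi_pair_universe <- function(tessellation, roi_ids, include_self = TRUE) {
  locs <- tessellation$locations
  out <- lapply(roi_ids, function(roi) {
    ids <- locs$id[locs$roi_id == roi]
    if (!length(ids)) return(NULL)
    eg <- expand.grid(origin = ids, destination = ids,
                      stringsAsFactors = FALSE)
    if (!include_self) eg <- eg[eg$origin != eg$destination, ]
    eg
  })
  do.call(rbind, out)
}

#' Run the repeated stratified split/train/generate/evaluate experiment
#'
#' For each run r = 1..n_runs: a stratified population-decile split with seed
#' `seed + r - 1`, each requested model trained on the training ROIs only,
#' flows generated on every test ROI from real outflows, and metrics computed
#' both pooled over all test pairs ("global") and per ROI. Metrics are
#' aggregated as mean and standard deviation across runs; relative
#' improvements use G as baseline when present.
#'
#' @param config an `experiment_config`.
#' @return list of class `experiment_report`: `global` (data frame of
#'   per-model metric means/stds), `per_roi_cpc` (per model: ROI x run
#'   matrix), `deciles` (per model `decile_report`, when >= 10 test ROIs and
#'   G is present), `splits`, `history` (training-loss traces).
#' @export
run_experiment <- function(config) {
  tess <- config$tessellation
  flows <- restrict_flows_within_rois(config$flows, tess)
  features_norm <- normalize_by_area(config$features_raw, tess,
                                     include_population = config$normalize_population)
  distances <- pairwise_distance(tess)
  all_rois <- tess$grid$roi_id
  outflows_all <- total_outflows(flows, tess$locations$id)

  per_roi <- lapply(config$models, function(m)
    matrix(NA_real_, nrow = length(all_rois), ncol = config$n_runs,
           dimnames = list(all_rois, NULL)))
  names(per_roi) <- config$models
  global_rows <- list()
  history <- list()
  splits <- list()

  for (r in seq_len(config$n_runs)) {
    run_seed <- config$seed + r - 1L
    plan <- stratified_split(tess, config$train_fraction, seed = run_seed)
    splits[[r]] <- plan
    train_data <- prepare_model_data(tess, features_norm, flows, distances,
                                     plan$train_roi_ids)
    test_data <- prepare_model_data(tess, features_norm, flows, distances,
                                    plan$test_roi_ids)
    universe <- roi_pair_universe(tess, plan$test_roi_ids,
                                  config$training$include_self)
    real_test <- test_data$flows

    for (kind in config$models) {
      tc <- config$training
      tc$seed <- (run_seed * 1000L + model_seed_offset(kind)) %% 2147483647L
      model <- train_flow_model(kind, train_data, tc,
                                variant = config$dg_variant,
                                spec = config$mlp)
      history[[paste0(kind, "_run", r)]] <- model$history
      gen <- lapply(plan$test_roi_ids, function(roi)
        generate_flows(model, test_data,
                       outflows_all[test_data$tessellation$locations$id], roi))
      gen <- do.call(rbind, gen)
      class(gen) <- c("flow_table", "data.frame")
      ms <- metric_suite(gen, real_test, universe)
      global_rows[[length(global_rows) + 1L]] <-
        data.frame(run = r, model = kind, cpc = ms$cpc, nrmse = ms$nrmse,
                   pearson = ms$pearson, jsd = ms$jsd)
      for (roi in plan$test_roi_ids) {
        locs_roi <- tess$locations$id[tess$locations$roi_id == roi]
        g_roi <- gen[gen$origin %in% locs_roi, , drop = FALSE]
        r_roi <- real_test[real_test$origin %in% locs_roi, , drop = FALSE]
        if (sum(g_roi$flow) + sum(r_roi$flow) > 0)
          per_roi[[kind]][roi, r] <- cpc(as_flow_table(g_roi), as_flow_table(r_roi))
      }
    }
  }

  runs <- do.call(rbind, global_rows)
  agg <- do.call(rbind, lapply(split(runs, runs$model), function(df) {
    data.frame(model = df$model[1],
               cpc_mean = mean(df$cpc), cpc_std = stats::sd(df$cpc),
               nrmse_mean = mean(df$nrmse), pearson_mean = mean(df$pearson),
               jsd_mean = mean(df$jsd))
  }))
  if ("G" %in% config$models)
    agg$improvement_vs_G_pct <- relative_improvement(
      agg$cpc_mean, agg$cpc_mean[agg$model == "G"])
  rownames(agg) <- NULL

  deciles <- NULL
  if ("G" %in% config$models && length(all_rois) >= 10) {
    roi_pops <- stats::setNames(tess$grid$total_population, tess$grid$roi_id)
    deciles <- lapply(setdiff(config$models, "G"), function(kind)
      decile_report(per_roi[[kind]], roi_pops, per_roi[["G"]]))
    names(deciles) <- setdiff(config$models, "G")
  }

  structure(list(global = agg, runs = runs, per_roi_cpc = per_roi,
                 deciles = deciles, splits = splits, history = history,
                 config_seed = config$seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Flow-generation experiment over", length(x$splits), "run(s)\n")
  print(x$global, row.names = FALSE)
  invisible(x)
}

#' Leave-one-city-out transferability protocol
#'
#' One train/test cycle per labelled city: the model is trained on all other
#' cities' regions of interest and evaluated on the held-out city's ROIs.
#' Per-city CPC is reported next to the pooled-training CPC obtained on the
#' same city's ROIs under the stratified protocol, when a stratified report
#' is supplied.
#'
#' @param config an `experiment_config` whose tessellation carries city
#'   labels; `models` should usually be a single kind.
#' @param stratified_report optional `experiment_report` for the difference
#'   column.
#' @return data frame: `city`, `n_rois`, `cpc`, and `cpc_stratified` /
#'   `difference` when a report is given.
#' @export
run_leave_one_city_out <- function(config, stratified_report = NULL) {
  tess <- config$tessellation
  flows <- restrict_flows_within_rois(config$flows, tess)
  features_norm <- normalize_by_area(config$features_raw, tess,
                                     include_population = config$normalize_population)
  distances <- pairwise_distance(tess)
  outflows_all <- total_outflows(flows, tess$locations$id)
  plans <- leave_one_city_out_splits(tess)
  kind <- config$models[1]

  rows <- lapply(names(plans), function(city) {
    plan <- plans[[city]]
    tc <- config$training
    tc$seed <- (config$seed * 1000L + model_seed_offset(kind) +
                  model_seed_offset(city)) %% 2147483647L
    train_data <- prepare_model_data(tess, features_norm, flows, distances,
                                     plan$train_roi_ids)
    test_data <- prepare_model_data(tess, features_norm, flows, distances,
                                    plan$test_roi_ids)
    model <- train_flow_model(kind, train_data, tc,
                              variant = config$dg_variant, spec = config$mlp)
    gen <- do.call(rbind, lapply(plan$test_roi_ids, function(roi)
      generate_flows(model, test_data,
                     outflows_all[test_data$tessellation$locations$id], roi)))
    class(gen) <- c("flow_table", "data.frame")
    value <- cpc(gen, test_data$flows)
    out <- data.frame(city = city, n_rois = length(plan$test_roi_ids),
                      cpc = value, stringsAsFactors = FALSE)
    if (!is.null(stratified_report)) {
      m <- stratified_report$per_roi_cpc[[kind]]
      strat <- mean(m[plan$test_roi_ids, ], na.rm = TRUE)
      out$cpc_stratified <- strat
      out$difference <- value - strat
    }
    out
  })
  do.call(rbind, rows)
}

#' Study defaults for the bundled synthetic experiments
#'
#' The training configuration and network architecture used by the package's
#' synthetic studies (vignette, experiment scripts): 600 epochs of RMSprop
#' (learning rate 5e-4, momentum 0.9), batches of 64 origins, negative
#' sampling cap 512, log1p/z-score input conditioning with decoupled weight
#' decay 15, and a narrow 15-hidden-layer network (six layers of 32, nine of
#' 16). These are deliberate small-data adaptations of the reference recipe;
#' see the methods vignette for the reasoning.
#'
#' @param seed integer seed.
#' @return a `training_config` / `mlp_spec`.
#' @export
study_training_config <- function(seed = 1L) {
  training_config(epochs = 600L, learning_rate = 5e-4, momentum = 0.9,
                  batch_origins = 64L, max_sampled_destinations = 512L,
                  seed = seed, standardize = "log1p_zscore",
                  weight_decay = 15)
}

#' @rdname study_training_config
#' @export
study_mlp_spec <- function() mlp_spec(hidden_dims = c(rep(32L, 6), rep(16L, 9)))
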