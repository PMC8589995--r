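# Flow-evaluation metric suite: Common Part of Commuters (Sorensen-Dice on
# flows), NRMSE, Pearson correlation, Jensen-Shannon divergence, and the
# population-decile experiment summaries.

# Align two flow tables onto their union of pairs (or an explicit universe of
# pairs); missing pairs count as zero.
align_flows <- function(generated, real, universe = NULL) {
  key <- function(ft) paste(ft$origin, ft$destination, sep = "\r")
  if (is.null(universe)) {
    keys <- union(key(generated), key(real))
  } else {
    keys <- paste(universe$origin, universe$destination, sep = "\r")
  }
  g <- stats::setNames(rep(0, length(keys)), keys)
  r <- g
  kg <- key(generated)
  kr <- key(real)
  gg <- tapply(generated$flow, kg, sum)
  rr <- tapply(real$flow, kr, sum)
  g[intersect(names(gg), keys)] <- gg[intersect(names(gg), keys)]
  r[intersect(names(rr), keys)] <- rr[intersect(names(rr), keys)]
  list(generated = unname(g), real = unname(r))
}

#' Common Part of Commuters (CPC)
#'
#' Sorensen-Dice similarity between generated and real flow tables:
#' 2 sum min(yhat, y) / (sum yhat + sum y). 1 for identical tables, 0 for
#' disjoint supports.
#'
#' @param generated,real `flow_table`s over the same location universe
#'   (missing pairs count as zero).
#' @return CPC in \[0, 1\].
#' @export
cpc <- function(generated, real) {
  al <- align_flows(generated, real)
  denom <- sum(al$generated) + sum(al$real)
  if (denom == 0) stop("CPC undefined: both flow tables are all-zero")
  2 * sum(pmin(al$generated, al$real)) / denom
}

#' Check the CPC/accuracy equivalence
#'
#' When per-origin generated totals equal the real totals, CPC equals the
#' fraction of trips assigned to the correct destination. The accuracy side
#' is computed by an explicit trip-level assignment (per origin, matched
#' trips destination by destination), independent of the CPC formula.
#'
#' @param generated,real `flow_table`s; the check applies when per-origin
#'   totals match within `tol`.
#' @param tol tolerance for the outflow-matching precondition and the
#'   equality assertion.
#' @return list with `applicable`, `cpc`, `accuracy`, `equal`.
#' @export
cpc_accuracy_equivalence_check <- function(generated, real, tol = 1e-9) {
  ids <- union(unique(generated$origin), unique(real$origin))
  Og <- total_outflows(generated, ids)
  Or <- total_outflows(real, ids)
  if (any(abs(Og - Or) > tol * pmax(1, Or))) {
    return(list(applicable = FALSE, cpc = NA_real_, accuracy = NA_real_,
                equal = NA))
  }
  # trip-level assignment: per origin, count trips whose predicted
  # destination matches, destination by destination
  correct <- 0
  for (oi in ids) {
    g <- generated[generated$origin == oi, ]
    r <- real[real$origin == oi, ]
    dests <- union(g$destination, r$destination)
    for (d in dests) {
      ng <- sum(g$flow[g$destination == d])
      nr <- sum(r$flow[r$destination == d])
      correct <- correct + min(ng, nr)
    }
  }
  total <- sum(Or)
  acc <- correct / total
  value <- cpc(generated, real)
  list(applicable = TRUE, cpc = value, accuracy = acc,
       equal = abs(value - acc) <= tol)
}

#' Normalized root mean squared error between flow tables
#'
#' RMSE over all pairs of the universe divided by a normalizer of the real
#' flows: their range (default), mean, or standard deviation.
#'
#' @param generated,real `flow_table`s.
#' @param universe optional data frame of `origin`, `destination` pairs
#'   fixing the comparison universe (absent pairs contribute zeros); default
#'   the union of supports.
#' @param normalizer `"range"`, `"mean"` or `"sd"`.
#' @return NRMSE (>= 0).
#' @export
nrmse <- function(generated, real, universe = NULL,
                  normalizer = c("range", "mean", "sd")) {
  normalizer <- match.arg(normalizer)
  al <- align_flows(generated, real, universe)
  norm <- switch(normalizer,
                 range = max(al$real) - min(al$real),
                 mean = mean(al$real),
                 sd = stats::sd(al$real))
  if (!is.finite(norm) || norm == 0) stop("NRMSE normalizer is zero (constant real flows)")
  sqrt(mean((al$generated - al$real)^2)) / norm
}

#' Jensen-Shannon divergence between flow distributions
#'
#' Natural-log JSD between the two normalized distributions, either at the
#' pair level (each origin-destination pair a category; default) or between
#' histograms of flow magnitudes. Symmetric, 0 iff the distributions are
#' equal, at most ln 2.
#'
#' @param generated,real `flow_table`s, each with at least one positive flow.
#' @param mode `"pairs"` or `"magnitude"`.
#' @param breaks histogram breaks for `mode = "magnitude"`.
#' @return JSD in \[0, ln 2\].
#' @export
jsd <- function(generated, real, mode = c("pairs", "magnitude"), breaks = 30) {
  mode <- match.arg(mode)
  if (sum(generated$flow) == 0 || sum(real$flow) == 0)
    stop("JSD undefined for an all-zero flow table")
  if (mode == "pairs") {
    al <- align_flows(generated, real)
    p <- al$generated / sum(al$generated)
    q <- al$real / sum(al$real)
  } else {
    rng <- range(c(generated$flow, real$flow))
    br <- seq(rng[1], rng[2], length.out = breaks + 1)
    p <- graphics::hist(generated$flow, breaks = br, plot = FALSE)$counts
    q <- graphics::hist(real$flow, breaks = br, plot = FALSE)$counts
    p <- p / sum(p)
    q <- q / sum(q)
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Pearson correlation between flow tables
#'
#' Product-moment correlation over all pairs of the universe (zeros
#' included for pairs absent from one table).
#'
#' @inheritParams nrmse
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(generated, real, universe = NULL) {
  al <- align_flows(generated, real, universe)
  if (length(al$real) < 2) stop("Pearson correlation needs at least 2 pairs")
  if (stats::sd(al$real) == 0 || stats::sd(al$generated) == 0)
    stop("Pearson correlation undefined for constant flows")
  stats::cor(al$generated, al$real)
}

#' Population-decile experiment summary
#'
#' Regions of interest are cut into ten population deciles (ranked by
#' population, ties broken by ROI id, remainders to the lowest deciles).
#' Per decile and run, the decile CPC is the mean per-ROI CPC; the report
#' carries the mean and standard deviation over runs and the relative
#' improvement over a baseline model, 100 (CPC_model - CPC_base) / CPC_base.
#'
#' @param per_roi_cpc matrix of per-ROI CPC values (rows = ROIs, rownames set,
#'   columns = runs) for the model.
#' @param roi_populations named vector of ROI total populations.
#' @param baseline_per_roi_cpc matrix like `per_roi_cpc` for the baseline
#'   model (typically G).
#' @return data frame of class `decile_report`: `decile`, `n_rois`,
#'   `cpc_mean`, `cpc_std`, `baseline_cpc_mean`, `improvement_pct`.
#' @export
decile_report <- function(per_roi_cpc, roi_populations, baseline_per_roi_cpc) {
  per_roi_cpc <- as.matrix(per_roi_cpc)
  baseline_per_roi_cpc <- as.matrix(baseline_per_roi_cpc)
  ids <- rownames(per_roi_cpc)
  if (length(ids) < 10) stop("decile report needs at least 10 ROIs")
  dec <- population_deciles(ids, roi_populations[ids])
  out <- lapply(1:10, function(d) {
    members <- ids[dec == d]
    run_means <- colMeans(per_roi_cpc[members, , drop = FALSE], na.rm = TRUE)
    base_means <- colMeans(baseline_per_roi_cpc[members, , drop = FALSE], na.rm = TRUE)
    mb <- mean(base_means)
    data.frame(decile = d, n_rois = length(members),
               cpc_mean = mean(run_means),
               cpc_std = stats::sd(run_means),
               baseline_cpc_mean = mb,
               improvement_pct = if (is.finite(mb) && mb > 0)
                 100 * (mean(run_means) - mb) / mb else NA_real_)
  })
  out <- do.call(rbind, out)
  class(out) <- c("decile_report", "data.frame")
  out
}

#' Relative improvement between two metric values
#'
#' 100 (value - baseline) / baseline, the convention used for model
#' comparisons (e.g. a CPC of 0.32 against a baseline of 0.11 is a ~190%
#' improvement).
#'
#' @param value,baseline metric values; `baseline` must be nonzero.
#' @return percentage improvement.
#' @export
relative_improvement <- function(value, baseline) {
  if (any(baseline == 0)) stop("relative improvement undefined for zero baseline")
  100 * (value - baseline) / baseline
}

# Full metric set for one generated/real pair over a fixed universe.
metric_suite <- function(generated, real, universe = NULL) {
  list(cpc = cpc(generated, real),
       nrmse = nrmse(generated, real, universe),
       pearson = pearson(generated, real, universe),
       jsd = jsd(generated, real))
}
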