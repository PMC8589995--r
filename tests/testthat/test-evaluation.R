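test_that("CPC has the Sorensen-Dice identity, disjoint and scale properties", {
  a <- flow_table(c("A", "A"), c("B", "C"), c(2, 2))
  b <- flow_table(c("A", "A"), c("B", "C"), c(4, 0))
  expect_equal(cpc(a, a), 1)
  expect_equal(cpc(a, b), 0.5)   # 2*min sums: 2*2 / (4 + 4)
  disj <- flow_table("A", "D", 5)
  expect_equal(cpc(a, disj), 0)
  # symmetry and scale invariance on random tables
  set.seed(2)
  for (k in 1:5) {
    fx <- random_matched_flows(letters[1:6])
    expect_equal(cpc(fx$generated, fx$real), cpc(fx$real, fx$generated))
    scaled_g <- flow_table(fx$generated$origin, fx$generated$destination,
                           fx$generated$flow * 3.7)
    scaled_r <- flow_table(fx$real$origin, fx$real$destination,
                           fx$real$flow * 3.7)
    expect_equal(cpc(scaled_g, scaled_r), cpc(fx$generated, fx$real))
  }
  expect_error(cpc(flow_table(), flow_table()), "all-zero")
})

test_that("CPC equals trip-level accuracy when outflows match", {
  set.seed(11)
  for (k in 1:20) {
    fx <- random_matched_flows(sprintf("l%d", 1:8))
    chk <- cpc_accuracy_equivalence_check(fx$generated, fx$real)
    expect_true(chk$applicable)
    expect_true(chk$equal)
    expect_equal(chk$cpc, chk$accuracy, tolerance = 1e-12)
  }
  perfect <- flow_table(c("A", "B"), c("B", "A"), c(3, 4))
  chk <- cpc_accuracy_equivalence_check(perfect, perfect)
  expect_equal(chk$cpc, 1)
  expect_equal(chk$accuracy, 1)
  # deliberately unmatched outflows: not applicable
  off <- flow_table(c("A", "B"), c("B", "A"), c(30, 4))
  chk2 <- cpc_accuracy_equivalence_check(off, perfect)
  expect_false(chk2$applicable)
})

test_that("NRMSE matches its closed forms and a dense oracle", {
  a <- flow_table(c("A", "A", "B"), c("B", "C", "C"), c(1, 5, 9))
  expect_equal(nrmse(a, a), 0)
  # constant offset: |c| / range
  b <- flow_table(a$origin, a$destination, a$flow + 2)
  expect_equal(nrmse(b, a), 2 / (9 - 1))
  expect_equal(nrmse(b, a, normalizer = "mean"), 2 / 5)
  # random sparse pair against a dense computation
  set.seed(4)
  ids <- letters[1:5]
  u <- expand.grid(origin = ids, destination = ids, stringsAsFactors = FALSE)
  g <- flow_table(sample(ids, 8, TRUE), sample(ids, 8, TRUE), rpois(8, 6))
  r <- flow_table(sample(ids, 8, TRUE), sample(ids, 8, TRUE), rpois(8, 6))
  Mg <- matrix(0, 5, 5, dimnames = list(ids, ids))
  Mr <- Mg
  for (i in seq_len(nrow(g))) Mg[g$origin[i], g$destination[i]] <-
      Mg[g$origin[i], g$destination[i]] + g$flow[i]
  for (i in seq_len(nrow(r))) Mr[r$origin[i], r$destination[i]] <-
      Mr[r$origin[i], r$destination[i]] + r$flow[i]
  expect_equal(nrmse(g, r, universe = u),
               sqrt(mean((Mg - Mr)^2)) / (max(Mr) - min(Mr)))
  expect_error(nrmse(a, flow_table(c("A", "B"), c("B", "C"), c(3, 3)),
                     universe = data.frame(origin = c("A", "B"),
                                           destination = c("B", "C"))),
               "normalizer")
})

test_that("JSD is symmetric, bounded by ln 2 and matches the KL-mixture definition", {
  a <- flow_table(c("A", "A"), c("B", "C"), c(2, 6))
  prop <- flow_table(c("A", "A"), c("B", "C"), c(1, 3))   # same distribution
  expect_equal(jsd(a, prop), 0)
  disj <- flow_table(c("A", "A"), c("D", "E"), c(1, 1))
  expect_equal(jsd(a, disj), log(2))
  set.seed(9)
  g <- flow_table(sample(letters[1:4], 6, TRUE), sample(letters[1:4], 6, TRUE),
                  runif(6, 0, 5))
  r <- flow_table(sample(letters[1:4], 6, TRUE), sample(letters[1:4], 6, TRUE),
                  runif(6, 0, 5))
  al <- gravityflows:::align_flows(g, r)
  p <- al$generated / sum(al$generated)
  q <- al$real / sum(al$real)
  m <- (p + q) / 2
  kl <- function(x, y) sum(ifelse(x > 0, x * log(x / y), 0))
  expect_equal(jsd(g, r), 0.5 * kl(p, m) + 0.5 * kl(q, m))
  expect_equal(jsd(g, r), jsd(r, g))
  expect_gte(jsd(g, r), 0)
  expect_lte(jsd(g, r), log(2) + 1e-12)
  expect_error(jsd(flow_table("A", "B", 0), a), "all-zero")
})

test_that("Pearson correlation covers the universe with zeros and hits the +/-1 cases", {
  a <- flow_table(c("A", "A", "B"), c("B", "C", "C"), c(1, 5, 9))
  expect_equal(pearson(a, a), 1)
  neg <- flow_table(a$origin, a$destination, -a$flow + 10)
  expect_equal(pearson(neg, a), -1)
  set.seed(14)
  ids <- letters[1:4]
  u <- expand.grid(origin = ids, destination = ids, stringsAsFactors = FALSE)
  g <- flow_table(sample(ids, 6, TRUE), sample(ids, 6, TRUE), rpois(6, 5) + 1)
  r <- flow_table(sample(ids, 6, TRUE), sample(ids, 6, TRUE), rpois(6, 5) + 1)
  al <- gravityflows:::align_flows(g, r, u)
  expect_equal(pearson(g, r, u), stats::cor(al$generated, al$real))
  expect_error(pearson(flow_table("A", "B", 3),
                       flow_table("A", "B", 3)), "at least 2")
})

test_that("decile reports reproduce the headline relative improvements", {
  ids <- sprintf("r%02d", 1:20)
  pops <- stats::setNames(100 * (1:20), ids)
  model_cpc <- matrix(0.32, 20, 5, dimnames = list(ids, NULL))
  base_cpc <- matrix(0.11, 20, 5, dimnames = list(ids, NULL))
  rep1 <- decile_report(model_cpc, pops, base_cpc)
  expect_equal(nrow(rep1), 10)
  expect_equal(rep1$n_rois, rep(2, 10))
  expect_equal(rep1$improvement_pct, rep(100 * (0.32 - 0.11) / 0.11, 10),
               tolerance = 1e-12)
  expect_equal(round(rep1$improvement_pct[1]), 191)
  rep2 <- decile_report(model_cpc, pops, matrix(0.23, 20, 5, dimnames = list(ids, NULL)))
  expect_equal(round(rep2$improvement_pct[1]), 39)
  rep3 <- decile_report(base_cpc, pops, base_cpc)
  expect_equal(rep3$improvement_pct, rep(0, 10))
  expect_equal(relative_improvement(0.32, 0.11), 100 * 0.21 / 0.11)
})

test_that("decile assignment partitions ROIs into near-equal groups", {
  ids <- sprintf("q%02d", 1:23)
  dec <- gravityflows:::population_deciles(ids, sample(100:999, 23))
  sizes <- table(dec)
  expect_equal(length(sizes), 10L)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 23)
})
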