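# Random-forest attribution: design assembly, forest fitting, permutation
# importance and subsampling confidence intervals.

make_xy_table <- function(n = 34, seed = 1, signal = TRUE) {
  set.seed(seed)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  X$area_ha <- if (signal) 10 + 5 * X$x1 + rnorm(n, 0, 0.5) else rnorm(n)
  X
}

test_that("assemble_design joins watershed-years and truncates regions", {
  b <- fixture_bundle(seed = 6, grid = 32)
  res <- run_pipeline(b)
  tb <- suppressMessages(assemble_design(res$water, b$climate, res$human,
                                         "snowmelt", "lake"))
  expect_s3_class(tb, "model_table")
  expect_equal(nrow(tb), 34)           # 35 years minus the 2012 gap
  expect_false(2012 %in% tb$year)
  expect_true(all(c("ET", "PR", "RO", "SWE", "irrigated_frac",
                    "density_km2") %in% names(tb)))
  bm <- fixture_bundle(seed = 6, regime = "monsoonal", grid = 32)
  tbm <- suppressMessages(truth_design(bm, "lake"))
  expect_equal(max(tbm$year), 2017)    # monsoonal record ends 2017
  expect_equal(nrow(tbm), 33)
  hbad <- res$human; hbad$watershed <- "other"
  expect_error(assemble_design(res$water, b$climate, hbad, "snowmelt"),
               "mismatched watershed")
})

test_that("fit_forest learns signal, ignores noise, and is deterministic", {
  tb <- make_xy_table(seed = 2, signal = TRUE)
  f <- fit_forest(tb, n_trees = 500, predictors = c("x1", "x2", "x3"),
                  seed = 1)
  expect_gt(f$oob_r2, 0.5)
  fn <- fit_forest(make_xy_table(seed = 3, signal = FALSE), n_trees = 500,
                   predictors = c("x1", "x2", "x3"), seed = 1)
  expect_lte(fn$oob_r2, 0.1)
  f2 <- fit_forest(tb, n_trees = 500, predictors = c("x1", "x2", "x3"),
                   seed = 1)
  expect_identical(f$oob_pred, f2$oob_pred)
  # predictions reproduce OOB-style fits on training rows
  expect_equal(length(predict(f, tb)), nrow(tb))
})

test_that("permutation VIMP separates signal from noise", {
  tb <- make_xy_table(n = 60, seed = 4, signal = TRUE)
  f <- fit_forest(tb, n_trees = 1000, predictors = c("x1", "x2", "x3"),
                  seed = 2)
  v <- permutation_vimp(f)
  expect_equal(v$predictor[v$rank == 1], "x1")
  expect_gt(v$vimp[v$predictor == "x1"], v$vimp[v$predictor == "x2"])
  # null property: noise importance within 2 tree-level SEs of zero
  for (p in c("x2", "x3"))
    expect_lt(abs(v$vimp[v$predictor == p]),
              2 * v$se_trees[v$predictor == p] +
                0.05 * v$vimp[v$predictor == "x1"])
  # duplicating the response as a predictor puts it first
  tb2 <- tb; tb2$leak <- tb$area_ha
  f2 <- fit_forest(tb2, n_trees = 500,
                   predictors = c("x1", "x2", "x3", "leak"), seed = 3)
  v2 <- permutation_vimp(f2)
  expect_equal(v2$predictor[v2$rank == 1], "leak")
  # same seed -> identical importances
  expect_identical(permutation_vimp(f, seed = 9)$vimp,
                   permutation_vimp(f, seed = 9)$vimp)
})

test_that("subsampling CIs cover zero for noise and exclude it for signal", {
  tb <- make_xy_table(n = 60, seed = 5, signal = TRUE)
  expect_warning(
    ci_small <- vimp_confidence(tb, B = 20, n_trees = 200,
                                n_trees_sub = 100, seed = 1,
                                predictors = c("x1", "x2", "x3")),
    "B < 50")
  ci <- vimp_confidence(tb, B = 100, n_trees = 500, n_trees_sub = 200,
                        seed = 1, predictors = c("x1", "x2", "x3"))
  expect_gt(ci$lower[ci$predictor == "x1"], 0)
  expect_true(ci$lower[ci$predictor == "x2"] <= 0 &&
                ci$upper[ci$predictor == "x2"] >= 0)
  expect_true(all(ci$lower <= ci$vimp & ci$vimp <= ci$upper))
  ci2 <- vimp_confidence(tb, B = 100, n_trees = 500, n_trees_sub = 200,
                         seed = 1, predictors = c("x1", "x2", "x3"))
  expect_identical(ci$lower, ci2$lower)
})

test_that("irrigation-coupled wetland response ranks irrigation first", {
  hits <- 0
  for (s in 1:10) {
    b <- fixture_bundle(seed = 300 + s, grid = 32)
    tb <- suppressMessages(truth_design(b, "wetland"))
    v <- permutation_vimp(fit_forest(tb, n_trees = 500, seed = s))
    hits <- hits + (v$predictor[v$rank == 1] == "irrigated_frac")
  }
  expect_gte(hits, 9)
})

test_that("zero-variance SWE carries no importance in monsoonal forests", {
  # SWE forced to exactly zero variance: no tree can split on it, so its
  # permutation importance is identically zero and every predictor with
  # positive importance out-ranks it
  b <- fixture_bundle(seed = 17, regime = "monsoonal", grid = 32)
  tb <- suppressMessages(truth_design(b, "lake"))
  expect_lt(sd(tb$SWE), 1)   # mm: snow is essentially absent as generated
  tb$SWE <- 0
  v <- permutation_vimp(fit_forest(tb, n_trees = 1000, seed = 4))
  swe <- v[v$predictor == "SWE", ]
  expect_identical(swe$vimp, 0)
  expect_true(all(v$rank[v$vimp > 0] < swe$rank))
  # in the stated monsoonal world (near-zero, not exactly zero, variance)
  # SWE sits in the bottom half of the ranking on average; single fits
  # are noise-dominated because monsoonal lake area is mostly interannual
  # variability
  rk <- vapply(1:16, function(s) {
    bs <- fixture_bundle(seed = s, regime = "monsoonal", grid = 32)
    ts <- suppressMessages(truth_design(bs, "lake"))
    vs <- permutation_vimp(fit_forest(ts, n_trees = 1000, seed = s))
    vs$rank[vs$predictor == "SWE"]
  }, numeric(1))
  expect_gt(mean(rk), 3)
})

test_that("an added irrelevant predictor leaves importances stable", {
  b <- fixture_bundle(seed = 21, grid = 32)
  tb <- suppressMessages(truth_design(b, "wetland"))
  ci <- vimp_confidence(tb, B = 60, n_trees = 500, n_trees_sub = 200,
                        seed = 2)
  tb2 <- tb
  set.seed(99); tb2$junk <- rnorm(nrow(tb2))
  ci2 <- vimp_confidence(tb2, B = 60, n_trees = 500, n_trees_sub = 200,
                         seed = 2,
                         predictors = c(ci$predictor, "junk"))
  for (p in ci$predictor) {
    a <- ci$vimp[ci$predictor == p]
    bb <- ci2$vimp[ci2$predictor == p]
    hw <- (ci$upper[ci$predictor == p] - ci$lower[ci$predictor == p]) / 2
    expect_lt(abs(a - bb), max(2 * hw, 0.1 * max(abs(ci$vimp))))
  }
})

test_that("rank_predictors standardizes and orders across watersheds", {
  vs <- lapply(1:4, function(s) {
    b <- fixture_bundle(seed = 400 + s, grid = 32)
    tb <- suppressMessages(truth_design(b, "wetland"))
    permutation_vimp(fit_forest(tb, n_trees = 500, seed = s))
  })
  single <- rank_predictors(vs[[1]])
  expect_equal(single$predictor[1], vs[[1]]$predictor[vs[[1]]$rank == 1])
  multi <- rank_predictors(vs)
  expect_equal(multi$predictor[1], "irrigated_frac")
  expect_true(all(multi$median <= 1 + 1e-12))
  expect_true(all(diff(multi$median) <= 1e-12))
})
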