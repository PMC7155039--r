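# Two-period change statistics.

test_that("percent_change reproduces printed-table arithmetic", {
  expect_identical(percent_change(700109, 509184), -27L)  # snowmelt lakes
  expect_identical(percent_change(3216, 3448), 7L)        # monsoonal wetlands
  expect_identical(percent_change(100, 100), 0L)
  # half-away-from-zero rounding, both signs
  expect_identical(percent_change(100, 100.5), 1L)
  expect_identical(percent_change(100, 99.5), -1L)
  expect_error(percent_change(0, 5), "zero baseline")
  # sign consistency property
  set.seed(1)
  for (i in 1:50) {
    m1 <- runif(1, 1, 100); m2 <- runif(1, 1, 100)
    pc <- percent_change(m1, m2)
    expect_true(sign(pc) == sign(m2 - m1) || pc == 0)
  }
})

test_that("wilcoxon exact path matches direct enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)        # 2 * 1/20 over all C(6,3) labelings
  expect_equal(r$method, "exact")
  expect_equal(wilcoxon_rank_sum(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
  # seeded no-tie samples across sizes, against the combn oracle
  set.seed(33)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p and handles ties", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.3)
    pe <- wilcoxon_rank_sum(x, y, exact_max = 10)
    pa <- wilcoxon_rank_sum(x, y, exact_max = 0)
    expect_equal(pe$method, "exact"); expect_equal(pa$method, "normal")
    expect_lt(abs(pe$p - pa$p), 0.02)
    # and the approximation agrees with the reference implementation
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(pa$p, ref$p.value, tolerance = 1e-9)
    expect_equal(pa$U, unname(ref$statistic))
  }
  xt <- c(1, 2, 2, 3, 5); yt <- c(2, 3, 3, 4, 6)
  rt <- wilcoxon_rank_sum(xt, yt)
  expect_equal(rt$method, "normal")  # ties force the approximation
  ref <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE))
  expect_equal(rt$p, ref$p.value, tolerance = 1e-9)
})

test_that("linear_trend handles exact, degenerate and noisy inputs", {
  yrs <- 1984:2018
  tr <- linear_trend(yrs, 2 * yrs + 1)
  expect_equal(tr$slope, 2, tolerance = 1e-9)
  expect_lt(tr$p, 1e-12)
  trc <- linear_trend(yrs, rep(5, 35))
  expect_equal(trc$slope, 0)
  expect_true(is.nan(trc$p)); expect_true(trc$degenerate)
  expect_error(linear_trend(rep(2000, 5), 1:5), "identical")
  # seeded noisy line: estimate within +/- 3 SE of the true slope
  set.seed(5)
  v <- -3 * (1:34) + rnorm(34, 0, 1)
  trn <- linear_trend(1:34, v)
  expect_lt(abs(trn$slope - (-3)), 3 * trn$se)
  # reference check against lm()
  fit <- summary(lm(v ~ x, data.frame(x = 1:34)))$coefficients
  expect_equal(trn$slope, fit[2, 1], tolerance = 1e-12)
  expect_equal(trn$se, fit[2, 2], tolerance = 1e-12)
  expect_equal(trn$p, fit[2, 4], tolerance = 1e-12)
})

test_that("period_summary populates all fields and respects the 2012 gap", {
  pd <- period_definition()
  expect_equal(length(pd$P1), 16)
  expect_equal(length(pd$P2), 18)
  yrs <- c(pd$P1, 2000:2018)
  vals <- c(rep(10, 16), rep(5, 19))
  vals[yrs == 2012] <- NA  # satellite gap
  s <- period_summary(yrs, vals)
  expect_equal(s$n1, 16); expect_equal(s$n2, 18)
  expect_equal(s$change, -5); expect_identical(s$pct, -50L)
  expect_equal(s$sd1, 0)
  # printed regional means as constant inputs reproduce the printed -27%
  s2 <- period_summary(yrs, ifelse(yrs <= 1999, 700109, 509184))
  expect_identical(s2$pct, -27L)
  expect_error(period_summary(c(1984, 2000:2018),
                              c(1, rnorm(19))), "at least 2")
})

test_that("change vectors are zero for identical periods and scale-free", {
  set.seed(3)
  # identical distributions in both periods -> zero vector
  pd16 <- period_definition(1984:1999, 2000:2015)
  base <- runif(16, 10, 20)
  cv0 <- change_vector(c(pd16$P1, pd16$P2), c(base, base), pd16)
  expect_equal(cv0$dmean, 0, tolerance = 1e-12)
  expect_equal(cv0$dvar, 0, tolerance = 1e-12)
  expect_equal(cv0$magnitude, 0, tolerance = 1e-12)
  pd <- period_definition()
  yrs <- c(pd$P1, pd$P2)
  # hand case: proportions 0.6 then 0.4 of the record max
  v <- c(rep(60, 16), rep(40, 17), 100)
  cv <- change_vector(yrs, v, pd)
  expect_equal(cv$mean1, 0.6)
  expect_equal(cv$dmean, (mean(c(rep(0.4, 17), 1)) - 0.6))
  # variance-axis-only case: equal means, wider P2
  v2 <- c(rep(c(4, 6), 8), rep(c(2, 8), 8), 5, 5)
  cv2 <- change_vector(yrs, v2, pd)
  expect_equal(cv2$dmean, 0, tolerance = 1e-12)
  expect_gt(cv2$dvar, 0)
  expect_equal(cv2$direction, pi / 2, tolerance = 1e-9)
  # scale invariance
  v3 <- abs(rnorm(34)) + 1
  a <- change_vector(yrs, v3, pd); bb <- change_vector(yrs, 1000 * v3, pd)
  expect_equal(a$dmean, bb$dmean, tolerance = 1e-12)
  expect_equal(a$dvar, bb$dvar, tolerance = 1e-12)
  expect_error(change_vector(yrs, rep(0, 34), pd), "maximum")
})

test_that("regional_rollup pools sums and counts significance", {
  pd <- period_definition()
  yrs <- c(pd$P1, pd$P2)
  mk <- function(m1, m2, region) {
    set.seed(m1)
    period_summary(yrs, ifelse(yrs <= 1999, m1, m2) + rnorm(34, 0, 1e-6),
                   pd, watershed = paste0("w", m1), region = region,
                   variable = "lake_ha")
  }
  one <- regional_rollup(list(mk(100, 80, "snowmelt")))
  expect_equal(one$pct, -20L)
  expect_equal(one$n_watersheds, 1)
  # equal bases -20% and -40% pool to -30%
  two <- regional_rollup(list(mk(100, 80, "snowmelt"),
                              mk(101, 60.6, "snowmelt")))
  expect_identical(two$pct[two$region == "snowmelt"], -30L)
  bad <- list(mk(100, 80, "snowmelt"), mk(50, 40, "snowmelt"))
  bad[[2]]$variable <- "ET_mm"
  expect_error(regional_rollup(bad), "mixed")
})

test_that("a declining snowmelt ensemble is significant in every watershed", {
  pd <- period_definition()
  summaries <- lapply(1:18, function(s) {
    b <- fixture_bundle(seed = 100 + s, grid = 32)
    la <- b$truth_areas[b$truth_areas$class == "lake", ]
    period_summary(la$year, la$area_ha, pd, watershed = s,
                   region = "snowmelt", variable = "lake_ha")
  })
  roll <- regional_rollup(summaries)
  expect_equal(roll$n_watersheds, 18)
  expect_equal(roll$n_wilcox_sig, 18)
  expect_equal(roll$n_trend_sig, 18)
  expect_lt(roll$pct, 0)
})
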