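# Polygon rasterization, area accounting, irrigation mapping and
# population splines.

test_that("rasterize_polygons labels by pixel-center containment", {
  set <- polygon_set(list(ew_rect(0, 0, 4, 4, "lake", id = "L")))
  lab <- rasterize_polygons(set, 4, 4)
  expect_true(all(lab == "lake"))
  # boundary pixel centers: rect edge passing exactly through centers
  set2 <- polygon_set(list(ew_rect(0.5, 0.5, 2.5, 2.5, "wetland")))
  lab2 <- rasterize_polygons(set2, 4, 4)
  expect_equal(sum(lab2 == "wetland", na.rm = TRUE), 9)  # 3x3 inclusive
  # overlapping lake and excluded: excluded wins regardless of order
  set3 <- polygon_set(list(ew_rect(0, 0, 2, 4, "excluded",
                                   subtype = "reservoir"),
                           ew_rect(0, 0, 4, 4, "lake")))
  lab3 <- rasterize_polygons(set3, 4, 4)
  expect_true(all(lab3[, 1:2] == "excluded"))
  expect_true(all(lab3[, 3:4] == "lake"))
  expect_error(rasterize_polygons(set3, 4, 4, frame = "utm"),
               "frame mismatch")
})

fm_from <- function(w, valid = NULL, pixel_area = 900) {
  d <- dim(w)
  fr <- array(0, c(d, 4), dimnames = list(NULL, NULL, EW_ENDMEMBERS))
  fr[, , 1] <- w
  if (is.null(valid)) valid <- !is.na(w)
  structure(list(fractions = fr, rmse = w * 0, valid = valid,
                 classes = EW_ENDMEMBERS, pixel_area = pixel_area),
            class = "fraction_map")
}

test_that("water_area applies the inclusive 10% full-pixel rule", {
  w <- matrix(c(0.05, 1.00, 0.20, 0.00), 2, 2)  # column-major 2x2
  lab <- matrix("lake", 2, 2)
  a <- water_area(fm_from(w), lab)
  expect_equal(unname(a["lake"]), 0.18)  # two pixels >= 0.10 -> 1800 m2
  expect_equal(unname(water_area(fm_from(w * 0), lab)["lake"]), 0)
  # exact threshold counts (inclusive)
  w2 <- matrix(c(0.10, 0, 0, 0), 2, 2)
  expect_equal(unname(water_area(fm_from(w2), lab)["lake"]), 0.09)
  # excluded and unlabeled pixels contribute nothing
  lab2 <- matrix(c("lake", "excluded", NA, "lake"), 2, 2)
  expect_equal(unname(water_area(fm_from(w), lab2)["lake"]), 0)
  expect_error(water_area(fm_from(w), matrix("lake", 3, 3)), "misaligned")
})

test_that("class areas are monotone in threshold and additive over partitions", {
  set.seed(8)
  w <- matrix(runif(100), 10, 10)
  lab <- matrix("wetland", 10, 10)
  fm <- fm_from(w)
  areas <- vapply(c(0.05, 0.1, 0.3, 0.6, 0.9),
                  function(th) water_area(fm, lab, threshold = th)["wetland"],
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  # partition the polygon into two halves: areas add up
  labL <- lab; labL[, 6:10] <- NA
  labR <- lab; labR[, 1:5] <- NA
  expect_equal(water_area(fm, labL)["wetland"] +
                 water_area(fm, labR)["wetland"],
               water_area(fm, lab)["wetland"])
})

test_that("max_ndvi_composite takes the per-pixel max over unmasked obs", {
  lo <- fixture_image(matrix(0.1, 2, 2), red = matrix(0.2, 2, 2),
                      nir = matrix(0.3, 2, 2), date = "1990-06-01")
  hi <- fixture_image(matrix(0.1, 2, 2), red = matrix(0.05, 2, 2),
                      nir = matrix(0.45, 2, 2), date = "1990-08-01")
  solo <- max_ndvi_composite(list(lo))
  expect_equal(solo$values, compute_index(lo, "ndvi")$values)
  both <- max_ndvi_composite(list(lo, hi))
  expect_equal(both$values[1, 1], 0.8, tolerance = 1e-12)
  # cloud in the higher-NDVI image: lower value returned there
  hi_cl <- hi; hi_cl$qa[1, 1] <- 1L
  part <- max_ndvi_composite(list(lo, hi_cl))
  expect_equal(part$values[1, 1], 0.2, tolerance = 1e-12)
  expect_equal(part$values[2, 2], 0.8, tolerance = 1e-12)
  # December image is outside the Feb-Nov growing window
  expect_error(max_ndvi_composite(list(fixture_image(matrix(0.1, 2, 2),
                                                     date = "1990-12-15"))),
               "window")
})

test_that("irrigated_area uses a strict NDVI cut within field polygons", {
  nd <- structure(list(values = matrix(c(0.39, 0.40, 0.41, 0.90), 2, 2),
                       kind = "ndvi", valid = matrix(TRUE, 2, 2)),
                  class = "index_grid")
  lab <- matrix(c("field", "field", "field", NA), 2, 2)
  expect_equal(irrigated_area(nd, lab), 0.09)   # only 0.41 passes > 0.4
  expect_equal(irrigated_area(nd, matrix(NA_character_, 2, 2)), 0)
  expect_error(irrigated_area(nd, matrix("field", 3, 3)), "misaligned")
})

test_that("population spline interpolates anchors and extends the terminal cubic", {
  anchors <- c("1975" = 100, "1990" = 130, "2000" = 160, "2015" = 190)
  ps <- population_series(anchors, 1975:2018, watershed_area_km2 = 10)
  # anchors reproduced exactly
  expect_equal(ps$population[ps$year %in% c(1975, 1990, 2000, 2015)],
               unname(anchors), tolerance = 1e-9)
  # midpoint of the symmetric anchor pattern: 145 (the anchors are
  # mirror-symmetric about 1995, and so is the natural spline)
  expect_equal(ps$population[ps$year == 1995], 145, tolerance = 1e-6)
  # truly collinear anchors: the spline is the line everywhere, including
  # the extrapolated tail
  lin <- c("1975" = 100, "1990" = 145, "2000" = 175, "2015" = 220)
  psl <- population_series(lin, 1975:2018, watershed_area_km2 = 10)
  expect_equal(psl$population, 100 + 3 * (1975:2018 - 1975),
               tolerance = 1e-9)
  # extrapolation continues the terminal cubic: fitting a cubic through
  # four interior points of the last piece predicts the 2016-2018 values
  yc <- c(2003, 2007, 2011, 2015) - 2000   # centered: raw cubic in
  co <- coef(lm(p ~ poly(y, 3, raw = TRUE), # calendar years is singular
                data.frame(y = yc,
                           p = ps$population[ps$year %in% (yc + 2000)])))
  ye <- 2016:2018 - 2000
  pred <- drop(cbind(1, ye, ye^2, ye^3) %*% co)
  expect_equal(ps$population[ps$year %in% 2016:2018], pred,
               tolerance = 1e-6)
  expect_equal(ps$density_km2, ps$population / 10)
  # interior evaluation matches the reference natural spline
  a2 <- c("1975" = 100, "1990" = 180, "2000" = 150, "2015" = 260)
  ps2 <- population_series(a2, 1976:2014, watershed_area_km2 = 1)
  ref <- spline(as.numeric(names(a2)), a2, method = "natural",
                xout = 1976:2014)$y
  expect_equal(ps2$population, ref, tolerance = 1e-9)
  expect_error(population_series(a2[c(2, 1, 3, 4)], 1975:2018, 10),
               "ordered")
  expect_error(population_series(c(a2, "2015" = 5), 1975:2018, 10))
})

test_that("build_series flags the 2012 gap and bounds irrigated fraction", {
  b <- fixture_bundle(seed = 9, grid = 32)
  res <- run_pipeline(b)
  w <- res$water
  expect_true(all(w$missing[w$year == 2012]))
  expect_true(all(is.na(w$area_ha[w$year == 2012])))
  expect_equal(sum(!w$missing[w$class == "lake"]), 34)
  h <- res$human
  expect_true(all(h$irrigated_frac >= 0 & h$irrigated_frac <= 1,
                  na.rm = TRUE))
  expect_error(build_series("x", "snowmelt",
                            list("1990" = c(lake = 1), "1990" = c(lake = 2)),
                            c("1990" = 1), res$human[, c("year", "population",
                                                         "density_km2")],
                            years = 1990, watershed_area_ha = 10),
               "duplicate")
})

test_that("pipeline on a noiseless small bundle reproduces truth exactly", {
  b <- fixture_bundle(seed = 12, grid = 32)
  res <- run_pipeline(b)
  m <- merge(res$water, b$truth_areas,
             by = c("watershed", "region", "year", "class"),
             suffixes = c("_est", "_truth"))
  expect_equal(m$area_ha_est, m$area_ha_truth, tolerance = 1e-12)
  hm <- merge(res$human, b$human_truth, by = "year",
              suffixes = c("_est", "_truth"))
  expect_equal(hm$irrigated_ha_est, hm$irrigated_ha_truth,
               tolerance = 1e-12)
})
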