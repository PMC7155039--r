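# Synthetic endorheic watershed generator. Emulates the statistical
# structure the analysis assumes — a 35-year annual scene record
# (1984-2018, 2012 absent) over a 64 x 64 grid of 30 m pixels holding a
# terminal lake on an alkali playa, fringing (peripheral) wetlands,
# seasonally flooded wetlands, irrigated fields and an excluded reservoir —
# so that every downstream stage can be verified offline against known
# truth. Two regimes are stated: snowmelt (strong linear lake decline,
# modest interannual variance, snow-fed climate) and monsoonal (stable
# long-term mean, high interannual variance, SWE near zero).

#' Regime parameters for the synthetic watershed
#'
#' Defaults are the stated world of the generator. Lake truth proportion
#' follows `p_t = clamp(p0 + lake_trend * t + coupling . z_t + eps_t)`
#' with `eps_t` AR(1) Gaussian (`ar1 = 0` by default) and `z_t` the
#' standardized predictor series; wetland truth responds to irrigation
#' through its own coupling. Climate means/trends/SDs echo the regional
#' magnitudes of the study area (mm units): snowmelt ET drifts upward,
#' monsoonal SWE is essentially zero.
#'
#' @param regime "snowmelt" or "monsoonal"
#' @param n_years record length (>= 4; default 35, calendar 1984-2018)
#' @param grid grid side in pixels (default 64)
#' @param p0 baseline lake proportion of maximum extent
#' @param lake_trend fraction-of-max change per year
#' @param interannual_sd SD of the lake AR(1) innovation
#'   (fraction-of-max)
#' @param ar1 lake-noise autocorrelation (default 0)
#' @param cloud_fraction i.i.d. per-pixel cloud rate in \[0, 1)
#' @param noise_sd additive Gaussian reflectance noise SD
#' @param coupling named effect sizes (fraction-of-max per predictor SD)
#'   for the lake response; names among ET, PR, RO, SWE, irrigation,
#'   population
#' @param wetland_coupling same, for the wetland response
#' @param seed integer RNG seed; a fixed seed gives byte-identical bundles
#' @param watershed watershed id tag
#' @return a `regime_params` list
#' @export
regime_params <- function(regime = c("snowmelt", "monsoonal"),
                          n_years = 35, grid = 64,
                          p0 = NULL, lake_trend = NULL,
                          interannual_sd = NULL, ar1 = 0,
                          cloud_fraction = 0.05, noise_sd = 0.01,
                          coupling = NULL, wetland_coupling = NULL,
                          seed = 1, watershed = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_years >= 4, cloud_fraction >= 0, cloud_fraction < 1,
            noise_sd >= 0, abs(ar1) < 1)
  snow <- regime == "snowmelt"
  if (is.null(p0)) p0 <- if (snow) 0.85 else 0.50
  if (is.null(lake_trend)) lake_trend <- if (snow) -0.010 else 0
  if (is.null(interannual_sd)) interannual_sd <- if (snow) 0.04 else 0.18
  if (is.null(coupling))
    coupling <- if (snow)
      c(irrigation = -0.12, ET = -0.02, PR = 0.02, RO = 0.02, SWE = 0.02,
        population = -0.01)
    else
      c(irrigation = -0.03, ET = -0.03, PR = 0.08, RO = 0.05, SWE = 0,
        population = 0.01)
  if (is.null(wetland_coupling))
    wetland_coupling <- c(irrigation = if (snow) 0.12 else 0.08)
  # climate nominal mean / linear trend (per year) / interannual SD, in mm
  climate <- if (snow) list(
    ET = c(1110, 1.8, 45), PR = c(376, -1.0, 95),
    RO = c(104, -0.7, 55), SWE = c(310, -1.3, 140))
  else list(
    ET = c(1615, 0.6, 45), PR = c(420, 0.0, 90),
    RO = c(26, 0.0, 13), SWE = c(0.12, 0.0, 0.10))
  irrigation <- if (snow) c(0.10, 5e-4, 0.010) else c(0.08, 1e-3, 0.010)
  structure(list(regime = regime, n_years = n_years, grid = grid,
                 years = 1984:(1984 + n_years - 1), missing_years = 2012,
                 p0 = p0, lake_trend = lake_trend,
                 interannual_sd = interannual_sd, ar1 = ar1,
                 cloud_fraction = cloud_fraction, noise_sd = noise_sd,
                 coupling = coupling, wetland_coupling = wetland_coupling,
                 w0 = 0.5, wetland_sd = 0.05,
                 climate = climate, irrigation = irrigation,
                 seed = as.integer(seed),
                 watershed = if (is.null(watershed))
                   paste0(regime, "_1") else watershed),
            class = "regime_params")
}

# canonical 6-band shapes; interpolated when n_bands differs
EW_BASE_SPECTRA <- rbind(
  water              = c(0.06, 0.08, 0.06, 0.03, 0.010, 0.005),
  wetland_vegetation = c(0.04, 0.07, 0.05, 0.45, 0.220, 0.100),
  upland             = c(0.10, 0.14, 0.18, 0.26, 0.300, 0.280),
  alkali_soil        = c(0.30, 0.38, 0.45, 0.50, 0.550, 0.520))

#' Generate a plausible endmember library
#'
#' Four spectra in \[0, 1\] with field-typical shapes (water dark in the
#' NIR/SWIR, vegetation bright in the NIR, alkali soil bright throughout),
#' seeded with small uniform jitter so different seeds give different
#' libraries.
#'
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @param n_bands number of bands (>= 4; 6 gives the standard
#'   blue/green/red/nir/swir1/swir2 set)
#' @return an `endmember_library`
#' @export
make_library <- function(seed = 1, n_bands = 6) {
  stopifnot(n_bands >= 4)
  if (!is.null(seed)) set.seed(seed)
  base <- t(apply(EW_BASE_SPECTRA, 1, function(s)
    approx(seq_len(6), s, xout = seq(1, 6, length.out = n_bands))$y))
  jit <- matrix(runif(4 * n_bands, -0.01, 0.01), 4, n_bands)
  spectra <- pmin(pmax(base + jit, 0), 1)
  colnames(spectra) <- if (n_bands <= 6) EW_BANDS[seq_len(n_bands)]
                       else c(EW_BANDS, paste0("b", 7:n_bands))
  endmember_library(spectra, provenance = rep("synthetic", 4))
}

#' Render a scene from truth fractions under the linear mixing model
#'
#' Pixel reflectance is the fraction-weighted sum of the endmember spectra
#' plus additive Gaussian noise (clipped at 0); pixels are QA-flagged
#' cloud independently at rate `cloud_fraction`.
#'
#' @param truth_fractions nrow x ncol x 4 array; each pixel's 4-vector
#'   must be non-negative and sum to 1
#' @param library an `endmember_library`
#' @param noise_sd Gaussian noise SD in reflectance units
#' @param cloud_fraction Bernoulli cloud rate per pixel
#' @param seed integer seed; `NULL` uses the current stream
#' @param date scene date
#' @param pixel_area m^2 per pixel (default 900)
#' @return a `spectral_image`
#' @export
render_scene <- function(truth_fractions, library, noise_sd = 0,
                         cloud_fraction = 0, seed = NULL, date = NULL,
                         pixel_area = 900) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(truth_fractions)
  stopifnot(length(d) == 3, d[3] == 4)
  F <- matrix(truth_fractions, d[1] * d[2], 4)
  if (any(F < -1e-12) || any(abs(rowSums(F) - 1) > 1e-9))
    stop("truth fraction vectors must be non-negative and sum to 1")
  R <- F %*% library$spectra  # (pixels x 4) %*% (4 x bands)
  if (noise_sd > 0)
    R <- R + matrix(rnorm(length(R), 0, noise_sd), nrow(R), ncol(R))
  R <- pmax(R, 0)
  bands <- lapply(seq_len(ncol(R)), function(j) matrix(R[, j], d[1], d[2]))
  names(bands) <- library$bands
  qa <- matrix(EW_QA_VALID, d[1], d[2])
  if (cloud_fraction > 0)
    qa[runif(d[1] * d[2]) < cloud_fraction] <- 1L
  spectral_image(bands, qa = qa, date = date, pixel_area = pixel_area)
}

# fixed scene layout on a g x g grid (pixel-unit coordinates)
watershed_layout <- function(g = 64) {
  s <- g / 64  # scale factor for non-default grids
  lake <- ew_circle(32 * s, 32 * s, 14 * s, "lake", id = "lake1")
  periph <- ew_polygon(list(
    cbind(32 * s + 17.5 * s * cos(seq(0, 2 * pi, length.out = 65)[-65]),
          32 * s + 17.5 * s * sin(seq(0, 2 * pi, length.out = 65)[-65])),
    cbind(32 * s + 15.5 * s * cos(seq(0, 2 * pi, length.out = 65)[-65]),
          32 * s + 15.5 * s * sin(seq(0, 2 * pi, length.out = 65)[-65]))),
    "peripheral_wetland", id = "periph1")
  wet1 <- ew_rect(4 * s, 4 * s, 20 * s, 16 * s, "wetland", id = "wet1")
  wet2 <- ew_rect(44 * s, 4 * s, 60 * s, 14 * s, "wetland", id = "wet2")
  field <- ew_rect(4 * s, 44 * s, 34 * s, 62 * s, "field", id = "field1")
  res <- ew_rect(40 * s, 44 * s, 46 * s, 50 * s, "excluded", id = "res1",
                 subtype = "reservoir")
  upland_plot <- ew_rect(50 * s, 30 * s, 56 * s, 36 * s, "plot",
                         id = "upland_plot")
  alkali_flat <- ew_rect(4 * s, 24 * s, 12 * s, 34 * s, "plot",
                         id = "alkali_flat")
  alkali_plot <- ew_rect(6 * s, 26 * s, 10 * s, 32 * s, "plot",
                         id = "alkali_plot")
  list(set = polygon_set(list(lake, periph, wet1, wet2, field, res)),
       lake = lake, upland_plot = upland_plot,
       alkali_flat = alkali_flat, alkali_plot = alkali_plot)
}

clampv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full synthetic watershed bundle
#'
#' Generates the coupled truth system for one watershed: climate and
#' human-use predictor series, annual truth fraction grids, rendered
#' scenes (one per seasonal window; the 2012 scene is absent, echoing the
#' satellite gap), functional polygons and static plots, truth area
#' tables, and population anchors at 1975/1990/2000/2015 only.
#'
#' @param params a [regime_params()] object
#' @return a `watershed_bundle`
#' @export
simulate_series <- function(params) {
  stopifnot(inherits(params, "regime_params"))
  set.seed(params$seed)
  g <- params$grid
  years <- params$years
  n <- params$n_years
  t <- seq_len(n) - 1
  snow <- params$regime == "snowmelt"

  lib <- make_library(seed = NULL, n_bands = 6)  # from the master stream

  # predictor series -----------------------------------------------------
  clim <- lapply(params$climate, function(cf)
    pmax(cf[1] + cf[2] * t + rnorm(n, 0, cf[3]), 0))
  irrf <- params$irrigation
  irr_field_frac <- clampv(irrf[1] + irrf[2] * t + rnorm(n, 0, irrf[3]),
                           0.01, 0.95)
  pop0 <- runif(1, 2e4, 2e5)
  rate <- runif(1, 0.008, 0.011)
  anchor_years <- c(1975, 1990, 2000, 2015)
  anchors <- round(pop0 * (1 + rate)^(anchor_years - 1975))
  names(anchors) <- anchor_years
  area_ha <- g * g * 900 / 1e4
  pop <- population_series(anchors, years = years,
                           watershed_area_km2 = area_ha / 100)

  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  z <- list(ET = zs(clim$ET), PR = zs(clim$PR), RO = zs(clim$RO),
            SWE = zs(clim$SWE), irrigation = zs(irr_field_frac),
            population = zs(pop$population))
  couple <- function(beta) {
    eff <- numeric(n)
    for (nm in names(beta)) eff <- eff + beta[[nm]] * z[[nm]]
    eff
  }

  # truth proportions -----------------------------------------------------
  innov <- rnorm(n, 0, params$interannual_sd *
                   sqrt(1 - params$ar1^2))
  eps <- numeric(n)
  eps[1] <- rnorm(1, 0, params$interannual_sd)
  for (i in seq_len(n)[-1]) eps[i] <- params$ar1 * eps[i - 1] + innov[i]
  p_lake <- clampv(params$p0 + params$lake_trend * t +
                     couple(params$coupling) + eps, 0.02, 0.95)
  w_wet <- clampv(params$w0 + couple(params$wetland_coupling) +
                    rnorm(n, 0, params$wetland_sd), 0.05, 0.90)
  p_per <- clampv(p_lake + rnorm(n, 0, 0.03), 0.05, 0.90)

  # geometry --------------------------------------------------------------
  lay <- watershed_layout(g)
  labels <- rasterize_polygons(lay$set, g, g)
  cx <- rep(seq_len(g) - 0.5, each = g)
  cy <- rep(seq_len(g) - 0.5, times = g)
  in_alk <- matrix(point_in_polygon(cx, cy, lay$alkali_flat), g, g)
  region <- labels
  region[is.na(region)] <- "upland"
  region[in_alk & region == "upland"] <- "alkali"

  lake_idx <- which(region == "lake")
  dist <- sqrt((cx[lake_idx] - 32 * g / 64)^2 + (cy[lake_idx] - 32 * g / 64)^2)
  lake_idx <- lake_idx[order(dist, lake_idx)]  # deepest (central) first
  per_idx <- which(region == "peripheral_wetland")
  wet_idx <- which(region == "wetland")
  fld_idx <- which(region == "field")
  res_idx <- which(region == "excluded")

  # per-year truth fraction grids and scenes ------------------------------
  subseeds <- sample.int(2^30, n)
  mix <- function(idx, frac, F) { F[idx, ] <- rep(frac, each = length(idx)); F }
  truth <- list(); images <- list()
  counts <- data.frame(year = years, lake = NA_real_, wetland = NA_real_,
                       peripheral_wetland = NA_real_, irrigated = NA_real_)
  for (i in seq_len(n)) {
    y <- years[i]
    F <- matrix(0, g * g, 4)
    F[, 3] <- 1  # upland background
    F <- mix(which(region == "alkali"), c(0, 0, 0, 1), F)
    # lake: inundate deepest-first; one 45% shoreline pixel (counted at the
    # 10% rule) and one 5% pixel (omitted) exercise the sub-pixel threshold
    F <- mix(lake_idx, c(0, 0, 0, 1), F)
    k <- round(p_lake[i] * length(lake_idx))
    if (k > 0) F <- mix(lake_idx[seq_len(k)], c(1, 0, 0, 0), F)
    if (k + 1 <= length(lake_idx))
      F <- mix(lake_idx[k + 1], c(0.45, 0, 0, 0.55), F)
    if (k + 2 <= length(lake_idx))
      F <- mix(lake_idx[k + 2], c(0.05, 0, 0, 0.95), F)
    # wetlands: flooded pixels are half water / half emergent vegetation
    m <- round(w_wet[i] * length(wet_idx))
    F <- mix(wet_idx, c(0, 1, 0, 0), F)
    if (m > 0) F <- mix(wet_idx[seq_len(m)], c(0.5, 0.5, 0, 0), F)
    mp <- round(p_per[i] * length(per_idx))
    F <- mix(per_idx, c(0, 1, 0, 0), F)
    if (mp > 0) F <- mix(per_idx[seq_len(mp)], c(0.5, 0.5, 0, 0), F)
    # fields: irrigated pixels are pure productive vegetation
    nirr <- round(irr_field_frac[i] * length(fld_idx))
    F <- mix(fld_idx, c(0, 0.1, 0.9, 0), F)
    if (nirr > 0) F <- mix(fld_idx[seq_len(nirr)], c(0, 1, 0, 0), F)
    F <- mix(res_idx, c(1, 0, 0, 0), F)  # reservoir always full

    arr <- array(F, c(g, g, 4))
    wfrac <- arr[, , 1]
    counts$lake[i] <- sum(wfrac >= 0.10 & region == "lake") * 0.09
    counts$wetland[i] <- sum(wfrac >= 0.10 & region == "wetland") * 0.09
    counts$peripheral_wetland[i] <-
      sum(wfrac >= 0.10 & region == "peripheral_wetland") * 0.09
    counts$irrigated[i] <- nirr * 0.09
    if (y %in% params$missing_years) next  # satellite gap: no scene kept
    truth[[as.character(y)]] <- arr
    images[[as.character(y)]] <- render_scene(
      arr, lib, noise_sd = params$noise_sd,
      cloud_fraction = params$cloud_fraction, seed = subseeds[i],
      date = as.Date(sprintf(if (snow) "%d-06-15" else "%d-02-15", y)))
  }
  gap <- counts$year %in% params$missing_years
  counts[gap, c("lake", "wetland", "peripheral_wetland", "irrigated")] <- NA

  truth_areas <- do.call(rbind, lapply(
    c("lake", "wetland", "peripheral_wetland"), function(cl)
      data.frame(watershed = params$watershed, region = params$regime,
                 year = years, class = cl, area_ha = counts[[cl]],
                 missing = gap)))
  climate <- data.frame(year = years, ET = clim$ET, PR = clim$PR,
                        RO = clim$RO, SWE = clim$SWE)
  human_truth <- data.frame(year = years, irrigated_ha = counts$irrigated,
                            irrigated_frac = counts$irrigated / area_ha)

  structure(list(params = params, library = lib,
                 polygons = lay$set, lake_polygon = lay$lake,
                 upland_plot = lay$upland_plot,
                 alkali_plot = lay$alkali_plot,
                 images = images, truth_fractions = truth,
                 truth_areas = truth_areas, climate = climate,
                 human_truth = human_truth,
                 population_anchors = anchors, population = pop,
                 watershed_area_ha = area_ha,
                 truth_series = data.frame(
                   year = years, p_lake = p_lake, w_wet = w_wet,
                   p_per = p_per, irr_field_frac = irr_field_frac)),
            class = "watershed_bundle")
}

#' @export
print.watershed_bundle <- function(x, ...) {
  cat(sprintf(
    "<watershed_bundle> %s (%s), %d years (%d scenes), %dx%d px\n",
    x$params$watershed, x$params$regime, x$params$n_years,
    length(x$images), x$params$grid, x$params$grid))
  invisible(x)
}
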