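# Area accounting: clip fraction maps to functional polygons, convert
# sub-pixel water fractions to inundated hectares, map irrigated extent
# from annual maximum NDVI and build human-use series.

#' Inundated area per functional class
#'
#' A pixel counts as fully inundated when its water fraction is at least
#' `threshold` (inclusive; pixels holding < 10% water are omitted by
#' default to limit over-estimation), contributing its full ground area.
#' Pixels labeled `excluded` (reservoirs, evaporation ponds, livestock
#' ponds) or unlabeled contribute nothing, as do invalid pixels.
#'
#' @param fractions a `fraction_map`
#' @param labels character label matrix from [rasterize_polygons()], same
#'   shape
#' @param threshold water-fraction cut, default 0.10
#' @param classes classes to report (default lake, wetland,
#'   peripheral_wetland)
#' @return named numeric vector of hectares per class
#' @export
water_area <- function(fractions, labels,
                       threshold = 0.10,
                       classes = c("lake", "wetland",
                                   "peripheral_wetland")) {
  if (!identical(dim(labels), dim(fractions$rmse)))
    stop("label grid and fraction map are misaligned")
  w <- fraction_plane(fractions, "water")
  wet <- fractions$valid & !is.na(w) & w >= threshold
  out <- vapply(classes, function(cl) {
    sum(wet & !is.na(labels) & labels == cl) * fractions$pixel_area / 1e4
  }, numeric(1))
  names(out) <- classes
  out
}

#' Annual maximum-NDVI composite
#'
#' Per-pixel maximum NDVI over unmasked observations dated inside the
#' growing window (1 February - 30 November by default), the annual peak
#' of primary productivity.
#'
#' @param images list of `spectral_image`
#' @param months integer months defining the window (default 2:11)
#' @return an `index_grid` of kind "ndvi"
#' @export
max_ndvi_composite <- function(images, months = 2:11) {
  if (length(images) == 0) stop("empty image list")
  keep <- vapply(images, function(im) {
    is.null(im$date) ||
      as.integer(format(as.Date(im$date), "%m")) %in% months
  }, logical(1))
  images <- images[keep]
  if (length(images) == 0) stop("no image dated within the NDVI window")
  d <- dim(images[[1]]$bands[[1]])
  best <- matrix(-Inf, d[1], d[2])
  seen <- matrix(FALSE, d[1], d[2])
  for (im in images) {
    g <- compute_index(im, "ndvi")
    upd <- g$valid & (!seen | g$values > best)
    best[upd] <- g$values[upd]
    seen <- seen | g$valid
  }
  best[!seen] <- NA_real_
  structure(list(values = best, kind = "ndvi", valid = seen),
            class = "index_grid")
}

#' Irrigated area from a maximum-NDVI composite
#'
#' Field-labeled pixels whose annual maximum NDVI strictly exceeds
#' `threshold` (> 0.4 by default) count as irrigated; the summary is
#' constrained to the field polygons so productive non-agricultural cover
#' (e.g. riparian forest) is ignored.
#'
#' @param max_ndvi an `index_grid` from [max_ndvi_composite()]
#' @param labels character label matrix aligned to the grid
#' @param threshold NDVI cut, strict inequality (default 0.4)
#' @param pixel_area pixel ground area in square metres (default 900)
#' @return hectares of irrigated fields
#' @export
irrigated_area <- function(max_ndvi, labels, threshold = 0.4,
                           pixel_area = 900) {
  if (!identical(dim(labels), dim(max_ndvi$values)))
    stop("label grid and NDVI grid are misaligned")
  hit <- max_ndvi$valid & !is.na(max_ndvi$values) &
    max_ndvi$values > threshold & !is.na(labels) & labels == "field"
  sum(hit) * pixel_area / 1e4
}

# Natural cubic interpolating spline. Interior evaluation matches
# stats::spline(method = "natural"); beyond the anchor range the terminal
# cubic piece is continued (rather than the linear continuation some
# implementations use), which is the documented extrapolation rule here.
natural_spline <- function(x, y) {
  n <- length(x)
  if (n < 2 || any(duplicated(x))) stop("anchor years must be distinct")
  if (is.unsorted(x)) stop("anchor years must be ordered")
  h <- diff(x)
  # second derivatives (natural boundary: M1 = Mn = 0), tridiagonal solve
  M <- numeric(n)
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    rhs <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      k <- i - 1
      A[k, k] <- 2 * (h[i - 1] + h[i])
      if (k > 1) A[k, k - 1] <- h[i - 1]
      if (k < n - 2) A[k, k + 1] <- h[i]
      rhs[k] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
    }
    M[2:(n - 1)] <- solve(A, rhs)
  }
  function(t) {
    i <- findInterval(t, x, all.inside = TRUE)  # end pieces extend outward
    dx <- t - x[i]
    hi <- h[i]
    a <- y[i]
    b <- (y[i + 1] - y[i]) / hi - hi * (2 * M[i] + M[i + 1]) / 6
    cc <- M[i] / 2
    dd <- (M[i + 1] - M[i]) / (6 * hi)
    a + b * dx + cc * dx^2 + dd * dx^3
  }
}

#' Annual population series from sparse census anchors
#'
#' Fits a natural cubic interpolating spline through the anchor years
#' (1975, 1990, 2000, 2015 in the settlement-layer record) and evaluates it
#' at integer years; beyond the last anchor the terminal cubic piece is
#' continued. Density is count / watershed area.
#'
#' @param anchors named numeric vector, names are anchor years
#' @param years integer years to evaluate (default 1975:2018)
#' @param watershed_area_km2 watershed area in km^2 (> 0)
#' @return data.frame with `year`, `population`, `density_km2`
#' @export
population_series <- function(anchors, years = 1975:2018,
                              watershed_area_km2) {
  stopifnot(length(anchors) >= 4, watershed_area_km2 > 0)
  ax <- as.numeric(names(anchors))
  if (any(is.na(ax))) stop("anchors must be named by year")
  if (any(duplicated(ax)) || is.unsorted(ax))
    stop("anchor years must be ordered and distinct")
  f <- natural_spline(ax, as.numeric(anchors))
  pop <- pmax(f(years), 0)
  data.frame(year = years, population = pop,
             density_km2 = pop / watershed_area_km2)
}

#' Assemble annual surface-water and human-use series
#'
#' @param watershed watershed identifier
#' @param region "snowmelt" or "monsoonal"
#' @param water_by_year named list: year -> named hectare vector from
#'   [water_area()]; years absent from the list (e.g. the 2012 satellite
#'   gap) appear in the output with `NA` area and `missing = TRUE`
#' @param irrigated_by_year named numeric: year -> irrigated hectares
#' @param population data.frame from [population_series()]
#' @param years full span of the record (default 1984:2018)
#' @param watershed_area_ha watershed area in hectares, used to normalize
#'   irrigated area
#' @return list with `water` (watershed, region, year, class, area_ha,
#'   missing) and `human` (watershed, year, irrigated_ha, irrigated_frac,
#'   population, density_km2). Monsoonal series carry
#'   `attr(water, "model_years")` ending 2017 (climate coverage rule).
#' @export
build_series <- function(watershed, region = c("snowmelt", "monsoonal"),
                         water_by_year, irrigated_by_year, population,
                         years = 1984:2018, watershed_area_ha) {
  region <- match.arg(region)
  wy <- as.integer(names(water_by_year))
  if (any(duplicated(wy))) stop("duplicate year entries in water series")
  classes <- names(water_by_year[[1]])
  water <- do.call(rbind, lapply(years, function(y) {
    i <- match(y, wy)
    area <- if (is.na(i)) rep(NA_real_, length(classes))
            else as.numeric(water_by_year[[i]])
    data.frame(watershed = watershed, region = region, year = y,
               class = classes, area_ha = area, missing = is.na(i))
  }))
  iy <- as.integer(names(irrigated_by_year))
  if (any(duplicated(iy))) stop("duplicate year entries in irrigation series")
  irr <- as.numeric(irrigated_by_year)[match(years, iy)]
  human <- data.frame(watershed = watershed, year = years,
                      irrigated_ha = irr,
                      irrigated_frac = irr / watershed_area_ha)
  human <- merge(human, population, by = "year", all.x = TRUE)
  human <- human[order(human$year),
                 c("watershed", "year", "irrigated_ha", "irrigated_frac",
                   "population", "density_km2")]
  rownames(human) <- NULL
  attr(water, "model_years") <-
    if (region == "monsoonal") years[years <= 2017] else years
  class(water) <- c("surface_water_series", "data.frame")
  list(water = water, human = human)
}

#' Write / read surface-water series CSV
#' @param series the `water` data.frame from [build_series()]
#' @param path CSV path
#' @export
write_series <- function(series, path) {
  write.csv(series[, c("watershed", "region", "year", "class", "area_ha")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- read.csv(path)
  df$missing <- is.na(df$area_ha)
  class(df) <- c("surface_water_series", "data.frame")
  df
}
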