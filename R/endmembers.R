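# Endmember training: spectral indices, percentile masks, plot means and
# library assembly. Water endmembers come from the upper tail of NDWI,
# wetland-vegetation endmembers from the upper NDVI tail inside seasonally
# flooded wetland polygons, and upland / alkali-soil endmembers from small
# static plots of homogeneous cover.

#' Compute a normalized-difference spectral index
#'
#' NDWI = (green - nir) / (green + nir) (McFeeters form, high over open
#' water); NDVI = (nir - red) / (nir + red) (high over productive
#' vegetation). QA-masked pixels and zero denominators are invalid.
#'
#' @param image a `spectral_image` with named `green`, `red`, `nir` bands as
#'   required by `kind`
#' @param kind "ndwi" or "ndvi"
#' @return an `index_grid`: list of `values` (matrix in \[-1, 1\]), `kind`
#'   and logical `valid`
#' @export
compute_index <- function(image, kind = c("ndwi", "ndvi")) {
  kind <- match.arg(kind)
  if (kind == "ndwi") {
    a <- band(image, "green"); b <- band(image, "nir")
  } else {
    a <- band(image, "nir"); b <- band(image, "red")
  }
  den <- a + b
  valid <- qa_valid(image) & den != 0
  vals <- (a - b) / den
  vals[!valid] <- NA_real_
  structure(list(values = vals, kind = kind, valid = valid),
            class = "index_grid")
}

#' Upper-percentile mask of an index grid
#'
#' Selects valid pixels at or above the q-th percentile of the valid values
#' (percentile by linear interpolation of order statistics, i.e.
#' `quantile(type = 7)`).
#'
#' @param index an `index_grid`
#' @param q percentile in (0, 100)
#' @return logical matrix
#' @export
percentile_mask <- function(index, q) {
  stopifnot(q > 0, q < 100)
  v <- index$values[index$valid]
  if (length(v) == 0) stop("no valid pixels to take a percentile over")
  cut <- quantile(v, q / 100, names = FALSE, type = 7)
  index$valid & !is.na(index$values) & index$values >= cut
}

#' Mean spectrum over masked pixels
#'
#' @param image a `spectral_image`
#' @param mask logical matrix; QA-masked pixels inside the mask are ignored
#' @param agg aggregation over selected pixels, `mean` (default) or another
#'   summary such as `median`
#' @return named reflectance vector, one entry per band
#' @export
extract_endmember <- function(image, mask, agg = mean) {
  sel <- mask & qa_valid(image)
  if (!any(sel)) stop("endmember mask selects no unmasked pixels")
  vapply(image$bands, function(m) agg(m[sel]), numeric(1))
}

#' Mean spectrum over a static plot polygon
#'
#' Averages band reflectance over pixels whose centers fall inside the plot
#' (even-odd containment, boundary inclusive).
#'
#' @param image a `spectral_image`
#' @param plot an `ew_polygon`
#' @inheritParams extract_endmember
#' @return named reflectance vector
#' @export
plot_endmember <- function(image, plot, agg = mean) {
  d <- dim(image$bands[[1]])
  cx <- rep(seq_len(d[2]) - 0.5, each = d[1])
  cy <- rep(seq_len(d[1]) - 0.5, times = d[2])
  hit <- matrix(point_in_polygon(cx, cy, plot), d[1], d[2])
  if (!any(hit)) stop("no pixel centers fall inside the plot")
  extract_endmember(image, hit, agg = agg)
}

#' Assemble an endmember library
#'
#' @param spectra 4 x n_bands numeric matrix, rows ordered water,
#'   wetland_vegetation, upland, alkali_soil; column names are band names.
#' @param provenance optional character notes, one per endmember.
#' @return an `endmember_library`
#' @export
endmember_library <- function(spectra, provenance = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != 4)
    stop("library must hold exactly 4 endmembers (water, wetland ",
         "vegetation, upland, alkali soil)")
  rownames(spectra) <- EW_ENDMEMBERS
  if (any(!is.finite(spectra)) || any(spectra < 0))
    stop("endmember spectra must be finite and non-negative")
  if (any(duplicated(round(spectra, 12))))
    stop("two endmember spectra are identical")
  M <- t(spectra)  # bands x 4 mixing matrix
  if (qr(M)$rank < 4)
    stop("mixing matrix is rank-deficient; endmembers are collinear")
  structure(list(spectra = spectra, bands = colnames(spectra),
                 provenance = provenance),
            class = "endmember_library")
}

#' @export
print.endmember_library <- function(x, ...) {
  cat("<endmember_library> 4 endmembers x", ncol(x$spectra), "bands\n")
  print(round(x$spectra, 4))
  invisible(x)
}

#' Extract a full endmember library from one composite image
#'
#' Water: pixels at/above the `q_water` NDWI percentile, optionally
#' restricted to a constraint polygon (e.g. a large deep lake). Wetland
#' vegetation: pixels at/above the `q_veg` NDVI percentile inside the
#' supplied seasonally flooded wetland polygons. Upland and alkali soil:
#' mean spectra of small homogeneous static plots.
#'
#' @param image composite `spectral_image`
#' @param wetland_polygons list of `ew_polygon` delimiting seasonally
#'   flooded wetlands (classes wetland / peripheral_wetland)
#' @param upland_plot,alkali_plot static `ew_polygon` plots
#' @param water_constraint optional `ew_polygon` restricting the NDWI mask
#' @param q_water,q_veg percentiles for the water / vegetation masks
#' @param agg spectrum aggregation (mean by default)
#' @return an `endmember_library`
#' @export
extract_library <- function(image, wetland_polygons, upland_plot,
                            alkali_plot, water_constraint = NULL,
                            q_water = 99, q_veg = 95, agg = mean) {
  d <- dim(image$bands[[1]])
  cx <- rep(seq_len(d[2]) - 0.5, each = d[1])
  cy <- rep(seq_len(d[1]) - 0.5, times = d[2])

  ndwi <- compute_index(image, "ndwi")
  if (!is.null(water_constraint)) {
    inpoly <- matrix(point_in_polygon(cx, cy, water_constraint), d[1], d[2])
    ndwi$valid <- ndwi$valid & inpoly
    ndwi$values[!ndwi$valid] <- NA_real_
  }
  water <- extract_endmember(image, percentile_mask(ndwi, q_water), agg)

  if (inherits(wetland_polygons, "ew_polygon"))
    wetland_polygons <- list(wetland_polygons)
  inwet <- Reduce(`|`, lapply(wetland_polygons, function(p)
    matrix(point_in_polygon(cx, cy, p), d[1], d[2])))
  ndvi <- compute_index(image, "ndvi")
  ndvi$valid <- ndvi$valid & inwet
  ndvi$values[!ndvi$valid] <- NA_real_
  veg <- extract_endmember(image, percentile_mask(ndvi, q_veg), agg)

  upland <- plot_endmember(image, upland_plot, agg)
  alkali <- plot_endmember(image, alkali_plot, agg)

  endmember_library(
    rbind(water, veg, upland, alkali),
    provenance = c(
      water = sprintf("NDWI >= p%g mask%s", q_water,
                      if (is.null(water_constraint)) ""
                      else " within constraint polygon"),
      wetland_vegetation = sprintf("NDVI >= p%g within wetland polygons",
                                   q_veg),
      upland = "static plot mean", alkali_soil = "static plot mean"))
}

#' Write / read an endmember library as CSV with a JSON provenance sidecar
#' @param library an `endmember_library`
#' @param path CSV path (sidecar written to `<path>.json`)
#' @export
write_endmembers <- function(library, path) {
  df <- data.frame(endmember = rownames(library$spectra),
                   library$spectra, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(library$provenance))
    jsonlite::write_json(as.list(library$provenance),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_endmembers
#' @export
read_endmembers <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$endmember
  prov <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side))
    prov <- unlist(jsonlite::read_json(side))
  endmember_library(m, provenance = prov)
}
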