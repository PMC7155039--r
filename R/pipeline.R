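# End-to-end pipeline over a watershed bundle: composite -> per-composite
# endmember extraction -> FCLS unmixing -> polygon clipping and area
# accounting -> human-use series. On a noiseless, cloud-free bundle this
# reproduces the truth area tables exactly.

#' Run the full surface-water pipeline on a bundle
#'
#' For every available year: build the seasonal composite, extract a fresh
#' endmember library from the composite itself (NDWI 99th-percentile water
#' mask constrained to the lake polygon; NDVI 95th-percentile vegetation
#' mask inside wetland polygons; upland/alkali static plots), unmix, clip
#' to the functional polygons and account inundated area; in parallel map
#' irrigated extent from the annual maximum-NDVI composite. Population
#' comes from the spline through the census anchors.
#'
#' @param bundle a `watershed_bundle`
#' @param threshold water-fraction cut for full-inundation counting
#'   (default 0.10, inclusive)
#' @param ndvi_threshold irrigation cut on annual maximum NDVI (default
#'   0.4, strict)
#' @param q_water,q_veg endmember percentile masks
#' @param use_truth_library skip per-composite extraction and unmix with
#'   the generator's library (default FALSE)
#' @return list from [build_series()]: `water` and `human` annual series
#' @export
run_pipeline <- function(bundle, threshold = 0.10, ndvi_threshold = 0.4,
                         q_water = 99, q_veg = 95,
                         use_truth_library = FALSE) {
  stopifnot(inherits(bundle, "watershed_bundle"))
  params <- bundle$params
  g <- params$grid
  labels <- rasterize_polygons(bundle$polygons, g, g)
  wet_polys <- Filter(function(p)
    p$class %in% c("wetland", "peripheral_wetland"),
    bundle$polygons$polygons)

  water_by_year <- list()
  irr_by_year <- numeric(0)
  for (y in names(bundle$images)) {
    comp <- seasonal_composite(bundle$images[y], window = params$regime,
                               year = as.integer(y))
    lib <- if (use_truth_library) bundle$library else
      extract_library(comp, wet_polys, bundle$upland_plot,
                      bundle$alkali_plot,
                      water_constraint = bundle$lake_polygon,
                      q_water = q_water, q_veg = q_veg)
    fm <- unmix_image(comp, lib)
    water_by_year[[y]] <- water_area(fm, labels, threshold = threshold)
    nd <- max_ndvi_composite(bundle$images[y])
    irr_by_year[y] <- irrigated_area(nd, labels,
                                     threshold = ndvi_threshold)
  }
  pop <- population_series(bundle$population_anchors,
                           years = params$years,
                           watershed_area_km2 = bundle$watershed_area_ha / 100)
  build_series(params$watershed, params$regime, water_by_year,
               irr_by_year, pop, years = params$years,
               watershed_area_ha = bundle$watershed_area_ha)
}

# Serialization: the documented flat-text fallback (no GeoTIFF machinery
# is assumed). Rasters go to per-band CSV matrices with a JSON header,
# polygons to GeoJSON, series to CSV, config to JSON.

write_matrix <- function(m, path)
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)

read_matrix <- function(path)
  as.matrix(read.table(path, sep = ","))

polygon_geojson <- function(set) {
  feats <- lapply(set$polygons, function(p) {
    coords <- lapply(p$rings, function(r) {
      rc <- rbind(r, r[1, ])  # close the ring
      lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1], rc[i, 2]))
    })
    list(type = "Feature",
         properties = list(class = p$class, id = p$id,
                           subtype = p$subtype, frame = p$frame),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  list(type = "FeatureCollection", features = feats)
}

#' Serialize a watershed bundle to a directory
#'
#' Layout: `config.json` (regime parameters), `endmembers.csv` (+ JSON
#' provenance sidecar), `polygons.geojson`, `truth_areas.csv`,
#' `climate.csv`, `human_truth.csv`, `population_anchors.csv`, and
#' `scenes/<year>/<band>.csv` flat matrices with `scenes/<year>/meta.json`
#' headers (date, pixel area, QA in `qa.csv`).
#'
#' @param bundle a `watershed_bundle`
#' @param dir target directory (created)
#' @param scenes write the per-year rasters too (default TRUE)
#' @export
write_bundle <- function(bundle, dir, scenes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pj <- unclass(bundle$params)
  pj$coupling <- as.list(pj$coupling)
  pj$wetland_coupling <- as.list(pj$wetland_coupling)
  jsonlite::write_json(pj, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_endmembers(bundle$library, file.path(dir, "endmembers.csv"))
  jsonlite::write_json(polygon_geojson(bundle$polygons),
                       file.path(dir, "polygons.geojson"),
                       auto_unbox = TRUE, digits = NA)
  plots <- list(polygons = list(bundle$upland_plot, bundle$alkali_plot),
                frame = "pixel")
  jsonlite::write_json(polygon_geojson(plots),
                       file.path(dir, "plots.geojson"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(bundle$truth_areas, file.path(dir, "truth_areas.csv"),
            row.names = FALSE)
  write.csv(bundle$climate, file.path(dir, "climate.csv"),
            row.names = FALSE)
  write.csv(bundle$human_truth, file.path(dir, "human_truth.csv"),
            row.names = FALSE)
  write.csv(data.frame(year = as.integer(names(bundle$population_anchors)),
                       population = as.numeric(bundle$population_anchors)),
            file.path(dir, "population_anchors.csv"), row.names = FALSE)
  if (scenes) {
    for (y in names(bundle$images)) {
      im <- bundle$images[[y]]
      sdir <- file.path(dir, "scenes", y)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      for (b in names(im$bands))
        write_matrix(im$bands[[b]], file.path(sdir, paste0(b, ".csv")))
      write_matrix(im$qa, file.path(sdir, "qa.csv"))
      jsonlite::write_json(
        list(date = format(im$date), pixel_area = im$pixel_area,
             bands = names(im$bands)),
        file.path(sdir, "meta.json"), auto_unbox = TRUE)
    }
  }
  invisible(dir)
}

read_polygon_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt)
        c(pt[[1]], pt[[2]])))
      m[-nrow(m), , drop = FALSE]  # drop the closing vertex
    })
    ew_polygon(rings, class = f$properties$class,
               id = f$properties$id,
               subtype = f$properties$subtype,
               frame = if (is.null(f$properties$frame)) "pixel"
                       else f$properties$frame)
  })
}

#' Read a serialized bundle back from a directory
#'
#' Restores everything [run_pipeline()] needs (scenes, polygons, plots,
#' population anchors, parameters); truth fraction grids are not
#' serialized and come back empty.
#'
#' @param dir directory written by [write_bundle()]
#' @return a `watershed_bundle`
#' @export
read_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  params <- regime_params(cfg$regime, n_years = cfg$n_years,
                          grid = cfg$grid, p0 = cfg$p0,
                          lake_trend = cfg$lake_trend,
                          interannual_sd = cfg$interannual_sd,
                          ar1 = cfg$ar1,
                          cloud_fraction = cfg$cloud_fraction,
                          noise_sd = cfg$noise_sd,
                          coupling = unlist(cfg$coupling),
                          wetland_coupling = unlist(cfg$wetland_coupling),
                          seed = cfg$seed, watershed = cfg$watershed)
  polys <- read_polygon_geojson(file.path(dir, "polygons.geojson"))
  plots <- read_polygon_geojson(file.path(dir, "plots.geojson"))
  names(plots) <- vapply(plots, `[[`, character(1), "id")
  anch <- read.csv(file.path(dir, "population_anchors.csv"))
  anchors <- anch$population
  names(anchors) <- anch$year
  lake <- Filter(function(p) p$class == "lake", polys)[[1]]
  structure(list(params = params,
                 library = read_endmembers(file.path(dir,
                                                     "endmembers.csv")),
                 polygons = polygon_set(polys),
                 lake_polygon = lake,
                 upland_plot = plots[["upland_plot"]],
                 alkali_plot = plots[["alkali_plot"]],
                 images = read_bundle_scenes(dir),
                 truth_fractions = list(),
                 truth_areas = read.csv(file.path(dir, "truth_areas.csv")),
                 climate = read.csv(file.path(dir, "climate.csv")),
                 human_truth = read.csv(file.path(dir, "human_truth.csv")),
                 population_anchors = anchors,
                 watershed_area_ha = cfg$grid^2 * 900 / 1e4),
            class = "watershed_bundle")
}

#' Read scenes back from a serialized bundle directory
#' @param dir directory written by [write_bundle()]
#' @return named list of `spectral_image`
#' @export
read_bundle_scenes <- function(dir) {
  ydirs <- list.dirs(file.path(dir, "scenes"), recursive = FALSE)
  out <- list()
  for (yd in ydirs) {
    meta <- jsonlite::read_json(file.path(yd, "meta.json"),
                                simplifyVector = TRUE)
    bands <- lapply(meta$bands, function(b)
      read_matrix(file.path(yd, paste0(b, ".csv"))))
    names(bands) <- meta$bands
    out[[basename(yd)]] <- spectral_image(
      bands, qa = read_matrix(file.path(yd, "qa.csv")),
      date = meta$date, pixel_area = meta$pixel_area)
  }
  out
}
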