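# Lightweight planar geometry: polygons, point-in-polygon (even-odd rule)
# and rasterization by pixel-center containment. Coordinates are in pixel
# units: the center of pixel (row i, col j) sits at (x = j - 0.5,
# y = i - 0.5). No geographic CRS is modelled; a free-text `frame` tag on
# polygons and grids guards against mixing coordinate frames.

#' Construct a polygon with a functional class
#'
#' @param rings list of numeric n x 2 matrices (x, y vertex columns); a
#'   single matrix is accepted. Multiple rings are interpreted under the
#'   even-odd rule, so a second ring inside the first cuts a hole.
#' @param class one of `EW_CLASSES` (lake, wetland, peripheral_wetland,
#'   field, excluded).
#' @param id polygon identifier.
#' @param subtype free-text functional note (e.g. "reservoir",
#'   "salt evaporation pond", "livestock pond") for excluded polygons.
#' @param frame coordinate-frame tag (default "pixel").
#' @return an `ew_polygon`.
#' @export
ew_polygon <- function(rings, class, id = NULL, subtype = NULL,
                       frame = "pixel") {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1)
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
      stop("each ring must be an n x 2 matrix with n >= 3")
    if (polygon_ring_area(r) <= 0)
      stop("degenerate (zero-area) ring")
  }
  # "plot" marks standalone static training plots, never members of a
  # polygon set (polygon_set() rejects it)
  class <- match.arg(class, c(EW_CLASSES, "plot"))
  structure(list(rings = rings, class = class, id = id, subtype = subtype,
                 frame = frame),
            class = "ew_polygon")
}

polygon_ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Axis-aligned rectangle polygon helper
#' @param x0,y0,x1,y1 corners in pixel units
#' @inheritParams ew_polygon
#' @export
ew_rect <- function(x0, y0, x1, y1, class, id = NULL, subtype = NULL) {
  ew_polygon(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)), class, id, subtype)
}

#' Regular-polygon approximation of a circle
#' @param cx,cy,r center and radius in pixel units
#' @param n number of vertices
#' @inheritParams ew_polygon
#' @export
ew_circle <- function(cx, cy, r, class, id = NULL, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ew_polygon(cbind(cx + r * cos(th), cy + r * sin(th)), class, id)
}

#' Bundle polygons into a set
#' @param ... `ew_polygon` objects (or a single list of them)
#' @param frame coordinate-frame tag; all members must agree
#' @return an `ew_polygon_set`
#' @export
polygon_set <- function(..., frame = "pixel") {
  polys <- list(...)
  if (length(polys) == 1 && !inherits(polys[[1]], "ew_polygon"))
    polys <- polys[[1]]
  for (p in polys) {
    stopifnot(inherits(p, "ew_polygon"))
    if (p$class == "plot")
      stop("static plots do not belong in a polygon set")
    if (!identical(p$frame, frame))
      stop("polygon coordinate frame '", p$frame,
           "' does not match set frame '", frame, "'")
  }
  structure(list(polygons = polys, frame = frame),
            class = "ew_polygon_set")
}

# even-odd containment of points in one ring; boundary points count inside
pip_ring <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- ring[j, 1]; y1 <- ring[j, 2]
    x2 <- ring[i, 1]; y2 <- ring[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xi))
    }
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    tproj <- ((px - x1) * dx + (py - y1) * dy) / len2
    cross <- (px - x1) * dy - (py - y1) * dx
    onedge <- onedge |
      (abs(cross) < tol * sqrt(len2) & tproj >= -tol & tproj <= 1 + tol)
    j <- i
  }
  list(inside = inside, onedge = onedge)
}

#' Even-odd point-in-polygon test
#'
#' Points exactly on a ring edge are counted as inside (documented
#' convention for pixel centers on boundaries).
#'
#' @param px,py point coordinates (vectors)
#' @param polygon an `ew_polygon`
#' @return logical vector
#' @export
point_in_polygon <- function(px, py, polygon) {
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  for (ring in polygon$rings) {
    r <- pip_ring(px, py, ring)
    inside <- xor(inside, r$inside)
    onedge <- onedge | r$onedge
  }
  inside | onedge
}

#' Rasterize a polygon set onto a pixel grid
#'
#' Each pixel is labeled by the class of the polygon containing its center
#' (even-odd rule, boundary counts as inside). Overlaps resolve by
#' precedence: `excluded` always wins (so reservoirs, evaporation ponds and
#' livestock ponds are filtered from every summary); among the remaining
#' classes the later polygon in the set wins.
#'
#' @param polygons an `ew_polygon_set`
#' @param nrow,ncol grid dimensions in pixels
#' @param frame coordinate-frame tag of the grid (must match the set)
#' @return character matrix of class labels, `NA` where unlabeled
#' @export
rasterize_polygons <- function(polygons, nrow, ncol, frame = "pixel") {
  stopifnot(inherits(polygons, "ew_polygon_set"))
  if (!identical(polygons$frame, frame))
    stop("coordinate frame mismatch: polygons are '", polygons$frame,
         "', grid is '", frame, "'")
  cx <- rep(seq_len(ncol) - 0.5, each = nrow)
  cy <- rep(seq_len(nrow) - 0.5, times = ncol)
  labels <- rep(NA_character_, nrow * ncol)
  excl <- vapply(polygons$polygons,
                 function(p) p$class == "excluded", logical(1))
  ord <- c(which(!excl), which(excl))  # excluded drawn last => wins
  for (p in polygons$polygons[ord]) {
    hit <- point_in_polygon(cx, cy, p)
    labels[hit] <- p$class
  }
  matrix(labels, nrow, ncol)
}
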