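# Multi-band reflectance grids with per-pixel QA, the basic imagery unit.

#' Create a spectral image
#'
#' A `spectral_image` holds named reflectance bands (matrices sharing one
#' shape), a per-pixel QA code matrix (0 = valid; 1 = cloud, 2 = cloud
#' shadow, 3 = snow/ice — all non-zero codes are excluded identically), an
#' acquisition date and the ground area of one pixel.
#'
#' @param bands named list of numeric matrices (default band names
#'   `EW_BANDS`); all finite and non-negative, identical dimensions.
#' @param qa integer matrix of QA codes aligned to the bands; `NULL` means
#'   all-valid.
#' @param date acquisition date (`Date` or coercible).
#' @param pixel_area ground area of one pixel in square metres (default 900,
#'   the 30 m Landsat grid).
#' @return an object of class `spectral_image`.
#' @export
spectral_image <- function(bands, qa = NULL, date = NULL, pixel_area = 900) {
  stopifnot(is.list(bands), length(bands) >= 1)
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("bands must be a named list")
  dims <- dim(bands[[1]])
  for (b in names(bands)) {
    m <- bands[[b]]
    if (!is.matrix(m) || !identical(dim(m), dims))
      stop("band '", b, "' does not share the common grid shape")
    if (any(!is.finite(m)) || any(m < 0))
      stop("band '", b, "' contains non-finite or negative reflectance")
  }
  if (is.null(qa)) qa <- matrix(EW_QA_VALID, dims[1], dims[2])
  qa <- matrix(as.integer(qa), dims[1], dims[2])
  if (!identical(dim(qa), dims)) stop("qa mask not aligned to bands")
  if (!is.null(date)) date <- as.Date(date)
  structure(list(bands = bands, qa = qa, date = date,
                 pixel_area = pixel_area),
            class = "spectral_image")
}

#' Valid-pixel mask of a spectral image
#' @param image a `spectral_image`
#' @return logical matrix, `TRUE` where the pixel is usable
#' @export
qa_valid <- function(image) image$qa == EW_QA_VALID

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat("<spectral_image> ", d[1], "x", d[2], " px, bands: ",
      paste(names(x$bands), collapse = ", "),
      if (!is.null(x$date)) paste0(", date: ", format(x$date)), "\n",
      sprintf("  valid pixels: %d/%d\n", sum(qa_valid(x)), prod(d)),
      sep = "")
  invisible(x)
}

band <- function(image, name) {
  if (!name %in% names(image$bands))
    stop("required band '", name, "' is missing from the image")
  image$bands[[name]]
}
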