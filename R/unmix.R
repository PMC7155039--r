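# Seasonal compositing and fully constrained least-squares (FCLS) spectral
# mixture analysis. Imagery inside a 6-month seasonal window is averaged
# per pixel/band over unmasked observations and the composite is unmixed
# against a 4-endmember library under non-negativity and sum-to-one
# constraints.

#' Seasonal window definition
#'
#' Snowmelt watersheds composite April-September; monsoonal watersheds
#' composite October-March, with October-December scenes labeled to the
#' following calendar year (so the "1990" monsoonal composite spans
#' Oct 1989 - Mar 1990).
#'
#' @param date Date vector
#' @param window "snowmelt" or "monsoonal"
#' @return integer composite-year labels; `NA` for dates outside the window
#' @export
composite_year <- function(date, window = c("snowmelt", "monsoonal")) {
  window <- match.arg(window)
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  if (window == "snowmelt") {
    ifelse(m >= 4 & m <= 9, y, NA_integer_)
  } else {
    ifelse(m >= 10, y + 1L, ifelse(m <= 3, y, NA_integer_))
  }
}

#' Average imagery into a single seasonal composite
#'
#' Per pixel and band, the mean over observations not QA-masked. Pixels
#' masked in every observation are invalid (QA cloud) in the composite.
#' When `year` is given, only images whose date labels to that composite
#' year are used; otherwise all supplied images must share one label.
#'
#' @param images list of `spectral_image`
#' @param window "snowmelt" or "monsoonal"
#' @param year optional composite-year label to select
#' @return a `spectral_image` composite
#' @export
seasonal_composite <- function(images, window = c("snowmelt", "monsoonal"),
                               year = NULL) {
  window <- match.arg(window)
  if (length(images) == 0) stop("empty image list")
  labs <- vapply(images, function(im) {
    if (is.null(im$date)) stop("images must carry dates for compositing")
    composite_year(im$date, window)
  }, integer(1))
  keep <- !is.na(labs) & if (is.null(year)) TRUE else labs == year
  images <- images[keep]
  if (length(images) == 0)
    stop("no image dated within the ", window, " window",
         if (!is.null(year)) paste0(" for year ", year))
  labs <- labs[keep]
  if (is.null(year) && length(unique(labs)) > 1)
    stop("images span multiple composite years; pass `year`")

  bands <- names(images[[1]]$bands)
  d <- dim(images[[1]]$bands[[1]])
  nobs <- matrix(0, d[1], d[2])
  sums <- lapply(bands, function(b) matrix(0, d[1], d[2]))
  names(sums) <- bands
  for (im in images) {
    ok <- qa_valid(im)
    nobs <- nobs + ok
    for (b in bands) sums[[b]] <- sums[[b]] + im$bands[[b]] * ok
  }
  out <- lapply(sums, function(s) {
    m <- s / pmax(nobs, 1)
    m[nobs == 0] <- 0
    m
  })
  qa <- matrix(EW_QA_VALID, d[1], d[2])
  qa[nobs == 0] <- 1L  # never observed => masked in the composite
  spectral_image(out, qa = qa, date = images[[1]]$date,
                 pixel_area = images[[1]]$pixel_area)
}

fcls_delta <- function(M) 1e3 * max(abs(M))

#' Unmix one reflectance spectrum against an endmember library
#'
#' Solves min ||s - M f||_2 subject to f >= 0 and sum(f) = 1 (fully
#' constrained least squares), via Lawson-Hanson non-negative least squares
#' on the mixing matrix augmented with a sum-to-one row weighted by
#' delta = 1e3 * max|M|. RMSE is the residual root-mean-square over bands
#' of the unaugmented system.
#'
#' @param spectrum reflectance vector, one value per library band
#' @param library an `endmember_library`
#' @return list with `fractions` (named 4-vector on the simplex) and `rmse`
#' @export
unmix_pixel <- function(spectrum, library) {
  M <- t(library$spectra)
  if (length(spectrum) != nrow(M))
    stop("spectrum length ", length(spectrum),
         " does not match library band count ", nrow(M))
  r <- .fcls_cpp(matrix(spectrum, nrow = 1), M, fcls_delta(M))
  f <- drop(r$fractions)
  names(f) <- EW_ENDMEMBERS
  list(fractions = f, rmse = r$rmse[1])
}

#' Unmix every valid pixel of a composite
#'
#' @param composite a `spectral_image` (typically from
#'   [seasonal_composite()])
#' @param library an `endmember_library`; band names must match the image
#' @return a `fraction_map`: `fractions` (nrow x ncol x 4 array in library
#'   order), `rmse` matrix, logical `valid`, `pixel_area`
#' @export
unmix_image <- function(composite, library) {
  if (!identical(sort(library$bands), sort(names(composite$bands))))
    stop("band names of composite and library differ: image has [",
         paste(names(composite$bands), collapse = ", "), "], library [",
         paste(library$bands, collapse = ", "), "]")
  M <- t(library$spectra)            # bands x 4, library band order
  d <- dim(composite$bands[[1]])
  valid <- qa_valid(composite)
  spectra <- sapply(library$bands, function(b) composite$bands[[b]][valid])
  fr <- array(NA_real_, c(d[1], d[2], 4),
              dimnames = list(NULL, NULL, EW_ENDMEMBERS))
  rmse <- matrix(NA_real_, d[1], d[2])
  if (any(valid)) {
    spectra <- matrix(spectra, ncol = length(library$bands))
    # duplicate spectra (common in composites of homogeneous cover) are
    # solved once and broadcast
    key <- do.call(paste, c(as.data.frame(spectra), sep = ","))
    first <- !duplicated(key)
    ru <- .fcls_cpp(spectra[first, , drop = FALSE], M, fcls_delta(M))
    idx <- match(key, key[first])
    r <- list(fractions = ru$fractions[idx, , drop = FALSE],
              rmse = ru$rmse[idx])
    for (k in 1:4) {
      plane <- matrix(NA_real_, d[1], d[2])
      plane[valid] <- r$fractions[, k]
      fr[, , k] <- plane
    }
    rmse[valid] <- r$rmse
  }
  structure(list(fractions = fr, rmse = rmse, valid = valid,
                 classes = EW_ENDMEMBERS,
                 pixel_area = composite$pixel_area),
            class = "fraction_map")
}

#' Water-fraction plane of a fraction map
#' @param fm a `fraction_map`
#' @param class endmember name (default "water")
#' @export
fraction_plane <- function(fm, class = "water") fm$fractions[, , class]

#' @export
print.fraction_map <- function(x, ...) {
  d <- dim(x$rmse)
  cat("<fraction_map> ", d[1], "x", d[2], " px, classes: ",
      paste(x$classes, collapse = ", "), "\n",
      sprintf("  valid: %d/%d, mean RMSE %.4g\n", sum(x$valid), prod(d),
              mean(x$rmse[x$valid])), sep = "")
  invisible(x)
}
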