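# Shared fixtures, all built in code at test time.

fixture_library <- function(seed = 1) make_library(seed)

# a small image with known band values and optional qa
fixture_image <- function(green, red = green, nir = green,
                          qa = NULL, date = NULL) {
  blue <- green * 0 + 0.05
  spectral_image(list(blue = blue, green = green, red = red, nir = nir,
                      swir1 = blue, swir2 = blue),
                 qa = qa, date = date)
}

# noiseless cloud-free bundle on a reduced grid for fast module tests
fixture_bundle <- function(seed = 7, regime = "snowmelt", grid = 32, ...) {
  simulate_series(regime_params(regime, seed = seed, grid = grid,
                                cloud_fraction = 0, noise_sd = 0, ...))
}

# random spectra drawn as noisy mixtures plus a few off-simplex outliers
fixture_random_spectra <- function(n, library, seed = 1) {
  set.seed(seed)
  M <- t(library$spectra)
  k <- ncol(M)
  F <- matrix(rexp(n * k), n, k)
  F <- F / rowSums(F)
  S <- F %*% t(M) + matrix(rnorm(n * nrow(M), 0, 0.02), n)
  pmax(S, 0)
}
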