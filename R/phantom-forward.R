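#' Forward SRS imaging model
#'
#' Produces the raw 3-band stimulated-Raman stack a microscope would record
#' from known concentrations: at every pixel the band intensities are
#' `A(x) * S %*% c(x) + noise`, where `S` is the reference-spectra matrix,
#' `c(x)` the (protein, lipid, water) concentrations, `A(x)` a smooth
#' multiplicative attenuation field in `(0, 1]` emulating heterogeneous light
#' scattering in thick tissue, and the noise is additive Gaussian sensor
#' noise clipped at zero.
#'
#' @param gt a filled `tissue_ground_truth` (see [fill_concentrations()]).
#' @param spectra a [nori_spectra()] object.
#' @param atten either a single number in `(0, 1]` (constant attenuation), a
#'   matrix (explicit per-pixel field), or a list
#'   `list(a_min, a_max, smoothness)` describing a Gaussian-smoothed random
#'   field rescaled to `[a_min, a_max]` with smoothness length in px
#'   (defaults 0.4, 1, 32).
#' @param noise_sd additive noise standard deviation in intensity units.
#' @param noise_frac alternatively, noise as a fraction of the mean noiseless
#'   band intensity (e.g. `0.01` for 1%); overrides `noise_sd`.
#' @param seed integer seed (attenuation field and noise).
#' @return An object of class `raw_srs_stack`: `bands` (side x side x 3 array,
#'   bands ordered 2853, 2935, 3420 cm^-1), `pixel_size`,
#'   `attenuation_truth`, and `noise_sd`.
#' @examples
#' gt <- sample_tissue_layout(phantom_config(side = 192, n_tubules = 2), seed = 1)
#' gt <- fill_concentrations(gt, seed = 2)
#' stack <- forward_srs(gt, nori_spectra(), atten = 1, noise_sd = 0, seed = 3)
#' dim(stack$bands)
#' @export
forward_srs <- function(gt, spectra = nori_spectra(),
                        atten = list(a_min = 0.4, a_max = 1, smoothness = 32),
                        noise_sd = 0, noise_frac = NULL, seed = 1) {
  stopifnot(inherits(gt, "tissue_ground_truth"))
  if (is.null(gt$conc))
    stop("phantom has no concentrations; call fill_concentrations() first",
         call. = FALSE)
  if (!inherits(spectra, "nori_spectra")) spectra <- nori_spectra(spectra)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, forward_impl(gt, spectra, atten, noise_sd, noise_frac))
}

forward_impl <- function(gt, spectra, atten, noise_sd, noise_frac) {
  side <- gt$side
  A <- attenuation_field(atten, side)
  S <- spectra$matrix

  conc <- cbind(as.vector(gt$conc$protein),
                as.vector(gt$conc$lipid),
                as.vector(gt$conc$water))
  clean <- conc %*% t(S)          # pixels x bands, noiseless, unattenuated
  clean <- clean * as.vector(A)
  if (!is.null(noise_frac)) {
    if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
    noise_sd <- noise_frac * mean(clean)
  }
  bands <- clean
  if (noise_sd > 0)
    bands <- bands + rnorm(length(bands), 0, noise_sd)
  bands[bands < 0] <- 0
  out <- array(bands, dim = c(side, side, 3),
               dimnames = list(NULL, NULL, c("2853", "2935", "3420")))
  structure(list(bands = out, pixel_size = gt$pixel_size,
                 attenuation_truth = A, noise_sd = noise_sd),
            class = "raw_srs_stack")
}

# Build the attenuation field for forward_srs(); see that function's docs.
attenuation_field <- function(atten, side) {
  if (is.matrix(atten)) {
    if (!identical(dim(atten), c(side, side)))
      stop("attenuation field shape does not match the image", call. = FALSE)
    if (any(atten <= 0) || any(atten > 1))
      stop("attenuation field values must lie in (0, 1]", call. = FALSE)
    return(atten)
  }
  if (is.numeric(atten) && length(atten) == 1L) {
    if (atten <= 0 || atten > 1)
      stop("constant attenuation must lie in (0, 1]", call. = FALSE)
    return(matrix(atten, side, side))
  }
  a_min <- atten$a_min %||% 0.4
  a_max <- atten$a_max %||% 1
  smoothness <- atten$smoothness %||% 32
  if (a_min <= 0 || a_min > a_max || a_max > 1)
    stop("attenuation bounds must satisfy 0 < a_min <= a_max <= 1",
         call. = FALSE)
  u <- matrix(runif(side * side), side, side)
  g <- EBImage::gblur(u, sigma = smoothness)
  rng <- range(g)
  if (diff(rng) < .Machine$double.eps) return(matrix(a_max, side, side))
  a_min + (g - rng[1]) / diff(rng) * (a_max - a_min)
}

#' @export
print.raw_srs_stack <- function(x, ...) {
  cat(sprintf(
    "raw_srs_stack: %dx%d px, bands (2853, 2935, 3420 cm^-1), noise sd %.4g\n",
    dim(x$bands)[1], dim(x$bands)[2], x$noise_sd))
  cat(sprintf("attenuation range [%.3f, %.3f]\n",
              min(x$attenuation_truth), max(x$attenuation_truth)))
  invisible(x)
}
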