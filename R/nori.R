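#' Spectral unmixing of a 3-band SRS stack
#'
#' Solves the per-pixel linear system `S %*% c = I` mapping band intensities
#' to raw (protein, lipid, water) component amounts. The closed-form inverse
#' is used everywhere; pixels where it returns a negative component (possible
#' under noise) are re-solved by exact 3-variable nonnegative least squares
#' (best feasible support enumeration), so the noiseless nonnegative solution
#' is always recovered exactly.
#'
#' @param stack a `raw_srs_stack` (or a side x side x 3 numeric array).
#' @param spectra a [nori_spectra()] object.
#' @param nonneg apply the nonnegative least-squares fallback to pixels with
#'   negative closed-form components (default `TRUE`).
#' @return A list of class `component_maps` with matrices `protein`, `lipid`,
#'   `water` (arbitrary units, same shape as the input bands) and the count
#'   of pixels that took the NNLS path.
#' @examples
#' sp <- nori_spectra()
#' I <- sp$matrix %*% c(194.3, 52.2, 753.5)
#' stack <- array(rep(I, each = 1), dim = c(1, 1, 3))
#' unlist(lapply(unmix(stack, sp)[c("protein", "lipid", "water")], as.numeric))
#' @export
unmix <- function(stack, spectra = nori_spectra(), nonneg = TRUE) {
  bands <- if (inherits(stack, "raw_srs_stack")) stack$bands else stack
  if (length(dim(bands)) != 3L || dim(bands)[3] != 3L)
    stop("stack must have exactly 3 bands", call. = FALSE)
  if (!inherits(spectra, "nori_spectra")) spectra <- nori_spectra(spectra)
  n_na <- sum(is.na(bands))
  if (n_na > 0)
    stop(sprintf("stack contains NaN/NA band values at %d pixel entries", n_na),
         call. = FALSE)
  S <- spectra$matrix
  d <- dim(bands)[1:2]
  I <- matrix(bands, ncol = 3L)
  C <- I %*% t(solve(S))
  n_nnls <- 0L
  if (nonneg) {
    neg <- which(rowSums(C < 0) > 0L)
    n_nnls <- length(neg)
    if (n_nnls > 0)
      C[neg, ] <- nnls3(S, I[neg, , drop = FALSE])
  }
  out <- list(
    protein = matrix(C[, 1], d[1], d[2]),
    lipid = matrix(C[, 2], d[1], d[2]),
    water = matrix(C[, 3], d[1], d[2]),
    n_nnls = n_nnls
  )
  class(out) <- "component_maps"
  out
}

# Exact nonnegative least squares for the 3x3 system, batched over pixels.
# Enumerates all 8 support sets, solves each by least squares, and keeps the
# feasible solution with the smallest residual. Exact for 3 variables.
nnls3 <- function(S, I) {
  n <- nrow(I)
  best <- matrix(0, n, 3)
  best_res <- rowSums(I^2)           # empty support: c = 0
  supports <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
  for (J in supports) {
    SJ <- S[, J, drop = FALSE]
    # Least-squares coefficients for all pixels at once.
    M <- solve(crossprod(SJ), t(SJ))        # |J| x 3
    CJ <- I %*% t(M)                        # n x |J|
    feas <- rowSums(CJ < -1e-12) == 0L
    if (!any(feas)) next
    fit <- CJ %*% t(SJ)
    res <- rowSums((I - fit)^2)
    take <- feas & res < best_res - 1e-12
    if (any(take)) {
      best[take, ] <- 0
      best[take, J] <- pmax(CJ[take, , drop = FALSE], 0)
      best_res[take] <- res[take]
    }
  }
  best
}

#' Normalize raw components to absolute concentrations
#'
#' The NoRI normalization: each component is divided by the per-pixel sum of
#' the three components and scaled by the total density constant, giving
#' absolute concentrations in mg/mL. Any positive per-pixel factor common to
#' all bands -- in particular light-scattering attenuation -- cancels in the
#' ratio. Background pixels (outside `tissue_mask`) and pixels with a
#' degenerate component sum are set to 0 and excluded downstream.
#'
#' @param components `component_maps` from [unmix()] (or a list with
#'   `protein`, `lipid`, `water` matrices).
#' @param rho_total total density constant in mg/mL (default 1000).
#' @param tissue_mask optional logical matrix; `NULL` treats every pixel as
#'   tissue.
#' @param pixel_size pixel size in micrometres carried into the result.
#' @param eps component sums at or below `eps * rho_total` are flagged
#'   invalid (default 1e-6).
#' @return An object of class `concentration_stack`: matrices `protein`,
#'   `lipid`, `water` in mg/mL, `rho_total`, `pixel_size`, `tissue_mask`,
#'   and `n_invalid` (degenerate tissue pixels).
#' @examples
#' comps <- list(protein = matrix(1), lipid = matrix(1), water = matrix(2))
#' conc <- nori_normalize(comps, rho_total = 1000)
#' c(conc$protein, conc$lipid, conc$water)  # 250 250 500
#' @export
nori_normalize <- function(components, rho_total = 1000, tissue_mask = NULL,
                           pixel_size = 0.414, eps = 1e-6) {
  p <- components$protein; l <- components$lipid; w <- components$water
  stopifnot(is.matrix(p), same_shape(p, l), same_shape(p, w))
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(p), ncol(p))
  if (!same_shape(p, tissue_mask))
    stop("tissue_mask shape mismatch", call. = FALSE)
  s <- p + l + w
  valid <- tissue_mask & s > eps * rho_total
  n_invalid <- sum(tissue_mask & !valid)
  scale <- ifelse(valid, rho_total / s, 0)
  structure(list(
    protein = p * scale, lipid = l * scale, water = w * scale,
    rho_total = rho_total, pixel_size = pixel_size,
    tissue_mask = valid, n_invalid = n_invalid
  ), class = "concentration_stack")
}

#' Unmix and normalize in one step
#'
#' @inheritParams unmix
#' @inheritParams nori_normalize
#' @return A `concentration_stack`; see [nori_normalize()].
#' @export
nori_concentrations <- function(stack, spectra = nori_spectra(),
                                rho_total = 1000, tissue_mask = NULL,
                                eps = 1e-6) {
  px <- if (inherits(stack, "raw_srs_stack")) stack$pixel_size else 0.414
  nori_normalize(unmix(stack, spectra), rho_total = rho_total,
                 tissue_mask = tissue_mask, pixel_size = px, eps = eps)
}

#' Tissue/background decision from raw band intensities
#'
#' A pixel is tissue when its summed band intensity exceeds
#' `factor * quantile(band sum, q)`. Useful when a stack contains true
#' background (empty slide); phantoms are tissue everywhere.
#'
#' @param stack a `raw_srs_stack`.
#' @param q quantile of the band-sum distribution (default 0.05).
#' @param factor multiplier applied to the quantile (default 2).
#' @return Logical matrix, `TRUE` for tissue pixels.
#' @export
tissue_mask_from_stack <- function(stack, q = 0.05, factor = 2) {
  bands <- if (inherits(stack, "raw_srs_stack")) stack$bands else stack
  s <- bands[, , 1] + bands[, , 2] + bands[, , 3]
  s > factor * quantile(s, q)
}

#' Per-image normalization (the non-quantitative comparator)
#'
#' Rescales each concentration plane independently to `[0, 1]` by its own
#' image minimum and maximum, emulating intensity-based histogram adjustment
#' in conventional histology. This deliberately destroys cross-image
#' comparability: two images differing only by a global concentration shift
#' become identical.
#'
#' @param conc a `concentration_stack`.
#' @return A list of class `pseudo_intensity_stack` with unit-scaled
#'   `protein`, `lipid`, `water` planes.
#' @export
denormalize_per_image <- function(conc) {
  stopifnot(inherits(conc, "concentration_stack"))
  rescale <- function(x) {
    v <- x[conc$tissue_mask]
    if (length(v) == 0L) stop("empty stack", call. = FALSE)
    rng <- range(v)
    if (diff(rng) < .Machine$double.eps) {
      warning("constant plane rescaled to 0")
      return(x * 0)
    }
    out <- (x - rng[1]) / diff(rng)
    out[!conc$tissue_mask] <- 0
    pmax(pmin(out, 1), 0)
  }
  structure(list(
    protein = rescale(conc$protein),
    lipid = rescale(conc$lipid),
    water = rescale(conc$water),
    tissue_mask = conc$tissue_mask,
    pixel_size = conc$pixel_size
  ), class = "pseudo_intensity_stack")
}

#' @export
print.concentration_stack <- function(x, ...) {
  cat(sprintf(
    "concentration_stack: %dx%d px (%.3f um/px), rho_total %g mg/mL\n",
    nrow(x$protein), ncol(x$protein), x$pixel_size, x$rho_total))
  for (pl in c("protein", "lipid", "water")) {
    v <- x[[pl]][x$tissue_mask]
    cat(sprintf("  %-7s mean %7.1f  range [%.1f, %.1f] mg/mL\n",
                pl, mean(v), min(v), max(v)))
  }
  if (x$n_invalid > 0)
    cat(sprintf("  %d invalid tissue pixel(s) flagged\n", x$n_invalid))
  invisible(x)
}
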