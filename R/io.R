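# TIFF + YAML sidecar input/output. Concentration planes are stored as
# 32-bit float pages scaled to [0, 1] by rho_total (the TIFF writer clips
# outside that range); the scale lives in the sidecar.

#' Write / read a concentration stack as multi-page TIFF
#'
#' Three 32-bit float pages (protein, lipid, water) scaled by `rho_total`,
#' with a YAML sidecar (`<path>.yaml`) recording units, `rho_total` and
#' pixel size.
#'
#' @param conc a `concentration_stack`.
#' @param path output TIFF path.
#' @return `write_concentration_tiff` returns `path` invisibly;
#'   `read_concentration_tiff` returns a `concentration_stack`.
#' @export
write_concentration_tiff <- function(conc, path) {
  stopifnot(inherits(conc, "concentration_stack"))
  pages <- lapply(conc[c("protein", "lipid", "water")],
                  function(m) m / conc$rho_total)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(
    units = "mg/mL", planes = c("protein", "lipid", "water"),
    rho_total = conc$rho_total, pixel_size_um = conc$pixel_size,
    n_invalid = conc$n_invalid
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_concentration_tiff
#' @export
read_concentration_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  p <- pages[[1]] * meta$rho_total
  l <- pages[[2]] * meta$rho_total
  w <- pages[[3]] * meta$rho_total
  structure(list(
    protein = p, lipid = l, water = w,
    rho_total = meta$rho_total, pixel_size = meta$pixel_size_um,
    tissue_mask = (p + l + w) > 0, n_invalid = meta$n_invalid %||% 0L
  ), class = "concentration_stack")
}

#' Write / read a raw SRS stack as multi-page TIFF
#'
#' Three 32-bit float pages (2853, 2935, 3420 cm^-1 bands) scaled to `[0, 1]`
#' by the recorded maximum intensity.
#'
#' @param stack a `raw_srs_stack`.
#' @param path output TIFF path.
#' @return `path` invisibly / a `raw_srs_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "raw_srs_stack"))
  scale <- max(stack$bands, 1e-12)
  pages <- lapply(1:3, function(b) stack$bands[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(
    bands = c("2853", "2935", "3420"), intensity_scale = scale,
    pixel_size_um = stack$pixel_size, noise_sd = stack$noise_sd
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- dim(pages[[1]])
  bands <- array(0, dim = c(side[1], side[2], 3),
                 dimnames = list(NULL, NULL, c("2853", "2935", "3420")))
  for (b in 1:3) bands[, , b] <- pages[[b]] * meta$intensity_scale
  structure(list(bands = bands, pixel_size = meta$pixel_size_um,
                 attenuation_truth = NULL,
                 noise_sd = meta$noise_sd %||% NA_real_),
            class = "raw_srs_stack")
}

#' Write / read an integer label image as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background, labels < 65536).
#' @param path output TIFF path.
#' @return `path` invisibly / an integer matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot_matrix(labels)
  if (max(labels) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write / read a binary mask as 8-bit TIFF
#'
#' @param mask logical matrix.
#' @param path output TIFF path.
#' @return `path` invisibly / a logical matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(as_mask(mask) * 1.0, path, bits.per.sample = 8L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write a phantom's ground truth to a directory
#'
#' Concentration planes (32-bit multi-page TIFF), instance labels (16-bit),
#' one 8-bit mask per substructure, and a YAML sidecar with seed, pixel size
#' and density constant.
#'
#' @param gt a filled `tissue_ground_truth`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "tissue_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(gt$conc)) {
    conc <- structure(list(
      protein = gt$conc$protein, lipid = gt$conc$lipid, water = gt$conc$water,
      rho_total = gt$rho_total, pixel_size = gt$pixel_size,
      tissue_mask = matrix(TRUE, gt$side, gt$side), n_invalid = 0L),
      class = "concentration_stack")
    write_concentration_tiff(conc, file.path(dir, "concentrations.tif"))
  }
  write_label_tiff(gt$tubule_labels, file.path(dir, "tubule_labels.tif"))
  write_label_tiff(gt$droplet_labels, file.path(dir, "droplet_labels.tif"))
  for (nm in names(gt$masks))
    write_mask_tiff(gt$masks[[nm]], file.path(dir, paste0("mask_", nm, ".tif")))
  yaml::write_yaml(list(
    seed = gt$seed, pixel_size_um = gt$pixel_size,
    rho_total = gt$rho_total, side = gt$side,
    tubule_types = as.list(table(gt$tubules$type))
  ), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Write a feature table with a YAML schema sidecar
#'
#' @param table a feature `data.frame`.
#' @param path output CSV path; the sidecar is `<path>.yaml`.
#' @return `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  units <- list(
    tubule_id = "instance label", cytoplasm_protein = "mg/mL",
    cytoplasm_lipid = "mg/mL", nuclear_protein = "mg/mL",
    nucleolus_protein = "mg/mL", brush_border_protein = "mg/mL",
    brush_border_lipid = "mg/mL", lumen_protein = "mg/mL",
    droplet_lipid = "mg/mL", nuclei_area_fraction = "fraction of footprint",
    area_um2 = "um^2", perimeter_um = "um",
    equivalent_diameter_um = "um", eccentricity = "dimensionless")
  yaml::write_yaml(units[intersect(names(units), names(table))],
                   paste0(path, ".yaml"))
  invisible(path)
}
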