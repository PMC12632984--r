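#' Cytoplasm compartment by mask subtraction
#'
#' The cytoplasm of a tubule is its footprint minus the segmented nuclei,
#' nucleoli, lumen and brush-border regions.
#'
#' @param tubule binary footprint of one tubule.
#' @param nuclei,nucleoli,lumen,brush_border binary substructure maps of the
#'   same shape (`NULL` treated as empty).
#' @return A binary map; an all-empty result carries attribute
#'   `empty = TRUE`.
#' @export
cytoplasm_mask <- function(tubule, nuclei = NULL, nucleoli = NULL,
                           lumen = NULL, brush_border = NULL) {
  tubule <- as_mask(tubule)
  out <- tubule
  for (m in list(nuclei, nucleoli, lumen, brush_border)) {
    if (is.null(m)) next
    if (!same_shape(m, tubule)) stop("mask shape mismatch", call. = FALSE)
    out <- out & !as_mask(m)
  }
  if (!any(out)) attr(out, "empty") <- TRUE
  out
}

# Mask-restricted mean; structures with no pixels yield NA (missing, never 0).
masked_mean <- function(plane, mask) {
  if (!any(mask)) return(NA_real_)
  mean(plane[mask])
}

#' Summarize one tubule into a feature-table row
#'
#' Computes per-structure mean concentrations over the tubule's pixels
#' (cytoplasm protein/lipid, nuclear protein excluding nucleoli, brush-border
#' protein/lipid, lumen protein), the nuclear area fraction (nuclear envelope
#' = nuclei + nucleoli pixels over footprint pixels), and footprint geometry
#' at the stated pixel size (area um^2, perimeter um, equivalent diameter um,
#' eccentricity). Structures with zero pixels are reported as `NA`, never 0.
#'
#' @param conc a `concentration_stack`.
#' @param masks a `mask_set` carrying substructure maps.
#' @param tubule_id instance label present in the label map.
#' @return A one-row `data.frame`.
#' @export
summarize_tubule <- function(conc, masks, tubule_id) {
  stopifnot(inherits(conc, "concentration_stack"), inherits(masks, "mask_set"))
  inst <- masks$tubule_labels == tubule_id
  if (!any(inst))
    stop(sprintf("tubule_id %s not present in label map", tubule_id),
         call. = FALSE)
  gm <- function(name) {
    m <- masks$masks[[name]]
    if (is.null(m)) inst & FALSE else inst & m
  }
  nuclei <- gm("nuclei"); nucleoli <- gm("nucleoli")
  lumen <- gm("lumen"); brush <- gm("brush_border")
  droplets <- gm("lipid_droplets")
  cyto <- inst & !nuclei & !nucleoli & !lumen & !brush & !droplets

  px <- conc$pixel_size
  area_px <- sum(inst)
  geom <- footprint_geometry(inst, px)

  data.frame(
    tubule_id = tubule_id,
    cytoplasm_protein = masked_mean(conc$protein, cyto),
    cytoplasm_lipid = masked_mean(conc$lipid, cyto),
    nuclear_protein = masked_mean(conc$protein, nuclei),
    nucleolus_protein = masked_mean(conc$protein, nucleoli),
    brush_border_protein = masked_mean(conc$protein, brush),
    brush_border_lipid = masked_mean(conc$lipid, brush),
    lumen_protein = masked_mean(conc$protein, lumen),
    droplet_lipid = masked_mean(conc$lipid, droplets),
    nuclei_area_fraction = (sum(nuclei) + sum(nucleoli)) / area_px,
    area_um2 = geom$area_um2,
    perimeter_um = geom$perimeter_um,
    equivalent_diameter_um = geom$equivalent_diameter_um,
    eccentricity = geom$eccentricity,
    stringsAsFactors = FALSE
  )
}

# Footprint geometry from the instance mask: area, boundary-pixel perimeter,
# equivalent circular diameter, moment-based eccentricity.
footprint_geometry <- function(inst, pixel_size) {
  area_px <- sum(inst)
  idx <- which(inst, arr.ind = TRUE)
  mu_y <- mean(idx[, 1]); mu_x <- mean(idx[, 2])
  cyy <- mean((idx[, 1] - mu_y)^2); cxx <- mean((idx[, 2] - mu_x)^2)
  cxy <- mean((idx[, 1] - mu_y) * (idx[, 2] - mu_x))
  tr <- cyy + cxx
  det_ <- cyy * cxx - cxy^2
  disc <- max(0, (tr / 2)^2 - det_)
  l1 <- tr / 2 + sqrt(disc); l2 <- tr / 2 - sqrt(disc)
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(
    area_um2 = area_px * pixel_size^2,
    perimeter_um = sum(boundary_pixels(inst)) * pixel_size,
    equivalent_diameter_um = 2 * sqrt(area_px / pi) * pixel_size,
    eccentricity = ecc
  )
}

#' Per-tubule feature table
#'
#' Applies [summarize_tubule()] to every instance and joins per-tubule
#' metadata (type, depth) when `gt` is supplied.
#'
#' @param conc a `concentration_stack`.
#' @param masks a `mask_set`.
#' @param gt optional `tissue_ground_truth` providing `type` and `depth`
#'   columns (matched by instance label).
#' @return A `data.frame`, one row per tubule.
#' @export
tubule_feature_table <- function(conc, masks, gt = NULL) {
  ids <- sort(unique(masks$tubule_labels[masks$tubule_labels > 0L]))
  if (length(ids) == 0L)
    return(data.frame())
  tab <- do.call(rbind, lapply(ids, function(i)
    summarize_tubule(conc, masks, i)))
  if (!is.null(gt)) {
    m <- match(tab$tubule_id, gt$tubules$tubule)
    tab$type <- gt$tubules$type[m]
    tab$depth <- gt$tubules$depth[m]
  }
  tab
}

#' Interstitial (microvasculature) protein summary
#'
#' Mean protein concentration over tissue pixels outside every tubule
#' instance, excluding a dilation ring of `margin` px around tubule
#' boundaries to avoid edge bleed.
#'
#' @param conc a `concentration_stack`.
#' @param masks a `mask_set`.
#' @param margin exclusion margin around tubules in px (default 2).
#' @return Mean protein in mg/mL, or `NA` if the interstitium is empty.
#' @export
microvasculature_protein <- function(conc, masks, margin = 2) {
  stopifnot(inherits(conc, "concentration_stack"), inherits(masks, "mask_set"))
  tub <- masks$tubule_labels > 0L
  if (margin > 0) {
    kern <- EBImage::makeBrush(2 * ceiling(margin) + 1, shape = "disc")
    tub <- EBImage::dilate(tub, kern) > 0
  }
  inter <- !tub & conc$tissue_mask
  if (!any(inter)) return(NA_real_)
  mean(conc$protein[inter])
}

#' Cortex-to-medulla concentration trend
#'
#' Ordinary least squares of a per-tubule concentration on normalized depth
#' (0 = cortex edge, 1 = medulla edge).
#'
#' @param table a feature table with a `depth` column.
#' @param response name of the concentration column (default
#'   `"cytoplasm_protein"`).
#' @return A list with `slope` (mg/mL per unit depth), `r_squared`, and
#'   `p_value`.
#' @export
cortex_medulla_trend <- function(table, response = "cytoplasm_protein") {
  if (!all(c("depth", response) %in% names(table)))
    stop("table must contain `depth` and the response column", call. = FALSE)
  d <- table[stats::complete.cases(table[, c("depth", response)]), ]
  if (nrow(d) < 3L)
    stop("need at least 3 tubules with depth values", call. = FALSE)
  if (stats::sd(d$depth) == 0)
    stop("depth is constant; trend undefined", call. = FALSE)
  if (stats::sd(d[[response]]) == 0)
    return(list(slope = 0, r_squared = 0, p_value = 1))
  fit <- stats::lm(stats::reformulate("depth", response), data = d)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}
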