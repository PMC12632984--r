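#' Extract candidate pixels by intensity threshold
#'
#' Selects the pixels of a region whose statistic passes a threshold in the
#' stated direction. The statistic image is typically a single concentration
#' plane or the max-projection of several planes (see [max_projection()]).
#'
#' @param x numeric statistic matrix.
#' @param region_mask non-empty binary map restricting the search.
#' @param threshold intensity threshold.
#' @param direction `"below"` (strictly less) or `"above"` (strictly greater).
#' @return An n x 2 integer matrix of (row, col) pixel coordinates; empty
#'   with a warning when the threshold selects nothing.
#' @export
extract_candidate_pixels <- function(x, region_mask, threshold,
                                     direction = c("below", "above")) {
  direction <- match.arg(direction)
  stopifnot_matrix(x)
  region_mask <- as_mask(region_mask)
  if (!same_shape(x, region_mask)) stop("shape mismatch", call. = FALSE)
  if (!any(region_mask)) stop("region_mask is empty", call. = FALSE)
  sel <- if (direction == "below") x < threshold else x > threshold
  sel <- sel & region_mask
  if (!any(sel)) {
    rng <- range(x[region_mask])
    if (threshold < rng[1] || threshold > rng[2])
      warning(sprintf(
        "threshold %g outside region data range [%g, %g]: empty pixel set",
        threshold, rng[1], rng[2]))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  idx <- which(sel, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Max-projection of concentration planes
#'
#' @param conc a `concentration_stack`.
#' @param channels planes to project (default protein and lipid; the water
#'   plane is near-constant in tissue and would erase contrast).
#' @return A numeric matrix of per-pixel maxima.
#' @export
max_projection <- function(conc, channels = c("protein", "lipid")) {
  stopifnot(inherits(conc, "concentration_stack"), length(channels) >= 1)
  Reduce(pmax, conc[channels])
}

#' Single-linkage agglomeration of a pixel set
#'
#' Agglomerative hierarchical clustering of pixel coordinates cut at a
#' Euclidean distance threshold. With single linkage this equals the
#' connected components of the graph joining every pixel pair at distance
#' `<= distance_threshold`, which is how it is computed (bucketed union-find;
#' no n^2 distance matrix). Clusters below `min_size` pixels are discarded.
#' Defaults are the 5 px / 75 px detector settings.
#'
#' @param pixels n x 2 matrix of (row, col) coordinates.
#' @param distance_threshold Euclidean linkage cutoff in px (> 0).
#' @param min_size minimum retained cluster size in pixels (>= 1).
#' @return An object of class `pixel_cluster_set`: `clusters` (list of
#'   coordinate matrices, ordered by first pixel), `n_discarded`,
#'   `distance_threshold`, `min_size`.
#' @examples
#' px <- rbind(cbind(1:5, 1), cbind(1:5, 20))
#' length(agglomerate(px, 5, min_size = 1)$clusters)  # 2 separated blobs
#' @export
agglomerate <- function(pixels, distance_threshold = 5, min_size = 75) {
  if (distance_threshold <= 0) stop("distance_threshold must be > 0", call. = FALSE)
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (n == 0L)
    return(structure(list(clusters = list(), n_discarded = 0L,
                          distance_threshold = distance_threshold,
                          min_size = min_size,
                          source_channel = NULL, threshold_used = NULL,
                          direction = NULL),
                     class = "pixel_cluster_set"))

  comp <- union_find_components(pixels, distance_threshold)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_size)
  clusters <- lapply(keep, function(k) {
    m <- pixels[comp == k, , drop = FALSE]
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
  ord <- order(vapply(clusters, function(m) m[1, 1] * 1e6 + m[1, 2], numeric(1)))
  structure(list(clusters = clusters[ord],
                 n_discarded = length(sizes) - length(keep),
                 distance_threshold = distance_threshold,
                 min_size = min_size,
                 source_channel = NULL, threshold_used = NULL,
                 direction = NULL),
            class = "pixel_cluster_set")
}

# Connected components of the <=threshold pixel graph, exactly. Pixel
# coordinates are integer grid positions, so the neighbourhood of a pixel is
# a fixed set of integer offsets with dy^2 + dx^2 <= threshold^2; close pairs
# are found by hashed coordinate lookup (no n^2 distance matrix) and the
# components come from the resulting graph.
union_find_components <- function(pixels, threshold) {
  n <- nrow(pixels)
  if (n == 1L) return(1L)
  r <- floor(threshold)
  offs <- expand.grid(dy = 0:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= threshold^2 &
                 (offs$dy > 0 | offs$dx > 0), , drop = FALSE]
  K <- max(pixels[, 2]) - min(pixels[, 2]) + 2 * r + 3
  keys <- (pixels[, 1] - min(pixels[, 1])) * K +
          (pixels[, 2] - min(pixels[, 2]))
  ei <- integer(0); ej <- integer(0)
  for (k in seq_len(nrow(offs))) {
    j <- match(keys + offs$dy[k] * K + offs$dx[k], keys)
    i <- which(!is.na(j))
    if (length(i)) { ei <- c(ei, i); ej <- c(ej, j[i]) }
  }
  if (length(ei) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  match(memb, unique(memb))
}

#' Detect luminal regions
#'
#' Low-intensity pixel clustering inside segmented tubules: candidate pixels
#' fall below a predefined threshold on the max-projection of the protein
#' and lipid planes, then single-linkage agglomeration at 5 px with the
#' 75-px size filter. Because NoRI concentrations are absolutely calibrated,
#' the default threshold is a fixed 40 mg/mL -- chosen to sit between
#' luminal protein levels and the lipid-droplet lipid distribution and
#' transferable across images; a fraction-of-median mode is available via
#' `threshold_frac`. Clusters whose mean lipid exceeds `lipid_max` are
#' discarded: luminal fluid is lipid-poor, so a low-intensity cluster with
#' appreciable lipid is a droplet, not a lumen.
#'
#' @param conc a `concentration_stack`.
#' @param region_mask binary map of the search region (typically the tubule
#'   footprints).
#' @param threshold absolute max-projection threshold in mg/mL (default 40).
#' @param threshold_frac if non-`NULL`, overrides `threshold` with this
#'   fraction of the region's median max-projection intensity.
#' @param lipid_max maximum mean lipid (mg/mL) of a retained lumen cluster.
#' @param distance_threshold,min_size see [agglomerate()].
#' @return A `pixel_cluster_set`.
#' @export
detect_lumens <- function(conc, region_mask, threshold = 40,
                          threshold_frac = NULL, lipid_max = 20,
                          distance_threshold = 5, min_size = 75) {
  mp <- max_projection(conc)
  thr <- if (!is.null(threshold_frac))
    threshold_frac * median(mp[as_mask(region_mask)]) else threshold
  px <- extract_candidate_pixels(mp, region_mask, thr, "below")
  out <- agglomerate(px, distance_threshold, min_size)
  if (length(out$clusters) && is.finite(lipid_max)) {
    keep <- vapply(out$clusters,
                   function(m) mean(conc$lipid[m]) <= lipid_max, logical(1))
    out$n_discarded <- out$n_discarded + sum(!keep)
    out$clusters <- out$clusters[keep]
  }
  out$source_channel <- "max_projection(protein, lipid)"
  out$threshold_used <- thr
  out$direction <- "below"
  out
}

#' Detect lipid droplets
#'
#' Default mode `"protein_below"` follows the low-intensity reading: droplets
#' are protein-poor relative to cytoplasm, so candidate pixels fall below a
#' fraction of the region's median protein concentration, making detection
#' independent of each droplet's lipid content. Mode `"lipid_above"` instead
#' selects pixels above the region's lipid mean + 2 SD.
#'
#' @param conc a `concentration_stack`.
#' @param region_mask binary search region (typically cytoplasm).
#' @param mode `"protein_below"` or `"lipid_above"`.
#' @param threshold_frac fraction of median protein for `"protein_below"`.
#' @param distance_threshold,min_size see [agglomerate()].
#' @return A `pixel_cluster_set`.
#' @export
detect_droplets <- function(conc, region_mask,
                            mode = c("protein_below", "lipid_above"),
                            threshold_frac = 0.5,
                            distance_threshold = 5, min_size = 75) {
  mode <- match.arg(mode)
  region_mask <- as_mask(region_mask)
  if (mode == "protein_below") {
    thr <- threshold_frac * median(conc$protein[region_mask])
    px <- extract_candidate_pixels(conc$protein, region_mask, thr, "below")
    src <- "protein"; dir <- "below"
  } else {
    v <- conc$lipid[region_mask]
    thr <- mean(v) + 2 * sd(v)
    px <- extract_candidate_pixels(conc$lipid, region_mask, thr, "above")
    src <- "lipid"; dir <- "above"
  }
  out <- agglomerate(px, distance_threshold, min_size)
  out$source_channel <- src
  out$threshold_used <- thr
  out$direction <- dir
  out
}

#' Per-droplet morphometry
#'
#' @param clusters a `pixel_cluster_set` from droplet detection.
#' @param conc a `concentration_stack`.
#' @return A `data.frame`, one row per cluster: `size_px`,
#'   `equivalent_diameter_um`, `volume_um3` (sphere of the equivalent
#'   diameter), and `mean_lipid` in mg/mL.
#' @export
droplet_morphometry <- function(clusters, conc) {
  stopifnot(inherits(clusters, "pixel_cluster_set"),
            inherits(conc, "concentration_stack"))
  if (length(clusters$clusters) == 0L)
    return(data.frame(cluster = integer(0), size_px = integer(0),
                      equivalent_diameter_um = numeric(0),
                      volume_um3 = numeric(0), mean_lipid = numeric(0)))
  px <- conc$pixel_size
  do.call(rbind, lapply(seq_along(clusters$clusters), function(i) {
    m <- clusters$clusters[[i]]
    n <- nrow(m)
    d_um <- 2 * sqrt(n / pi) * px
    data.frame(cluster = i, size_px = n,
               equivalent_diameter_um = d_um,
               volume_um3 = (4 / 3) * pi * (d_um / 2)^3,
               mean_lipid = mean(conc$lipid[m]))
  }))
}

#' Binary mask of a cluster set
#'
#' @param clusters a `pixel_cluster_set`.
#' @param dim dimensions `c(nrow, ncol)` of the output mask.
#' @return A logical matrix covering every retained cluster.
#' @export
clusters_to_mask <- function(clusters, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (cl in clusters$clusters) m[cl] <- TRUE
  m
}

#' @export
print.pixel_cluster_set <- function(x, ...) {
  cat(sprintf(
    "pixel_cluster_set: %d cluster(s) retained (>= %d px), %d discarded; linkage %.3g px\n",
    length(x$clusters), x$min_size, x$n_discarded, x$distance_threshold))
  if (!is.null(x$source_channel))
    cat(sprintf("  %s %s %.4g\n", x$source_channel, x$direction,
                x$threshold_used))
  invisible(x)
}
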