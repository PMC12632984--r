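#' Phantom layout configuration
#'
#' Parameters of the synthetic kidney-tissue layout generator. All lengths are
#' in pixels at `pixel_size` um/px (default 0.414, matching a 60x/1.2NA
#' acquisition). Tubules are annular epithelial rings around a central lumen;
#' proximal tubules additionally carry a brush-border ring lining the lumen;
#' each tubule holds 1-3 elliptical nuclei (each with 0-2 nucleoli) placed at
#' an exact drawn nuclear area fraction, plus a Poisson number of circular
#' lipid droplets in the cytoplasm. Inter-tubule space is interstitial
#' microvasculature.
#'
#' @param side image side in pixels (>= 128).
#' @param n_tubules number of tubule instances to place (>= 1).
#' @param pixel_size pixel size in micrometres.
#' @param tubule_radius range (min, max) of outer tubule radii in px.
#' @param lumen_frac lumen radius as a fraction of the outer radius.
#' @param brush_px brush-border thickness in px (proximal tubules only).
#' @param type_probs named probabilities for tubule types
#'   `proximal`, `distal`, `collecting_duct`.
#' @param nuclei_count integer range (min, max) of nuclei per tubule.
#' @param nuclei_fraction `c(mean, sd)` of the per-tubule nuclear area
#'   fraction prior (default 0.129 +/- 0.047); draws are clamped to
#'   `[0.02, 0.35]`.
#' @param nucleoli_count integer range (min, max) of nucleoli per nucleus.
#' @param nucleolus_radius radius range of nucleoli in px.
#' @param droplet_lambda Poisson mean of lipid droplets per tubule.
#' @param droplet_radius radius range of lipid droplets in px.
#' @param min_gap minimum clearance between tubule footprints in px.
#' @param margin clearance between tubules and the image border in px.
#' @param min_area minimum tubule footprint area in px.
#' @param max_retries placement retries per tubule before giving up.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(side = 512, n_tubules = 12, pixel_size = 0.414,
                           tubule_radius = c(18, 26), lumen_frac = 0.42,
                           brush_px = 2,
                           type_probs = c(proximal = 0.4, distal = 0.35,
                                          collecting_duct = 0.25),
                           nuclei_count = c(1, 3),
                           nuclei_fraction = c(mean = 0.129, sd = 0.047),
                           nucleoli_count = c(0, 2),
                           nucleolus_radius = c(1.5, 2.5),
                           droplet_lambda = 2, droplet_radius = c(5.2, 7),
                           min_gap = 4, margin = 2, min_area = 150,
                           max_retries = 200) {
  cfg <- list(side = side, n_tubules = n_tubules, pixel_size = pixel_size,
              tubule_radius = tubule_radius, lumen_frac = lumen_frac,
              brush_px = brush_px, type_probs = type_probs,
              nuclei_count = nuclei_count, nuclei_fraction = nuclei_fraction,
              nucleoli_count = nucleoli_count,
              nucleolus_radius = nucleolus_radius,
              droplet_lambda = droplet_lambda, droplet_radius = droplet_radius,
              min_gap = min_gap, margin = margin, min_area = min_area,
              max_retries = max_retries)
  bad <- character(0)
  if (!is.numeric(side) || side < 128) bad <- c(bad, "side (must be >= 128)")
  if (!is.numeric(n_tubules) || n_tubules < 1) bad <- c(bad, "n_tubules (>= 1)")
  if (pixel_size <= 0) bad <- c(bad, "pixel_size (> 0)")
  if (length(tubule_radius) != 2 || any(tubule_radius <= 0) ||
      tubule_radius[1] > tubule_radius[2]) bad <- c(bad, "tubule_radius")
  if (lumen_frac <= 0 || lumen_frac >= 0.8) bad <- c(bad, "lumen_frac ((0, 0.8))")
  if (brush_px < 0) bad <- c(bad, "brush_px (>= 0)")
  if (length(type_probs) != 3 || any(type_probs < 0) || sum(type_probs) <= 0 ||
      !setequal(names(type_probs), c("proximal", "distal", "collecting_duct")))
    bad <- c(bad, "type_probs")
  if (nuclei_fraction[1] <= 0 || nuclei_fraction[2] < 0)
    bad <- c(bad, "nuclei_fraction")
  if (droplet_lambda < 0) bad <- c(bad, "droplet_lambda")
  if (any(droplet_radius <= 0)) bad <- c(bad, "droplet_radius")
  if (min_gap < 0 || margin < 0) bad <- c(bad, "min_gap/margin (>= 0)")
  if (pi * tubule_radius[1]^2 < min_area)
    bad <- c(bad, "min_area (unreachable at tubule_radius minimum)")
  if (length(bad))
    stop("invalid phantom configuration fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Sample a synthetic kidney-tissue layout
#'
#' Places non-overlapping annular tubules with their substructure masks
#' (lumen, brush border on proximal tubules, nuclei with nucleoli, lipid
#' droplets); inter-tubule space is labelled interstitial microvasculature.
#' Deterministic for a fixed `(config, seed)` pair. Concentrations are not
#' filled; see [fill_concentrations()].
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return An object of class `tissue_ground_truth` with fields
#'   `tubule_labels` (integer instance map, 0 = interstitium),
#'   `masks` (binary maps: `nuclei`, `nucleoli`, `lumen`, `brush_border`,
#'   `lipid_droplets`, `microvasculature`), `droplet_labels` (integer map of
#'   droplet instances), `tubules` (per-instance table: type, centre, radii,
#'   drawn nuclear area fraction, normalized cortex-to-medulla depth),
#'   `pixel_size`, and `seed`. Substructure masks are pairwise disjoint and
#'   contained in their tubule's footprint.
#' @examples
#' gt <- sample_tissue_layout(phantom_config(side = 192, n_tubules = 3), seed = 1)
#' table(gt$tubules$type)
#' @export
sample_tissue_layout <- function(config = phantom_config(), seed = 1) {
  if (!inherits(config, "phantom_config"))
    config <- do.call(phantom_config, config)
  with_seed(seed, sample_layout_impl(config, seed))
}

sample_layout_impl <- function(cfg, seed) {
  side <- as.integer(cfg$side)
  n <- as.integer(cfg$n_tubules)
  labels <- matrix(0L, side, side)
  droplet_labels <- matrix(0L, side, side)
  masks <- list(
    nuclei = matrix(FALSE, side, side),
    nucleoli = matrix(FALSE, side, side),
    lumen = matrix(FALSE, side, side),
    brush_border = matrix(FALSE, side, side),
    lipid_droplets = matrix(FALSE, side, side)
  )

  types <- sample(names(cfg$type_probs), n, replace = TRUE,
                  prob = cfg$type_probs / sum(cfg$type_probs))
  radii <- runif(n, cfg$tubule_radius[1], cfg$tubule_radius[2])

  # Non-overlapping placement by rejection sampling.
  cy <- numeric(n); cx <- numeric(n)
  for (i in seq_len(n)) {
    lo <- radii[i] + cfg$margin + 1
    hi <- side - radii[i] - cfg$margin
    if (hi <= lo)
      stop("tubule radius too large for image side", call. = FALSE)
    ok <- FALSE
    for (try in seq_len(cfg$max_retries)) {
      y <- runif(1, lo, hi); x <- runif(1, lo, hi)
      if (i == 1L ||
          all(sqrt((cy[seq_len(i - 1)] - y)^2 + (cx[seq_len(i - 1)] - x)^2) >
              radii[seq_len(i - 1)] + radii[i] + cfg$min_gap)) {
        cy[i] <- y; cx[i] <- x; ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not place tubule %d of %d after %d retries: requested density too high for side %d",
        i, n, cfg$max_retries, side), call. = FALSE)
  }

  nf_mean <- cfg$nuclei_fraction[[1]]; nf_sd <- cfg$nuclei_fraction[[2]]
  nf_drawn <- numeric(n)
  droplet_id <- 0L
  droplet_tubule <- integer(0)

  for (i in seq_len(n)) {
    r_out <- radii[i]
    r_lum <- cfg$lumen_frac * r_out
    brush <- if (types[i] == "proximal") cfg$brush_px else 0

    rows <- max(1L, floor(cy[i] - r_out - 1)):min(side, ceiling(cy[i] + r_out + 1))
    cols <- max(1L, floor(cx[i] - r_out - 1)):min(side, ceiling(cx[i] + r_out + 1))
    dy <- rows - cy[i]; dx <- cols - cx[i]
    d2 <- outer(dy^2, dx^2, "+")
    foot <- d2 <= r_out^2
    lum <- d2 <= r_lum^2
    br <- if (brush > 0) (d2 <= (r_lum + brush)^2) & !lum else foot & FALSE

    sub <- function(m, v) { m[rows, cols][v] <- TRUE; m }
    labels[rows, cols][foot] <- i
    masks$lumen <- sub(masks$lumen, lum)
    if (brush > 0) masks$brush_border <- sub(masks$brush_border, br)

    # Epithelial ring available for nuclei: clear of lumen/brush and of the
    # outer boundary so nuclei stay inside the footprint.
    ring <- d2 > (r_lum + brush + 1)^2 & d2 <= (r_out - 1)^2
    foot_area <- sum(foot)

    # Draw the nuclear area fraction and realize it exactly in pixels.
    f <- min(0.35, max(0.02, rnorm(1, nf_mean, nf_sd)))
    nf_drawn[i] <- f
    target <- round(f * foot_area)
    k <- sample(seq(cfg$nuclei_count[1], cfg$nuclei_count[2]), 1)
    w <- runif(k); w <- w / sum(w)
    targets <- floor(target * w)
    targets[1] <- targets[1] + (target - sum(targets))

    allowed <- ring
    nuc_local <- vector("list", k)
    for (j in seq_len(k)) {
      if (targets[j] <= 0) { nuc_local[[j]] <- allowed & FALSE; next }
      theta <- runif(1, 0, 2 * pi)
      dc <- runif(1, r_lum + brush + 2, max(r_lum + brush + 2, r_out - 3))
      ny <- cy[i] + dc * sin(theta); nx <- cx[i] + dc * cos(theta)
      alpha <- runif(1, 0, pi)
      aspect <- runif(1, 0.55, 0.95)
      idx <- which(allowed, arr.ind = TRUE)
      if (nrow(idx) == 0L) { nuc_local[[j]] <- allowed & FALSE; next }
      py <- rows[idx[, 1]]; px <- cols[idx[, 2]]
      u <- (py - ny) * cos(alpha) + (px - nx) * sin(alpha)
      v <- -(py - ny) * sin(alpha) + (px - nx) * cos(alpha)
      m <- (u / aspect)^2 + v^2
      take <- head(order(m, idx[, 1], idx[, 2]),
                   min(targets[j], nrow(idx)))
      nm <- allowed & FALSE
      nm[idx[take, , drop = FALSE]] <- TRUE
      nuc_local[[j]] <- nm
      allowed <- allowed & !nm
    }
    nuc_all <- Reduce(`|`, nuc_local)

    # Nucleoli: small discs carved out of each nucleus (masks stay disjoint;
    # the nuclear envelope is nuclei + nucleoli).
    nol_all <- nuc_all & FALSE
    for (j in seq_len(k)) {
      nm <- nuc_local[[j]]
      npx <- which(nm, arr.ind = TRUE)
      if (nrow(npx) < 20L) next
      n_nol <- sample(seq(cfg$nucleoli_count[1], cfg$nucleoli_count[2]), 1)
      for (q in seq_len(n_nol)) {
        rho <- runif(1, cfg$nucleolus_radius[1], cfg$nucleolus_radius[2])
        tgt <- max(4L, round(pi * rho^2))
        avail <- which(nm & !nol_all, arr.ind = TRUE)
        if (nrow(avail) <= tgt) break
        ctr <- avail[sample(nrow(avail), 1), ]
        dd <- (avail[, 1] - ctr[1])^2 + (avail[, 2] - ctr[2])^2
        take <- head(order(dd, avail[, 1], avail[, 2]), tgt)
        nol_all[avail[take, , drop = FALSE]] <- TRUE
      }
    }
    nuc_all <- nuc_all & !nol_all
    masks$nuclei <- sub(masks$nuclei, nuc_all)
    masks$nucleoli <- sub(masks$nucleoli, nol_all)

    # Lipid droplets: circular, fully inside the remaining cytoplasm.
    cyto_free <- foot & d2 <= (r_out - 1)^2 & !lum & !br & !nuc_all & !nol_all
    n_d <- rpois(1, cfg$droplet_lambda)
    for (q in seq_len(n_d)) {
      rho <- runif(1, cfg$droplet_radius[1], cfg$droplet_radius[2])
      placed <- FALSE
      for (try in seq_len(50L)) {
        avail <- which(cyto_free, arr.ind = TRUE)
        if (nrow(avail) == 0L) break
        ctr <- avail[sample(nrow(avail), 1), ]
        ddy <- seq_along(rows) - ctr[1]; ddx <- seq_along(cols) - ctr[2]
        dd2 <- outer(ddy^2, ddx^2, "+")
        disc <- dd2 <= rho^2
        if (all(cyto_free[disc])) {
          droplet_id <- droplet_id + 1L
          droplet_tubule <- c(droplet_tubule, i)
          masks$lipid_droplets <- sub(masks$lipid_droplets, disc)
          droplet_labels[rows, cols][disc] <- droplet_id
          cyto_free <- cyto_free & !disc
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
  }

  areas <- tabulate(labels[labels > 0L], nbins = n)
  if (any(areas < cfg$min_area))
    stop("tubule footprint below configured minimum area", call. = FALSE)

  masks$microvasculature <- labels == 0L

  structure(list(
    tubule_labels = labels,
    droplet_labels = droplet_labels,
    masks = masks,
    tubules = data.frame(
      tubule = seq_len(n), type = types, cy = cy, cx = cx,
      r_out = radii, r_lumen = cfg$lumen_frac * radii,
      nuclei_fraction_drawn = nf_drawn,
      depth = (cy - 1) / (side - 1),
      stringsAsFactors = FALSE),
    droplet_tubule = droplet_tubule,
    conc = NULL,
    rho_total = NULL,
    pixel_size = cfg$pixel_size,
    side = side,
    config = cfg,
    seed = seed,
    metadata = list()
  ), class = "tissue_ground_truth")
}

#' Sample a droplet-field phantom
#'
#' A single cytoplasm background (one instance covering the image) holding
#' `n_droplets` well-separated circular lipid droplets. Used to validate
#' droplet detection and morphometry at scale without full tubule geometry.
#'
#' @param side image side in px.
#' @param n_droplets number of droplets to place.
#' @param droplet_radius radius range in px.
#' @param min_sep minimum clearance between droplet rims in px; keep it above
#'   the clustering distance threshold so droplets stay distinct clusters.
#' @param tubule_type type label of the background (selects cytoplasm priors).
#' @param pixel_size pixel size in micrometres.
#' @param seed integer seed.
#' @return A `tissue_ground_truth` whose only substructure is
#'   `lipid_droplets`.
#' @export
sample_droplet_field <- function(side = 512, n_droplets = 60,
                                 droplet_radius = c(5.2, 7), min_sep = 8,
                                 tubule_type = "proximal", pixel_size = 0.414,
                                 seed = 1) {
  stopifnot(side >= 64, n_droplets >= 1)
  with_seed(seed, {
    labels <- matrix(1L, side, side)
    droplet_labels <- matrix(0L, side, side)
    drop_mask <- matrix(FALSE, side, side)
    cy <- numeric(0); cx <- numeric(0); rr <- numeric(0)
    for (i in seq_len(n_droplets)) {
      rho <- runif(1, droplet_radius[1], droplet_radius[2])
      ok <- FALSE
      for (try in seq_len(400L)) {
        y <- runif(1, rho + 2, side - rho - 1)
        x <- runif(1, rho + 2, side - rho - 1)
        if (length(cy) == 0L ||
            all(sqrt((cy - y)^2 + (cx - x)^2) > rr + rho + min_sep)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf(
          "could not place droplet %d of %d: density too high for side %d",
          i, n_droplets, side), call. = FALSE)
      cy <- c(cy, y); cx <- c(cx, x); rr <- c(rr, rho)
      rows <- max(1L, floor(y - rho)):min(side, ceiling(y + rho))
      cols <- max(1L, floor(x - rho)):min(side, ceiling(x + rho))
      d2 <- outer((rows - y)^2, (cols - x)^2, "+")
      disc <- d2 <= rho^2
      drop_mask[rows, cols][disc] <- TRUE
      droplet_labels[rows, cols][disc] <- i
    }
    masks <- list(
      nuclei = matrix(FALSE, side, side),
      nucleoli = matrix(FALSE, side, side),
      lumen = matrix(FALSE, side, side),
      brush_border = matrix(FALSE, side, side),
      lipid_droplets = drop_mask,
      microvasculature = matrix(FALSE, side, side)
    )
    structure(list(
      tubule_labels = labels,
      droplet_labels = droplet_labels,
      masks = masks,
      tubules = data.frame(
        tubule = 1L, type = tubule_type, cy = side / 2, cx = side / 2,
        r_out = NA_real_, r_lumen = NA_real_,
        nuclei_fraction_drawn = 0, depth = 0.5, stringsAsFactors = FALSE),
      droplet_tubule = rep(1L, n_droplets),
      conc = NULL, rho_total = NULL,
      pixel_size = pixel_size, side = side,
      config = list(side = side, n_droplets = n_droplets,
                    droplet_radius = droplet_radius),
      seed = seed, metadata = list()
    ), class = "tissue_ground_truth")
  })
}

#' @export
print.tissue_ground_truth <- function(x, ...) {
  cat(sprintf("tissue_ground_truth: %dx%d px (%.3f um/px), %d tubule(s)\n",
              x$side, x$side, x$pixel_size, nrow(x$tubules)))
  print(table(x$tubules$type))
  cat(sprintf("droplets: %d; concentrations %s\n",
              max(x$droplet_labels),
              if (is.null(x$conc)) "unfilled" else
                sprintf("filled (rho_total = %g mg/mL)", x$rho_total)))
  invisible(x)
}
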