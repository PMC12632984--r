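#' Pipeline configuration
#'
#' @param side image side in px.
#' @param n_images number of phantom images to generate.
#' @param n_tubules tubules per image.
#' @param seed master seed; per-stage, per-image seeds are derived from it
#'   (`seed * 100000 + image * 10 + stage`), so stages are individually
#'   reproducible without seed collisions.
#' @param priors a [default_priors()] table.
#' @param rho_total density constant in mg/mL.
#' @param atten attenuation description (see [forward_srs()]).
#' @param noise_frac sensor noise as a fraction of mean band intensity.
#' @param segmentation `"ground_truth"` (use phantom masks) or
#'   `"classical"` ([segment_tubules_classical()]).
#' @param phantom extra arguments for [phantom_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(side = 512, n_images = 2, n_tubules = 12,
                            seed = 1, priors = default_priors(),
                            rho_total = 1000,
                            atten = list(a_min = 0.4, a_max = 1,
                                         smoothness = 32),
                            noise_frac = 0.01,
                            segmentation = c("ground_truth", "classical"),
                            phantom = list()) {
  segmentation <- match.arg(segmentation)
  structure(list(side = side, n_images = n_images, n_tubules = n_tubules,
                 seed = seed, priors = priors, rho_total = rho_total,
                 atten = atten, noise_frac = noise_frac,
                 segmentation = segmentation, phantom = phantom),
            class = "pipeline_config")
}

stage_seed <- function(seed, image, stage) {
  (as.integer(seed) %% 20000L) * 100000L + image * 10L +
    match(stage, c("layout", "fill", "forward", "segment", "detect",
                   "stats", "classify", "tiles", "split"))
}

#' Run the full pipeline
#'
#' Executes phantom generation, the forward imaging model, unmixing and
#' normalization, segmentation (ground truth or classical), per-tubule
#' quantification, lumen and droplet detection, the tubule-type statistical
#' comparison, and tubule-type classification; writes all artifacts and a
#' run manifest to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return An object of class `run_manifest` (also written to
#'   `manifest.yaml`): config hash, per-stage seeds, output paths, stage
#'   timings, warnings, and the collected results (`features`,
#'   `microvasculature`, `droplets`, `stats`, `classification`).
#' @export
run_all <- function(config = pipeline_config(), out_dir = tempfile("nori_run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  warns <- character(0)
  paths <- character(0)
  seeds <- list()

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(
    side = config$side, n_images = config$n_images,
    n_tubules = config$n_tubules, seed = config$seed,
    rho_total = config$rho_total, noise_frac = config$noise_frac,
    segmentation = config$segmentation,
    priors = as.data.frame(config$priors)
  ), cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  paths <- c(paths, cfg_path)

  features <- list(); micro <- numeric(0); droplets <- list()
  spectra <- nori_spectra()
  pc_args <- c(list(side = config$side, n_tubules = config$n_tubules),
               config$phantom)
  withCallingHandlers({
    for (i in seq_len(config$n_images)) {
      s_layout <- stage_seed(config$seed, i, "layout")
      s_fill <- stage_seed(config$seed, i, "fill")
      s_forward <- stage_seed(config$seed, i, "forward")
      seeds[[paste0("image_", i)]] <- list(layout = s_layout, fill = s_fill,
                                           forward = s_forward)
      gt <- sample_tissue_layout(do.call(phantom_config, pc_args), s_layout)
      gt <- fill_concentrations(gt, config$priors, s_fill,
                                rho_total = config$rho_total)
      stack <- forward_srs(gt, spectra, atten = config$atten,
                           noise_frac = config$noise_frac, seed = s_forward)
      conc <- nori_concentrations(stack, spectra,
                                  rho_total = config$rho_total)
      masks <- if (config$segmentation == "classical")
        segment_tubules_classical(conc) else as_mask_set(gt)
      if (config$segmentation == "classical")
        masks$masks <- lapply(gt$masks, identity)  # substructures from truth
      tab <- tubule_feature_table(conc, masks, gt = gt)
      tab$image <- i
      features[[i]] <- tab
      mv <- microvasculature_protein(conc, masks)
      if (!is.na(mv)) micro <- c(micro, mv)
      cyto <- masks$tubule_labels > 0L & !gt$masks$nuclei &
        !gt$masks$nucleoli & !gt$masks$lumen & !gt$masks$brush_border
      det <- detect_droplets(conc, cyto)
      dm <- droplet_morphometry(det, conc)
      if (nrow(dm)) { dm$image <- i; droplets[[length(droplets) + 1L]] <- dm }
      if (i == 1L) {
        write_ground_truth(gt, file.path(out_dir, "image_1"))
        write_stack_tiff(stack, file.path(out_dir, "image_1", "raw_stack.tif"))
        write_concentration_tiff(conc,
          file.path(out_dir, "image_1", "measured_concentrations.tif"))
        paths <- c(paths, file.path(out_dir, "image_1"))
      }
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  timings["images"] <- proc.time()[["elapsed"]] - t0

  features <- do.call(rbind, features)
  fpath <- file.path(out_dir, "features.csv")
  write_feature_table(features, fpath)
  paths <- c(paths, fpath)

  droplets <- if (length(droplets)) do.call(rbind, droplets) else
    data.frame()
  if (nrow(droplets)) {
    dpath <- file.path(out_dir, "droplets.csv")
    utils::write.csv(droplets, dpath, row.names = FALSE)
    paths <- c(paths, dpath)
  }

  # Tubule-type statistics on cytoplasmic protein, when >= 3 types present.
  stats_res <- NULL
  groups <- split(features$cytoplasm_protein, features$type)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) >= 3) {
    stats_res <- kruskal_dunn(groups)
    spath <- file.path(out_dir, "stats.csv")
    utils::write.csv(tidy_comparison(stats_res), spath, row.names = FALSE)
    paths <- c(paths, spath)
  }

  # Tubule-type classification on the feature table, when feasible.
  cls <- NULL
  if (length(unique(features$type)) >= 2 &&
      all(table(features$type) >= 10)) {
    cls <- run_experiment(features, label_col = "type",
                          mode = "features_both",
                          seed = stage_seed(config$seed, 0L, "classify"))
    cpath <- file.path(out_dir, "classification.csv")
    utils::write.csv(cls$per_class, cpath, row.names = FALSE)
    paths <- c(paths, cpath)
  }
  timings["analysis"] <- proc.time()[["elapsed"]] - t0 - timings[["images"]]

  manifest <- structure(list(
    config_hash = config_hash,
    seeds = seeds,
    version = as.character(utils::packageVersion("noriq")),
    provenance = config$segmentation,
    paths = paths,
    timings = as.list(timings),
    warnings = warns,
    features = features,
    microvasculature = micro,
    droplets = droplets,
    stats = stats_res,
    classification = cls
  ), class = "run_manifest")
  yaml::write_yaml(list(
    config_hash = config_hash, seeds = seeds,
    version = manifest$version, provenance = config$segmentation,
    paths = paths, timings = as.list(timings), warnings = warns
  ), file.path(out_dir, "manifest.yaml"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (%s): %d tubules, %d warnings, %.1f s\n",
              x$provenance, nrow(x$features), length(x$warnings),
              sum(unlist(x$timings))))
  invisible(x)
}

#' Full-pipeline parameter-recovery experiment
#'
#' Generates phantoms at the given priors, images them through the forward
#' model (smooth attenuation field, sensor noise), unmixes and normalizes,
#' quantifies with ground-truth masks, and returns the pooled per-tubule
#' feature table together with per-image interstitial protein summaries.
#' The workhorse behind the parameter-recovery checks: the across-tubule
#' mean of a measured summary should match the generating prior mean within
#' sampling tolerance.
#'
#' @param n_tubules total number of tubules to generate (spread over as many
#'   images as needed).
#' @param priors a [default_priors()] table.
#' @param seed master seed.
#' @param side image side in px.
#' @param per_image tubules per image.
#' @param noise_frac noise fraction of mean band intensity (default 0.01).
#' @param atten attenuation description (default smooth field in
#'   `[0.4, 1]`).
#' @param phantom extra [phantom_config()] arguments.
#' @param rho_total density constant in mg/mL.
#' @return A list: `features` (pooled per-tubule table with `type` and
#'   `image`), `microvasculature` (one value per image), `n_images`.
#' @export
recovery_experiment <- function(n_tubules, priors = default_priors(),
                                seed = 1, side = 512, per_image = 24,
                                noise_frac = 0.01,
                                atten = list(a_min = 0.4, a_max = 1,
                                             smoothness = 32),
                                phantom = list(), rho_total = 1000) {
  n_images <- ceiling(n_tubules / per_image)
  spectra <- nori_spectra()
  feats <- vector("list", n_images)
  micro <- numeric(n_images)
  for (i in seq_len(n_images)) {
    n_i <- min(per_image, n_tubules - (i - 1L) * per_image)
    cfg <- do.call(phantom_config,
                   c(list(side = side, n_tubules = n_i), phantom))
    gt <- sample_tissue_layout(cfg, stage_seed(seed, i, "layout"))
    gt <- fill_concentrations(gt, priors, stage_seed(seed, i, "fill"),
                              rho_total = rho_total)
    stack <- forward_srs(gt, spectra, atten = atten,
                         noise_frac = noise_frac,
                         seed = stage_seed(seed, i, "forward"))
    conc <- nori_concentrations(stack, spectra, rho_total = rho_total)
    tab <- tubule_feature_table(conc, as_mask_set(gt), gt = gt)
    tab$image <- i
    feats[[i]] <- tab
    micro[i] <- microvasculature_protein(conc, as_mask_set(gt))
  }
  list(features = do.call(rbind, feats), microvasculature = micro,
       n_images = n_images)
}

#' Droplet-detection recovery experiment
#'
#' Places droplets with per-droplet lipid draws in a cytoplasm background,
#' runs the forward model, unmixing, normalization, droplet detection
#' (single-linkage 5 px, 75 px size filter) and morphometry, and returns the
#' per-detected-droplet table.
#'
#' @param n_droplets total droplets (spread over images of `per_image`).
#' @param priors a [default_priors()] table (the `lipid_droplet` entry is
#'   the recovery target).
#' @param seed master seed.
#' @param side image side in px.
#' @param per_image droplets per image.
#' @param droplet_radius radius range in px; the default keeps every droplet
#'   above the 75-px cluster filter.
#' @param noise_frac,atten,rho_total as in [recovery_experiment()].
#' @return A `data.frame` of per-droplet morphometry pooled across images,
#'   with an `image` column.
#' @export
droplet_recovery_experiment <- function(n_droplets, priors = default_priors(),
                                        seed = 1, side = 512, per_image = 60,
                                        droplet_radius = c(5.6, 7),
                                        noise_frac = 0.01,
                                        atten = list(a_min = 0.4, a_max = 1,
                                                     smoothness = 32),
                                        rho_total = 1000) {
  n_images <- ceiling(n_droplets / per_image)
  spectra <- nori_spectra()
  out <- list()
  for (i in seq_len(n_images)) {
    n_i <- min(per_image, n_droplets - (i - 1L) * per_image)
    gt <- sample_droplet_field(side = side, n_droplets = n_i,
                               droplet_radius = droplet_radius,
                               seed = stage_seed(seed, i, "layout"))
    gt <- fill_concentrations(gt, priors, stage_seed(seed, i, "fill"),
                              rho_total = rho_total)
    stack <- forward_srs(gt, spectra, atten = atten,
                         noise_frac = noise_frac,
                         seed = stage_seed(seed, i, "forward"))
    conc <- nori_concentrations(stack, spectra, rho_total = rho_total)
    det <- detect_droplets(conc, gt$tubule_labels > 0L)
    dm <- droplet_morphometry(det, conc)
    if (nrow(dm)) { dm$image <- i; out[[length(out) + 1L]] <- dm }
  }
  do.call(rbind, out)
}
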