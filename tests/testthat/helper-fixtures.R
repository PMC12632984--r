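# Shared fixtures, built in code. Small phantoms keep the suite fast; the
# helpers memoise within a test file run.

small_layout <- function(seed = 1, side = 192, n_tubules = 4, ...) {
  sample_tissue_layout(phantom_config(side = side, n_tubules = n_tubules, ...),
                       seed = seed)
}

small_filled <- function(seed = 1, fill_seed = 2, ...) {
  gt <- small_layout(seed = seed, ...)
  suppressWarnings(fill_concentrations(gt, default_priors(), seed = fill_seed))
}

# Noiseless, unattenuated chain: measured concentrations equal ground truth.
small_conc <- function(seed = 1, ...) {
  gt <- small_filled(seed = seed, ...)
  stack <- forward_srs(gt, nori_spectra(), atten = 1, noise_sd = 0, seed = 3)
  list(gt = gt, stack = stack, conc = nori_concentrations(stack))
}

# Brute-force O(n^2) connected components of the <=threshold pixel graph;
# the independent oracle for agglomerate().
brute_force_components <- function(pixels, threshold) {
  n <- nrow(pixels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(dist(pixels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical form of a pixel partition for comparison across implementations.
partition_signature <- function(pixels, membership) {
  groups <- split(paste(pixels[, 1], pixels[, 2]), membership)
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = ";"),
                     character(1))))
}

# Concentration-shift ablation fixture: two classes of images differing only
# by a global +45 mg/mL protein shift; returns tile-feature tables from the
# quantitative stacks and from their per-image-normalized counterparts, with
# an image column for grouped splitting.
build_shift_ablation <- function(base_seed, n_per_class = 5, side = 224,
                                 n_tubules = 5, shift = 45) {
  quant <- list(); pseudo <- list()
  n_img <- 2 * n_per_class
  for (img in seq_len(n_img)) {
    cls <- if (img <= n_per_class) "control" else "shifted"
    pr <- default_priors()
    pr$protein_sd <- pr$protein_sd * 0.5
    pr$lipid_sd <- pr$lipid_sd * 0.5
    if (cls == "shifted") pr$protein_mean <- pr$protein_mean + shift
    gt <- sample_tissue_layout(
      phantom_config(side = side, n_tubules = n_tubules),
      seed = base_seed + img)
    gt <- suppressWarnings(fill_concentrations(gt, pr,
                                               seed = base_seed + 100 + img))
    conc <- nori_concentrations(forward_srs(gt, atten = 1, noise_frac = 0.01,
                                            seed = img))
    tiles <- extract_tiles(conc, as_mask_set(gt),
                           rep(cls, nrow(gt$tubules)), tile_px = 40,
                           n_tiles = 20, seed = img)
    fq <- tile_features(tiles, conc)
    fp <- tile_features(tiles, denormalize_per_image(conc))
    fq$image <- fp$image <- img
    quant[[img]] <- fq; pseudo[[img]] <- fp
  }
  list(quant = do.call(rbind, quant), pseudo = do.call(rbind, pseudo))
}

# Exhaustive maximum bipartite matching size on the IoU >= threshold graph
# (predictions x truths), for <= 10 instances.
max_matching_size <- function(iou, thr) {
  np <- nrow(iou); nt <- ncol(iou)
  if (np == 0 || nt == 0) return(0L)
  best <- 0L
  recurse <- function(p, used) {
    if (p > np) { best <<- max(best, sum(used)); return(invisible()) }
    recurse(p + 1L, used)                      # leave prediction p unmatched
    for (t in seq_len(nt)) {
      if (!used[t] && iou[p, t] >= thr) {
        used[t] <- TRUE
        recurse(p + 1L, used)
        used[t] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt))
  best
}
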