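# Cytoplasm subtraction, per-tubule summaries, interstitial protein, trends.

test_that("cytoplasm subtraction equals the brute-force set difference", {
  gt <- small_layout(seed = 40, n_tubules = 3)
  for (i in 1:3) {
    inst <- gt$tubule_labels == i
    cyto <- cytoplasm_mask(inst, gt$masks$nuclei, gt$masks$nucleoli,
                           gt$masks$lumen, gt$masks$brush_border)
    # exhaustive pixel audit
    manual <- inst & !(gt$masks$nuclei | gt$masks$nucleoli |
                         gt$masks$lumen | gt$masks$brush_border)
    expect_identical(unclass(cyto), unclass(manual))
    # partition: cytoplasm + subtracted substructures tile the footprint
    parts <- cyto | (inst & gt$masks$nuclei) | (inst & gt$masks$nucleoli) |
      (inst & gt$masks$lumen) | (inst & gt$masks$brush_border)
    expect_identical(unclass(parts), unclass(inst))
    overlap <- sum(cyto & (gt$masks$nuclei | gt$masks$nucleoli |
                             gt$masks$lumen | gt$masks$brush_border))
    expect_equal(overlap, 0L)
  }
})

test_that("empty and full subtraction behave as specified", {
  tub <- matrix(FALSE, 10, 10); tub[3:8, 3:8] <- TRUE
  expect_identical(unclass(cytoplasm_mask(tub)), unclass(tub))
  full <- cytoplasm_mask(tub, nuclei = tub)
  expect_false(any(full))
  expect_true(isTRUE(attr(full, "empty")))
  expect_error(cytoplasm_mask(tub, nuclei = matrix(FALSE, 3, 3)), "shape")
})

test_that("summaries equal the ground-truth draws on a constant phantom", {
  x <- small_conc(seed = 41, n_tubules = 3)
  gt <- x$gt
  tab <- tubule_feature_table(x$conc, as_mask_set(gt), gt = gt)
  for (i in 1:3) {
    d <- subset(gt$draws, tubule == i)
    expect_equal(tab$cytoplasm_protein[i],
                 d$protein[d$structure == "cytoplasm"], tolerance = 1e-6)
    if ("nucleus" %in% d$structure)
      expect_equal(tab$nuclear_protein[i],
                   d$protein[d$structure == "nucleus"], tolerance = 1e-6)
  }
  # summaries agree with an independent brute-force pixel loop
  inst <- gt$tubule_labels == 1L
  cyto <- inst & !gt$masks$nuclei & !gt$masks$nucleoli & !gt$masks$lumen &
    !gt$masks$brush_border & !gt$masks$lipid_droplets
  acc <- 0; n <- 0
  for (r in seq_len(gt$side)) for (c in seq_len(gt$side)) {
    if (cyto[r, c]) { acc <- acc + x$conc$protein[r, c]; n <- n + 1 }
  }
  expect_equal(tab$cytoplasm_protein[1], acc / n, tolerance = 1e-12)
})

test_that("nuclear area fractions are measured exactly as drawn", {
  gt <- small_layout(seed = 42, side = 256, n_tubules = 5)
  conc <- nori_concentrations(forward_srs(
    suppressWarnings(fill_concentrations(gt, default_priors(), seed = 1)),
    atten = 1, noise_sd = 0, seed = 1))
  tab <- tubule_feature_table(conc, as_mask_set(gt), gt = gt)
  areas <- tabulate(gt$tubule_labels[gt$tubule_labels > 0L], 5)
  for (i in 1:5) {
    target <- round(gt$tubules$nuclei_fraction_drawn[i] * areas[i]) / areas[i]
    expect_equal(tab$nuclei_area_fraction[i], target, tolerance = 1e-12)
  }
})

test_that("single-pixel structures summarize to that pixel's value; empty to NA", {
  conc <- structure(list(
    protein = matrix(1:16 * 10, 4, 4), lipid = matrix(0, 4, 4),
    water = matrix(0, 4, 4), rho_total = 1000, pixel_size = 1,
    tissue_mask = matrix(TRUE, 4, 4), n_invalid = 0L),
    class = "concentration_stack")
  lab <- matrix(0L, 4, 4); lab[2:3, 2:3] <- 1L
  nuc <- matrix(FALSE, 4, 4); nuc[2, 2] <- TRUE
  ms <- mask_set(lab, list(nuclei = nuc))
  row <- summarize_tubule(conc, ms, 1L)
  expect_equal(row$nuclear_protein, conc$protein[2, 2])
  expect_true(is.na(row$lumen_protein))      # missing, never zero
  expect_error(summarize_tubule(conc, ms, 9L), "not present")
})

test_that("interstitial protein recovers region-specific priors (mask-restricted oracle)", {
  pr <- default_priors(region = "caudal")
  gt <- small_layout(seed = 43, side = 256, n_tubules = 4)
  gt <- suppressWarnings(fill_concentrations(gt, pr, seed = 2))
  conc <- nori_concentrations(forward_srs(gt, atten = 1, noise_sd = 0, seed = 1))
  ms <- as_mask_set(gt)
  got <- microvasculature_protein(conc, ms, margin = 2)
  truth <- subset(gt$draws, structure == "microvasculature")$protein
  expect_equal(got, truth, tolerance = 1e-6)
  # brute-force mask-restricted oracle with the same margin
  tub <- gt$tubule_labels > 0L
  tub_d <- EBImage::dilate(tub, EBImage::makeBrush(5, "disc")) > 0
  expect_equal(got, mean(conc$protein[!tub_d]), tolerance = 1e-12)
  # all-tubule image -> missing
  all_tub <- mask_set(matrix(1L, 8, 8))
  tiny <- structure(list(protein = matrix(1, 8, 8), lipid = matrix(0, 8, 8),
                         water = matrix(0, 8, 8), rho_total = 1000,
                         pixel_size = 1, tissue_mask = matrix(TRUE, 8, 8),
                         n_invalid = 0L), class = "concentration_stack")
  expect_true(is.na(microvasculature_protein(tiny, all_tub, margin = 0)))
})

test_that("cortex-medulla trend: flat, exact line, and noisy threshold cases", {
  flat <- data.frame(depth = seq(0, 1, length.out = 20),
                     cytoplasm_protein = rep(100, 20))
  tr <- cortex_medulla_trend(flat)
  expect_equal(tr$slope, 0, tolerance = 1e-12)
  expect_equal(tr$r_squared, 0, tolerance = 1e-12)

  line <- data.frame(depth = seq(0, 1, length.out = 20),
                     cytoplasm_protein = 200 - 30 * seq(0, 1, length.out = 20))
  tr <- suppressWarnings(cortex_medulla_trend(line))
  expect_equal(tr$slope, -30, tolerance = 1e-9)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)

  # noise scaled for r^2 ~ 0.33 over 500 tubules clears the 0.281 threshold
  set.seed(7)
  depth <- runif(500)
  y <- 200 - 30 * depth + rnorm(500, 0, sqrt(var(30 * depth) * 2))
  tr <- cortex_medulla_trend(data.frame(depth = depth, cytoplasm_protein = y))
  expect_gt(tr$r_squared, 0.281)
  expect_lt(tr$p_value, 1e-4)

  expect_error(cortex_medulla_trend(
    data.frame(depth = rep(0.5, 5), cytoplasm_protein = rnorm(5))), "constant")
  expect_error(cortex_medulla_trend(
    data.frame(depth = c(0, 1), cytoplasm_protein = c(1, 2))), "3 tubules")
})
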