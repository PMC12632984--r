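# Layout generator, concentration filling, and the forward imaging model.

test_that("single-tubule layout is an annulus with enclosed lumen and disjoint masks", {
  gt <- sample_tissue_layout(phantom_config(side = 256, n_tubules = 1), seed = 7)
  expect_equal(max(gt$tubule_labels), 1L)
  inst <- gt$tubule_labels == 1L
  expect_true(any(gt$masks$lumen))
  # lumen lies strictly inside the footprint
  expect_true(all(inst[gt$masks$lumen]))
  # pairwise disjointness of substructure masks inside the tubule
  subs <- gt$masks[c("nuclei", "nucleoli", "lumen", "brush_border",
                     "lipid_droplets")]
  for (i in seq_along(subs)) for (j in seq_along(subs)) {
    if (i < j) expect_equal(sum(subs[[i]] & subs[[j]]), 0L)
  }
  # every substructure inside the footprint; interstitium outside
  for (m in subs) expect_true(all(inst[m]))
  expect_true(all(!inst[gt$masks$microvasculature]))
  # the epithelium is an annulus: cytoplasm ring surrounds the lumen
  cyto <- cytoplasm_mask(inst, gt$masks$nuclei, gt$masks$nucleoli,
                         gt$masks$lumen, gt$masks$brush_border)
  expect_true(any(cyto))
})

test_that("layout is byte-identical for a fixed seed and differs across seeds", {
  cfg <- phantom_config(side = 256, n_tubules = 6)
  a <- sample_tissue_layout(cfg, seed = 1)
  b <- sample_tissue_layout(cfg, seed = 1)
  expect_identical(a$tubule_labels, b$tubule_labels)
  expect_identical(a$masks, b$masks)
  expect_identical(a$droplet_labels, b$droplet_labels)
  c <- sample_tissue_layout(cfg, seed = 2)
  expect_false(identical(a$tubule_labels, c$tubule_labels))
})

test_that("proximal-only phantoms give every instance a brush border (mask audit)", {
  gt <- sample_tissue_layout(
    phantom_config(side = 320, n_tubules = 8,
                   type_probs = c(proximal = 1, distal = 0,
                                  collecting_duct = 0)),
    seed = 1)
  expect_true(all(gt$tubules$type == "proximal"))
  # exhaustive scan: every instance footprint intersects the brush mask
  for (i in seq_len(8)) {
    inst <- gt$tubule_labels == i
    expect_gt(sum(inst & gt$masks$brush_border), 0)
  }
})

test_that("invalid configs and impossible densities raise informative errors", {
  expect_error(phantom_config(side = 64), "side")
  expect_error(phantom_config(side = 256, lumen_frac = 0.9), "lumen_frac")
  expect_error(phantom_config(side = 256, type_probs = c(a = 1, b = 1, c = 1)),
               "type_probs")
  expect_error(
    sample_tissue_layout(
      phantom_config(side = 128, n_tubules = 40, max_retries = 10), seed = 1),
    "density")
})

test_that("zero-variance priors give identical concentrations per tubule type", {
  pr <- default_priors()
  pr$protein_sd[] <- 0
  pr$lipid_sd[] <- 0
  gt <- small_layout(seed = 3, n_tubules = 6)
  gt <- fill_concentrations(gt, pr, seed = 4)
  cyto <- subset(gt$draws, structure == "cytoplasm")
  cyto$type <- gt$tubules$type[match(cyto$tubule, gt$tubules$tubule)]
  for (ty in unique(cyto$type))
    expect_equal(length(unique(cyto$protein[cyto$type == ty])), 1L)
})

test_that("protein + lipid + water equals the density constant at every pixel", {
  gt <- small_filled(seed = 5)
  total <- gt$conc$protein + gt$conc$lipid + gt$conc$water
  expect_lt(max(abs(total - gt$rho_total)), 1e-9)
  expect_true(all(gt$conc$protein >= 0))
  expect_true(all(gt$conc$lipid >= 0))
  expect_true(all(gt$conc$water >= 0))
})

test_that("across-tubule draw means converge to the prior means", {
  pr <- default_priors()
  gt <- sample_tissue_layout(
    phantom_config(side = 448, n_tubules = 20,
                   type_probs = c(proximal = 1, distal = 0,
                                  collecting_duct = 0)),
    seed = 11)
  # pool draws over several fills to reach n = 140 cheaply
  draws <- do.call(rbind, lapply(1:7, function(s)
    suppressWarnings(fill_concentrations(gt, pr, seed = s))$draws))
  cyto <- subset(draws, structure == "cytoplasm")
  n <- nrow(cyto)
  expect_equal(n, 140L)
  expect_lt(abs(mean(cyto$protein) - 194.3), 3 * 18.4 / sqrt(n))
  expect_lt(abs(mean(cyto$lipid) - 52.2), 3 * 9.5 / sqrt(n))
})

test_that("filling is seed-reproducible and records draws", {
  gt <- small_layout(seed = 6)
  a <- fill_concentrations(gt, default_priors(), seed = 9)
  b <- fill_concentrations(gt, default_priors(), seed = 9)
  expect_identical(a$conc, b$conc)
  expect_identical(a$draws, b$draws)
  expect_true(all(c("cytoplasm", "microvasculature") %in% a$draws$structure))
})

test_that("forward model: identity attenuation reproduces S %*% c exactly", {
  x <- small_conc(seed = 2)
  S <- nori_spectra()$matrix
  i <- 40; j <- 120
  truth <- S %*% c(x$gt$conc$protein[i, j], x$gt$conc$lipid[i, j],
                   x$gt$conc$water[i, j])
  expect_equal(as.numeric(x$stack$bands[i, j, ]), as.numeric(truth),
               tolerance = 1e-12)
})

test_that("forward model is linear in the attenuation field", {
  gt <- small_filled(seed = 4)
  full <- forward_srs(gt, atten = 1, noise_sd = 0, seed = 1)
  half <- forward_srs(gt, atten = 0.5, noise_sd = 0, seed = 1)
  expect_equal(half$bands, full$bands / 2, tolerance = 1e-12)
})

test_that("single-pixel band values equal the hand-computed matrix product", {
  # S %*% (100, 50, 850), rows written out by hand from the default matrix
  b1 <- 0.30 * 100 + 1.00 * 50 + 0.05 * 850   # 122.5
  b2 <- 1.00 * 100 + 0.45 * 50 + 0.10 * 850   # 207.5
  b3 <- 0.05 * 100 + 0.02 * 50 + 1.00 * 850   # 856
  got <- as.numeric(nori_spectra()$matrix %*% c(100, 50, 850))
  expect_equal(got, c(b1, b2, b3), tolerance = 1e-12)
  expect_equal(got, c(122.5, 207.5, 856), tolerance = 1e-12)
})

test_that("random attenuation field respects its bounds and smoothness setting", {
  gt <- small_filled(seed = 8)
  st <- forward_srs(gt, atten = list(a_min = 0.4, a_max = 1, smoothness = 16),
                    noise_sd = 0, seed = 5)
  A <- st$attenuation_truth
  expect_gte(min(A), 0.4)
  expect_lte(max(A), 1)
  st2 <- forward_srs(gt, atten = list(a_min = 0.4, a_max = 1, smoothness = 16),
                     noise_sd = 0, seed = 5)
  expect_identical(st$bands, st2$bands)
  expect_error(forward_srs(gt, atten = list(a_min = -0.1), seed = 1), "a_min")
})
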