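# Unmixing, normalization, and the attenuation-cancellation core.

test_that("unmix recovers pure-component and mixed pixels exactly", {
  sp <- nori_spectra()
  mk <- function(conc) {
    I <- sp$matrix %*% conc
    array(I, dim = c(1, 1, 3))
  }
  water <- unmix(mk(c(0, 0, 1)), sp)
  expect_equal(c(water$protein, water$lipid, water$water), c(0, 0, 1),
               tolerance = 1e-12)
  prox <- unmix(mk(c(194.3, 52.2, 753.5)), sp)
  expect_equal(c(prox$protein, prox$lipid, prox$water),
               c(194.3, 52.2, 753.5), tolerance = 1e-9)
})

test_that("unmix matches an independent per-pixel solve on random pixels", {
  sp <- nori_spectra()
  set.seed(42)
  n <- 1000
  truth <- matrix(runif(3 * n, 0, 400), n, 3)
  truth[, 3] <- truth[, 3] + 400
  I <- truth %*% t(sp$matrix)
  stack <- array(0, dim = c(n, 1, 3))
  for (b in 1:3) stack[, 1, b] <- I[, b]
  got <- unmix(stack, sp)
  got_m <- cbind(as.vector(got$protein), as.vector(got$lipid),
                 as.vector(got$water))
  # oracle: independent pixel-by-pixel 3x3 solve
  oracle <- t(apply(I, 1, function(row) solve(sp$matrix, row)))
  expect_lt(max(abs(got_m - oracle)), 1e-9)
  expect_lt(max(abs(got_m - truth)), 1e-9 * 1000)
})

test_that("NNLS fallback clips negative components to the best feasible fit", {
  sp <- nori_spectra()
  # band vector engineered so the plain inverse goes negative
  I <- sp$matrix %*% c(5, 0, 1000)
  I[1] <- I[1] * 0.5
  stack <- array(I, dim = c(1, 1, 3))
  got <- unmix(stack, sp)
  expect_gte(got$protein[1, 1], 0)
  expect_gte(got$lipid[1, 1], 0)
  expect_gte(got$water[1, 1], 0)
  expect_equal(got$n_nnls, 1L)
  # residual no worse than any vertex of the feasible region (spot check)
  res <- function(c3) sum((sp$matrix %*% c3 - I)^2)
  got_res <- res(c(got$protein, got$lipid, got$water))
  expect_lte(got_res, res(c(0, 0, as.numeric(I[3]))) + 1e-8)
})

test_that("unmix refuses NaN bands and ill-conditioned spectra", {
  sp <- nori_spectra()
  bad <- array(1, dim = c(2, 2, 3)); bad[1, 1, 2] <- NA
  expect_error(unmix(bad, sp), "NaN")
  expect_error(nori_spectra(matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3)),
               "condition number")
})

test_that("normalization splits proportionally and is scale invariant", {
  comps <- list(protein = matrix(1), lipid = matrix(1), water = matrix(2))
  conc <- nori_normalize(comps, rho_total = 1000)
  expect_equal(c(conc$protein, conc$lipid, conc$water), c(250, 250, 500))
  scaled <- lapply(comps, function(m) m * 7.3)
  conc2 <- nori_normalize(scaled, rho_total = 1000)
  expect_equal(conc$protein, conc2$protein, tolerance = 1e-12)
})

test_that("noiseless phantom round trip recovers ground truth below 0.1 mg/mL", {
  gt <- small_filled(seed = 10)
  st <- forward_srs(gt, atten = list(a_min = 0.4, a_max = 1, smoothness = 24),
                    noise_sd = 0, seed = 11)
  conc <- nori_concentrations(st)
  expect_lt(max(abs(conc$protein - gt$conc$protein)), 0.1)
  expect_lt(max(abs(conc$lipid - gt$conc$lipid)), 0.1)
  expect_lt(max(abs(conc$water - gt$conc$water)), 0.1)
})

test_that("unmix + normalize is invariant to any positive per-pixel attenuation", {
  gt <- small_filled(seed = 12)
  side <- gt$side
  ref <- nori_concentrations(forward_srs(gt, atten = 1, noise_sd = 0, seed = 1))
  for (s in 1:3) {
    A <- with(list(), {
      set.seed(s)
      matrix(runif(side * side, 0.05, 1), side, side)
    })
    got <- nori_concentrations(forward_srs(gt, atten = A, noise_sd = 0,
                                           seed = 1))
    expect_lt(max(abs(got$protein - ref$protein)), 1e-6)
  }
})

test_that("output planes sum to rho_total at every tissue pixel", {
  x <- small_conc(seed = 13)
  total <- x$conc$protein + x$conc$lipid + x$conc$water
  expect_lt(max(abs(total[x$conc$tissue_mask] - 1000)), 1e-6)
})

test_that("1% sensor noise keeps per-structure mean errors below 2 mg/mL", {
  gt <- small_filled(seed = 14, side = 256, n_tubules = 6)
  st <- forward_srs(gt, atten = list(a_min = 0.4, a_max = 1, smoothness = 32),
                    noise_frac = 0.01, seed = 15)
  conc <- nori_concentrations(st)
  for (i in gt$tubules$tubule) {
    cyto <- cytoplasm_mask(gt$tubule_labels == i, gt$masks$nuclei,
                           gt$masks$nucleoli, gt$masks$lumen,
                           gt$masks$brush_border) & !gt$masks$lipid_droplets
    err <- abs(mean(conc$protein[cyto]) - mean(gt$conc$protein[cyto]))
    expect_lt(err, 2)
  }
})

test_that("degenerate component sums are flagged, not propagated", {
  comps <- list(protein = matrix(c(1, 0), 1, 2),
                lipid = matrix(c(1, 0), 1, 2),
                water = matrix(c(2, 0), 1, 2))
  conc <- nori_normalize(comps, rho_total = 1000)
  expect_equal(conc$n_invalid, 1L)
  expect_equal(conc$protein[1, 2], 0)
})

test_that("per-image normalization erases global concentration shifts", {
  x <- small_conc(seed = 16)
  conc <- x$conc
  shifted <- conc
  shifted$protein <- conc$protein * 2
  shifted$lipid <- conc$lipid * 2
  shifted$water <- conc$water * 2
  a <- denormalize_per_image(conc)
  b <- denormalize_per_image(shifted)
  expect_equal(a$protein, b$protein, tolerance = 1e-12)
  # affine rescale: plane with min 0, max 200 is divided by 200
  plane <- matrix(seq(0, 200, length.out = 16), 4, 4)
  fake <- structure(list(protein = plane, lipid = plane, water = plane,
                         tissue_mask = matrix(TRUE, 4, 4), pixel_size = 0.414,
                         rho_total = 1000, n_invalid = 0L),
                    class = "concentration_stack")
  expect_equal(denormalize_per_image(fake)$protein, plane / 200,
               tolerance = 1e-12)
})
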