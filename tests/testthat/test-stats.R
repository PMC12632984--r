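# The statistical battery: rank tests, post-hoc corrections, effect sizes.

test_that("Kruskal-Wallis H equals the hand rank computation", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_dunn(g)
  # rank sums 6, 15, 24; H = 12/(9*10) * 3*(2^2 + 5^2 + 8^2) - 3*10 = 7.2
  expect_equal(res$statistic, 7.2, tolerance = 1e-9)
})

test_that("identical groups give H near 0 and pairwise p near 1", {
  v <- c(5, 6, 7, 8, 9)
  res <- kruskal_dunn(list(a = v, b = v, c = v))
  expect_lt(res$statistic, 1e-9)
  expect_true(all(res$pairwise$p_adjusted > 0.99))
  expect_true(all(abs(res$pairwise$d) < 1e-12))
})

test_that("Dunn corrections never decrease a p-value", {
  set.seed(1)
  for (s in 1:10) {
    g <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1), d = rnorm(8))
    res <- kruskal_dunn(g)
    expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-15))
    expect_true(all(res$pairwise$p_adjusted <= 1))
  }
})

test_that("Dunn z p-values are calibrated against the permutation null", {
  # tiny fixed samples; compare the normal-approximation p for one pair with
  # an exhaustive-ish permutation of group labels
  set.seed(2)
  x <- c(2.1, 3.4, 1.7, 4.2, 2.8, 3.9, 1.2, 3.3, 2.5, 4.8, 0.9, 3.0)
  g0 <- rep(c("a", "b", "c"), each = 4)
  obs <- kruskal_dunn(split(x, g0))$pairwise
  obs_z <- abs(obs$z[obs$group1 == "a" & obs$group2 == "b"])
  perm <- replicate(4000, {
    gp <- sample(g0)
    pw <- kruskal_dunn(split(x, gp))$pairwise
    abs(pw$z[pw$group1 == "a" & pw$group2 == "b"])
  })
  p_perm <- mean(perm >= obs_z - 1e-12)
  p_norm <- obs$p_raw[obs$group1 == "a" & obs$group2 == "b"]
  expect_lt(abs(p_perm - p_norm), 0.06)
})

test_that("Mann-Whitney exact p matches the 6-arrangement enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  # all 6 arrangements of ranks; P(U <= 0) = 1/6 per tail, two-sided 1/3
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(res$test, "exact")
  same <- mann_whitney(c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_gt(same$p_value, 0.9)
})

test_that("Mann-Whitney has near-complete power at d = 1, n = 100", {
  set.seed(3)
  rejections <- replicate(200, {
    mann_whitney(rnorm(100, 1), rnorm(100, 0))$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("KS statistic matches the exhaustive ECDF sweep and analytic limits", {
  a <- c(0.1, 0.4, 0.7); b <- c(0.2, 0.5, 0.9, 1.1)
  res <- ks_compare(a, b)
  grid <- sort(unique(c(a, b)))
  d_oracle <- max(vapply(grid, function(t)
    abs(mean(a <= t) - mean(b <= t)), numeric(1)))
  expect_equal(res$statistic, d_oracle, tolerance = 1e-12)
  expect_equal(ks_compare(a, a)$statistic, 0)
  set.seed(4)
  big <- ks_compare(runif(4000), runif(4000, 0.5, 1.5))
  expect_lt(abs(big$statistic - 0.5), 0.05)
})

test_that("Cohen's d: unit case, antisymmetry, degenerate case", {
  set.seed(5)
  a <- rnorm(2000, 1, 1); b <- rnorm(2000, 0, 1)
  expect_lt(abs(cohens_d(a, b) - 1), 0.1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a), tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 1), c(1, 1)), NA_real_)
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("balanced two-way ANOVA F statistics equal hand sums of squares", {
  d <- data.frame(
    y = c(10, 12, 20, 22, 14, 16, 30, 32),
    A = rep(c("a1", "a2"), each = 4),
    B = rep(rep(c("b1", "b2"), each = 2), 2))
  res <- two_way_anova_bonferroni(d, "y", "A", "B")
  # hand decomposition: grand mean 19.5; cell means 11, 21, 15, 31
  # SS_A = 4*((16-19.5)^2 + (23-19.5)^2) = 98
  # SS_B = 4*((13-19.5)^2 + (26-19.5)^2) = 338
  # SS_AB total cell SS minus main effects; SSE = 8 * 1 = 8 (each cell var 2, df 1 -> 2 per cell)
  cell <- rbind(a1 = c(b1 = 11, b2 = 21), a2 = c(b1 = 15, b2 = 31))
  ssa <- 4 * sum((rowMeans(cell) - 19.5)^2)            # 98
  ssb <- 4 * sum((colMeans(cell) - 19.5)^2)            # 338
  sscell <- 2 * sum((cell - 19.5)^2)
  ssab <- sscell - ssa - ssb                           # 18
  sse <- sum((d$y - rep(c(11, 21, 15, 31), each = 2))^2)  # 8
  f_oracle <- c(ssa, ssb, ssab) / (sse / 4)
  eff <- res$effects
  expect_equal(eff$F[eff$term == "A"], f_oracle[1], tolerance = 1e-9)
  expect_equal(eff$F[eff$term == "B"], f_oracle[2], tolerance = 1e-9)
  expect_equal(eff$F[eff$term == "A:B"], f_oracle[3], tolerance = 1e-9)
})

test_that("an additive time effect shows a small time p and large interaction p", {
  set.seed(6)
  d <- expand.grid(arm = c("con", "iri"), day = c("d1", "d2", "d5", "d25"),
                   rep = 1:12)
  d$y <- rnorm(nrow(d), 0, 1) + 2 * as.integer(d$day)
  res <- two_way_anova_bonferroni(d, "y", "arm", "day")
  eff <- res$effects
  expect_lt(eff$p_value[eff$term == "day"], 1e-6)
  expect_gt(eff$p_value[eff$term == "arm:day"], 0.05)
  expect_error(two_way_anova_bonferroni(d[d$arm == "con", ], "y", "arm", "day"),
               "2 levels")
})

test_that("all tests hold their type-I error at alpha 0.05 (2000 null replicates)", {
  set.seed(7)
  n_rep <- 2000
  alpha <- 0.05
  band <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
  mw <- mean(replicate(n_rep, mann_whitney(rnorm(15), rnorm(15))$p_value) < alpha)
  ks <- mean(replicate(n_rep, ks_compare(rnorm(15), rnorm(15))$p_value) < alpha)
  kw <- mean(replicate(n_rep,
    kruskal_dunn(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$p_value) < alpha)
  av <- mean(replicate(n_rep, {
    d <- expand.grid(A = c("x", "y"), B = c("u", "v"), rep = 1:5)
    d$y <- rnorm(nrow(d))
    min(two_way_anova_bonferroni(d, "y", "A", "B")$effects$p_value[1])
  }) < alpha)
  # exact tests may be conservative; they must never be anti-conservative
  expect_lt(mw, alpha + band)
  expect_lt(ks, alpha + band)
  expect_gt(ks, alpha - 2 * band)
  expect_lt(kw, alpha + band)
  expect_gt(kw, alpha - 2 * band)
  expect_lt(av, alpha + band)
  expect_gt(av, alpha - 2 * band)
})

test_that("group validation errors name the offending group", {
  expect_error(kruskal_dunn(list(a = 1:3, b = 2, c = 1:3)), "'b'")
  expect_error(kruskal_dunn(list(a = 1:3, b = 1:3)), "at least 3")
  expect_error(mann_whitney(numeric(0), 1:3), "n < 2")
})
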