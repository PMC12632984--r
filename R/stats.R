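#' Cohen's d effect size
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled standard deviation
#' weighted by degrees of freedom. Undefined (returned as `NA`) when the
#' pooled SD is zero.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return The effect size `d`; its sign follows `a - b`.
#' @examples
#' cohens_d(rnorm(50, 1), rnorm(50, 0))
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

group_summaries <- function(groups) {
  do.call(rbind, lapply(names(groups), function(g) data.frame(
    group = g, n = length(groups[[g]]), mean = mean(groups[[g]]),
    sd = sd(groups[[g]]), median = median(groups[[g]]),
    stringsAsFactors = FALSE)))
}

pairwise_d <- function(groups) {
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    d = apply(pairs, 2, function(p) cohens_d(groups[[p[1]]], groups[[p[2]]])),
    stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based H test across three or more groups (tie-corrected, via
#' [stats::kruskal.test()]), followed by Dunn's pairwise z tests on mean
#' ranks with a tie-corrected variance and Bonferroni-family multiplicity
#' adjustment, plus Cohen's d per pair.
#'
#' @param groups named list of >= 3 numeric samples, each with n >= 2.
#' @param p_adjust multiplicity correction family passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return An object of class `group_comparison` with fields `test`,
#'   `statistic`, `p_value`, `pairwise` (z, raw and corrected p, Cohen's d),
#'   and `summaries`.
#' @examples
#' g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
#' kruskal_dunn(g)
#' @export
kruskal_dunn <- function(groups, p_adjust = "bonferroni") {
  check_groups(groups, min_groups = 3)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)

  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  nn <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / nn[[p[1]]] + 1 / nn[[p[2]]]))
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z,
    p_raw = p_raw, p_adjusted = pmin(1, p.adjust(p_raw, p_adjust)),
    stringsAsFactors = FALSE)
  pw$d <- pairwise_d(groups)$d

  structure(list(
    test = "Kruskal-Wallis with Dunn's post-hoc",
    statistic = unname(kw$statistic), p_value = kw$p.value,
    pairwise = pw, summaries = group_summaries(groups)
  ), class = "group_comparison")
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test via [stats::wilcox.test()]: exact null
#' distribution (full enumeration) when both samples have n <= 8 and no
#' ties, normal approximation with continuity and tie correction otherwise.
#' Cohen's d is attached as the effect size.
#'
#' @param a,b numeric samples with n >= 2 each.
#' @return A `group_comparison` with the U statistic (`statistic`, counted
#'   for the first sample), `p_value`, `effect_size`, and `summaries`.
#' @export
mann_whitney <- function(a, b) {
  check_groups(list(a = a, b = b), min_groups = 2)
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(
    test = if (exact) "Mann-Whitney U (exact)" else
      "Mann-Whitney U (normal approximation)",
    statistic = unname(wt$statistic), p_value = wt$p.value,
    effect_size = cohens_d(a, b),
    summaries = group_summaries(list(a = a, b = b))
  ), class = "group_comparison")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value.
#'
#' @param a,b numeric samples with n >= 2 each.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(a, b) {
  check_groups(list(a = a, b = b), min_groups = 2)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Two-way ANOVA with Bonferroni-corrected cell contrasts
#'
#' Fixed-effects two-way decomposition `y ~ A * B`. Balanced designs use the
#' standard sequential sums of squares (equal to any other type when
#' balanced); unbalanced designs are assessed with type-II sums of squares.
#' Pairwise cell-mean contrasts are Bonferroni-corrected t tests.
#'
#' @param data a `data.frame`.
#' @param response,factor_a,factor_b column names.
#' @return An object of class `two_way_anova`: `effects` (one row per term:
#'   F, df, p), `pairwise_cells` (corrected pairwise cell p-values), and the
#'   fitted `aov` object.
#' @export
two_way_anova_bonferroni <- function(data, response, factor_a, factor_b) {
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data))
      stop(sprintf("column '%s' not in data", col), call. = FALSE)
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("each factor needs >= 2 levels", call. = FALSE)
  if (any(table(A, B) == 0L))
    stop("empty factor-level cell", call. = FALSE)
  y <- data[[response]]
  d <- data.frame(y = y, A = A, B = B)
  fit <- stats::aov(y ~ A * B, data = d)
  balanced <- length(unique(table(A, B))) == 1L
  if (balanced) {
    tab <- summary(fit)[[1]]
    terms <- rownames(tab)
    eff <- data.frame(
      term = trimws(terms), df = tab$Df, F = tab$`F value`,
      p_value = tab$`Pr(>F)`, stringsAsFactors = FALSE)
    eff <- eff[eff$term != "Residuals", ]
  } else {
    tab <- car::Anova(fit, type = 2)
    keep <- !rownames(tab) %in% "Residuals"
    eff <- data.frame(
      term = trimws(rownames(tab)[keep]), df = tab$Df[keep],
      F = tab$`F value`[keep], p_value = tab$`Pr(>F)`[keep],
      stringsAsFactors = FALSE)
  }
  eff$term <- sub("^A$", factor_a, eff$term)
  eff$term <- sub("^B$", factor_b, eff$term)
  eff$term <- sub("^A:B$", paste(factor_a, factor_b, sep = ":"), eff$term)
  cells <- interaction(A, B, sep = ":")
  pw <- stats::pairwise.t.test(y, cells, p.adjust.method = "bonferroni")
  structure(list(effects = eff, pairwise_cells = pw$p.value,
                 balanced = balanced, fit = fit),
            class = "two_way_anova")
}

check_groups <- function(groups, min_groups) {
  if (length(groups) < min_groups)
    stop(sprintf("need at least %d groups", min_groups), call. = FALSE)
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) < 2)
      stop(sprintf("group '%s' has n < 2", nm), call. = FALSE)
    if (!is.numeric(g))
      stop(sprintf("group '%s' is not numeric", nm), call. = FALSE)
  }
  invisible(groups)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$effect_size))
    cat(sprintf("Cohen's d = %.3f\n", x$effect_size))
  invisible(x)
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (%s)\n",
              if (x$balanced) "balanced" else "type-II, unbalanced"))
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy export of comparison results
#'
#' One row per comparison, suitable for CSV output.
#'
#' @param x a `group_comparison`.
#' @return A `data.frame`.
#' @export
tidy_comparison <- function(x) {
  stopifnot(inherits(x, "group_comparison"))
  if (!is.null(x$pairwise))
    data.frame(test = x$test, comparison = paste(x$pairwise$group1, "vs",
                                                 x$pairwise$group2),
               statistic = x$pairwise$z, p_value = x$pairwise$p_adjusted,
               effect_size = x$pairwise$d, stringsAsFactors = FALSE)
  else
    data.frame(test = x$test, comparison = "a vs b",
               statistic = x$statistic, p_value = x$p_value,
               effect_size = x$effect_size %||% NA_real_,
               stringsAsFactors = FALSE)
}
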