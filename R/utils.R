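# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All seeded operations in the package go through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from one pipeline seed; keeps results
# below .Machine$integer.max and avoids collisions between stages.
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 211L + match(
    stage,
    c("layout", "fill", "forward", "segment", "quantify",
      "detect", "stats", "classify", "tiles", "split")
  )
}

stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  invisible(x)
}

same_shape <- function(a, b) identical(dim(a), dim(b))

# Truncated-at-zero normal draws by rejection; records the redraw count so
# callers can warn when truncation is not negligible.
rnorm_trunc0 <- function(n, mean, sd, max_iter = 100L) {
  x <- rnorm(n, mean, sd)
  redraws <- 0L
  for (it in seq_len(max_iter)) {
    bad <- which(x < 0)
    if (length(bad) == 0L) break
    redraws <- redraws + length(bad)
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  x[x < 0] <- 0
  attr(x, "redraws") <- redraws
  x
}

# Binary mask utilities ------------------------------------------------------

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  m <- x > 0
  dim(m) <- dim(x)
  m
}

mask_area <- function(x) sum(as_mask(x))

# 4-connected boundary pixel count of a logical mask (used for perimeter).
boundary_pixels <- function(mask) {
  m <- as_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  up    <- rbind(FALSE, m[-nr, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, m[, -nc, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}
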