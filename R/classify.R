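#' Macro-averaged F1 score from a confusion matrix
#'
#' Per-class F1 is the harmonic mean of precision and recall,
#' `2 / (precision^-1 + recall^-1)`; the macro score is the unweighted mean
#' over classes with at least one true instance. A class that is never
#' predicted (or never correctly predicted) scores F1 = 0.
#'
#' @param confusion square matrix of counts, rows = truth, columns =
#'   predicted, identical row/column class order.
#' @return A list with `macro_f1` and a `per_class` data frame (precision,
#'   recall, F1).
#' @examples
#' cm <- rbind(c(5, 1), c(2, 4))
#' macro_f1(cm)$macro_f1
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0L || sum(confusion) == 0)
    stop("empty confusion matrix", call. = FALSE)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square (same class order on both axes)",
         call. = FALSE)
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  has_truth <- true_n > 0
  if (!any(has_truth)) stop("no class has a true instance", call. = FALSE)
  list(
    macro_f1 = mean(f1[has_truth]),
    per_class = data.frame(
      class = colnames(confusion) %||% as.character(seq_along(tp)),
      precision = precision, recall = recall, f1 = f1,
      n_true = as.numeric(true_n), stringsAsFactors = FALSE)
  )
}

#' Extract labelled image tiles centred on tubule pixels
#'
#' Samples square tiles of side `tile_px` whose centres lie on tubule pixels;
#' each tile inherits the class of its covering tubule. Tiles crossing the
#' image border are never produced. Sampling is without replacement and
#' fully seeded.
#'
#' @param conc a `concentration_stack`.
#' @param masks a `mask_set`.
#' @param labels per-instance class labels, indexed by instance id (e.g.
#'   tubule types).
#' @param tile_px tile side in pixels, 40--320.
#' @param n_tiles maximum number of tiles to sample.
#' @param seed integer seed.
#' @return A `data.frame` (class `tile_set`) with tile centres, instance id
#'   and class label; attributes `tile_px` and `tile_um` (physical side,
#'   `tile_px * pixel_size`).
#' @export
extract_tiles <- function(conc, masks, labels, tile_px = 64, n_tiles = 200,
                          seed = 1) {
  stopifnot(inherits(conc, "concentration_stack"), inherits(masks, "mask_set"))
  if (tile_px < 1 || tile_px > nrow(conc$protein))
    stop("tile_px must be within the image side", call. = FALSE)
  half <- floor(tile_px / 2)
  side <- nrow(conc$protein)
  lab <- masks$tubule_labels
  eligible <- lab > 0L
  eligible[c(seq_len(min(half, side)), side - seq_len(min(half, side)) + 1), ] <- FALSE
  eligible[, c(seq_len(min(half, side)), side - seq_len(min(half, side)) + 1)] <- FALSE
  idx <- which(eligible, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no eligible tile centres")
    out <- data.frame(row = integer(0), col = integer(0),
                      tubule = integer(0), label = character(0))
  } else {
    take <- with_seed(seed, sample(nrow(idx), min(n_tiles, nrow(idx))))
    take <- sort(take)
    out <- data.frame(
      row = idx[take, 1], col = idx[take, 2],
      tubule = lab[idx[take, , drop = FALSE]],
      stringsAsFactors = FALSE)
    out$label <- labels[out$tubule]
  }
  attr(out, "tile_px") <- tile_px
  attr(out, "tile_um") <- tile_px * conc$pixel_size
  class(out) <- c("tile_set", "data.frame")
  out
}

#' Summary features of each tile
#'
#' Fixed, deterministic per-tile features used by the tiles-mode classifier:
#' mean, SD and quartiles of the protein and lipid planes over the tile.
#'
#' @param tiles a `tile_set` from [extract_tiles()].
#' @param conc the `concentration_stack` (or `pseudo_intensity_stack`) the
#'   tiles were drawn from.
#' @return A `data.frame` of tile features plus the `label` column.
#' @export
tile_features <- function(tiles, conc) {
  tile_px <- attr(tiles, "tile_px")
  half <- floor(tile_px / 2)
  feat <- lapply(seq_len(nrow(tiles)), function(i) {
    rows <- (tiles$row[i] - half):(tiles$row[i] + half)
    cols <- (tiles$col[i] - half):(tiles$col[i] + half)
    p <- conc$protein[rows, cols]; l <- conc$lipid[rows, cols]
    data.frame(
      protein_mean = mean(p), protein_sd = sd(p),
      protein_q25 = quantile(p, 0.25)[[1]], protein_q75 = quantile(p, 0.75)[[1]],
      lipid_mean = mean(l), lipid_sd = sd(l),
      lipid_q25 = quantile(l, 0.25)[[1]], lipid_q75 = quantile(l, 0.75)[[1]])
  })
  out <- do.call(rbind, feat)
  out$label <- tiles$label
  out
}

# Feature-column groups of the tubule feature table used by input modes.
concentration_feature_cols <- function()
  c("cytoplasm_protein", "cytoplasm_lipid", "nuclear_protein",
    "brush_border_protein", "brush_border_lipid", "lumen_protein",
    "droplet_lipid")

geometry_feature_cols <- function()
  c("area_um2", "perimeter_um", "equivalent_diameter_um", "eccentricity",
    "nuclei_area_fraction")

#' Run a feature-table classification experiment
#'
#' Trains a multinomial logistic classifier on a stratified train split and
#' reports validation macro-F1 with a per-class breakdown. Input modes select
#' feature-table column groups (`features_concentration_only`,
#' `features_geometry_only`, `features_both`) or an explicit feature frame
#' (`tiles`, from [tile_features()]). Missing feature values are imputed by
#' the train-split column median. Fully seeded: identical seeds give
#' identical splits and scores.
#'
#' @param data a feature `data.frame` containing the feature columns and a
#'   label column.
#' @param label_col name of the class-label column (default `"type"`).
#' @param mode input mode; determines which columns are used.
#' @param train_frac train fraction of the stratified split (default 0.7).
#' @param seed integer seed for the split.
#' @param group_col optional grouping column (e.g. tubule or image id): the
#'   split is then stratified over whole groups, so no group contributes to
#'   both train and validation -- required when rows are tiles sampled from
#'   shared tubules or images, which would otherwise leak between splits.
#' @return An object of class `classification_experiment` with `macro_f1`,
#'   `per_class`, `confusion`, the mode, and split sizes.
#' @export
run_experiment <- function(data, label_col = "type",
                           mode = c("features_both",
                                    "features_concentration_only",
                                    "features_geometry_only", "tiles"),
                           train_frac = 0.7, seed = 1, group_col = NULL) {
  mode <- match.arg(mode)
  if (!label_col %in% names(data))
    stop(sprintf("label column '%s' not in data", label_col), call. = FALSE)
  y <- factor(data[[label_col]])
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(y) < 10))
    stop("need >= 10 instances per class", call. = FALSE)
  cols <- switch(mode,
    features_concentration_only = concentration_feature_cols(),
    features_geometry_only = geometry_feature_cols(),
    features_both = c(concentration_feature_cols(), geometry_feature_cols()),
    tiles = setdiff(names(data), c(label_col, group_col)))
  cols <- intersect(cols, names(data))
  if (length(cols) == 0L) stop("no feature columns available", call. = FALSE)
  X <- data[, cols, drop = FALSE]
  # Drop all-missing columns (e.g. brush border on non-proximal-only data).
  cols <- cols[vapply(X, function(v) any(is.finite(v)), logical(1))]
  X <- data[, cols, drop = FALSE]

  if (is.null(group_col)) {
    train <- with_seed(seed, unlist(lapply(split(seq_along(y), y), function(i)
      sample(i, max(1L, round(train_frac * length(i)))))))
  } else {
    if (!group_col %in% names(data))
      stop(sprintf("group column '%s' not in data", group_col), call. = FALSE)
    grp <- data[[group_col]]
    grp_class <- tapply(as.character(y), grp, function(v) v[1])
    train_groups <- with_seed(seed, unlist(lapply(
      split(names(grp_class), unname(grp_class)), function(g)
        sample(g, max(1L, round(train_frac * length(g)))))))
    train <- which(as.character(grp) %in% train_groups)
  }
  train <- sort(unname(train))
  test <- setdiff(seq_along(y), train)
  if (length(test) == 0L || nlevels(droplevels(y[train])) < nlevels(y))
    stop("stratification failed: class absent from a split", call. = FALSE)

  for (cl in names(X)) {
    med <- median(X[train, cl], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    X[[cl]][!is.finite(X[[cl]])] <- med
  }
  mu <- vapply(X[train, , drop = FALSE], mean, numeric(1))
  sg <- vapply(X[train, , drop = FALSE], sd, numeric(1))
  sg[sg == 0 | !is.finite(sg)] <- 1
  Xs <- as.data.frame(scale(X, center = mu, scale = sg))

  dtrain <- cbind(Xs[train, , drop = FALSE], .y = y[train])
  fit <- nnet::multinom(.y ~ ., data = dtrain, trace = FALSE, maxit = 300,
                        MaxNWts = 5000)
  pred <- predict(fit, newdata = Xs[test, , drop = FALSE])
  pred <- factor(pred, levels = levels(y))
  confusion <- table(truth = y[test], predicted = pred)
  score <- macro_f1(unclass(confusion))
  structure(list(
    macro_f1 = score$macro_f1, per_class = score$per_class,
    confusion = confusion, mode = mode, features = names(X),
    n_train = length(train), n_validation = length(test), seed = seed
  ), class = "classification_experiment")
}

#' @export
print.classification_experiment <- function(x, ...) {
  cat(sprintf(
    "classification_experiment (%s): macro-F1 = %.3f (train %d / validation %d)\n",
    x$mode, x$macro_f1, x$n_train, x$n_validation))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}
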