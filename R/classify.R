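#' Split samples into training and test sets
#'
#' Random split at an integer ratio (default 2:1, giving 160/80 from 240
#' samples). Stratified by class by default; set `stratify = FALSE` to draw
#' the split over the pooled samples, which yields unequal per-class test
#' counts like those of the published tables.
#'
#' @param labels Class labels (one per sample).
#' @param ratio Integer train:test ratio as a length-2 vector, default
#'   `c(2, 1)`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratify Logical, default `TRUE`.
#'
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, ratio = c(2, 1), seed = 1, stratify = TRUE) {
  labels <- as_wheat_factor(labels)
  if (length(ratio) != 2 || any(ratio < 0) || any(ratio != round(ratio)) ||
      sum(ratio) == 0) {
    stop("ratio must be two non-negative integers", call. = FALSE)
  }
  n <- length(labels)
  frac <- ratio[1] / sum(ratio)
  set.seed(seed)
  if (stratify) {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, round(length(idx) * frac)))
    }
    train <- sort(train)
  } else {
    train <- sort(sample(n, round(n * frac)))
  }
  test <- setdiff(seq_len(n), train)
  if (length(test) == 0L) {
    warning("empty test set: all samples assigned to training", call. = FALSE)
  }
  present <- levels(labels)[levels(labels) %in% labels]
  if (any(!present %in% labels[train])) {
    stop("degenerate split: a class is absent from the training set",
         call. = FALSE)
  }
  list(train = train, test = test)
}

# Standardisation fitted on training features only. With blocks = NULL every
# feature is z-scored. With a block id per column (e.g. one id per PCA
# modality block), columns are centred and each block is divided by the root
# mean column variance of the block: the blocks become commensurate (so one
# SVM gamma suits both modalities) while the relative variance ordering of
# the components inside a block -- which carries their signal content -- is
# preserved instead of being flattened to 1.
fit_scaler <- function(x, blocks = NULL) {
  center <- colMeans(x)
  if (is.null(blocks)) {
    scale <- apply(x, 2, sd)
  } else {
    stopifnot(length(blocks) == ncol(x))
    v <- apply(x, 2, var)
    scale <- sqrt(ave(v, blocks))
  }
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' Train a kernel-SVM sub-classifier
#'
#' Fits a C-classification support vector machine (one-vs-one multiclass
#' scheme) with Platt-style pairwise-coupled probability outputs, on
#' standardised features. The standardiser is fitted on the training
#' features only and stored with the model.
#'
#' @param x Feature matrix (samples x features), e.g. PCA scores.
#' @param y Class labels.
#' @param kernel `"radial"`, `"linear"` or `"polynomial"`.
#' @param gamma Kernel width (radial/polynomial), default `1/ncol(x)`.
#' @param cost Penalty parameter C, default 1.
#' @param degree Polynomial degree, default 3.
#' @param blocks Optional block id per feature column. `NULL` (default)
#'   z-scores every column; with blocks (one id per PCA modality block),
#'   each block is scaled by its root mean component variance, which keeps
#'   the within-block variance ordering of the components.
#' @param seed Seed for the internal probability-calibration folds.
#'
#' @return An object of class `thz_svm`: `scaler`, the fitted `e1071::svm`
#'   `model`, `classes` (fixed label order) and `config`.
#' @export
train_svm <- function(x, y, kernel = c("radial", "linear", "polynomial"),
                      gamma = NULL, cost = 1, degree = 3, blocks = NULL,
                      seed = 1) {
  kernel <- match.arg(kernel)
  y <- as_wheat_factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    stop("degenerate labels: need at least two classes to train", call. = FALSE)
  }
  x <- as.matrix(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  scaler <- fit_scaler(x, blocks)
  set.seed(seed)
  # coef0 = 1 gives the usual inhomogeneous polynomial kernel
  model <- e1071::svm(apply_scaler(scaler, x), y, kernel = kernel,
                      gamma = gamma, cost = cost, degree = degree, coef0 = 1,
                      probability = TRUE, scale = FALSE)
  structure(list(scaler = scaler, model = model, classes = levels(y),
                 config = list(kernel = kernel, gamma = gamma, cost = cost,
                               degree = degree, seed = seed)),
            class = "thz_svm")
}

#' @export
print.thz_svm <- function(x, ...) {
  cat(sprintf("<thz_svm> kernel %s (gamma %.4g, C %.4g), %d classes, %d SVs\n",
              x$config$kernel, x$config$gamma, x$config$cost,
              length(x$classes), x$model$tot.nSV))
  invisible(x)
}

#' Per-class probability estimates from a trained SVM
#'
#' @param clf A `thz_svm`.
#' @param x Feature matrix with the same columns as the training features.
#' @return Matrix (samples x classes) of probabilities in the fixed class
#'   order; each row is nonnegative and sums to 1.
#' @export
predict_proba <- function(clf, x) {
  stopifnot(inherits(clf, "thz_svm"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(clf$scaler$center)) {
    stop("dimension error: feature length does not match the classifier",
         call. = FALSE)
  }
  pred <- predict(clf$model, apply_scaler(clf$scaler, x), probability = TRUE)
  p <- attr(pred, "probabilities")[, clf$classes, drop = FALSE]
  rownames(p) <- rownames(x)
  p
}

#' Hard class predictions from a trained SVM
#'
#' Argmax of [predict_proba()], so hard labels and probability outputs are
#' always consistent.
#'
#' @inheritParams predict_proba
#' @return Factor of predicted labels in the fixed class order.
#' @export
predict_class <- function(clf, x) {
  p <- predict_proba(clf, x)
  factor(clf$classes[max.col(p, ties.method = "first")], levels = clf$classes)
}

#' Grid search for SVM hyperparameters
#'
#' Exhaustive search over candidate `(gamma, cost)` pairs by k-fold
#' cross-validated accuracy on the training set. Ties are broken toward the
#' smaller cost, then the smaller gamma.
#'
#' @inheritParams train_svm
#' @param gamma_grid,cost_grid Candidate values (log2 grids by default).
#'   For the linear kernel the gamma grid collapses to a single placeholder
#'   value.
#' @param folds Number of cross-validation folds (default 5).
#'
#' @return List with the selected `gamma`, `cost`, the cross-validated
#'   `accuracy` at the optimum, and the full `results` table.
#' @export
grid_search <- function(x, y, kernel = c("radial", "linear", "polynomial"),
                        gamma_grid = 2^seq(-12, 4, by = 2),
                        cost_grid = 2^seq(-6, 10, by = 2),
                        degree = 3, blocks = NULL, folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  y <- as_wheat_factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("degenerate labels: need at least two classes", call. = FALSE)
  }
  if (length(gamma_grid) == 0L || length(cost_grid) == 0L) {
    stop("invalid grid: empty candidate list", call. = FALSE)
  }
  if (kernel == "linear") gamma_grid <- gamma_grid[1]
  x <- as.matrix(x)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(x)))
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < 2) next
      scaler <- fit_scaler(x[tr, , drop = FALSE], blocks)
      m <- e1071::svm(apply_scaler(scaler, x[tr, , drop = FALSE]),
                      droplevels(y[tr]), kernel = kernel,
                      gamma = grid$gamma[i], cost = grid$cost[i],
                      degree = degree, coef0 = 1, scale = FALSE)
      pr <- predict(m, apply_scaler(scaler, x[!tr, , drop = FALSE]))
      hits <- hits + sum(as.character(pr) == as.character(y[!tr]))
    }
    hits / nrow(x)
  }, numeric(1))
  ord <- order(-acc, grid$cost, grid$gamma)
  best <- ord[1]
  list(gamma = grid$gamma[best], cost = grid$cost[best], accuracy = acc[best],
       results = cbind(grid, accuracy = acc))
}
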