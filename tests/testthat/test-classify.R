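test_that("2:1 split of 240 samples gives 160 train and 80 test", {
  labels <- rep(wheat_classes(), each = 60)
  sp <- split_dataset(labels, ratio = c(2, 1), seed = 4)
  expect_length(sp$train, 160)
  expect_length(sp$test, 80)
  expect_identical(sort(c(sp$train, sp$test)), 1:240)
  # stratified: 40/20 per class
  expect_true(all(table(labels[sp$train]) == 40))
  # deterministic given the seed; non-stratified draws differ per class
  expect_identical(split_dataset(labels, seed = 4), sp)
  sp2 <- split_dataset(labels, seed = 4, stratify = FALSE)
  expect_length(sp2$train, 160)
})

test_that("degenerate splits are flagged", {
  labels <- rep(wheat_classes(), each = 6)
  expect_warning(split_dataset(labels, ratio = c(1, 0), seed = 1),
                 "empty test")
  expect_error(split_dataset(labels, ratio = c(0, 1), seed = 1),
               "degenerate split")
  expect_error(split_dataset(labels, ratio = c(1.5, 1), seed = 1),
               "integers")
  expect_error(split_dataset(c("normal", "oats"), seed = 1), "unknown class")
})

test_that("grid search finds a perfect separator on separable data", {
  fx <- blob_features(n_per_class = 10)
  two <- fx$y %in% c("normal", "moldy")
  gs <- grid_search(fx$x[two, ], droplevels(fx$y[two]), kernel = "radial",
                    folds = 3, seed = 2)
  expect_equal(gs$accuracy, 1)
  single <- grid_search(fx$x, fx$y, gamma_grid = 0.5, cost_grid = 2,
                        folds = 3, seed = 2)
  expect_equal(c(single$gamma, single$cost), c(0.5, 2))
  expect_error(grid_search(fx$x, fx$y, gamma_grid = numeric(0)),
               "invalid grid")
  expect_error(grid_search(fx$x, rep("normal", nrow(fx$x))),
               "degenerate labels")
})

test_that("grid-search ties break toward smaller cost then smaller gamma", {
  fx <- blob_features(n_per_class = 8)
  gs <- grid_search(fx$x, fx$y, kernel = "radial",
                    gamma_grid = c(0.1, 0.01), cost_grid = c(1, 10),
                    folds = 3, seed = 2)
  # fully separable: many grid points reach 100%; smallest (cost, gamma) wins
  hits <- gs$results[gs$results$accuracy == gs$accuracy, ]
  expect_equal(gs$cost, min(hits$cost))
  expect_equal(gs$gamma, min(hits$gamma[hits$cost == gs$cost]))
})

test_that("SVM separates Gaussian blobs and yields calibrated probabilities", {
  fx <- blob_features(n_per_class = 45)
  idx <- rep(rep(c(TRUE, FALSE), c(40, 5)), 4)
  clf <- train_svm(fx$x[idx, ], fx$y[idx], kernel = "radial", gamma = 0.5,
                   cost = 10, seed = 3)
  p <- predict_proba(clf, fx$x[!idx, ])
  expect_equal(rowSums(p), rep(1, sum(!idx)), tolerance = 1e-9)
  expect_true(all(p >= 0))
  hard <- predict_class(clf, fx$x[!idx, ])
  expect_equal(as.character(hard), as.character(fx$y[!idx]))  # 100% accuracy
  # argmax of probabilities agrees with the hard prediction
  expect_identical(as.integer(hard), max.col(p, ties.method = "first"))
  # a point deep inside the normal blob is confidently normal
  expect_gt(predict_proba(clf, matrix(c(0, 0), 1))[1, "normal"], 0.9)
})

test_that("training is deterministic and support-set invariant", {
  fx <- blob_features(n_per_class = 8)
  c1 <- train_svm(fx$x, fx$y, kernel = "radial", gamma = 0.3, cost = 5,
                  seed = 6)
  c2 <- train_svm(fx$x, fx$y, kernel = "radial", gamma = 0.3, cost = 5,
                  seed = 6)
  grid <- as.matrix(expand.grid(seq(-2, 10, 2), seq(-2, 10, 2)))
  expect_equal(predict_proba(c1, grid), predict_proba(c2, grid))
  # duplicating every training point leaves the decision function unchanged
  c3 <- train_svm(rbind(fx$x, fx$x), c(as.character(fx$y), as.character(fx$y)),
                  kernel = "radial", gamma = 0.3, cost = 5, seed = 6)
  expect_equal(as.character(predict_class(c1, grid)),
               as.character(predict_class(c3, grid)))
})

test_that("degenerate classifier inputs error clearly", {
  fx <- blob_features(n_per_class = 5)
  expect_error(train_svm(fx$x, rep("moldy", nrow(fx$x))), "degenerate labels")
  clf <- train_svm(fx$x, fx$y, seed = 1)
  expect_error(predict_proba(clf, matrix(0, 1, 5)), "dimension error")
})

test_that("block scaling preserves within-block variance ordering", {
  set.seed(12)
  x <- cbind(rnorm(50, sd = 4), rnorm(50, sd = 2), rnorm(50, sd = 1))
  sc_z <- thzwheat:::fit_scaler(x)
  sc_b <- thzwheat:::fit_scaler(x, blocks = c(1, 1, 2))
  xz <- thzwheat:::apply_scaler(sc_z, x)
  xb <- thzwheat:::apply_scaler(sc_b, x)
  expect_equal(unname(apply(xz, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # z-scoring flattens the 4:2 ratio of block 1; block scaling keeps it
  expect_equal(sd(xb[, 1]) / sd(xb[, 2]), sd(x[, 1]) / sd(x[, 2]),
               tolerance = 1e-12)
  # each block ends up with unit mean variance
  expect_equal(mean(apply(xb[, 1:2], 2, var)), 1, tolerance = 1e-12)
  expect_equal(var(xb[, 3]), 1, tolerance = 1e-12)
})
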