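#' Fit a multi-source wheat-quality fusion model
#'
#' Central fitting interface. From per-modality spectral matrices
#' (absorption coefficient and refractive index over the analysis band) it
#' fits per-modality PCA feature models and then fuses the two optical
#' sources in one of two ways:
#'
#' * `method = "feature"` — feature-layer fusion: the absorption and
#'   refraction PCA scores (8 + 10 components by default) are concatenated
#'   and a single kernel SVM is trained on the fused vector.
#' * `method = "decision"` — decision-layer fusion: one RBF-SVM
#'   sub-classifier per modality (10 and 8 components by default), whose
#'   probability outputs are discounted into Dempster-Shafer basic
#'   probability assignments, combined by Dempster's rule over the frame
#'   \{normal, germinated, moldy, worm-eaten, U\} and resolved by an
#'   epsilon-threshold decision rule. Each source's belief weight is its
#'   sub-classifier's cross-validated training accuracy.
#'
#' Hyperparameters are grid-searched by cross-validated accuracy unless
#' `gamma`/`cost` are given explicitly.
#'
#' @param absorption,refraction Numeric matrices (samples x frequency bins)
#'   of training spectra, same row order; e.g. the `alpha` and `n` elements
#'   of [extract_dataset()].
#' @param labels Training class labels.
#' @param method `"feature"` or `"decision"`.
#' @param kernel SVM kernel for feature-layer fusion: `"radial"` (default),
#'   `"linear"` or `"polynomial"`. Decision-layer sub-classifiers always use
#'   the radial kernel.
#' @param k_abs,k_ref PCA components per modality. Defaults: 8/10 for the
#'   feature layer, 10/8 for the decision layer.
#' @param gamma,cost Optional fixed SVM hyperparameters; when `NULL` they
#'   are grid-searched. For `method = "decision"` supply length-2 vectors
#'   (absorption, refraction).
#' @param gamma_grid,cost_grid Candidate grids for [grid_search()].
#' @param degree Polynomial-kernel degree.
#' @param epsilon1,epsilon2 Decision-rule thresholds (decision layer only).
#' @param cv_folds Cross-validation folds for the grid search.
#' @param seed Integer seed controlling the grid-search folds and the SVM
#'   probability calibration.
#'
#' @return An object of class `thz_fusion` (subclass `thz_feature_fusion`
#'   or `thz_decision_fusion`) with `print`, `summary` and `predict`
#'   methods.
#' @seealso [predict.thz_fusion()], [run_all()]
#' @export
thz_fusion <- function(absorption, refraction, labels,
                       method = c("feature", "decision"),
                       kernel = c("radial", "linear", "polynomial"),
                       k_abs = NULL, k_ref = NULL,
                       gamma = NULL, cost = NULL,
                       gamma_grid = 2^seq(-12, 4, by = 2),
                       cost_grid = 2^seq(-6, 10, by = 2),
                       degree = 3, epsilon1 = 0.1, epsilon2 = 0.3,
                       cv_folds = 5, seed = 1) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  labels <- as_wheat_factor(labels)
  absorption <- as.matrix(absorption)
  refraction <- as.matrix(refraction)
  stopifnot(nrow(absorption) == nrow(refraction),
            nrow(absorption) == length(labels))
  if (is.null(k_abs)) k_abs <- if (method == "feature") 8L else 10L
  if (is.null(k_ref)) k_ref <- if (method == "feature") 10L else 8L

  pca_abs <- fit_pca(absorption, k_abs, "absorption")
  pca_ref <- fit_pca(refraction, k_ref, "refraction")
  sc_abs <- predict(pca_abs, absorption)
  sc_ref <- predict(pca_ref, refraction)

  if (method == "feature") {
    fused <- concat_features(sc_abs, sc_ref)
    blocks <- rep(1:2, c(k_abs, k_ref))   # per-modality scaling blocks
    if (is.null(gamma) || is.null(cost)) {
      gs <- grid_search(fused, labels, kernel = kernel,
                        gamma_grid = gamma_grid, cost_grid = cost_grid,
                        degree = degree, blocks = blocks, folds = cv_folds,
                        seed = seed)
      gamma <- gs$gamma; cost <- gs$cost; cv_accuracy <- gs$accuracy
    } else {
      cv_accuracy <- NA_real_
    }
    clf <- train_svm(fused, labels, kernel = kernel, gamma = gamma,
                     cost = cost, degree = degree, blocks = blocks,
                     seed = seed)
    obj <- list(method = method, kernel = kernel,
                pca_abs = pca_abs, pca_ref = pca_ref, clf = clf,
                cv_accuracy = cv_accuracy, labels = labels, seed = seed)
    class(obj) <- c("thz_feature_fusion", "thz_fusion")
  } else {
    if (is.null(gamma) || is.null(cost)) {
      gs_a <- grid_search(sc_abs, labels, kernel = "radial",
                          gamma_grid = gamma_grid, cost_grid = cost_grid,
                          blocks = rep(1L, k_abs), folds = cv_folds,
                          seed = seed)
      gs_r <- grid_search(sc_ref, labels, kernel = "radial",
                          gamma_grid = gamma_grid, cost_grid = cost_grid,
                          blocks = rep(1L, k_ref), folds = cv_folds,
                          seed = seed + 1L)
      gamma <- c(gs_a$gamma, gs_r$gamma)
      cost <- c(gs_a$cost, gs_r$cost)
      bel <- c(absorption = gs_a$accuracy, refraction = gs_r$accuracy)
    } else {
      gamma <- rep_len(gamma, 2); cost <- rep_len(cost, 2)
      bel <- c(absorption = 1, refraction = 1)
    }
    clf_abs <- train_svm(sc_abs, labels, kernel = "radial", gamma = gamma[1],
                         cost = cost[1], blocks = rep(1L, k_abs), seed = seed)
    clf_ref <- train_svm(sc_ref, labels, kernel = "radial", gamma = gamma[2],
                         cost = cost[2], blocks = rep(1L, k_ref),
                         seed = seed + 1L)
    obj <- list(method = method, kernel = "radial",
                pca_abs = pca_abs, pca_ref = pca_ref,
                clf_abs = clf_abs, clf_ref = clf_ref, bel = bel,
                epsilon1 = epsilon1, epsilon2 = epsilon2,
                labels = labels, seed = seed)
    class(obj) <- c("thz_decision_fusion", "thz_fusion")
  }
  obj
}

#' Predict wheat quality from a fitted fusion model
#'
#' @param object A `thz_fusion` model.
#' @param absorption,refraction Spectral matrices for the samples to
#'   classify, on the training frequency grid and in the same row order.
#' @param type `"class"` for hard labels (decision-layer deferrals fall
#'   back to the argmax of the combined masses so confusion tables stay
#'   4-way); `"prob"` for per-class probabilities (feature layer) or
#'   combined masses including U (decision layer); `"full"` for the
#'   complete per-sample decision frame of the decision layer (includes the
#'   raw `"uncertain"` decisions and conflict K).
#' @param ... Unused.
#' @return Factor, matrix, or data.frame according to `type`.
#' @export
predict.thz_fusion <- function(object, absorption, refraction,
                               type = c("class", "prob", "full"), ...) {
  type <- match.arg(type)
  sc_abs <- predict(object$pca_abs, as.matrix(absorption))
  sc_ref <- predict(object$pca_ref, as.matrix(refraction))
  if (inherits(object, "thz_feature_fusion")) {
    fused <- concat_features(sc_abs, sc_ref)
    if (type == "prob") return(predict_proba(object$clf, fused))
    cls <- predict_class(object$clf, fused)
    if (type == "class") return(cls)
    data.frame(decision = as.character(cls), fallback = as.character(cls),
               predict_proba(object$clf, fused), check.names = FALSE)
  } else {
    df <- ds_pipeline(object$clf_abs, object$clf_ref, sc_abs, sc_ref,
                      bel_abs = object$bel[["absorption"]],
                      bel_ref = object$bel[["refraction"]],
                      epsilon1 = object$epsilon1, epsilon2 = object$epsilon2)
    switch(type,
           full = df,
           prob = as.matrix(df[, c(object$clf_abs$classes, "m_U")]),
           class = factor(df$fallback, levels = object$clf_abs$classes))
  }
}

#' @export
print.thz_fusion <- function(x, ...) {
  if (inherits(x, "thz_feature_fusion")) {
    cat(sprintf(
      "Feature-layer fusion model (%s kernel)\n  PCA: %d absorption + %d refraction components\n  SVM: gamma %.4g, C %.4g%s\n",
      x$kernel, x$pca_abs$k, x$pca_ref$k,
      x$clf$config$gamma, x$clf$config$cost,
      if (is.na(x$cv_accuracy)) "" else
        sprintf(" (CV accuracy %.1f%%)", 100 * x$cv_accuracy)))
  } else {
    cat(sprintf(
      "Decision-layer fusion model (Dempster-Shafer over {%s, U})\n  PCA: %d absorption + %d refraction components\n  Sub-classifiers: RBF-SVM gamma (%.4g, %.4g), C (%.4g, %.4g)\n  Belief weights: absorption %.3f, refraction %.3f; eps1 %.2f, eps2 %.2f\n",
      paste(x$clf_abs$classes, collapse = ", "),
      x$pca_abs$k, x$pca_ref$k,
      x$clf_abs$config$gamma, x$clf_ref$config$gamma,
      x$clf_abs$config$cost, x$clf_ref$config$cost,
      x$bel[["absorption"]], x$bel[["refraction"]],
      x$epsilon1, x$epsilon2))
  }
  cat(sprintf("  Trained on %d samples\n", length(x$labels)))
  invisible(x)
}

#' Summarise a fitted fusion model on given data
#'
#' @param object A `thz_fusion` model.
#' @param absorption,refraction Optional spectra to evaluate; when omitted,
#'   only the model description is printed by the associated print method.
#' @param labels True labels for the supplied spectra.
#' @param ... Unused.
#' @return A `recognition_report` (invisibly the model if no data given).
#' @export
summary.thz_fusion <- function(object, absorption = NULL, refraction = NULL,
                               labels = NULL, ...) {
  if (is.null(absorption)) {
    print(object)
    return(invisible(object))
  }
  pred <- predict(object, absorption, refraction, type = "class")
  unc <- NA_integer_
  if (inherits(object, "thz_decision_fusion")) {
    full <- predict(object, absorption, refraction, type = "full")
    unc <- sum(full$decision == "uncertain")
  }
  rates(confusion(labels, pred), uncertain_count = unc)
}
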