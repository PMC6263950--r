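#' Fit a PCA feature model for one optical modality
#'
#' Centered (not variance-scaled) principal component analysis of a
#' samples-by-bins spectral matrix, fitted on training data only. The sign
#' of each component is fixed so its largest-magnitude loading element is
#' positive, making the decomposition deterministic.
#'
#' @param x Numeric matrix, samples in rows, frequency bins in columns.
#' @param k Number of components to keep. Defaults in the fusion models
#'   follow the published feature sets (8 absorption / 10 refraction at the
#'   feature layer; 10 / 8 for the decision-layer sub-classifiers).
#' @param modality `"absorption"` or `"refraction"`; carried onto scores.
#'
#' @return An object of class `thz_pca`: `mean` (per-bin mean), `loadings`
#'   (bins x k, orthonormal columns), `explained_variance` (fraction per
#'   component, non-increasing), `k`, `modality`.
#' @export
fit_pca <- function(x, k, modality = c("absorption", "refraction")) {
  modality <- match.arg(modality)
  x <- as.matrix(x)
  if (nrow(x) < k + 1) {
    stop("rank deficiency: need at least k + 1 training samples", call. = FALSE)
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  if (k > ncol(p$rotation) || p$sdev[k] < 1e-12 * p$sdev[1]) {
    stop("rank deficiency: k exceeds the rank of the training data",
         call. = FALSE)
  }
  load <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  structure(list(mean = p$center, loadings = load,
                 explained_variance = p$sdev^2 / sum(p$sdev^2), k = k,
                 modality = modality),
            class = "thz_pca")
}

#' @export
print.thz_pca <- function(x, ...) {
  cat(sprintf("<thz_pca> %s, %d components (%.1f%% variance)\n", x$modality,
              x$k, 100 * sum(x$explained_variance[seq_len(x$k)])))
  invisible(x)
}

#' Project spectra onto a fitted PCA model
#'
#' @param object A `thz_pca` model.
#' @param newdata Matrix (samples x bins) or a single spectrum vector on the
#'   training grid.
#' @param ... Unused.
#' @return Score matrix (samples x k) with attribute `modality`.
#' @export
predict.thz_pca <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != length(object$mean)) {
    stop("grid mismatch: spectrum length differs from the training grid",
         call. = FALSE)
  }
  scores <- sweep(x, 2, object$mean) %*% object$loadings
  colnames(scores) <- paste0(substr(object$modality, 1, 3), "_pc",
                             seq_len(object$k))
  structure(scores, modality = object$modality)
}

#' Concatenate feature vectors from two modalities
#'
#' Feature-layer fusion: the per-modality PCA score blocks of the same
#' samples are concatenated into one fused feature matrix (by convention
#' absorption scores first, then refraction; 8 + 10 = 18 columns under the
#' feature-layer defaults).
#'
#' @param a,b Score matrices from [predict.thz_pca()] with distinct
#'   modalities and identical row order.
#' @return Fused score matrix with attribute `modality = "fused"`.
#' @export
concat_features <- function(a, b) {
  if (ncol(a) == 0L) return(b)
  if (ncol(b) == 0L) return(a)
  ma <- attr(a, "modality"); mb <- attr(b, "modality")
  if (!is.null(ma) && !is.null(mb) && identical(ma, mb)) {
    stop("invalid fusion: both feature blocks come from the same modality",
         call. = FALSE)
  }
  if (nrow(a) != nrow(b) ||
      (!is.null(rownames(a)) && !is.null(rownames(b)) &&
       !identical(rownames(a), rownames(b)))) {
    stop("invalid fusion: feature blocks describe different samples",
         call. = FALSE)
  }
  structure(cbind(a, b), modality = "fused")
}
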