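# Shared fixtures built in code at test time.

# Four well-separated Gaussian blobs in 2-D feature space, one per quality
# class; separation 8 sd units makes them linearly separable.
blob_features <- function(n_per_class = 12, sd = 0.5, seed = 42) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:4, function(k) {
    cbind(rnorm(n_per_class, centers[k, 1], sd),
          rnorm(n_per_class, centers[k, 2], sd))
  }))
  list(x = x, y = factor(rep(wheat_classes(), each = n_per_class),
                         levels = wheat_classes()))
}

# Small simulated dataset + extracted spectra (cheap; ~1 s)
small_spectra <- function(n_per_class = 8, seed = 7, n_scans = 2) {
  extract_dataset(generate_dataset(n_per_class = n_per_class, seed = seed,
                                   n_scans = n_scans))
}

# Random mass function on a given frame (singletons + U)
random_mass <- function(frame = c(wheat_classes(), "U")) {
  x <- runif(length(frame))
  mass_function(setNames(x / sum(x), frame), frame = frame)
}

# Independent oracle: Dempster combination by exhaustive enumeration over
# focal-element pairs with explicit set intersection (U = the whole frame).
ds_combine_oracle <- function(m1, m2) {
  frame <- names(m1)
  sing <- setdiff(frame, "U")
  sets <- c(as.list(sing), list(sing))
  names(sets) <- frame
  K <- 0
  comb <- setNames(numeric(length(frame)), frame)
  for (i in frame) {
    for (j in frame) {
      p <- unclass(m1)[[i]] * unclass(m2)[[j]]
      inter <- intersect(sets[[i]], sets[[j]])
      if (length(inter) == 0L) {
        K <- K + p
      } else {
        target <- if (setequal(inter, sing)) "U" else inter
        comb[[target]] <- comb[[target]] + p
      }
    }
  }
  list(mass = comb / (1 - K), K = K)
}

# Expand a confusion-count matrix into (truth, predicted) label lists
labels_from_counts <- function(counts) {
  classes <- rownames(counts)
  truth <- character(0); pred <- character(0)
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      truth <- c(truth, rep(classes[i], counts[i, j]))
      pred <- c(pred, rep(classes[j], counts[i, j]))
    }
  }
  list(truth = truth, pred = pred)
}

# Plain named numeric view of a mass function (drops class/source attributes)
mvec <- function(m) setNames(as.numeric(m), names(m))
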