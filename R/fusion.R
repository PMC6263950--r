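#' Basic probability assignment over the wheat-quality frame
#'
#' A Dempster-Shafer mass function over the frame of discernment
#' Theta = {normal, germinated, moldy, worm-eaten, U}, where U is the whole
#' frame ("wheat of uncertain quality"). Focal elements are restricted to
#' the four singletons plus U.
#'
#' @param masses Named numeric vector of nonnegative masses over the four
#'   class singletons and `"U"`, summing to 1 (within 1e-9). Missing focal
#'   elements are taken as 0.
#' @param source Evidence source tag: `"absorption"`, `"refraction"` or
#'   `"combined"`.
#' @param frame Frame of discernment: singleton labels followed by `"U"`.
#'   Defaults to the wheat-quality frame; smaller frames are accepted so
#'   the combination algebra can be exercised on reduced hypothesis sets.
#' @return An object of class `mass_function` (a named numeric vector with a
#'   `source` attribute).
#' @export
mass_function <- function(masses, source = c("combined", "absorption",
                                             "refraction"),
                          frame = c(wheat_classes(), "U")) {
  source <- match.arg(source)
  if (frame[length(frame)] != "U" || anyDuplicated(frame)) {
    stop("frame must be distinct singletons followed by \"U\"", call. = FALSE)
  }
  bad <- setdiff(names(masses), frame)
  if (length(bad) > 0L) {
    stop("unknown focal element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- setNames(numeric(length(frame)), frame)
  m[names(masses)] <- masses
  if (any(m < -1e-12)) stop("masses must be nonnegative", call. = FALSE)
  if (abs(sum(m) - 1) > 1e-9) {
    stop("masses must sum to 1 (got ", format(sum(m)), ")", call. = FALSE)
  }
  structure(pmax(m, 0), source = source, class = "mass_function")
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  cat(sprintf("<mass_function> source: %s\n", attr(x, "source")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Convert classifier probabilities to a basic probability assignment
#'
#' Shafer discounting of a sub-classifier's probability output: each
#' singleton receives `reliability * probability` and the complement
#' `1 - reliability` goes to U, the whole frame. The reliability plays the
#' role of the source's belief weight; in the decision-layer fusion model it
#' is the sub-classifier's cross-validated training accuracy.
#'
#' @param probs Named per-class probability vector (must sum to 1).
#' @param reliability Source belief weight in \[0, 1\].
#' @param source Evidence source tag.
#' @return A `mass_function`.
#' @export
proba_to_bpa <- function(probs, reliability = 1,
                         source = c("absorption", "refraction", "combined")) {
  source <- match.arg(source)
  if (abs(sum(probs) - 1) > 1e-6 || any(probs < -1e-12)) {
    stop("invalid probability vector: entries must be nonnegative and sum to 1",
         call. = FALSE)
  }
  if (reliability < 0 || reliability > 1) {
    stop("reliability must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(probs))) names(probs) <- wheat_classes()
  m <- c(reliability * pmax(probs, 0) / sum(probs), U = 1 - reliability)
  mass_function(m, source = source)
}

#' Combine two mass functions by Dempster's rule
#'
#' Orthogonal sum over the singletons-plus-U frame. The conflict coefficient
#' K collects the mass products of focal pairs with empty intersection
#' (distinct singletons); pairs intersecting to a singleton A (A with A,
#' A with U, U with A) contribute to the combined mass of A, and U with U to
#' the combined mass of U. The result is normalised by 1 - K.
#'
#' @param m1,m2 `mass_function` objects on the same frame.
#' @return List with `mass` (the combined `mass_function`, source
#'   `"combined"`) and `K` (the conflict coefficient in \[0, 1)).
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  if (!identical(names(m1), names(m2))) {
    stop("mass functions are not defined on the same frame", call. = FALSE)
  }
  s <- setdiff(names(m1), "U")
  a <- unclass(m1)[s]; b <- unclass(m2)[s]
  u1 <- unclass(m1)[["U"]]; u2 <- unclass(m2)[["U"]]
  K <- sum(a) * sum(b) - sum(a * b)   # all cross products of distinct singletons
  if (1 - K < 1e-12) {
    stop("total conflict: the two sources fully contradict (K = 1)",
         call. = FALSE)
  }
  comb <- (a * b + a * u2 + u1 * b) / (1 - K)
  mU <- u1 * u2 / (1 - K)
  m <- c(comb, U = mU)
  list(mass = mass_function(m / sum(m), source = "combined",
                            frame = names(m1)),
       K = K)
}

#' Threshold decision rule on a combined mass function
#'
#' Let A1 be the singleton with the largest combined mass and A2 the
#' runner-up. A1 is accepted as the final decision iff all three conditions
#' hold: `m(A1) - m(A2) > epsilon1`, `m(U) < epsilon2`, and `m(A1) > m(U)`.
#' Otherwise the sample is deferred as `"uncertain"`. Argmax ties are broken
#' by the fixed class order and flagged via the `"tie"` attribute.
#'
#' @param mc A combined `mass_function`.
#' @param epsilon1 Minimum margin between the top two singleton masses
#'   (default 0.1).
#' @param epsilon2 Maximum tolerated mass on U (default 0.3).
#' @return Character scalar: a class label or `"uncertain"`, with attributes
#'   `A1` (the argmax label) and `tie`.
#' @export
ds_decide <- function(mc, epsilon1 = 0.1, epsilon2 = 0.3) {
  stopifnot(inherits(mc, "mass_function"))
  s <- unclass(mc)[setdiff(names(mc), "U")]
  mU <- unclass(mc)[["U"]]
  ord <- order(-s)                      # stable: ties keep fixed class order
  A1 <- names(s)[ord[1]]; A2 <- names(s)[ord[2]]
  tie <- s[ord[1]] == s[ord[2]]
  ok <- (s[ord[1]] - s[ord[2]] > epsilon1) && (mU < epsilon2) &&
    (s[ord[1]] > mU)
  structure(if (ok) A1 else "uncertain", A1 = A1, tie = unname(tie))
}

#' Decision-layer fusion of two sub-classifiers
#'
#' Runs the full Dempster-Shafer chain for every sample: per-modality
#' probability outputs are discounted into basic probability assignments,
#' combined by Dempster's rule, and passed through the epsilon-threshold
#' decision rule. For recognition-rate tables, deferred ("uncertain")
#' samples are also scored by the argmax of the combined singleton masses
#' (`fallback` column), so confusion matrices stay 4-way.
#'
#' @param abs_clf,ref_clf Trained `thz_svm` sub-classifiers for the
#'   absorption and refraction modalities (same class order).
#' @param abs_x,ref_x Feature matrices for the same samples in the same row
#'   order.
#' @param bel_abs,bel_ref Source reliabilities (belief weights) in \[0, 1\];
#'   typically the sub-classifiers' cross-validated training accuracies.
#' @param epsilon1,epsilon2 Decision thresholds, see [ds_decide()].
#' @return A data.frame with one row per sample: `decision` (label or
#'   `"uncertain"`), `fallback` (argmax label), `K` (conflict), the
#'   combined singleton masses and `m_U`.
#' @export
ds_pipeline <- function(abs_clf, ref_clf, abs_x, ref_x,
                        bel_abs = 1, bel_ref = 1,
                        epsilon1 = 0.1, epsilon2 = 0.3) {
  if (!identical(abs_clf$classes, ref_clf$classes)) {
    stop("sub-classifiers do not share a class order", call. = FALSE)
  }
  pa <- predict_proba(abs_clf, abs_x)
  pr <- predict_proba(ref_clf, ref_x)
  if (nrow(pa) != nrow(pr)) {
    stop("feature sets describe different numbers of samples", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(pa)), function(i) {
    ma <- proba_to_bpa(pa[i, ], bel_abs, source = "absorption")
    mr <- proba_to_bpa(pr[i, ], bel_ref, source = "refraction")
    comb <- dempster_combine(ma, mr)
    dec <- ds_decide(comb$mass, epsilon1, epsilon2)
    c(list(decision = as.character(dec), fallback = attr(dec, "A1"),
           K = comb$K), as.list(unclass(comb$mass)))
  })
  df <- do.call(rbind.data.frame, out)
  names(df) <- c("decision", "fallback", "K", abs_clf$classes, "m_U")
  rownames(df) <- rownames(pa)
  df
}
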