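#' Round half away from zero
#'
#' Display rounding used by the recognition-rate tables (e.g. 20/21 ->
#' 95.24), as opposed to base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion matrix of true vs predicted quality classes
#'
#' @param truth,predicted Label vectors of equal length; every label must be
#'   one of `wheat_classes()`.
#' @param split Optional tag, `"train"` or `"test"`.
#' @return An object of class `thz_confusion`: a 4x4 integer matrix (true
#'   class in rows, predicted in columns, fixed class order) with a `split`
#'   attribute.
#' @export
confusion <- function(truth, predicted, split = NULL) {
  truth <- as_wheat_factor(truth)
  predicted <- as_wheat_factor(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predictions differ in length", call. = FALSE)
  }
  cm <- table(truth, predicted)
  structure(unclass(cm)[wheat_classes(), wheat_classes()], split = split,
            class = "thz_confusion")
}

#' @export
print.thz_confusion <- function(x, ...) {
  cat("<thz_confusion>",
      if (!is.null(attr(x, "split"))) paste0(" (", attr(x, "split"), ")"),
      "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Recognition-rate report from a confusion matrix
#'
#' Per-class recognition rate (percent of each true class predicted
#' correctly), the false-judgment count per class (off-diagonal row mass),
#' and the overall recognition rate (trace over total). Percentages are
#' kept unrounded internally; the printed table rounds half-up to two
#' decimals in the style of the published tables.
#'
#' @param cm A `thz_confusion` (or plain square count matrix with class
#'   dimnames).
#' @param uncertain_count Optional count of samples the decision-layer rule
#'   deferred as uncertain (reported alongside, not part of the 4-way
#'   counts).
#' @return An object of class `recognition_report`: list with `counts`,
#'   `per_class_rate`, `false_judgments`, `overall_rate`, `uncertain_count`,
#'   `split`.
#' @export
rates <- function(cm, uncertain_count = NA_integer_) {
  counts <- unclass(cm)
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("undefined rate: a class has no samples", call. = FALSE)
  }
  per_class <- 100 * diag(counts) / rs
  structure(list(counts = counts,
                 per_class_rate = per_class,
                 false_judgments = rs - diag(counts),
                 overall_rate = 100 * sum(diag(counts)) / sum(counts),
                 uncertain_count = uncertain_count,
                 split = attr(cm, "split")),
            class = "recognition_report")
}

#' @export
print.recognition_report <- function(x, ...) {
  cat("Recognition report", if (!is.null(x$split)) paste0(" (", x$split, ")"),
      "\n", sep = "")
  df <- data.frame(
    n = rowSums(x$counts),
    false_judgments = x$false_judgments,
    rate_pct = round_half_up(x$per_class_rate)
  )
  print(df)
  cat(sprintf("Overall recognition rate: %.2f%%\n",
              round_half_up(x$overall_rate)))
  if (!is.na(x$uncertain_count)) {
    cat(sprintf("Deferred as uncertain: %d\n", x$uncertain_count))
  }
  invisible(x)
}

#' Compare fusion models by overall recognition rate
#'
#' @param reports Named list (>= 2 entries) of `recognition_report`s.
#' @return An object of class `model_comparison`: data.frame sorted by
#'   decreasing overall rate (stable for ties), with per-class rates.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2L) {
    stop("need at least two reports to compare", call. = FALSE)
  }
  stopifnot(!is.null(names(reports)))
  overall <- vapply(reports, `[[`, numeric(1), "overall_rate")
  per <- t(vapply(reports, `[[`, numeric(length(reports[[1]]$per_class_rate)),
                  "per_class_rate"))
  df <- data.frame(model = names(reports), overall_rate = overall, per,
                   check.names = FALSE, row.names = NULL)
  df <- df[order(-df$overall_rate), , drop = FALSE]  # radix sort: stable ties
  rownames(df) <- NULL
  structure(df, class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (overall test recognition rate, %):\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round_half_up)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Serialise a recognition report to a JSON-ready list
#'
#' @param report A `recognition_report`.
#' @param model Model name recorded in the output.
#' @return A plain list matching the report schema (`model`, `split`,
#'   `counts`, `per_class_rate`, `overall_rate`, `uncertain_count`).
#' @export
report_as_list <- function(report, model = "model") {
  list(model = model,
       split = if (is.null(report$split)) NA else report$split,
       counts = unname(apply(report$counts, 1, as.list)),
       classes = rownames(report$counts),
       per_class_rate = as.list(setNames(round_half_up(report$per_class_rate),
                                         rownames(report$counts))),
       overall_rate = round_half_up(report$overall_rate),
       uncertain_count = report$uncertain_count)
}
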