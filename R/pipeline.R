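#' Pipeline configuration
#'
#' Validated configuration for the end-to-end pipeline. Defaults mirror the
#' published measurement and modelling protocol: 60 samples per class
#' scanned 5 times through 1 mm pellets, a 0.2-1.6 THz analysis band, a 2:1
#' train/test split, feature-layer PCA counts 8 (absorption) / 10
#' (refraction) and decision-layer counts 10 / 8, and decision thresholds
#' epsilon1 = 0.1, epsilon2 = 0.3.
#'
#' @param seed Master seed; per-stage sub-seeds are derived by fixed
#'   offsets so stages can be rerun in isolation.
#' @param n_per_class,n_scans Simulation sizes.
#' @param d_mm Pellet thickness (mm).
#' @param band,grid_step Analysis band (THz) and grid step.
#' @param split_ratio Train:test ratio (two integers).
#' @param stratify Stratify the split by class.
#' @param k_feature,k_decision Length-2 integer vectors of PCA components
#'   (absorption, refraction) for the two fusion layers.
#' @param epsilon1,epsilon2 Dempster-Shafer decision thresholds.
#' @param gamma_grid,cost_grid Hyperparameter grids.
#' @param cv_folds Cross-validation folds.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_per_class = 60, n_scans = 5, d_mm = 1,
                            band = c(0.2, 1.6), grid_step = 0.01,
                            split_ratio = c(2, 1), stratify = TRUE,
                            k_feature = c(8L, 10L), k_decision = c(10L, 8L),
                            epsilon1 = 0.1, epsilon2 = 0.3,
                            gamma_grid = 2^seq(-12, 4, by = 2),
                            cost_grid = 2^seq(-6, 10, by = 2),
                            cv_folds = 5) {
  cfg <- list(seed = as.integer(seed), n_per_class = n_per_class,
              n_scans = n_scans, d_mm = d_mm, band = band,
              grid_step = grid_step, split_ratio = split_ratio,
              stratify = isTRUE(stratify), k_feature = k_feature,
              k_decision = k_decision, epsilon1 = epsilon1,
              epsilon2 = epsilon2, gamma_grid = gamma_grid,
              cost_grid = cost_grid, cv_folds = cv_folds)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("config error at '", field, "': ", msg, call. = FALSE)
  }
  chk(length(cfg$band) == 2 && cfg$band[1] < cfg$band[2], "band",
      "must be (lo, hi) with lo < hi")
  chk(cfg$band[1] > 0, "band", "lo must be positive")
  chk(cfg$d_mm > 0, "d_mm", "thickness must be positive")
  chk(cfg$n_per_class >= 1, "n_per_class", "must be >= 1")
  chk(cfg$n_scans >= 1, "n_scans", "must be >= 1")
  chk(cfg$grid_step > 0, "grid_step", "must be positive")
  chk(length(cfg$split_ratio) == 2 && all(cfg$split_ratio >= 0),
      "split_ratio", "must be two non-negative integers")
  chk(length(cfg$k_feature) == 2 && all(cfg$k_feature >= 1), "k_feature",
      "must be two positive counts")
  chk(length(cfg$k_decision) == 2 && all(cfg$k_decision >= 1), "k_decision",
      "must be two positive counts")
  chk(cfg$epsilon1 >= 0 && cfg$epsilon1 < 1, "epsilon1", "must be in [0, 1)")
  chk(cfg$epsilon2 > 0 && cfg$epsilon2 <= 1, "epsilon2", "must be in (0, 1]")
  chk(cfg$cv_folds >= 2, "cv_folds", "must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown fields raise a config error; missing fields take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("config error at '", bad[1], "': unknown field", call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full recognition pipeline
#'
#' Orchestrates simulate -> extract -> split -> fit (RBF / linear /
#' polynomial feature-layer fusion and Dempster-Shafer decision-layer
#' fusion) -> evaluate -> compare. Deterministic given `config$seed`; the
#' master seed fans out to the simulation, split and model stages by fixed
#' offsets.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, the simulated traces,
#'   extracted spectra and the JSON report are written there.
#' @param verbose Print progress to stderr.
#' @return A list of class `thz_run`: `comparison` (a `model_comparison` of
#'   test-set performance), `reports` (per model, train and test
#'   `recognition_report`s), `models`, `split`, `spectra`, `config`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  say("simulating ", 4 * config$n_per_class, " samples")
  dataset <- generate_dataset(n_per_class = config$n_per_class,
                              seed = config$seed, n_scans = config$n_scans,
                              d_mm = config$d_mm)
  say("extracting optical spectra")
  spectra <- extract_dataset(dataset, band = config$band,
                             grid_step = config$grid_step)
  split <- split_dataset(spectra$labels, ratio = config$split_ratio,
                         seed = config$seed + 1L,
                         stratify = config$stratify)
  tr <- split$train; te <- split$test

  fit_one <- function(method, kernel, k, seed_off) {
    say("fitting ", method, "-layer model (", kernel, ")")
    thz_fusion(spectra$alpha[tr, ], spectra$n[tr, ], spectra$labels[tr],
               method = method, kernel = kernel, k_abs = k[1], k_ref = k[2],
               gamma_grid = config$gamma_grid, cost_grid = config$cost_grid,
               epsilon1 = config$epsilon1, epsilon2 = config$epsilon2,
               cv_folds = config$cv_folds, seed = config$seed + seed_off)
  }
  models <- list(
    rbf_feature = fit_one("feature", "radial", config$k_feature, 10L),
    linear_feature = fit_one("feature", "linear", config$k_feature, 20L),
    poly_feature = fit_one("feature", "polynomial", config$k_feature, 30L),
    ds_decision = fit_one("decision", "radial", config$k_decision, 40L)
  )

  eval_split <- function(model, idx, split_name) {
    rep <- summary(model, spectra$alpha[idx, ], spectra$n[idx, ],
                   spectra$labels[idx])
    rep$split <- split_name
    rep
  }
  reports <- lapply(models, function(m) {
    list(train = eval_split(m, tr, "train"), test = eval_split(m, te, "test"))
  })
  comparison <- compare_models(lapply(reports, `[[`, "test"))

  run <- structure(list(comparison = comparison, reports = reports,
                        models = models, split = split, spectra = spectra,
                        config = config,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs"))),
                   class = "thz_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(dataset, file.path(out_dir, "dataset"))
    write_spectra(spectra, file.path(out_dir, "spectra"))
    jsonlite::write_json(run_report_list(run),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

run_report_list <- function(run) {
  list(
    config = unclass(run$config),
    n_train = length(run$split$train),
    n_test = length(run$split$test),
    models = lapply(names(run$reports), function(nm) {
      list(train = report_as_list(run$reports[[nm]]$train, nm),
           test = report_as_list(run$reports[[nm]]$test, nm))
    }),
    comparison = lapply(seq_len(nrow(run$comparison)), function(i) {
      list(model = run$comparison$model[i],
           overall_rate = run$comparison$overall_rate[i])
    }),
    elapsed_s = run$elapsed_s
  )
}

#' @export
print.thz_run <- function(x, ...) {
  cat(sprintf("THz wheat-quality recognition run (seed %d, %d train / %d test)\n\n",
              x$config$seed, length(x$split$train), length(x$split$test)))
  print(x$comparison)
  unc <- x$reports$ds_decision$test$uncertain_count
  if (!is.na(unc)) {
    cat(sprintf("\nDS decision layer deferred %d test sample(s) as uncertain.\n",
                unc))
  }
  cat(sprintf("Elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
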