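#' Write a simulated dataset to a directory of trace files
#'
#' Layout: one two-column whitespace-delimited text file per scan
#' (`time_ps`, `field`), a `manifest.tsv` (sample_id, class, scan, role,
#' path) and a `metadata.json` (seed, thickness, scan count).
#'
#' @param dataset A `thz_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "thz_dataset"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  k <- 0L
  for (s in dataset$samples) {
    for (j in seq_along(s$scans)) {
      for (role in c("reference", "sample")) {
        k <- k + 1L
        path <- file.path("traces", sprintf("%s_scan%d_%s.txt", s$id, j, role))
        tr <- s$scans[[j]][[role]]
        write.table(data.frame(time_ps = tr$t, field = tr$E),
                    file.path(dir, path), row.names = FALSE, quote = FALSE)
        rows[[k]] <- data.frame(sample_id = s$id, class = s$label, scan = j,
                                role = role, path = path)
      }
    }
  }
  write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = dataset$seed, d_mm = dataset$d_mm,
                            n_scans = dataset$n_scans,
                            n_samples = length(dataset$samples)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.tsv` and `metadata.json`.
#' @return A `thz_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  samples <- lapply(split(man, factor(man$sample_id, unique(man$sample_id))),
                    function(ms) {
    scans <- lapply(sort(unique(ms$scan)), function(j) {
      read_one <- function(role) {
        p <- ms$path[ms$scan == j & ms$role == role]
        d <- read.table(file.path(dir, p), header = TRUE)
        time_trace(d$time_ps, d$field, role = role)
      }
      list(reference = read_one("reference"), sample = read_one("sample"))
    })
    list(id = ms$sample_id[1], label = ms$class[1], scans = scans)
  })
  names(samples) <- NULL
  structure(list(samples = samples, seed = meta$seed, d_mm = meta$d_mm,
                 n_scans = meta$n_scans, pulse = NULL),
            class = "thz_dataset")
}

#' Write extracted per-sample spectra as delimited text
#'
#' One file per sample with columns `freq_THz`, `alpha_cm1`, `n`, plus a
#' manifest table.
#'
#' @param spectra A `thz_spectra` from [extract_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_spectra <- function(spectra, dir) {
  stopifnot(inherits(spectra, "thz_spectra"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(spectra$alpha)
  paths <- file.path("spectra", paste0(ids, ".txt"))
  for (i in seq_along(ids)) {
    write.table(data.frame(freq_THz = spectra$freq,
                           alpha_cm1 = spectra$alpha[i, ],
                           n = spectra$n[i, ]),
                file.path(dir, paths[i]), row.names = FALSE, quote = FALSE)
  }
  write.table(data.frame(sample_id = ids,
                         class = as.character(spectra$labels), path = paths),
              file.path(dir, "manifest.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}

#' Read spectra written by [write_spectra()]
#'
#' @param dir Directory containing the spectra manifest.
#' @return A `thz_spectra`.
#' @export
read_spectra <- function(dir) {
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tabs <- lapply(man$path, function(p) read.table(file.path(dir, p),
                                                  header = TRUE))
  alpha <- do.call(rbind, lapply(tabs, `[[`, "alpha_cm1"))
  n <- do.call(rbind, lapply(tabs, `[[`, "n"))
  rownames(alpha) <- rownames(n) <- man$sample_id
  structure(list(alpha = alpha, n = n, freq = tabs[[1]]$freq_THz,
                 labels = as_wheat_factor(man$class)),
            class = "thz_spectra")
}
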