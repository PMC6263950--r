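#' Fourier transform of a time-domain trace
#'
#' Computes the amplitude and unwrapped phase spectrum of a scan. The field
#' convention is `E(omega) = A(omega) * exp(-i * phi(omega))`, chosen so a
#' slab that delays the pulse yields a positive phase difference
#' `phi_sample - phi_reference`. The trace is zero-padded to the next power
#' of two at least `pad_factor` times its length to densify the frequency
#' grid; phase is unwrapped upward from the lowest non-DC bin, with the
#' branch fixed by linear extrapolation of the low-frequency phase through
#' the DC gap.
#'
#' @param trace A `time_trace`.
#' @param window Taper applied before the FFT: `"rectangular"` (default;
#'   simulated traces are windowed by construction) or `"hann"`.
#' @param pad_factor Zero-padding factor (default 4).
#'
#' @return An object of class `freq_spectrum`: list with `freq` (THz),
#'   `amplitude` (arbitrary units, >= 0) and `phase` (radians, unwrapped),
#'   covering DC to Nyquist.
#' @export
to_frequency <- function(trace, window = c("rectangular", "hann"),
                         pad_factor = 4) {
  stopifnot(inherits(trace, "time_trace"))
  window <- match.arg(window)
  check_uniform_axis(trace$t)
  dt <- trace_dt(trace)
  N <- length(trace$E)
  E <- trace$E
  if (window == "hann") E <- E * signal::hanning(N)
  M <- 2^ceiling(log2(pad_factor * N))
  X <- fft(c(E, rep(0, M - N)))
  half <- seq_len(M / 2 + 1)
  freq <- (half - 1) / (M * dt)              # ps^-1 == THz
  amplitude <- Mod(X[half])
  phase <- rep(NA_real_, length(half))
  phase[-1] <- signal::unwrap(-Arg(X[half][-1]))
  # fix the 2*pi branch through the DC gap: the phase of a causal pulse
  # extrapolates linearly to ~0 at zero frequency
  lo <- 2:9
  fit <- stats::lm.fit(cbind(1, freq[lo]), phase[lo])
  phase <- phase - 2 * pi * round(fit$coefficients[1] / (2 * pi))
  phase[1] <- 0
  structure(list(freq = freq, amplitude = amplitude, phase = phase),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("<freq_spectrum> %d bins, 0 to %.2f THz, step %.4g THz\n",
              length(x$freq), max(x$freq), x$freq[2] - x$freq[1]))
  invisible(x)
}

check_shared_grid <- function(a, b) {
  if (length(a$freq) != length(b$freq) ||
      max(abs(a$freq - b$freq)) > 1e-9) {
    stop("grid mismatch: spectra are not on a shared frequency grid",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Absorption coefficient from a reference/sample spectrum pair
#'
#' `alpha = (1/d) * ln(Ar / As)` with the thickness converted to cm so the
#' result is in cm^-1, evaluated per frequency bin.
#'
#' @param ref,sam `freq_spectrum` objects on a shared grid.
#' @param d_mm Sample thickness in mm.
#' @return Numeric vector of absorption coefficients (cm^-1), one per bin.
#' @export
extract_alpha <- function(ref, sam, d_mm = 1) {
  check_shared_grid(ref, sam)
  if (d_mm <= 0) stop("thickness must be positive", call. = FALSE)
  if (any(ref$amplitude <= 0) || any(sam$amplitude <= 0)) {
    stop("degenerate amplitude: non-positive spectral amplitude in band",
         call. = FALSE)
  }
  log(ref$amplitude / sam$amplitude) / (d_mm / 10)
}

#' Refractive index from a reference/sample spectrum pair
#'
#' `n = 1 + (phi_s - phi_r) * c / (omega * d)` with omega in rad/s and d in
#' m, so a slab that delays the pulse yields `n > 1`.
#'
#' @inheritParams extract_alpha
#' @return Numeric vector of refractive indices, one per bin.
#' @export
extract_n <- function(ref, sam, d_mm = 1) {
  check_shared_grid(ref, sam)
  if (d_mm <= 0) stop("thickness must be positive", call. = FALSE)
  if (any(ref$freq == 0)) {
    stop("division by zero: refractive index undefined at zero frequency",
         call. = FALSE)
  }
  omega <- 2 * pi * ref$freq * 1e12
  1 + (sam$phase - ref$phase) * .C_LIGHT / (omega * d_mm / 1000)
}

#' Optical parameter spectrum of one sample
#'
#' @param freq Frequency axis (THz).
#' @param alpha Absorption coefficient (cm^-1) per bin.
#' @param n Refractive index per bin.
#' @param d_mm Sample thickness (mm).
#' @param label Optional class label.
#' @return An object of class `optical_spectrum`.
#' @export
optical_spectrum <- function(freq, alpha, n, d_mm = 1, label = NULL) {
  stopifnot(length(freq) == length(alpha), length(freq) == length(n))
  if (!all(is.finite(freq)) || !all(is.finite(alpha)) || !all(is.finite(n))) {
    stop("optical spectrum contains non-finite values", call. = FALSE)
  }
  structure(list(freq = freq, alpha = alpha, n = n, d_mm = d_mm,
                 label = label),
            class = "optical_spectrum")
}

#' @export
print.optical_spectrum <- function(x, ...) {
  cat(sprintf("<optical_spectrum> %d bins, %.2f-%.2f THz%s\n",
              length(x$freq), min(x$freq), max(x$freq),
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' Restrict an optical spectrum to a frequency band
#'
#' Keeps the bins inside `[lo, hi]`, closed at both ends.
#'
#' @param spec An `optical_spectrum`.
#' @param lo,hi Band edges in THz (defaults 0.2 and 1.6).
#' @return An `optical_spectrum` on the restricted grid.
#' @export
restrict_band <- function(spec, lo = 0.2, hi = 1.6) {
  stopifnot(inherits(spec, "optical_spectrum"))
  if (lo >= hi) stop("empty band: lo must be < hi", call. = FALSE)
  keep <- spec$freq >= lo & spec$freq <= hi
  if (!any(keep)) stop("empty band: no frequency bins in [", lo, ", ", hi, "]",
                       call. = FALSE)
  optical_spectrum(spec$freq[keep], spec$alpha[keep], spec$n[keep],
                   d_mm = spec$d_mm, label = spec$label)
}

#' Extract optical parameters from a reference/sample trace pair
#'
#' Full extraction chain for one sample: FFT of both traces, linear
#' interpolation of amplitude and phase onto a common analysis grid, then
#' per-bin absorption coefficient and refractive index.
#'
#' @param ref,sam `time_trace` objects (reference and transmitted scans).
#' @param d_mm Sample thickness in mm.
#' @param band Analysis band in THz, default `c(0.2, 1.6)`.
#' @param grid_step Analysis grid step in THz (default 0.01).
#' @param window Taper passed to [to_frequency()].
#' @param label Optional class label carried on the result.
#' @return An `optical_spectrum` on the uniform analysis grid.
#' @export
extract_optical <- function(ref, sam, d_mm = 1, band = c(0.2, 1.6),
                            grid_step = 0.01,
                            window = c("rectangular", "hann"), label = NULL) {
  fr <- to_frequency(ref, window = window)
  fs <- to_frequency(sam, window = window)
  grid <- seq(band[1], band[2], by = grid_step)
  interp <- function(spec) {
    list(freq = grid,
         amplitude = approx(spec$freq, spec$amplitude, grid)$y,
         phase = approx(spec$freq, spec$phase, grid)$y)
  }
  fr_g <- structure(interp(fr), class = "freq_spectrum")
  fs_g <- structure(interp(fs), class = "freq_spectrum")
  optical_spectrum(grid,
                   alpha = extract_alpha(fr_g, fs_g, d_mm),
                   n = extract_n(fr_g, fs_g, d_mm),
                   d_mm = d_mm, label = label)
}

#' Extract per-sample spectra for a whole dataset
#'
#' Averages the replicate reference and sample scans of each sample, runs
#' the extraction chain, and stacks the results into per-modality matrices
#' ready for feature extraction.
#'
#' @param dataset A `thz_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @inheritParams extract_optical
#' @return A list of class `thz_spectra`: `alpha` and `n` are
#'   samples-by-bins matrices (rownames = sample ids), `freq` the analysis
#'   grid, `labels` a factor in fixed class order.
#' @export
extract_dataset <- function(dataset, band = c(0.2, 1.6), grid_step = 0.01,
                            window = c("rectangular", "hann")) {
  stopifnot(inherits(dataset, "thz_dataset"))
  specs <- lapply(dataset$samples, function(s) {
    ref <- average_scans(lapply(s$scans, `[[`, "reference"))
    sam <- average_scans(lapply(s$scans, `[[`, "sample"))
    extract_optical(ref, sam, d_mm = dataset$d_mm, band = band,
                    grid_step = grid_step, window = window, label = s$label)
  })
  ids <- vapply(dataset$samples, `[[`, character(1), "id")
  alpha <- do.call(rbind, lapply(specs, `[[`, "alpha"))
  n <- do.call(rbind, lapply(specs, `[[`, "n"))
  rownames(alpha) <- rownames(n) <- ids
  structure(list(alpha = alpha, n = n, freq = specs[[1]]$freq,
                 labels = dataset_labels(dataset)),
            class = "thz_spectra")
}

#' @export
print.thz_spectra <- function(x, ...) {
  cat(sprintf("<thz_spectra> %d samples x %d bins (%.2f-%.2f THz)\n",
              nrow(x$alpha), ncol(x$alpha), min(x$freq), max(x$freq)))
  invisible(x)
}
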