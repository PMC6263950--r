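#' Time-domain THz trace
#'
#' Container for one sampled electric-field scan (reference or sample) on a
#' uniform time axis.
#'
#' @param t Time axis in picoseconds; strictly increasing, uniform step.
#' @param E Electric field samples (arbitrary units), same length as `t`.
#' @param role `"reference"` or `"sample"`.
#'
#' @return An object of class `time_trace`: a list with elements `t`, `E`,
#'   `role`.
#' @export
time_trace <- function(t, E, role = c("reference", "sample")) {
  role <- match.arg(role)
  t <- as.numeric(t)
  E <- as.numeric(E)
  if (length(t) != length(E)) {
    stop("time axis and field must have the same length", call. = FALSE)
  }
  check_uniform_axis(t)
  structure(list(t = t, E = E, role = role), class = "time_trace")
}

# Uniform, strictly increasing axis to relative tolerance 1e-8.
check_uniform_axis <- function(t) {
  if (length(t) < 8L) stop("invalid grid: time axis too short", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("invalid grid: time axis not strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) {
    stop("invalid grid: time axis not uniform", call. = FALSE)
  }
  invisible(dt[1])
}

trace_dt <- function(trace) trace$t[2] - trace$t[1]

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %s, %d points, t = [%.2f, %.2f] ps, dt = %.4g ps\n",
              x$role, length(x$t), x$t[1], x$t[length(x$t)], trace_dt(x)))
  invisible(x)
}

#' Synthesise the system reference pulse
#'
#' Generates a single-cycle (differentiated-Gaussian) THz pulse, the standard
#' model for a photoconductive-antenna emitter. The default width puts the
#' spectral peak near 0.5 THz so the amplitude spectrum is non-negligible
#' across the full 0.2-1.6 THz analysis band.
#'
#' @param span_ps Total window length in ps. Must give a frequency resolution
#'   `1/span <= 0.05` THz, i.e. `span >= 20` ps.
#' @param dt_ps Sampling step in ps. The implied Nyquist frequency
#'   `1/(2*dt)` must exceed 1.6 THz.
#' @param t0_ps Pulse centre position in ps.
#' @param sigma_ps Gaussian width parameter in ps; the amplitude spectrum
#'   peaks at `1/(2*pi*sigma)` THz.
#'
#' @return A `time_trace` with role `"reference"`, peak amplitude normalised
#'   to 1.
#' @export
make_reference_pulse <- function(span_ps = 51.2, dt_ps = 0.05, t0_ps = 6,
                                 sigma_ps = 0.318) {
  if (span_ps < 20) {
    stop("invalid grid: span ", span_ps,
         " ps gives frequency resolution coarser than 0.05 THz", call. = FALSE)
  }
  if (1 / (2 * dt_ps) < 1.6) {
    stop("invalid grid: step ", dt_ps,
         " ps cannot resolve frequencies up to 1.6 THz", call. = FALSE)
  }
  n <- floor(span_ps / dt_ps)
  t <- seq(0, by = dt_ps, length.out = n)
  u <- (t - t0_ps) / sigma_ps
  E <- -u * exp(-u^2 / 2)
  time_trace(t, E / max(E), role = "reference")
}

#' Average replicate scans
#'
#' Pointwise mean of repeated scans of the same target, mirroring the
#' measurement protocol in which each sample is scanned several times and
#' the mean trace is analysed.
#'
#' @param traces List of `time_trace` objects sharing one time axis.
#' @return A single `time_trace` (role taken from the first trace).
#' @export
average_scans <- function(traces) {
  stopifnot(length(traces) >= 1L)
  t0 <- traces[[1]]$t
  for (tr in traces) {
    if (length(tr$t) != length(t0) || max(abs(tr$t - t0)) > 1e-9) {
      stop("axis mismatch: scans do not share a time axis", call. = FALSE)
    }
  }
  E <- rowMeans(vapply(traces, function(tr) tr$E, numeric(length(t0))))
  time_trace(t0, E, role = traces[[1]]$role)
}
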