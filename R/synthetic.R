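#' Homogeneous slab material
#'
#' Optical description of a pressed pellet: refractive index and absorption
#' coefficient as functions of frequency, plus slab thickness. Constant
#' values are promoted to constant functions.
#'
#' @param n Refractive index: a single number or a function of frequency
#'   (THz). Must be >= 1 over the analysis band.
#' @param alpha Absorption coefficient in cm^-1: a single number or a
#'   function of frequency (THz). Must be >= 0.
#' @param d_mm Slab thickness in mm (default 1, the pellet thickness used
#'   throughout).
#'
#' @return An object of class `slab_material`.
#' @export
slab_material <- function(n, alpha, d_mm = 1) {
  n_fun <- if (is.function(n)) n else {n0 <- n; function(f) rep(n0, length(f))}
  a_fun <- if (is.function(alpha)) alpha else {
    a0 <- alpha
    function(f) rep(a0, length(f))
  }
  if (d_mm <= 0) stop("slab thickness must be positive", call. = FALSE)
  probe <- seq(0.2, 1.6, by = 0.05)
  if (any(n_fun(probe) < 1)) stop("refractive index must be >= 1 in band", call. = FALSE)
  if (any(a_fun(probe) < 0)) stop("absorption coefficient must be >= 0 in band", call. = FALSE)
  structure(list(n = n_fun, alpha = a_fun, d_mm = d_mm), class = "slab_material")
}

#' Propagate the reference pulse through a slab
#'
#' Forward transmission model used by the simulator. In the frequency domain
#' the sample field is the reference field multiplied by the amplitude factor
#' `exp(-alpha * d)` (so that extracting `alpha = (1/d) * ln(Ar/As)` recovers
#' the material exactly) and phase-delayed by `(n - 1) * omega * d / c`.
#'
#' @param pulse A `time_trace` (the reference scan).
#' @param material A `slab_material`.
#' @return A `time_trace` with role `"sample"`.
#' @export
forward_transmit <- function(pulse, material) {
  stopifnot(inherits(pulse, "time_trace"), inherits(material, "slab_material"))
  dt <- trace_dt(pulse)
  N <- length(pulse$E)
  f <- c(seq(0, floor(N / 2)), seq(-(ceiling(N / 2) - 1), -1)) / (N * dt) # THz
  fa <- abs(f)
  d_cm <- material$d_mm / 10
  d_m <- material$d_mm / 1000
  amp <- exp(-material$alpha(fa) * d_cm)
  omega <- 2 * pi * fa * 1e12
  delay <- (material$n(fa) - 1) * d_m / .C_LIGHT          # seconds
  # a slab that delays the pulse past the end of the window would fold it
  # back circularly; reject before transforming
  probe <- seq(0.2, 1.6, by = 0.05)
  tau_max <- max(material$n(probe) - 1) * d_m / .C_LIGHT * 1e12   # ps
  t_peak <- pulse$t[which.max(abs(pulse$E))]
  if (t_peak + tau_max > pulse$t[N] - 2) {
    stop("window overflow: transmitted pulse delayed outside the time window",
         call. = FALSE)
  }
  H <- amp * exp(-1i * sign(f) * omega * delay)
  E_out <- Re(fft(fft(pulse$E) * H, inverse = TRUE)) / N
  time_trace(pulse$t, E_out, role = "sample")
}

#' Class-conditional generator specification
#'
#' Statistical description of one wheat quality class: the class-mean
#' refractive level, the parameters of a smooth featureless absorption curve
#' rising with frequency, between-sample spread and within-scan noise.
#'
#' @param label One of `wheat_classes()`.
#' @param n_mean Class mean refractive index level (dimensionless, expected
#'   in 1.50-1.56 at mid-band).
#' @param alpha_base Absorption at 0 THz (cm^-1).
#' @param alpha_slope Linear rise of absorption with frequency (cm^-1/THz).
#' @param noise_sd_n Between-sample SD of the refractive level.
#' @param noise_sd_alpha Between-sample SD of `alpha_base` (cm^-1).
#' @param scan_noise_sd Within-scan additive white field noise SD
#'   (fraction of the unit reference peak).
#' @param n_slope Frequency slope of the refractive index (per THz); the
#'   default mild negative slope emulates the near-flat measured index.
#'
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, n_mean, alpha_base, alpha_slope = 9,
                       noise_sd_n = 0.004, noise_sd_alpha = 1.2,
                       scan_noise_sd = 0.001, n_slope = -0.005) {
  label <- match.arg(label, wheat_classes())
  if (any(c(noise_sd_n, noise_sd_alpha, scan_noise_sd) < 0)) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(label = label, n_mean = n_mean, alpha_base = alpha_base,
                 alpha_slope = alpha_slope, noise_sd_n = noise_sd_n,
                 noise_sd_alpha = noise_sd_alpha,
                 scan_noise_sd = scan_noise_sd, n_slope = n_slope),
            class = "class_spec")
}

#' Default class specifications
#'
#' One `class_spec` per quality class. Refractive levels sit inside the
#' measured 1.50-1.56 range with the ordering
#' worm-eaten < moldy < germinated < normal; absorption levels follow the
#' reported ordering moldy < worm-eaten < germinated < normal, with normal
#' wheat absorbing most strongly.
#'
#' @return Named list of four `class_spec` objects in fixed class order.
#' @export
default_class_specs <- function() {
  list(
    normal       = class_spec("normal",       n_mean = 1.552, alpha_base = 17.0),
    germinated   = class_spec("germinated",   n_mean = 1.538, alpha_base = 13.5),
    moldy        = class_spec("moldy",        n_mean = 1.520, alpha_base = 10.0),
    `worm-eaten` = class_spec("worm-eaten",   n_mean = 1.505, alpha_base = 11.5)
  )
}

check_spec_ordering <- function(specs) {
  lv <- vapply(specs, `[[`, numeric(1), "n_mean")
  lab <- vapply(specs, `[[`, character(1), "label")
  names(lv) <- lab
  need <- c("worm-eaten", "moldy", "germinated", "normal")
  if (!setequal(lab, need)) {
    stop("invalid spec: need exactly one spec per class", call. = FALSE)
  }
  if (!all(diff(lv[need]) > 0)) {
    stop("invalid spec: class refractive levels must obey ",
         "worm-eaten < moldy < germinated < normal", call. = FALSE)
  }
  invisible(TRUE)
}

# Material for one individual sample, given its drawn (n level, alpha base).
# The refractive slope is centred at 0.9 THz so n_level is the mid-band value.
sample_material <- function(n_level, alpha_base, spec, d_mm) {
  slab_material(
    n = function(f) pmax(1, n_level + spec$n_slope * (f - 0.9)),
    alpha = function(f) pmax(0, alpha_base + spec$alpha_slope * f),
    d_mm = d_mm
  )
}

#' Generate a class-conditional synthetic THz dataset
#'
#' Draws per-sample material parameters from each class distribution, runs
#' the slab forward model, and records `n_scans` noisy reference/sample
#' trace pairs per sample (each scan gets independent additive white field
#' noise). Deterministic given `seed`.
#'
#' @param specs List of four `class_spec` objects (default
#'   [default_class_specs()]); the class refractive ordering is enforced.
#' @param n_per_class Samples per class (default 60, i.e. 240 in total).
#' @param seed Integer random seed.
#' @param n_scans Replicate scans per sample (default 5).
#' @param pulse Reference pulse, default [make_reference_pulse()].
#' @param d_mm Pellet thickness in mm.
#'
#' @return An object of class `thz_dataset`: list with `samples` (each a
#'   list `id`, `label`, `scans` of `(reference, sample)` trace pairs, and
#'   the true drawn `n_level`/`alpha_base`), plus `seed`, `d_mm`, `pulse`.
#' @export
generate_dataset <- function(specs = default_class_specs(), n_per_class = 60,
                             seed = 1, n_scans = 5,
                             pulse = make_reference_pulse(), d_mm = 1) {
  check_spec_ordering(specs)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  N <- length(pulse$E)
  samples <- list()
  k <- 0L
  for (spec in specs) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      n_level <- spec$n_mean + rnorm(1, 0, spec$noise_sd_n)
      a_base <- max(0, spec$alpha_base + rnorm(1, 0, spec$noise_sd_alpha))
      mat <- sample_material(n_level, a_base, spec, d_mm)
      clean <- forward_transmit(pulse, mat)
      scans <- lapply(seq_len(n_scans), function(s) {
        list(
          reference = time_trace(pulse$t, pulse$E + rnorm(N, 0, spec$scan_noise_sd),
                                 role = "reference"),
          sample = time_trace(pulse$t, clean$E + rnorm(N, 0, spec$scan_noise_sd),
                              role = "sample")
        )
      })
      samples[[k]] <- list(id = sprintf("%s_%03d", spec$label, i),
                           label = spec$label, scans = scans,
                           n_level = n_level, alpha_base = a_base)
    }
  }
  structure(list(samples = samples, seed = seed, d_mm = d_mm, pulse = pulse,
                 n_scans = n_scans),
            class = "thz_dataset")
}

#' @export
print.thz_dataset <- function(x, ...) {
  labs <- vapply(x$samples, `[[`, character(1), "label")
  cat(sprintf("<thz_dataset> %d samples (%s), %d scans each, d = %g mm, seed %d\n",
              length(x$samples),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)), collapse = ", "),
              x$n_scans, x$d_mm, x$seed))
  invisible(x)
}

dataset_labels <- function(dataset) {
  as_wheat_factor(vapply(dataset$samples, `[[`, character(1), "label"))
}
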