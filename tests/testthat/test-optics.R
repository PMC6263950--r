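test_that("FFT amplitude peaks at the tone frequency for a pure cosine", {
  dt <- 0.0625
  t <- seq(0, by = dt, length.out = 512)   # 32 ps: integer periods of 1 THz
  tr <- time_trace(t, cos(2 * pi * 1.0 * t))
  fs <- to_frequency(tr, pad_factor = 1)
  expect_equal(fs$freq[which.max(fs$amplitude)], 1.0, tolerance = 1e-9)
})

test_that("zero signal transforms to zero amplitude", {
  tr <- time_trace(seq(0, 10, by = 0.05), rep(0, 201))
  expect_true(all(to_frequency(tr)$amplitude == 0))
})

test_that("a pure delay produces phase difference omega * dt (shift theorem)", {
  p <- make_reference_pulse()
  shift <- 20L                                      # bins: 1 ps
  delayed <- time_trace(p$t, c(rep(0, shift), p$E[1:(length(p$E) - shift)]))
  f0 <- to_frequency(p); f1 <- to_frequency(delayed)
  band <- f0$freq >= 0.2 & f0$freq <= 1.6
  dphi <- (f1$phase - f0$phase)[band]
  expected <- 2 * pi * f0$freq[band] * 1.0          # omega * 1 ps
  expect_equal(dphi, expected, tolerance = 1e-6)
})

test_that("scan averaging matches its identities and reduces noise ~ 5x", {
  p <- make_reference_pulse()
  expect_equal(average_scans(rep(list(p), 5)), p)
  neg <- time_trace(p$t, -p$E)
  expect_true(all(abs(average_scans(list(p, neg))$E) < 1e-15))
  expect_error(average_scans(list(p, time_trace(p$t + 1, p$E))),
               "axis mismatch")
  set.seed(11)
  mse1 <- mse5 <- numeric(200)
  for (r in seq_len(200)) {
    noisy <- lapply(1:5, function(i)
      time_trace(p$t, p$E + rnorm(length(p$E), 0, 0.01)))
    mse1[r] <- mean((noisy[[1]]$E - p$E)^2)
    mse5[r] <- mean((average_scans(noisy)$E - p$E)^2)
  }
  expect_equal(mean(mse1) / mean(mse5), 5, tolerance = 0.15)
})

test_that("absorption extraction follows the amplitude-ratio law", {
  freq <- seq(0.2, 1.6, by = 0.01)
  ref <- structure(list(freq = freq, amplitude = rep(2, length(freq)),
                        phase = freq), class = "freq_spectrum")
  same <- ref
  expect_true(all(extract_alpha(ref, same, 1) == 0))
  sam <- ref
  sam$amplitude <- ref$amplitude * exp(-0.5)
  expect_equal(extract_alpha(ref, sam, 1), rep(5, length(freq)),
               tolerance = 1e-12)
  sam$amplitude[3] <- 0
  expect_error(extract_alpha(ref, sam, 1), "degenerate amplitude")
})

test_that("refractive extraction follows the phase-delay law", {
  freq <- seq(0.2, 1.6, by = 0.01)
  ref <- structure(list(freq = freq, amplitude = rep(1, length(freq)),
                        phase = rep(0, length(freq))), class = "freq_spectrum")
  expect_equal(extract_n(ref, ref, 1), rep(1, length(freq)))
  # phase of a d = 1 mm slab with n = 1.53
  sam <- ref
  sam$phase <- (1.53 - 1) * 2 * pi * freq * 1e12 * 1e-3 / 299792458
  expect_equal(extract_n(ref, sam, 1), rep(1.53, length(freq)),
               tolerance = 1e-12)
  ref0 <- ref; ref0$freq[1] <- 0
  sam0 <- sam; sam0$freq[1] <- 0
  expect_error(extract_n(ref0, sam0, 1), "zero frequency")
})

test_that("band restriction is closed on both ends and counts bins", {
  full <- optical_spectrum(seq(0.05, 3.5, by = 0.01),
                           alpha = rep(1, 346), n = rep(1.5, 346))
  os <- restrict_band(full, 0.2, 1.6)
  expect_length(os$freq, 141)
  expect_true(all(os$freq >= 0.2 & os$freq <= 1.6))
  expect_true(0.2 %in% round(os$freq, 10) && 1.6 %in% round(os$freq, 10))
  expect_error(restrict_band(full, 1.6, 0.2), "empty band")
  expect_error(restrict_band(full, 0.201, 0.2049), "empty band")
})

test_that("doubling the thickness halves the extraction error", {
  freq <- seq(0.2, 1.6, by = 0.01)
  set.seed(3)
  ref <- structure(list(freq = freq, amplitude = rep(1, length(freq)),
                        phase = rep(0, length(freq))), class = "freq_spectrum")
  sam <- ref
  sam$amplitude <- exp(rnorm(length(freq), 0, 0.01))  # fixed amplitude noise
  sam$phase <- rnorm(length(freq), 0, 0.01)           # fixed phase noise
  a1 <- extract_alpha(ref, sam, 1); a2 <- extract_alpha(ref, sam, 2)
  n1 <- extract_n(ref, sam, 1); n2 <- extract_n(ref, sam, 2)
  expect_equal(a2, a1 / 2, tolerance = 1e-12)
  expect_equal(n2 - 1, (n1 - 1) / 2, tolerance = 1e-12)
})
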