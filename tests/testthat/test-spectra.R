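test_that("power spectrum is Parseval-consistent and locates pure tones", {
  dt <- 1e-8; n <- 512
  x <- sin(2 * pi * 32 * (1:n) / n)            # bin-centred tone
  s <- power_spectrum(waveform(x, dt))
  expect_equal(sum(s$power), mean(x^2), tolerance = 1e-10)
  expect_equal(which.max(s$power) - 1L, 32L)
  expect_lt(sort(s$power, decreasing = TRUE)[2] / max(s$power), 1e-20)
  # delta pulse: flat to Nyquist
  d <- numeric(64); d[5] <- 1
  sd_ <- power_spectrum(waveform(d, dt))
  inner <- sd_$power[2:(length(sd_$power) - 1L)]
  expect_lt(diff(range(inner)) / mean(inner), 1e-10)
  expect_error(power_spectrum(waveform(rnorm(8), dt)), "16 samples")
})

test_that("Gaussian pulse bandwidth matches the analytic transform", {
  dt <- 2e-9; n <- 4096; tau <- 100e-9
  tt <- (1:n) * dt
  x <- exp(-(tt - 2e-6)^2 / (2 * tau^2))
  s <- power_spectrum(waveform(x, dt), nfft = 16384)
  be <- suppressWarnings(band_edges(s, 6.0206))  # low edge clips at dc
  # |X(f)| = exp(-2 pi^2 f^2 tau^2); half amplitude at f = sqrt(ln 2 / 2) / (pi tau)
  f_expect <- sqrt(log(2) / 2) / (pi * tau)
  expect_rel_equal(be$f_high, f_expect, 0.02)
})

test_that("band edges interpolate exactly on constructed spectra", {
  f <- seq(0, 10e6, by = 1e4)
  P <- ifelse(f >= 2e6 & f <= 5e6, 1, 1e-12)   # ideal rectangular band
  s <- structure(list(frequencies = f, power = P), class = "pa_spectrum")
  be <- band_edges(s)
  expect_equal(be$f_low, 2e6, tolerance = 2e4)
  expect_equal(be$f_high, 5e6, tolerance = 2e4)
  # Gaussian spectrum: edges against dense-grid search
  P2 <- exp(-(f - 3e6)^2 / (2 * (0.8e6)^2))
  s2 <- structure(list(frequencies = f, power = P2), class = "pa_spectrum")
  be2 <- band_edges(s2, 6.0206)
  fd <- seq(0, 10e6, by = 100)
  Pd <- exp(-(fd - 3e6)^2 / (2 * (0.8e6)^2))
  lim <- range(fd[10 * log10(Pd) >= -6.0206])
  expect_equal(be2$f_low, lim[1], tolerance = 5e3)
  expect_equal(be2$f_high, lim[2], tolerance = 5e3)
  # increasing the drop widens the band
  be12 <- band_edges(s2, 12)
  expect_lt(be12$f_low, be2$f_low)
  expect_gt(be12$f_high, be2$f_high)
  # level never reached: clipped flag and full range
  expect_warning(bef <- band_edges(structure(list(frequencies = f,
                                                  power = rep(1, length(f))),
                                             class = "pa_spectrum")), "clipped")
  expect_true(bef$clipped)
})

test_that("insertion loss identities: self, scalar scaling, antisymmetry", {
  set.seed(3)
  x <- waveform(stats::filter(rnorm(512), rep(1, 8), sides = 1)[9:480] |>
                  as.numeric(), 1e-8)
  il0 <- insertion_loss(x, x)
  expect_lt(max(abs(il0$loss_db[il0$valid])), 1e-9)
  xs <- waveform(x$samples / 10, x$dt)
  il20 <- insertion_loss(xs, x)
  expect_equal(il20$loss_db[il20$valid], rep(-20, sum(il20$valid)),
               tolerance = 1e-9)
  y <- waveform(as.numeric(stats::filter(x$samples, c(0.5, 0.3, 0.1),
                                         sides = 1))[4:470], 1e-8)
  ilab <- insertion_loss(y, x)
  ilba <- insertion_loss(x, y)
  sel <- ilab$valid & ilba$valid
  expect_lt(max(abs(ilab$loss_db[sel] + ilba$loss_db[sel])), 1e-9)
  expect_error(insertion_loss(x, waveform(numeric(128) + 0, 1e-8)), "zero")
})

test_that("loss slope fits constructed lines exactly", {
  f <- seq(0.2e6, 3e6, by = 2e4)
  il <- structure(list(frequencies = f, loss_db = -10 * f / 1e6,
                       valid = rep(TRUE, length(f)), valid_band = range(f)),
                  class = "pa_il")
  expect_equal(loss_slope(il, c(0.5e6, 2.5e6)), -10, tolerance = 1e-10)
  il$loss_db <- rep(-7, length(f))
  expect_equal(loss_slope(il, c(0.5e6, 2.5e6)), 0, tolerance = 1e-10)
  expect_error(loss_slope(il, c(2.9e6, 2.95e6)), "fewer than 5")
})

test_that("band-pass filtering and noise normalisation behave as specified", {
  dt <- 1e-8; n <- 4096
  set.seed(9)
  noise <- rnorm(n)
  w <- waveform(noise, dt)
  out <- filter_and_normalize(w, c(1, n), passband = c(10e3, 3e6))
  expect_equal(stats::sd(out$samples), 1, tolerance = 1e-9)
  # a 5 MHz tone is attenuated >= 12 dB by the two-pass 2nd-order filter
  tone <- sin(2 * pi * 5e6 * (1:n) * dt)
  sig <- waveform(c(noise[1:256] * 0.01, tone[257:n]), dt)
  outt <- filter_and_normalize(sig, c(1, 256))
  att <- max(abs(outt$samples[1000:3000])) * stats::sd(
    filter_and_normalize(sig, c(1, 256))$samples[1:256]) # normalised units
  raw <- signal::filtfilt(signal::butter(2, c(10e3, 3e6) / (0.5 / dt), "pass"),
                          tone)
  expect_lt(20 * log10(max(abs(raw[1000:3000]))), -12)
  # dc offsets are removed by the 10 kHz cut-on (record long vs 1/f_on);
  # the offset is 5 noise-sigmas, so the residual mean shows > 25x suppression
  set.seed(11)
  dcw <- waveform(rnorm(4096) + 5, 1e-7)
  outdc <- filter_and_normalize(dcw, c(1, 4096))
  expect_lt(abs(mean(outdc$samples)), 0.2)
  expect_error(filter_and_normalize(waveform(numeric(400), dt), c(1, 200)),
               "zero standard deviation")
})

test_that("top-percentile spectral summaries select and summarise correctly", {
  set.seed(5)
  nt <- 128
  base <- sin(2 * pi * 10 * (1:nt) / nt)
  m <- matrix(rep(base, each = 100), 100, nt)
  sc <- scan_set(m, 1e-3, 1e-8)
  ts <- top_percentile_spectra(sc, 0.05)
  expect_length(ts$selected, 5L)
  expect_lt(max(ts$sd_power), 1e-25)
  expect_equal(ts$mean_power, power_spectrum(waveform(base, 1e-8))$power,
               tolerance = 1e-12)
  # an outlier is always selected
  m2 <- m * (0.5 + runif(100) * 0.2)
  m2[37, ] <- base * 50
  ts2 <- top_percentile_spectra(scan_set(m2, 1e-3, 1e-8), 0.05)
  expect_true(37L %in% ts2$selected)
  expect_error(top_percentile_spectra(sc, 0), "fraction")
  expect_error(top_percentile_spectra(scan_set(m[1:10, ], 1e-3, 1e-8), 0.05),
               "20 waveforms")
})
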