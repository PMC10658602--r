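test_that("max supported frequency follows two points per wavelength", {
  water <- homogeneous_medium(c(16, 16), 125e-6)
  expect_equal(max_supported_frequency(water), 1480 / (2 * 125e-6))  # 5.92 MHz
  expect_equal(round(max_supported_frequency(water) / 1e6), 6)
  half <- homogeneous_medium(c(16, 16), 62.5e-6)
  expect_equal(max_supported_frequency(half), 2 * max_supported_frequency(water))
  two <- water
  two$sound_speed[1:8, ] <- 3100
  expect_equal(max_supported_frequency(two), 5.92e6)  # limited by water, not bone
})

test_that("plane-wave first arrival in water is kinematically exact", {
  med <- homogeneous_medium(400, 125e-6)
  res <- run_forward(med, source_plane(med, 60),
                     sensor_points(matrix(300, 1, 1)),
                     simulation_config(n_steps = 900))
  w <- result_waveform(res)
  t_arr <- waveform_time(w)[which.max(w$samples)]
  expect_lt(abs(t_arr - 240 * 125e-6 / 1480), res$dt)
  expect_equal(max(w$samples), 0.5, tolerance = 1e-3)  # initial pressure splits
})

test_that("acoustic energy is conserved in a lossless run", {
  med <- homogeneous_medium(c(128, 128), 125e-6)
  res <- run_forward(med, source_disk(med, 64, 2e-3),
                     sensor_points(matrix(c(40, 64), 1, 2)),
                     simulation_config(n_steps = 200, record_energy = TRUE))
  E <- res$energy
  sel <- 20:150                      # wave still inside the interior
  expect_lt(max(abs(E[sel] / E[20] - 1)), 1e-3)
})

test_that("PML keeps boundary reflections at least 40 dB below the direct wave", {
  med <- homogeneous_medium(c(192, 96), 125e-6)
  res <- run_forward(med, source_point(med, c(60, 48)),
                     sensor_points(matrix(c(120, 48), 1, 2)),
                     simulation_config(n_steps = 900))
  w <- res$waveforms[1, ]
  ipk <- which.max(abs(w))
  expect_gt(20 * log10(max(abs(w)) / max(abs(w[(ipk + 150):length(w)]))), 40)
})

test_that("spectral attenuation follows the alpha0 f^2 law within 2 percent", {
  # The loss term is integrated at collocation times, so its accuracy needs a
  # reduced Courant number; near the grid limit the model's own dispersion
  # relation (1 - i w tau)^(-1/2) departs from the pure f^2 law, so the
  # closed-form comparison is made over the band it actually describes.
  absmat <- material_properties(1480, 1000, 2.7)
  med <- homogeneous_medium(420, 125e-6, absmat)
  res <- run_forward(med, source_plane(med, 100),
                     sensor_points(matrix(c(120, 160), 2, 1)),
                     simulation_config(cfl = 0.03, n_steps = 7000))
  s1 <- power_spectrum(result_waveform(res, 1), nfft = 16384)
  s2 <- power_spectrum(result_waveform(res, 2), nfft = 16384)
  f <- s1$frequencies
  d <- 40 * 125e-6
  pred <- exp(-2 * alpha0_db_to_np(2.7) * (2 * pi * f)^2 * d)
  sel <- f > 0.3e6 & f < 0.6 * max_supported_frequency(med)
  expect_lt(max(abs((s2$power / s1$power)[sel] / pred[sel] - 1)), 0.02)
  # exact model dispersion holds further up the band
  tau <- 2 * alpha0_db_to_np(2.7) * 1480
  kim <- (2 * pi * f / 1480) * Im(1 / sqrt(1 - 1i * 2 * pi * f * tau))
  pred_x <- exp(-2 * kim * d)
  selx <- f > 0.3e6 & f < 0.7 * max_supported_frequency(med)
  expect_lt(max(abs((s2$power / s1$power)[selx] / pred_x[selx] - 1)), 0.02)
})

test_that("transmission through a solid plate matches the transfer-matrix oracle", {
  mats <- pa_materials()
  dx <- 125e-6
  med_w <- homogeneous_medium(640, dx)
  med_b <- med_w
  plate <- 200:259                       # 7.5 mm solid bone
  med_b$sound_speed[plate] <- 3100
  med_b$density[plate] <- 2190
  med_b$alpha0[plate] <- 2.7
  cfg <- simulation_config(dt = 0.3 * dx / 3100, n_steps = 6000)
  sens <- sensor_points(matrix(460, 1, 1))
  ref <- result_waveform(run_forward(med_w, source_plane(med_w, 60), sens, cfg))
  tst <- result_waveform(run_forward(med_b, source_plane(med_b, 60), sens, cfg))
  il <- insertion_loss(tst, ref)
  st <- film_stack(mats$water, material_properties(3100, 2190, 2.7),
                   mats$water, 7.5e-3)
  f <- il$frequencies
  Tdb <- 20 * log10(Mod(layer_transmission(st, pmax(f, 1))))
  sel <- il$valid & f > 0.3e6 & f < 4e6 & Tdb > (max(Tdb) - 15)  # off-null
  expect_gt(sum(sel), 30)
  expect_lt(max(abs(il$loss_db[sel] - Tdb[sel])), 0.5)
})

test_that("reciprocity holds for swapped source and sensor to numerical tolerance", {
  med <- homogeneous_medium(c(256, 256), 125e-6)
  xs <- 1:256
  blob <- outer(exp(-((xs - 128)^2) / 200), exp(-((xs - 128)^2) / 200))
  med$sound_speed <- 1480 + 600 * blob
  A <- c(100, 118); B <- c(156, 140)
  cfg <- simulation_config(n_steps = 260, smooth_p0 = FALSE)
  wAB <- run_forward(med, source_point(med, A),
                     sensor_points(matrix(B, 1, 2)), cfg)$waveforms[1, ]
  wBA <- run_forward(med, source_point(med, B),
                     sensor_points(matrix(A, 1, 2)), cfg)$waveforms[1, ]
  expect_lt(max(abs(wAB - wBA)) / max(abs(wAB)), 0.01)
})

test_that("axisymmetric disk-source waveform matches the analytic k-space oracle", {
  sc <- small_axisym_scene(dist = 15e-3)
  res <- run_forward(sc$medium, sc$source, sc$sensors,
                     simulation_config(n_steps = 1100))
  be <- band_edges(power_spectrum(result_waveform(res), nfft = 8192))
  wo <- oracle_disk_waveform(15e-3, 2.5e-3, 125e-6)
  beo <- band_edges(power_spectrum(wo, nfft = 16384))
  expect_rel_equal(be$f_low, beo$f_low, 0.08)
  expect_rel_equal(be$f_high, beo$f_high, 0.08)
})

test_that("grid refinement leaves the received spectrum unchanged below fmax/2", {
  # physically identical Gaussian plane pulse on both grids (no source
  # smoothing, so the initial condition is resolution-independent)
  run_at <- function(dx, nsc) {
    n <- round(220 * nsc)
    med <- homogeneous_medium(n, dx)
    x <- (seq_len(n) - round(40 * nsc)) * dx
    p0 <- exp(-x^2 / (2 * (180e-6)^2))
    cfg <- simulation_config(dt = 0.3 * dx / 1480, n_steps = round(420 * nsc),
                             smooth_p0 = FALSE)
    res <- run_forward(med, p0, sensor_points(matrix(round(160 * nsc), 1, 1)), cfg)
    power_spectrum(result_waveform(res), nfft = 4096 * nsc)
  }
  s1 <- run_at(125e-6, 1)
  s2 <- run_at(62.5e-6, 2)
  fmax <- 1480 / (2 * 125e-6)
  fg <- seq(0.2e6, 0.5 * fmax, by = 0.05e6)
  a1 <- sqrt(stats::approx(s1$frequencies, s1$power, fg)$y)
  a2 <- sqrt(stats::approx(s2$frequencies, s2$power, fg)$y)
  expect_lt(max(abs(a1 / a2 - 1)), 0.01)
})

test_that("solver rejects unstable configurations and negative absorption sweeps", {
  med <- homogeneous_medium(c(64, 64), 125e-6)
  expect_error(run_forward(med, source_point(med, c(32, 32)),
                           sensor_points(matrix(c(40, 32), 1, 2)),
                           simulation_config(dt = 1e-6, n_steps = 10)),
               "CFL violation")
  expect_error(attenuation_sweep(med, source_point(med, c(32, 32)),
                                 sensor_points(matrix(c(40, 32), 1, 2)),
                                 simulation_config(n_steps = 10), numeric(0)),
               "nonempty")
  expect_error(attenuation_sweep(med, source_point(med, c(32, 32)),
                                 sensor_points(matrix(c(40, 32), 1, 2)),
                                 simulation_config(n_steps = 10), c(-1)),
               "negative")
})

test_that("attenuation sweep reproduces the baseline and scales plate loss", {
  dx <- 250e-6
  med <- homogeneous_medium(500, dx)
  plate <- 200:229                        # 7.5 mm at 250 um
  med$sound_speed[plate] <- 3100
  med$density[plate] <- 2190
  med$alpha0[plate] <- 2.7
  cfg <- simulation_config(dt = 0.3 * dx / 3100, n_steps = 3200)
  sens <- sensor_points(matrix(380, 1, 1))
  src <- source_plane(med, 60)
  base <- run_forward(med, src, sens, cfg)
  sw <- attenuation_sweep(med, src, sens, cfg, c(2.7, 6.0))
  expect_equal(sw[[1]]$waveforms, base$waveforms, tolerance = 1e-12)
  ref <- result_waveform(run_forward(homogeneous_medium(500, dx), src, sens, cfg))
  il27 <- insertion_loss(result_waveform(sw[[1]]), ref)
  il60 <- insertion_loss(result_waveform(sw[[2]]), ref)
  # doubling absorption adds ~ (delta alpha0) f^2 d of extra loss through bone
  f0 <- 2e6
  extra_pred <- -(6.0 - 2.7) * (f0 / 1e6)^2 * 0.75   # dB over 7.5 mm
  extra_meas <- il_at(il60, f0) - il_at(il27, f0)
  expect_lt(abs(extra_meas - extra_pred), 1.5)
  expect_lt(extra_meas, -1)
})
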