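test_that("ITF matches the brute-force phasor sum and its metrics invert", {
  et <- etalon_spec(493e-6, refractive_index_n = 1.52, R1 = 0.949, R2 = 0.97)
  wl <- seq(1576e-9, 1584e-9, by = 1e-12)
  curve <- itf(et, wl)
  oracle <- phasor_sum_itf(0.949, 0.97, 1.52, 493e-6, wl)
  expect_lt(max(abs(curve$intensity - oracle)), 1e-8)

  m <- itf_metrics(curve)
  # closed-form free spectral range and finesse
  fsr <- (1580e-9)^2 / (2 * 1.52 * 493e-6)
  expect_rel_equal(m$free_spectral_range, fsr, 0.01)
  finesse <- pi * sqrt(sqrt(0.949 * 0.97)) / (1 - sqrt(0.949 * 0.97))
  expect_rel_equal(m$q_factor, 1580e-9 / (fsr / finesse), 0.02)
  expect_lte(m$fringe_visibility, 1)
  # thickness recovered from the measured FSR
  expect_rel_equal(thickness_from_fsr(m$free_spectral_range, 1.52, 1580e-9),
                   493e-6, 0.01)
})

test_that("ITF handles degenerate and under-resolved inputs", {
  flat <- itf(etalon_spec(493e-6, R1 = 1e-12, R2 = 1e-12),
              seq(1579e-9, 1581e-9, by = 5e-12))
  expect_lt(diff(range(flat$intensity)), 1e-6)
  expect_error(itf_metrics(flat$wavelengths, rep(0.5, length(flat$wavelengths))),
               "fewer than two minima")
  expect_error(itf(etalon_spec(493e-6), seq(1500e-9, 1600e-9, by = 1e-9)),
               "unresolved")
  # doubling L halves the FSR
  m1 <- itf_metrics(itf(etalon_spec(200e-6), seq(1570e-9, 1590e-9, by = 5e-12)))
  m2 <- itf_metrics(itf(etalon_spec(400e-6), seq(1570e-9, 1590e-9, by = 5e-12)))
  expect_rel_equal(m1$free_spectral_range / m2$free_spectral_range, 2, 0.02)
})

test_that("thickness_from_fsr closed form", {
  expect_equal(thickness_from_fsr(0.5e-9, 1, 1e-6), 1e-3)
  expect_lt(thickness_from_fsr(1, 1.5, 1.58e-6), 1e-11)  # fsr -> large => L -> 0
})

test_that("layer transmission matches the multiple-reflection series", {
  mats <- pa_materials()
  bone <- material_properties(3100, 2190, 2.7)
  st <- film_stack(mats$water, bone, mats$water, 7.5e-3)
  f <- seq(0.1e6, 4e6, by = 0.05e6)
  expect_lt(max(abs(Mod(layer_transmission(st, f)) -
                    Mod(series_layer_transmission(st, f)))), 1e-6)
  # matched media are transparent at every frequency
  stm <- film_stack(mats$water, pa_materials()$water, mats$water, 3e-3)
  expect_lt(max(abs(Mod(layer_transmission(stm, f)) - 1)), 1e-12)
  # thin-layer limit: two-media value between front and backing
  stt <- film_stack(mats$cop, bone, mats$water, 1e-3)
  T0 <- Mod(layer_transmission(stt, 1))
  Z1 <- acoustic_impedance(mats$water); Z3 <- acoustic_impedance(mats$cop)
  expect_rel_equal(T0, 2 * Z3 / (Z1 + Z3), 1e-6)
  # lossless energy balance |R|^2 + |T|^2 Z1/Z3 = 1
  bone0 <- material_properties(3100, 2190, 0)
  st0 <- film_stack(mats$cop, bone0, mats$water, 2e-3)
  Tt <- layer_transmission(st0, f); Rr <- layer_reflection(st0, f)
  expect_lt(max(abs(Mod(Rr)^2 + Mod(Tt)^2 * Z1 / Z3 - 1)), 1e-10)
})

test_that("film response is normalised at dc and scales inversely with thickness", {
  mats <- pa_materials()
  st <- film_stack(mats$cop, mats$parylene, mats$water, 20e-6)
  fr <- film_frequency_response(st, seq(1e4, 150e6, length.out = 3000))
  expect_equal(fr$sensitivity[1], 1, tolerance = 1e-6)
  # matched spacer reduces to |sinc|: first null at c/L, nulls move as 1/L
  wmat <- material_properties(1480, 1000, 0)
  for (L in c(100e-6, 250e-6, 500e-6)) {
    stm <- film_stack(wmat, wmat, wmat, L)
    fg <- seq(1e4, 2.2 * 1480 / L, length.out = 4000)
    frm <- film_frequency_response(stm, fg)
    sinc_ref <- abs(ifelse(fg == 0, 1, sin(pi * fg * L / 1480) / (pi * fg * L / 1480)))
    expect_lt(max(abs(frm$sensitivity - sinc_ref)), 1e-6)
    expect_rel_equal(frm$f_first_min, 1480 / L, 0.01)
  }
  # -3 dB bandwidth scales as 1/L with materials fixed
  f3 <- vapply(c(100e-6, 200e-6, 400e-6), function(L) {
    stl <- film_stack(mats$cop, mats$spacer, mats$water, L)
    film_frequency_response(stl, seq(1e4, 0.8 * 2500 / L, length.out = 3000))$f_3db
  }, numeric(1))
  expect_rel_equal(f3[1] / f3[2], 2, 0.02)
  expect_rel_equal(f3[2] / f3[3], 2, 0.02)
})

test_that("piezo band-pass and PVDF low-pass responses have the stated landmarks", {
  sp <- piezo_spec(1e6)
  expect_equal(piezo_response(sp, 1e6), 1)
  expect_equal(piezo_response(sp, 0.675e6), 0.5, tolerance = 1e-9)
  expect_equal(piezo_response(sp, 1.325e6), 0.5, tolerance = 1e-9)
  expect_lt(piezo_response(sp, 0), 0.01)       # blind near dc
  expect_equal(pvdf_response(20e6), 0.5, tolerance = 1e-9)
  expect_gt(pvdf_response(1e6), 0.999)
})

test_that("aperture averaging passes uniform fields and cancels antiphase fields", {
  nt <- 64
  uniform <- matrix(rep(sin(2 * pi * (1:nt) / 16), each = 21), 21, nt)
  sc <- scan_set(uniform, dx = 1e-3, dt = 1e-7)
  avg <- aperture_average(sc, 10e-3)
  expect_equal(avg$samples, uniform[1, ], tolerance = 1e-12)
  anti <- uniform; anti[1:10, ] <- -anti[1:10, ]; anti[11, ] <- 0
  avg2 <- aperture_average(scan_set(anti, 1e-3, 1e-7), 20e-3)
  expect_lt(max(abs(avg2$samples)), 1e-12)
  expect_error(aperture_average(sc, 60e-3), "exceeds")
})

test_that("NEP estimation recovers a known noise level and is self-consistent", {
  expect_error(estimate_nep(waveform(rnorm(100) * 0 + 0.001 * sin(1:100), 1e-8),
                            0, 1e6), "zero sensitivity")
  zero <- estimate_nep(waveform(numeric(2048), 1e-8), 1, 5e6)
  expect_equal(zero$nep, 0)
  set.seed(42)
  sigmas <- replicate(100, {
    w <- waveform(rnorm(4096, sd = 2.5), 1e-8)
    estimate_nep(w, 1, 50e6)$nep   # band >= Nyquist: no filtering
  })
  expect_rel_equal(mean(sigmas), 2.5, 0.05)
  # definitional consistency nep = density * sqrt(bandwidth)
  r <- estimate_nep(waveform(rnorm(8192, sd = 1), 1e-8), 2, 2.8e6)
  expect_equal(r$nep, r$nep_density * sqrt(r$measurement_bandwidth),
               tolerance = 1e-12)
})

test_that("modelled NEP improves monotonically as resonators thicken", {
  curve <- nep_design_curve(seq(100e-6, 500e-6, by = 50e-6))
  expect_true(all(diff(curve$nep_pa) < 0))
  expect_true(all(diff(curve$bandwidth_hz) < 0))
})
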