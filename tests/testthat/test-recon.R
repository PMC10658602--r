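test_that("zero scans reconstruct to zero and laterally uniform fields are exact", {
  dx <- 0.25e-3; c0 <- 1480; dt <- dx / c0
  z <- reconstruct_planar(scan_set(array(0, c(8, 8, 32)), dx, dt), c0)
  expect_equal(max(abs(z$p0)), 0)
  # plane layers (kx = 0 modes) round-trip to machine precision
  p0 <- matrix(0, 16, 64)
  for (iz in 1:64) p0[, iz] <- exp(-(iz - 30)^2 / 18)
  v <- reconstruct_planar(project_planar(p0, dx, dt, c0, nt = 64), c0)
  expect_lt(max(abs(v$p0 - p0)) / max(p0), 1e-12)
})

test_that("reconstruction is linear in the data", {
  dx <- 0.25e-3; c0 <- 1480; dt <- dx / c0
  s1 <- synthesize_ball_scan(c(0.5e-3, 0, 8e-3), nx = 32, dx = dx, nt = 64,
                             dt = dt, c = c0, sigma = 0.4e-3)
  s2 <- synthesize_ball_scan(c(-1e-3, 1e-3, 5e-3), nx = 32, dx = dx, nt = 64,
                             dt = dt, c = c0, sigma = 0.3e-3)
  va <- reconstruct_planar(s1, c0)$p0
  vb <- reconstruct_planar(s2, c0)$p0
  vab <- reconstruct_planar(scan_set(2 * s1$pressure - 3 * s2$pressure, dx, dt),
                            c0)$p0
  expect_lt(max(abs(vab - (2 * va - 3 * vb))) / max(abs(vab)), 1e-10)
})

test_that("a point-like source is localised within two voxels (analytic scan)", {
  dx <- 0.25e-3; c0 <- 1480; dt <- dx / c0
  pos <- c(1.2e-3, -0.8e-3, 12e-3)
  scan <- synthesize_ball_scan(pos, nx = 64, dx = dx, nt = 160, dt = dt,
                               c = c0, sigma = 0.4e-3)
  vol <- reconstruct_planar(scan, c0)
  m <- which(vol$p0 == max(vol$p0), arr.ind = TRUE)[1, ]
  expect_lte(abs(m[1] - (32.5 + pos[1] / dx)), 2)
  expect_lte(abs(m[2] - (32.5 + pos[2] / dx)), 2)
  expect_lte(abs(m[3] - (pos[3] / (c0 * dt) + 1)), 2)
})

test_that("a 5 mm disk source reconstructs with its diameter within 15 percent", {
  c0 <- 1480; dx <- 0.3125e-3; dt <- dx / c0
  nx <- 64
  p0 <- array(0, c(nx, nx, 112))
  xs <- (1:nx - (nx + 1) / 2) * dx
  mask <- outer(xs^2, xs^2, `+`) <= (2.5e-3)^2
  iz0 <- round(30e-3 / dx) + 1
  p0[, , iz0][mask] <- 1
  sc <- project_planar(p0, dx, dt, c0, nt = 130)
  vol <- reconstruct_planar(sc, c0)
  mip <- render(vol, "mip", axis = 3)
  fw <- profile_fwhm(mip[, (nx + 1) %/% 2]) * dx
  expect_lt(abs(fw - 5e-3) / 5e-3, 0.15)
  # MIP area at half max close to the disk area
  area <- sum(mip >= max(mip) / 2) * dx^2
  expect_lt(abs(area - pi * (2.5e-3)^2) / (pi * (2.5e-3)^2), 0.2)
})

test_that("sound-speed sweep peaks within 1 percent of the true water value", {
  c0 <- 1480; dx <- 0.25e-3; dt <- dx / c0
  scan <- synthesize_ball_scan(c(0, 0, 25e-3), nx = 95, dx = dx, nt = 240,
                               dt = dt, c = c0, sigma = 0.18e-3)
  sw <- sweep_sound_speed(scan, seq(1445, 1520, by = 5))
  best <- sw$c[which.max(sw$sharpness)]
  expect_lt(abs(best - 1480) / 1480, 0.01)
  # single value reduces to reconstruct_planar
  one <- sweep_sound_speed(scan, 1480, keep_volumes = TRUE)
  v <- attr(one, "volumes")[[1]]
  expect_equal(v$p0, reconstruct_planar(scan, 1480)$p0, tolerance = 1e-12)
  expect_error(sweep_sound_speed(scan, numeric(0)), "empty")
})

test_that("renderers obey MIP and slice semantics", {
  vol <- structure(list(p0 = array(0, c(5, 6, 7)), dx = 1e-3, dz = 1e-3,
                        assumed_sound_speed = 1480), class = "pa_volume")
  vol$p0[2, 3, 4] <- 1
  for (ax in 1:3) {
    m <- render(vol, "mip", axis = ax)
    expect_equal(sum(m > 0), 1L)
  }
  expect_equal(render(vol, "slice", axis = 3, index = 4)[2, 3], 1)
  expect_error(render(vol, "slice", axis = 3, index = 99), "out of range")
  # MIP dominates every slice elementwise
  vol$p0 <- array(abs(rnorm(5 * 6 * 7)), c(5, 6, 7))
  m3 <- render(vol, "mip", axis = 3)
  for (k in 1:7) expect_true(all(m3 >= vol$p0[, , k] - 1e-15))
})

test_that("projector agrees with the analytic spherical-wave oracle", {
  # independent cross-check of the spectral forward model used in tests;
  # the spectral world is laterally periodic, so the recording window is
  # kept shorter than the nearest replica path
  dx <- 0.25e-3; c0 <- 1480; dt <- dx / c0
  nx <- 96; nzv <- 64; sigma <- 0.5e-3
  x <- (1:nx - (nx + 1) / 2) * dx
  zc <- 8e-3
  p0 <- array(0, c(nx, nx, nzv))
  for (iz in 1:nzv) {
    z <- (iz - 1) * c0 * dt
    p0[, , iz] <- exp(-(outer(x^2, x^2, `+`) + (z - zc)^2) / (2 * sigma^2))
  }
  g1 <- project_planar(p0, dx, dt, c0, nt = 72)
  g2 <- synthesize_ball_scan(c(0, 0, zc), nx = nx, dx = dx, nt = 72, dt = dt,
                             c = c0, sigma = sigma)
  for (pix in list(c(48, 48), c(48, 49), c(56, 60))) {
    a <- g1$pressure[pix[1], pix[2], ]; b <- g2$pressure[pix[1], pix[2], ]
    expect_gt(stats::cor(a, b), 0.995)
    expect_lt(max(abs(a - b)) / max(abs(b)), 0.1)
  }
})
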