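# Independent oracles and shared fixtures for the test suite. These are
# deliberately written as brute-force / closed-form computations that do not
# reuse the implementation paths they check.

# Phasor-sum of partial reflections for a two-mirror cavity (reflected
# amplitude), summing `nterms` round trips explicitly.
phasor_sum_itf <- function(R1, R2, n, L, wavelengths, nterms = 600) {
  r1 <- sqrt(R1); r2 <- sqrt(R2)
  phi <- 4 * pi * n * L / wavelengths
  e <- exp(1i * phi)
  acc <- 0
  for (m in 0:nterms) acc <- acc + (r1 * r2 * e)^m
  r <- r1 - (1 - r1^2) * r2 * e * acc
  Mod(r)^2
}

# Brute-force multiple-reflection series for single-layer transmission.
series_layer_transmission <- function(stack, f, nrefl = 50) {
  Z1 <- acoustic_impedance(stack$front)
  Z2 <- acoustic_impedance(stack$spacer)
  Z3 <- acoustic_impedance(stack$backing)
  L <- stack$thickness
  w <- 2 * pi * f
  k2 <- w / stack$spacer$sound_speed +
    1i * alpha0_db_to_np(stack$spacer$alpha0) * w^2
  t12 <- 2 * Z2 / (Z1 + Z2); t23 <- 2 * Z3 / (Z2 + Z3)
  r21 <- (Z1 - Z2) / (Z1 + Z2); r23 <- (Z3 - Z2) / (Z3 + Z2)
  e <- exp(1i * k2 * L)
  acc <- 0
  for (m in 0:nrefl) acc <- acc + (r21 * r23 * e^2)^m
  t12 * t23 * e * acc
}

# Analytic on-axis waveform of a Blackman-smoothed single-voxel disk source
# in homogeneous water, via direct quadrature of the axisymmetric k-space
# solution (independent of the time-domain solver).
oracle_disk_waveform <- function(z, a, dx, c = 1480, h = dx, nk = 320,
                                 dt = 4e-9, pre = 1.5e-6, post = 4e-6) {
  kmax <- pi / dx
  kx <- seq(-kmax, kmax, length.out = 2 * nk)
  kr <- seq(kmax / (4 * nk), kmax, length.out = nk)
  B <- function(k) ifelse(abs(k) <= kmax,
                          0.42 + 0.5 * cos(pi * k / kmax) + 0.08 * cos(2 * pi * k / kmax), 0)
  p0 <- outer(h * ifelse(kx == 0, 1, sin(kx * h / 2) / (kx * h / 2)),
              2 * pi * a * besselJ(kr * a, 1) / kr)
  W <- outer(B(kx), B(kr))
  KR <- matrix(kr, length(kx), length(kr), byrow = TRUE)
  KX <- matrix(kx, length(kx), length(kr))
  K <- sqrt(KX^2 + KR^2)
  A <- p0 * W * KR * exp(1i * KX * z)
  tt <- seq(z / c - pre, z / c + post, by = dt)
  sig <- vapply(tt, function(ti) Re(sum(A * cos(c * K * ti))), numeric(1))
  waveform(sig - mean(sig[1:40]), dt)
}

# Small water medium + disk source + on-axis sensor, axisymmetric, reduced
# scale (sensor at `dist`), shared across solver tests.
small_axisym_scene <- function(dist = 15e-3, dx = 125e-6, radial = 6e-3,
                               diameter = 5e-3) {
  transmission_scene(NULL, dx, distance = dist, source_diameter = diameter,
                     radial_extent = radial)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
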