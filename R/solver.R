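#' Simulation configuration for the k-space solver
#'
#' Numerical parameters of the pseudospectral time-domain solver. The time
#' step defaults to `cfl * spacing / max(c)`; the k-space dispersion
#' correction uses the maximum sound speed in the map as reference (a
#' stability-biased choice) unless overridden.
#'
#' @param cfl Courant number used to derive `dt` when not given. Default 0.3.
#' @param dt Time step in seconds (overrides `cfl`).
#' @param n_steps Number of time steps; alternatively give `t_end`.
#' @param t_end Physical duration to simulate, seconds.
#' @param pml_size Thickness of the perfectly matched layer, voxels (>= 8).
#' @param pml_alpha Maximum PML absorption, Np per grid point.
#' @param c_ref Reference sound speed for the k-space correction, m/s.
#' @param smooth_p0 Apply Blackman source smoothing (default `TRUE`).
#' @param record_energy Also record total acoustic energy per step
#'   (Cartesian grids only).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(cfl = 0.3, dt = NULL, n_steps = NULL, t_end = NULL,
                              pml_size = 16, pml_alpha = 2, c_ref = NULL,
                              smooth_p0 = TRUE, record_energy = FALSE) {
  stopifnot(cfl > 0, pml_size >= 8)
  structure(list(cfl = cfl, dt = dt, n_steps = n_steps, t_end = t_end,
                 pml_size = as.integer(pml_size), pml_alpha = pml_alpha,
                 c_ref = c_ref, smooth_p0 = isTRUE(smooth_p0),
                 record_energy = isTRUE(record_energy)),
            class = "sim_config")
}

# ---- source helpers ---------------------------------------------------------

#' Disk, plane and point initial-pressure sources
#'
#' Build an initial pressure array matching a medium's grid. A `disk` source
#' is a flat disk normal to the acoustic axis (a strip in plain 2D, a true
#' disk in 3D and in axisymmetric media); a `plane` source fills the whole
#' cross-section at one axial index; a `point` source is a single voxel.
#'
#' @param medium A `pa_medium`.
#' @param x_index Axial voxel index of the source plane.
#' @param diameter Disk diameter in metres.
#' @param amplitude Initial pressure in Pa.
#' @param thickness Axial thickness in voxels (default 1).
#' @param center Lateral center in voxel coordinates (defaults to the grid
#'   centre; the axis for axisymmetric media).
#' @return Initial-pressure array with the medium's dimensions.
#' @export
source_disk <- function(medium, x_index, diameter, amplitude = 1,
                        thickness = 1L, center = NULL) {
  d <- dim(medium$sound_speed); if (is.null(d)) d <- length(medium$sound_speed)
  dx <- medium$spacing
  radius <- diameter / 2
  p0 <- array(0, d)
  xs <- x_index + seq_len(thickness) - 1L
  if (length(d) == 1L) { p0[xs] <- amplitude; return(p0) }
  if (medium$axisymmetric) {
    r <- (seq_len(d[2]) - 0.5) * dx
    p0[xs, r <= radius] <- amplitude
  } else if (length(d) == 2L) {
    yc <- if (is.null(center)) (d[2] + 1) / 2 else center[1]
    y <- (seq_len(d[2]) - yc) * dx
    p0[xs, abs(y) <= radius] <- amplitude
  } else {
    cc <- if (is.null(center)) (d[2:3] + 1) / 2 else center
    y <- (seq_len(d[2]) - cc[1]) * dx
    z <- (seq_len(d[3]) - cc[2]) * dx
    mask <- outer(y, z, function(a, b) sqrt(a^2 + b^2)) <= radius
    for (ix in xs) p0[ix, , ][mask] <- amplitude
  }
  p0
}

#' @rdname source_disk
#' @export
source_plane <- function(medium, x_index, amplitude = 1, thickness = 1L) {
  d <- dim(medium$sound_speed); if (is.null(d)) d <- length(medium$sound_speed)
  p0 <- array(0, d)
  xs <- x_index + seq_len(thickness) - 1L
  if (length(d) == 1L) p0[xs] <- amplitude
  else if (length(d) == 2L) p0[xs, ] <- amplitude
  else p0[xs, , ] <- amplitude
  p0
}

#' @rdname source_disk
#' @param index Voxel index vector (length = grid dimensions) of the point.
#' @export
source_point <- function(medium, index, amplitude = 1) {
  d <- dim(medium$sound_speed); if (is.null(d)) d <- length(medium$sound_speed)
  p0 <- array(0, d)
  p0[matrix(as.integer(index), 1)] <- amplitude
  p0
}

# ---- sensor layouts ---------------------------------------------------------

#' Sensor layouts for forward simulations
#'
#' `sensor_points()` records single-voxel time series at the given positions
#' (one row per sensor, voxel indices). `sensor_axis()` records on the
#' acoustic axis; in axisymmetric media the on-axis value is obtained by
#' quadratic extrapolation from the two innermost radial cells.
#' `sensor_plane()` records the full cross-sectional plane at one axial index
#' every time step, producing a planar scan.
#'
#' @param positions Integer matrix of voxel indices, one row per sensor.
#' @param x_indices Axial indices for on-axis sensors.
#' @param x_index Axial index of the recording plane.
#' @return A sensor layout object.
#' @export
sensor_points <- function(positions) {
  positions <- rbind(positions)
  structure(list(kind = "points", positions = positions), class = "pa_sensors")
}

#' @rdname sensor_points
#' @export
sensor_axis <- function(x_indices) {
  structure(list(kind = "axis", x_indices = as.integer(x_indices)),
            class = "pa_sensors")
}

#' @rdname sensor_points
#' @export
sensor_plane <- function(x_index) {
  structure(list(kind = "plane", x_index = as.integer(x_index)),
            class = "pa_sensors")
}

# ---- core solver ------------------------------------------------------------

# Mirror an (x, r >= 0) half-plane array about the axis into (x, 2 nr).
mirror_radial <- function(a) {
  nr <- dim(a)[2]
  cbind(a[, nr:1, drop = FALSE], a)
}

#' Forward-simulate acoustic propagation with a k-space pseudospectral solver
#'
#' Integrates the first-order coupled acoustic equations (momentum, mass
#' conservation, pressure-density relation) for longitudinal waves in
#' heterogeneous lossy media. Spatial gradients are evaluated spectrally on
#' staggered grids with a k-space correction `sinc(c_ref |k| dt / 2)` that
#' compensates the leapfrog time stepping; boundaries carry a split-field
#' perfectly matched layer; acoustic absorption follows a frequency-squared
#' power law (`alpha = alpha0 f^2`), for which the loss operator reduces to a
#' frequency-independent term proportional to the local divergence of
#' velocity and the dispersion correction vanishes.
#'
#' Supports 1D, 2D and 3D Cartesian grids and axisymmetric (x, r) media with
#' identical physics; axisymmetric media are propagated on a mirrored
#' cell-centred radial domain (the axis falls between grid cells) with the
#' cylindrical divergence term `u_r / r` evaluated pointwise.
#'
#' @param medium A `pa_medium`.
#' @param source Initial pressure array (same shape as the medium's fields),
#'   e.g. from [source_disk()].
#' @param sensors A sensor layout from [sensor_points()], [sensor_axis()] or
#'   [sensor_plane()].
#' @param config A [simulation_config()].
#' @return A list of class `pa_simresult`: `waveforms` (matrix, one row per
#'   sensor) or `scan` (plane recording), `dt`, `t`, and `energy` when
#'   requested.
#' @export
run_forward <- function(medium, source, sensors, config = simulation_config()) {
  dx <- medium$spacing
  axisym <- medium$axisymmetric
  c0 <- as.array(medium$sound_speed)
  rho0 <- as.array(medium$density)
  alpha0 <- as.array(medium$alpha0)
  p0 <- as.array(source)
  stopifnot(identical(dim(p0), dim(c0)))
  if (axisym) {
    if (length(dim(c0)) != 2L) stop("axisymmetric media must be 2D (x, r) half-planes")
    nr_half <- dim(c0)[2]
    c0 <- mirror_radial(c0); rho0 <- mirror_radial(rho0)
    alpha0 <- mirror_radial(alpha0); p0 <- mirror_radial(p0)
  }
  dims <- dim(c0); if (is.null(dims)) dims <- length(c0)
  D <- length(dims)
  cmax <- max(c0)

  dt <- config$dt
  if (is.null(dt)) dt <- config$cfl * dx / cmax
  dt_max <- 2 * dx / (pi * cmax)
  if (dt > dt_max)
    stop(sprintf("CFL violation: dt = %.3e s exceeds the maximum stable time step %.3e s",
                 dt, dt_max))
  n_steps <- config$n_steps
  if (is.null(n_steps)) {
    if (is.null(config$t_end)) stop("give n_steps or t_end")
    n_steps <- ceiling(config$t_end / dt)
  }
  c_ref <- if (is.null(config$c_ref)) cmax else config$c_ref

  # spectral operators -------------------------------------------------------
  kv <- lapply(seq_len(D), function(d) fft_wavenumbers(dims[d], dx))
  K <- array(0, dims)
  for (d in seq_len(D)) K <- K + sweep_dim(array(1, dims), d, kv[[d]]^2)
  K <- sqrt(K)
  arg <- c_ref * K * dt / 2
  kappa <- ifelse(arg == 0, 1, sin(arg) / arg)
  op_plus <- vector("list", D); op_minus <- vector("list", D)
  for (d in seq_len(D)) {
    k <- kv[[d]]
    if (dims[d] %% 2 == 0) k[dims[d] / 2 + 1] <- 0  # drop odd-derivative Nyquist
    op_plus[[d]]  <- sweep_dim(kappa, d, 1i * k * exp( 1i * k * dx / 2))
    op_minus[[d]] <- sweep_dim(kappa, d, 1i * k * exp(-1i * k * dx / 2))
  }
  shift_minus_r <- if (axisym)
    sweep_dim(array(1 + 0i, dims), 2, exp(-1i * kv[[2]] * dx / 2)) else NULL

  # PML ----------------------------------------------------------------------
  pml_profile <- function(n, staggered) {
    i <- seq_len(n) - 1 + if (staggered) 0.5 else 0
    s <- numeric(n)
    L <- config$pml_size
    left <- i < L
    s[left] <- config$pml_alpha * (c_ref / dx) * ((L - i[left]) / L)^4
    right <- i > (n - 1 - L)
    s[right] <- config$pml_alpha * (c_ref / dx) * ((i[right] - (n - 1 - L)) / L)^4
    exp(-s * dt / 2)
  }
  pml <- lapply(seq_len(D), function(d) sweep_dim(array(1, dims), d, pml_profile(dims[d], FALSE)))
  pml_sg <- lapply(seq_len(D), function(d) sweep_dim(array(1, dims), d, pml_profile(dims[d], TRUE)))

  # staggered density, absorption -------------------------------------------
  shift_fwd <- function(a, d) {
    idx <- lapply(dims, seq_len)
    idx[[d]] <- c(seq_len(dims[d])[-1], dims[d])
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  rho0_sg <- lapply(seq_len(D), function(d) 0.5 * (rho0 + array(shift_fwd(rho0, d), dims)))
  c0sq <- c0^2
  absorb <- 2 * alpha0_db_to_np(alpha0) * c0  # tau in p = c^2 (rho - tau rho0 div u)

  inv_r <- NULL
  if (axisym) {
    r <- (seq_len(dims[2]) - nr_half - 0.5) * dx
    inv_r <- sweep_dim(array(1, dims), 2, 1 / r)
  }

  # initial conditions -------------------------------------------------------
  if (config$smooth_p0) p0 <- smooth_source(p0)
  p <- p0
  rho <- lapply(seq_len(D), function(d) p0 / (D * c0sq))
  u <- vector("list", D)
  p_hat <- stats::fft(p)
  for (d in seq_len(D)) {
    dpdx <- Re(stats::fft(op_plus[[d]] * p_hat, inverse = TRUE)) / prod(dims)
    u[[d]] <- -(dt / 2) / rho0_sg[[d]] * dpdx
  }

  # recording ----------------------------------------------------------------
  rec_points <- NULL
  if (sensors$kind == "points") {
    pos <- sensors$positions
    if (axisym) pos[, 2] <- pos[, 2] + nr_half
    rec_points <- t(pos)
    out <- matrix(NA_real_, nrow(pos), n_steps)
  } else if (sensors$kind == "axis") {
    out <- matrix(NA_real_, length(sensors$x_indices), n_steps)
  } else {
    plane_dims <- if (D == 2L) c(if (axisym) 2L * nr_half else dims[2], n_steps)
                  else c(dims[2], dims[3], n_steps)
    out <- array(NA_real_, plane_dims)
  }
  energy <- if (config$record_energy) numeric(n_steps) else NULL

  # hermitian packing: two real fields share one complex transform
  rev_idx <- lapply(dims, function(n) c(1L, rev(seq_len(n)[-1L])))
  conj_rev <- function(a) {
    Conj(do.call(`[`, c(list(a), rev_idx, list(drop = FALSE))))
  }
  N <- prod(dims)

  nan_check_every <- 50L
  for (step in seq_len(n_steps)) {
    # mass conservation + equation of state
    dudx <- vector("list", D)
    if (D == 1L) {
      fu <- stats::fft(u[[1]])
      dudx[[1]] <- Re(stats::fft(op_minus[[1]] * fu, inverse = TRUE)) / N
    } else {
      C12 <- stats::fft(u[[1]] + 1i * u[[2]])
      Cr <- conj_rev(C12)
      U1 <- (C12 + Cr) / 2
      U2 <- (C12 - Cr) / 2i
      if (axisym) {
        # radial derivative and the on-grid radial velocity in one transform
        E <- stats::fft(op_minus[[1]] * U1 + 1i * op_minus[[2]] * U2,
                        inverse = TRUE) / N
        dudx[[1]] <- Re(E)
        dudx[[2]] <- Im(E)
        u_reg <- Re(stats::fft(shift_minus_r * U2, inverse = TRUE)) / N
        dudx[[2]] <- dudx[[2]] + u_reg * inv_r
      } else {
        E <- stats::fft(op_minus[[1]] * U1 + 1i * op_minus[[2]] * U2,
                        inverse = TRUE) / N
        dudx[[1]] <- Re(E)
        dudx[[2]] <- Im(E)
      }
      if (D == 3L) {
        U3 <- stats::fft(u[[3]])
        dudx[[3]] <- Re(stats::fft(op_minus[[3]] * U3, inverse = TRUE)) / N
      }
    }
    div <- array(0, dims)
    for (d in seq_len(D)) {
      rho[[d]] <- pml[[d]] * (pml[[d]] * rho[[d]] - dt * rho0 * dudx[[d]])
      div <- div + dudx[[d]]
    }
    rho_sum <- rho[[1]]
    if (D > 1L) for (d in 2:D) rho_sum <- rho_sum + rho[[d]]
    p <- c0sq * (rho_sum - absorb * rho0 * div)

    if (sensors$kind == "points") {
      for (s in seq_len(ncol(rec_points))) out[s, step] <- p[matrix(rec_points[, s], 1)]
    } else if (sensors$kind == "axis") {
      if (axisym) {
        out[, step] <- (9 * p[sensors$x_indices, nr_half + 1L] -
                          p[sensors$x_indices, nr_half + 2L]) / 8
      } else if (D == 1L) out[, step] <- p[sensors$x_indices]
      else if (D == 2L) out[, step] <- p[sensors$x_indices, (dims[2] + 1L) %/% 2]
      else out[, step] <- p[sensors$x_indices, (dims[2] + 1L) %/% 2, (dims[3] + 1L) %/% 2]
    } else {
      if (D == 2L) out[, step] <- p[sensors$x_index, ]
      else out[, , step] <- p[sensors$x_index, , ]
    }

    # momentum conservation
    p_hat <- stats::fft(p)
    if (config$record_energy) u_prev <- u
    if (D == 1L) {
      dpdx1 <- Re(stats::fft(op_plus[[1]] * p_hat, inverse = TRUE)) / N
      u[[1]] <- pml_sg[[1]] * (pml_sg[[1]] * u[[1]] - dt / rho0_sg[[1]] * dpdx1)
    } else {
      Gp <- stats::fft(op_plus[[1]] * p_hat + 1i * op_plus[[2]] * p_hat,
                       inverse = TRUE) / N
      u[[1]] <- pml_sg[[1]] * (pml_sg[[1]] * u[[1]] - dt / rho0_sg[[1]] * Re(Gp))
      u[[2]] <- pml_sg[[2]] * (pml_sg[[2]] * u[[2]] - dt / rho0_sg[[2]] * Im(Gp))
      if (D == 3L) {
        dpdx3 <- Re(stats::fft(op_plus[[3]] * p_hat, inverse = TRUE)) / N
        u[[3]] <- pml_sg[[3]] * (pml_sg[[3]] * u[[3]] - dt / rho0_sg[[3]] * dpdx3)
      }
    }
    if (config$record_energy) {
      kin <- 0
      for (d in seq_len(D)) kin <- kin + sum(rho0_sg[[d]] * u_prev[[d]] * u[[d]])
      energy[step] <- 0.5 * kin + sum(p^2 / (2 * rho0 * c0sq))
    }

    if (step %% nan_check_every == 0L && anyNA(p))
      stop("NaN detected in pressure field at step ", step)
  }
  if (anyNA(p) || any(!is.finite(p)))
    stop("non-finite pressure field at end of run (step ", n_steps, ")")

  res <- list(dt = dt, t = seq_len(n_steps) * dt, n_steps = n_steps,
              spacing = dx, axisymmetric = axisym, energy = energy,
              c_ref = c_ref)
  if (sensors$kind == "plane") res$scan <- out else res$waveforms <- out
  class(res) <- "pa_simresult"
  res
}

#' @export
print.pa_simresult <- function(x, ...) {
  what <- if (!is.null(x$scan)) sprintf("plane scan %s", paste(dim(x$scan), collapse = " x "))
          else sprintf("%d sensor trace(s)", nrow(x$waveforms))
  cat(sprintf("<pa_simresult> %s, %d steps @ %.3g ns\n", what, x$n_steps, x$dt * 1e9))
  invisible(x)
}

#' Extract one sensor trace as a waveform
#'
#' @param result A `pa_simresult` from [run_forward()].
#' @param i Sensor row index.
#' @return A [waveform()].
#' @export
result_waveform <- function(result, i = 1L) {
  waveform(result$waveforms[i, ], result$dt, t0 = result$dt)
}

#' Repeat a forward run over a set of bone absorption values
#'
#' Re-runs [run_forward()] with the bone voxels' absorption prefactor replaced
#' by each value in `alpha0_values`; water voxels are untouched. Bone voxels
#' are identified as those carrying the maximum density in the map.
#'
#' @param medium,source,sensors,config As in [run_forward()].
#' @param alpha0_values Numeric vector of alpha0 values, dB/cm/MHz^2.
#' @return List of `pa_simresult`, one per value.
#' @export
attenuation_sweep <- function(medium, source, sensors, config, alpha0_values) {
  if (length(alpha0_values) == 0L) stop("alpha0_values must be nonempty")
  if (any(alpha0_values < 0)) stop("negative alpha0")
  rho <- medium$density
  mask <- if (diff(range(rho)) > 0) rho == max(rho) else array(FALSE, dim(rho))
  lapply(alpha0_values, function(a0) {
    m <- medium
    m$alpha0[mask] <- a0
    run_forward(m, source, sensors, config)
  })
}
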