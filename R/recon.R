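#' Planar-sensor scan set
#'
#' Time-resolved pressure on a regular planar raster of detection points
#' (a line of points for 2D problems). The detection plane is z = 0 with z
#' increasing into the medium.
#'
#' @param pressure Array `(nx, ny, nt)` or matrix `(nx, nt)` of pressure
#'   samples.
#' @param dx Raster pitch in metres (isotropic).
#' @param dt Sampling interval in seconds.
#' @return An object of class `pa_scan`.
#' @export
scan_set <- function(pressure, dx, dt) {
  pressure <- as.array(pressure)
  stopifnot(length(dim(pressure)) %in% c(2L, 3L), dx > 0, dt > 0,
            all(is.finite(pressure)))
  structure(list(pressure = pressure, dx = dx, dt = dt), class = "pa_scan")
}

#' @export
print.pa_scan <- function(x, ...) {
  d <- dim(x$pressure)
  cat(sprintf("<pa_scan> %s raster x %d samples, pitch %.3g mm, dt %.3g ns\n",
              paste(d[-length(d)], collapse = " x "), d[length(d)],
              x$dx * 1e3, x$dt * 1e9))
  invisible(x)
}

# Map even-extended time spectra onto the kz shell omega = c |k|.
# Returns the complex interpolated values with Jacobian weighting.
planar_fft_core <- function(G, kxy2, dt, c, inverse_weight = FALSE) {
  # G: array with last dim = Nt frequency bins (fft order); kxy2: array of
  # squared lateral wavenumbers matching the leading dims of G.
  d <- dim(G); Nt <- d[length(d)]
  nzh <- Nt %/% 2 + 1L
  dw <- 2 * pi / (Nt * dt)
  kz <- (seq_len(nzh) - 1L) * dw / c          # kz grid (>= 0), dz = c dt
  out <- array(0i, c(d[-length(d)], nzh))
  wt <- (seq_len(nzh) - 1L) * dw              # omega bins of the data
  nlead <- prod(d[-length(d)])
  kxy2v <- as.vector(kxy2)
  Gm <- matrix(G, nlead, Nt)
  res <- matrix(0i, nlead, nzh)
  for (j in seq_len(nzh)) {
    w_tgt <- c * sqrt(kxy2v + kz[j]^2)
    pos <- w_tgt / dw
    lo <- floor(pos)
    ok <- lo < (nzh - 1L)                      # inside the positive-omega range
    frac <- pos - lo
    li <- pmin(lo, nzh - 2L) + 1L
    gv <- Gm[cbind(seq_len(nlead), li)] * (1 - frac) +
          Gm[cbind(seq_len(nlead), li + 1L)] * frac
    wgt <- if (inverse_weight) ifelse(kz[j] > 0, w_tgt / (c * kz[j]), 0)
           else ifelse(w_tgt > 0, c * kz[j] / w_tgt, 0)
    if (kz[j] == 0) wgt[kxy2v == 0] <- 1      # dc bin: Jacobian limit is 1
    res[, j] <- ifelse(ok, gv * wgt, 0i)
  }
  array(res, c(d[-length(d)], nzh))
}

# Even extension of the time axis (length 2 nt - 2), for fields that are
# time-symmetric about t = 0.
even_extend_t <- function(a) {
  d <- dim(a); nt <- d[length(d)]
  idx <- c(seq_len(nt), rev(seq_len(nt - 2L) + 1L))
  if (length(d) == 2L) a[, idx] else a[, , idx]
}

# Hermitian completion of the last (frequency/kz) axis from its first half.
fill_symmetric <- function(half, Nt, conjugate) {
  d <- dim(half); nzh <- d[length(d)]
  full <- array(0i, c(d[-length(d)], Nt))
  idx_src <- seq.int(2L, Nt - nzh + 1L)
  flip1 <- function(x) x[c(1L, rev(seq_len(dim(x)[1])[-1L])), , drop = FALSE]
  if (length(d) == 2L) {
    full[, seq_len(nzh)] <- half
    tail_ <- half[, rev(idx_src), drop = FALSE]
    tail_ <- flip1(tail_)                      # negative lateral frequencies
    full[, seq.int(nzh + 1L, Nt)] <- if (conjugate) Conj(tail_) else tail_
  } else {
    full[, , seq_len(nzh)] <- half
    tail_ <- half[, , rev(idx_src), drop = FALSE]
    tail_ <- tail_[c(1L, rev(seq_len(d[1])[-1L])), , , drop = FALSE]
    tail_ <- tail_[, c(1L, rev(seq_len(d[2])[-1L])), , drop = FALSE]
    full[, , seq.int(nzh + 1L, Nt)] <- if (conjugate) Conj(tail_) else tail_
  }
  full
}

#' Reconstruct an initial-pressure volume from a planar scan (FFT algorithm)
#'
#' Fourier-domain mapping for a planar detection geometry: the scan is
#' transformed over lateral position and time, the temporal frequency axis is
#' remapped onto the depth wavenumber through the dispersion relation
#' `omega = c sqrt(kx^2 + ky^2 + kz^2)` with linear interpolation and the
#' Jacobian weight `c kz / omega`, and the result is inverse-transformed to
#' give the initial pressure as a function of (x, y, depth). Components with
#' `omega` beyond the recorded band are zeroed. The sound speed is assumed
#' homogeneous.
#'
#' @param scan A [scan_set()] (2D matrix raster input reconstructs a 2D
#'   slice).
#' @param c Assumed sound speed in m/s.
#' @return An object of class `pa_volume` with `p0`, `dx`, `dz = c * dt` and
#'   `assumed_sound_speed`.
#' @export
reconstruct_planar <- function(scan, c = 1480) {
  stopifnot(inherits(scan, "pa_scan"), c > 0)
  a <- scan$pressure
  d <- dim(a)
  nt <- d[length(d)]
  if (c * scan$dt > scan$dx * 1.0001)
    warning("dt coarse for this sound speed and pitch; depth axis undersampled")
  ge <- even_extend_t(a)
  G <- stats::fft(ge)
  lead <- d[-length(d)]
  kx <- fft_wavenumbers(lead[1], scan$dx)
  kxy2 <- if (length(lead) == 1L) array(kx^2, lead)
          else outer(kx^2, fft_wavenumbers(lead[2], scan$dx)^2, `+`)
  half <- planar_fft_core(G, kxy2, scan$dt, c, inverse_weight = FALSE)
  Nt <- dim(ge)[length(dim(ge))]
  P0 <- fill_symmetric(half, Nt, conjugate = TRUE)   # even in kz, hermitian
  vol <- Re(stats::fft(P0, inverse = TRUE)) / prod(dim(P0))
  vol <- 2 * vol                                     # support z > 0 doubling
  keep <- seq_len(nt)
  vol <- if (length(lead) == 1L) vol[, keep] else vol[, , keep]
  structure(list(p0 = vol, dx = scan$dx, dz = c * scan$dt,
                 assumed_sound_speed = c),
            class = "pa_volume")
}

#' @export
print.pa_volume <- function(x, ...) {
  cat(sprintf("<pa_volume> %s voxels, dx %.3g mm, dz %.3g mm, c = %g m/s\n",
              paste(dim(x$p0), collapse = " x "), x$dx * 1e3, x$dz * 1e3,
              x$assumed_sound_speed))
  invisible(x)
}

#' Forward-project an initial-pressure volume to a planar scan
#'
#' Exact spectral solution of the wave equation in a homogeneous medium,
#' sampled on the detection plane z = 0: each lateral Fourier mode of the
#' (even-extended) volume evolves as a sum of cosines at the exact
#' frequencies `omega = c sqrt(kxy^2 + kz^2)` of its depth-wavenumber
#' content, with no frequency-axis interpolation. An independent, fast
#' simulator of planar scans for homogeneous media (the world is laterally
#' periodic: keep replica paths longer than the recording window). The
#' volume's depth spacing must satisfy `dz = c * dt`.
#'
#' @param p0 Initial-pressure array `(nx, ny, nz)` or matrix `(nx, nz)`;
#'   depth slice 1 sits on the detection plane.
#' @param dx Lateral pitch in metres.
#' @param dt Time sampling in seconds.
#' @param c Sound speed in m/s.
#' @param nt Number of time samples to synthesise (defaults to depth count).
#' @return A [scan_set()].
#' @export
project_planar <- function(p0, dx, dt, c = 1480, nt = NULL) {
  p0 <- as.array(p0)
  d <- dim(p0)
  nz <- d[length(d)]
  if (is.null(nt)) nt <- nz
  Nt <- 2L * nt - 2L
  stopifnot(nz <= nt)
  # volume on the doubled depth axis; spectral evenization about z = 0
  pad_dims <- c(d[-length(d)], Nt)
  pe <- array(0, pad_dims)
  if (length(d) == 2L) pe[, seq_len(nz)] <- p0 else pe[, , seq_len(nz)] <- p0
  Ph <- stats::fft(pe)
  Phe <- (Ph + conj_reverse_last(Ph)) / 2
  lead <- d[-length(d)]
  kx <- fft_wavenumbers(lead[1], dx)
  kxy2 <- if (length(lead) == 1L) array(kx^2, lead)
          else outer(kx^2, fft_wavenumbers(lead[2], dx)^2, `+`)
  kz <- fft_wavenumbers(Nt, c * dt)
  nzh <- Nt %/% 2 + 1L
  wgt <- rep(2, nzh); wgt[1] <- 1
  if (Nt %% 2 == 0) wgt[nzh] <- 1                   # shared Nyquist bin
  nlead <- prod(lead)
  Pm <- matrix(Phe, nlead, Nt)
  kxy2v <- as.vector(kxy2)
  tvec <- (seq_len(nt) - 1L) * dt
  G <- matrix(0i, nlead, nt)                        # per-mode time series
  for (m in seq_len(nzh)) {
    Km <- c * sqrt(kxy2v + kz[m]^2)
    G <- G + (wgt[m] * Pm[, m]) * cos(Km %o% tvec)
  }
  G <- G / Nt
  # inverse lateral FFT per time sample
  Ga <- array(G, c(lead, nt))
  g <- if (length(lead) == 1L) {
    Re(stats::mvfft(Ga, inverse = TRUE)) / lead[1]
  } else {
    out <- array(0, c(lead, nt))
    for (i in seq_len(nt))
      out[, , i] <- Re(stats::fft(Ga[, , i], inverse = TRUE)) / nlead
    out
  }
  scan_set(g, dx, dt)
}

# Reverse the last axis (FFT frequency negation) without conjugation.
conj_reverse_last <- function(a) {
  d <- dim(a); n <- d[length(d)]
  idx <- c(1L, rev(seq_len(n)[-1L]))
  if (length(d) == 2L) a[, idx] else a[, , idx]
}

#' Synthesise the planar scan of a Gaussian-ball source analytically
#'
#' Closed-form spherical-wave solution for an initial pressure
#' `p0(r) = A exp(-r^2 / (2 sigma^2))` centred at `position`, evaluated at
#' every raster point of a planar detector: an independent oracle for
#' simulate-then-reconstruct tests.
#'
#' @param position Source centre `(x, y, z)` in metres (z = depth), or
#'   `(x, z)` for a 2D line raster... only the 3D form is exact; use small
#'   sigma point-like targets for 2D checks.
#' @param nx,ny Raster points per lateral axis.
#' @param dx Raster pitch in metres.
#' @param nt,dt Time samples and interval.
#' @param c Sound speed in m/s.
#' @param sigma Gaussian radius in metres.
#' @param amplitude Peak initial pressure.
#' @return A [scan_set()].
#' @export
synthesize_ball_scan <- function(position, nx, ny = nx, dx, nt, dt, c = 1480,
                                 sigma = 0.3e-3, amplitude = 1) {
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  y <- (seq_len(ny) - (ny + 1) / 2) * dx
  R <- sqrt(outer((x - position[1])^2, (y - position[2])^2, `+`) + position[3]^2)
  tvec <- (seq_len(nt) - 1L) * dt
  g <- array(0, c(nx, ny, nt))
  phi <- function(s) exp(-s^2 / (2 * sigma^2))
  for (it in seq_len(nt)) {
    ct <- c * tvec[it]
    g[, , it] <- amplitude / (2 * R) * ((R - ct) * phi(R - ct) + (R + ct) * phi(R + ct))
  }
  scan_set(g, dx, dt)
}

#' Reconstruct a scan over a range of assumed sound speeds
#'
#' Runs [reconstruct_planar()] for each candidate sound speed and scores each
#' volume with a sharpness metric, supporting the heuristic selection of a
#' homogeneous reconstruction speed for transcranial data.
#'
#' @param scan A [scan_set()].
#' @param c_values Candidate sound speeds, m/s (physical range 1400-1800).
#' @param keep_volumes Return the reconstructed volumes as well.
#' @param method Sharpness metric, see [volume_sharpness()].
#' @return data.frame with `c` and `sharpness` (attribute `volumes` when
#'   requested); the best speed maximises sharpness.
#' @export
sweep_sound_speed <- function(scan, c_values, keep_volumes = FALSE,
                              method = c("peak", "entropy")) {
  if (length(c_values) == 0L) stop("empty sound-speed list")
  method <- match.arg(method)
  vols <- if (keep_volumes) vector("list", length(c_values)) else NULL
  sharp <- vapply(seq_along(c_values), function(i) {
    v <- suppressWarnings(reconstruct_planar(scan, c_values[i]))
    if (keep_volumes) vols[[i]] <<- v
    volume_sharpness(v, method)
  }, numeric(1))
  out <- data.frame(c = c_values, sharpness = sharp)
  if (keep_volumes) attr(out, "volumes") <- vols
  out
}

#' Sharpness of a reconstructed volume
#'
#' Focus metrics for autofocus-style sound-speed selection. `"peak"` (the
#' default) is the maximum coherent amplitude `max |p0|`, evaluated with
#' 8-fold Fourier upsampling along depth on the strongest columns so that the
#' score does not depend on where the focus falls relative to the voxel grid;
#' coherent summation is maximised when the assumed speed matches the medium.
#' `"entropy"` is the negative Shannon entropy of the normalised intensity
#' distribution; it is retained for comparison but is insensitive for
#' point-like targets under limited-view planar detection.
#'
#' @param volume A `pa_volume`.
#' @param method `"peak"` or `"entropy"`.
#' @return Sharpness score (dimensionless; larger = sharper).
#' @export
volume_sharpness <- function(volume, method = c("peak", "entropy")) {
  method <- match.arg(method)
  a <- abs(volume$p0)
  if (max(a) == 0) return(-Inf)
  if (method == "entropy") {
    s <- a / sum(a)
    s <- s[s > 0]
    return(sum(s * log(s)))
  }
  d <- dim(a)
  nz <- d[length(d)]
  m <- matrix(a, prod(d[-length(d)]), nz)
  cand <- order(apply(m, 1, max), decreasing = TRUE)[seq_len(min(48L, nrow(m)))]
  factor <- 8L
  best <- 0
  nh <- nz %/% 2
  for (i in cand) {
    X <- stats::fft(volume_column(volume, i))
    Xp <- complex(length.out = nz * factor)
    Xp[seq_len(nh)] <- X[seq_len(nh)]
    Xp[(nz * factor - nh + 1L):(nz * factor)] <- X[(nz - nh + 1L):nz]
    best <- max(best, max(abs(Re(stats::fft(Xp, inverse = TRUE)) / nz)))
  }
  best
}

volume_column <- function(volume, i) {
  d <- dim(volume$p0)
  m <- matrix(volume$p0, prod(d[-length(d)]), d[length(d)])
  m[i, ]
}

#' Render a volume as a maximum intensity projection or slice
#'
#' @param volume A `pa_volume`.
#' @param mode `"mip"` (per-pixel maximum along `axis`) or `"slice"` (plane
#'   extraction at `index`).
#' @param axis Axis number to project along / slice across.
#' @param index Slice index (`mode = "slice"`).
#' @return A 2D matrix (1D for 2D volumes) with attributes `dx`, `dz`,
#'   `mode`.
#' @export
render <- function(volume, mode = c("mip", "slice"), axis = 3L, index = NULL) {
  mode <- match.arg(mode)
  a <- volume$p0
  d <- dim(a)
  if (axis < 1 || axis > length(d)) stop("axis out of range")
  if (mode == "mip") {
    out <- apply(a, setdiff(seq_along(d), axis), max)
  } else {
    if (is.null(index)) index <- (d[axis] + 1L) %/% 2L
    if (index < 1 || index > d[axis]) stop("slice index out of range")
    idx <- lapply(d, seq_len)
    idx[[axis]] <- index
    out <- do.call(`[`, c(list(a), idx, list(drop = TRUE)))
  }
  attr(out, "dx") <- volume$dx; attr(out, "dz") <- volume$dz
  attr(out, "mode") <- mode
  out
}

#' Full width at half maximum of a profile
#'
#' Utility for measuring reconstructed target sizes: outermost half-maximum
#' crossings of a 1D profile, with linear interpolation, in sample units.
#'
#' @param profile Numeric vector (non-negative).
#' @return Width in samples.
#' @export
profile_fwhm <- function(profile) {
  p <- as.numeric(profile)
  mx <- max(p)
  half <- mx / 2
  above <- which(p >= half)
  i0 <- above[1]; i1 <- above[length(above)]
  left <- if (i0 > 1L) interp_cross(i0 - 1L, i0, p[i0 - 1L], p[i0], half) else i0
  right <- if (i1 < length(p)) interp_cross(i1, i1 + 1L, p[i1], p[i1 + 1L], half) else i1
  right - left
}
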