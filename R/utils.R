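# Shared numerical helpers (FFT grids, array broadcasting, waveform class).

# Angular wavenumbers in FFT bin order for n samples at spacing dx.
fft_wavenumbers <- function(n, dx) {
  n_neg <- n - floor(n / 2) - 1L
  m <- c(seq.int(0L, floor(n / 2)),
         if (n_neg >= 1L) seq.int(-n_neg, -1L) else integer(0))
  2 * pi * m / (n * dx)
}

# Multiply array `a` by vector `v` broadcast along dimension `d`.
sweep_dim <- function(a, d, v) {
  if (is.null(dim(a)) || length(dim(a)) == 1L) return(a * v)
  sweep(a, d, v, "*")
}

# Blackman taper over |k| up to the grid Nyquist wavenumber.
blackman_k <- function(k, k_nyq) {
  x <- pmin(abs(k) / k_nyq, 1)
  0.42 + 0.5 * cos(pi * x) + 0.08 * cos(2 * pi * x)
}

#' Spatially smooth a source distribution
#'
#' Applies a separable Blackman window in the spatial frequency domain, the
#' standard anti-aliasing treatment for broadband initial pressure sources on
#' a discrete grid, and rescales the result to the original maximum.
#'
#' @param p0 Numeric vector, matrix or 3D array.
#' @return Smoothed array of the same shape.
#' @export
smooth_source <- function(p0 ) {
  d <- dim(p0); if (is.null(d)) d <- length(p0)
  W <- 1
  ph <- stats::fft(p0)
  for (i in seq_along(d)) {
    k <- fft_wavenumbers(d[i], 1)
    ph <- sweep_dim(ph, i, blackman_k(k, pi))
  }
  sm <- Re(stats::fft(ph, inverse = TRUE)) / prod(d)
  mx <- max(abs(p0))
  if (max(abs(sm)) > 0) sm <- sm * mx / max(abs(sm))
  sm
}

#' Pressure waveform
#'
#' A time-resolved pressure trace with uniform sampling.
#'
#' @param samples Numeric vector of pressure samples (Pa).
#' @param dt Sampling interval in seconds.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `pa_waveform`.
#' @export
waveform <- function(samples, dt, t0 = 0) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), dt > 0)
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0),
            class = "pa_waveform")
}

#' @export
print.pa_waveform <- function(x, ...) {
  cat(sprintf("<pa_waveform> %d samples @ %g ns (%.3g us span), peak |p| = %.4g\n",
              length(x$samples), x$dt * 1e9,
              length(x$samples) * x$dt * 1e6, max(abs(x$samples))))
  invisible(x)
}

#' Time axis of a waveform
#' @param w A `pa_waveform`.
#' @return Numeric vector of sample times in seconds.
#' @export
waveform_time <- function(w) w$t0 + (seq_along(w$samples) - 1L) * w$dt

# Linear interpolation of y(x) at x0 (x ascending).
interp_at <- function(x, y, x0) stats::approx(x, y, xout = x0, rule = 2)$y
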