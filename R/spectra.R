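#' One-sided power spectrum of a waveform
#'
#' Periodogram of a pressure trace, scaled so that the sum over one-sided
#' bins equals the mean-square of the (windowed) time series (Parseval
#' consistency). Short pulse records are analysed with a rectangular window
#' by default; a Hann window is available.
#'
#' @param w A [waveform()].
#' @param window `"rect"` (default) or `"hann"`.
#' @param nfft Optional zero-padded transform length (>= number of samples).
#' @return An object of class `pa_spectrum` with fields `frequencies` (Hz,
#'   ascending from 0) and `power` (relative units).
#' @export
power_spectrum <- function(w, window = c("rect", "hann"), nfft = NULL) {
  stopifnot(inherits(w, "pa_waveform"))
  x <- w$samples
  if (length(x) < 16L) stop("waveform too short for a spectrum (need >= 16 samples)")
  window <- match.arg(window)
  if (window == "hann") {
    n <- length(x)
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  }
  n0 <- length(x)
  if (is.null(nfft)) nfft <- n0
  stopifnot(nfft >= n0)
  X <- stats::fft(c(x, numeric(nfft - n0)))
  nh <- floor(nfft / 2) + 1L
  P <- (Mod(X[seq_len(nh)])^2) / (n0 * nfft)
  scale <- rep(2, nh); scale[1] <- 1
  if (nfft %% 2 == 0) scale[nh] <- 1
  P <- P * scale
  structure(list(frequencies = (seq_len(nh) - 1L) / (nfft * w$dt), power = P,
                 db = FALSE),
            class = "pa_spectrum")
}

#' @export
print.pa_spectrum <- function(x, ...) {
  cat(sprintf("<pa_spectrum> %d bins, 0 .. %.3g MHz\n",
              length(x$frequencies), max(x$frequencies) / 1e6))
  invisible(x)
}

#' Band edges at a given drop below the spectral peak
#'
#' Finds the outermost crossings of `peak - drop_db` (in dB): the first
#' crossing coming up from dc and the last crossing before Nyquist, with
#' linear interpolation between bins. If the spectrum never falls `drop_db`
#' below its peak on a given side, the corresponding edge is 0 or Nyquist and
#' the result carries `clipped = TRUE`.
#'
#' @param s A `pa_spectrum`.
#' @param drop_db Drop below peak in dB (power); 6.02 dB corresponds to half
#'   amplitude.
#' @return List with `f_low`, `f_high` (Hz), `f_peak`, and `clipped`.
#' @export
band_edges <- function(s, drop_db = 6.0206) {
  f <- s$frequencies
  P <- s$power
  if (all(P <= 0)) stop("spectrum has no energy")
  Pdb <- 10 * log10(pmax(P, max(P) * 1e-300) / max(P))
  ipk <- which.max(Pdb)
  thr <- -abs(drop_db)
  above <- Pdb >= thr
  cross <- function(i0, i1) {
    # linear interpolation of the crossing between bins i0 (below) and i1 (above)
    f[i0] + (thr - Pdb[i0]) * (f[i1] - f[i0]) / (Pdb[i1] - Pdb[i0])
  }
  idx <- which(above)
  first <- idx[1]; last <- idx[length(idx)]
  clipped <- FALSE
  f_low <- if (first == 1L) { clipped <- clipped || Pdb[1] >= thr; f[1] }
           else cross(first - 1L, first)
  f_high <- if (last == length(f)) { clipped <- TRUE; f[last] }
            else cross(last + 1L, last)
  if (clipped) warning("band edge clipped at dc or Nyquist")
  list(f_low = f_low, f_high = f_high, f_peak = f[ipk], clipped = clipped)
}

#' Insertion loss spectrum
#'
#' Frequency-resolved transmission loss of a test path relative to a
#' reference path: `10 log10(P_test / P_ref)` of the one-sided power spectra
#' (negative values = attenuation). The spectrum is only meaningful where the
#' reference carries energy; the valid band is the contiguous frequency range
#' around the reference peak where the reference power stays at least 20 dB
#' above its own noise floor (estimated as the median reference power in the
#' top 20 % of frequencies).
#'
#' @param test,reference [waveform()]s with identical `dt`; the shorter is
#'   zero-padded.
#' @param window,nfft Passed to [power_spectrum()].
#' @param floor_margin_db Required headroom of the reference above its noise
#'   floor, dB.
#' @return An object of class `pa_il` with `frequencies`, `loss_db`,
#'   `valid_band` (Hz range) and `valid` (logical per bin).
#' @export
insertion_loss <- function(test, reference, window = "rect", nfft = NULL,
                           floor_margin_db = 20) {
  stopifnot(inherits(test, "pa_waveform"), inherits(reference, "pa_waveform"))
  if (abs(test$dt - reference$dt) > 1e-15 * reference$dt)
    stop("waveforms must share the sampling interval")
  if (all(reference$samples == 0)) stop("reference waveform is all zero")
  n <- max(length(test$samples), length(reference$samples))
  if (is.null(nfft)) nfft <- n
  pad <- function(w) waveform(c(w$samples, numeric(n - length(w$samples))), w$dt, w$t0)
  st <- power_spectrum(pad(test), window, nfft)
  sr <- power_spectrum(pad(reference), window, nfft)
  f <- sr$frequencies
  floor_est <- stats::median(sr$power[f >= 0.8 * max(f)])
  margin <- 10^(floor_margin_db / 10)
  valid <- sr$power >= pmax(floor_est * margin, max(sr$power) * 1e-12)
  # contiguous region containing the reference peak
  ipk <- which.max(sr$power)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  seg <- which(runs$values & starts <= ipk & ends >= ipk)
  if (length(seg) == 1L) {
    valid <- rep(FALSE, length(f))
    valid[starts[seg]:ends[seg]] <- TRUE
  }
  loss <- 10 * log10(pmax(st$power, .Machine$double.xmin) /
                     pmax(sr$power, .Machine$double.xmin))
  structure(list(frequencies = f, loss_db = loss, valid = valid,
                 valid_band = range(f[valid])),
            class = "pa_il")
}

#' @export
print.pa_il <- function(x, ...) {
  cat(sprintf("<pa_il> valid band %.3g .. %.3g MHz, IL(1 MHz) = %.2f dB\n",
              x$valid_band[1] / 1e6, x$valid_band[2] / 1e6,
              interp_at(x$frequencies, x$loss_db, 1e6)))
  invisible(x)
}

#' Evaluate an insertion-loss spectrum at given frequencies
#'
#' @param il A `pa_il`.
#' @param f Frequencies in Hz.
#' @return Loss in dB (linear interpolation between bins).
#' @export
il_at <- function(il, f) interp_at(il$frequencies, il$loss_db, f)

#' Least-squares slope of an insertion-loss spectrum
#'
#' Ordinary least-squares slope of loss (dB) against frequency (MHz) over the
#' intersection of `fit_band` with the valid band.
#'
#' @param il A `pa_il`.
#' @param fit_band Length-2 frequency range in Hz.
#' @return Slope in dB/MHz.
#' @export
loss_slope <- function(il, fit_band) {
  sel <- il$valid & il$frequencies >= fit_band[1] & il$frequencies <= fit_band[2]
  if (sum(sel) < 5L) stop("fewer than 5 spectral bins in the fit band")
  fmhz <- il$frequencies[sel] / 1e6
  unname(stats::coef(stats::lm(il$loss_db[sel] ~ fmhz))[2])
}

#' Band-pass filter and noise-normalise a waveform
#'
#' Zero-phase second-order Butterworth band-pass (applied forward and
#' backward), then division by the post-filter standard deviation of a noise
#' segment preceding the first arrival. The output is in units of SNR.
#'
#' @param w A [waveform()].
#' @param noise_range Length-2 sample index range of the noise segment.
#' @param passband Cut-on and cut-off frequencies, Hz (default 10 kHz-3 MHz).
#' @return A filtered, normalised [waveform()].
#' @export
filter_and_normalize <- function(w, noise_range, passband = c(10e3, 3e6)) {
  fs <- 1 / w$dt
  wn <- pmin(pmax(passband / (fs / 2), 1e-9), 0.999)
  bf <- signal::butter(2, wn, type = "pass")
  x <- signal::filtfilt(bf, w$samples)
  sel <- seq.int(noise_range[1], noise_range[2])
  sigma <- stats::sd(x[sel])
  if (sigma == 0) stop("noise segment has zero standard deviation")
  waveform(x / sigma, w$dt, w$t0)
}

#' Mean and spread of the spectra of the strongest scan waveforms
#'
#' Selects the top fraction of waveforms in a planar scan by peak absolute
#' amplitude and returns the per-frequency mean and standard deviation of
#' their one-sided power spectra -- the spectral summary used for whole
#' image data sets.
#'
#' @param scan A `pa_scan` (see [scan_set()]) or a `pa_simresult` with a
#'   plane recording.
#' @param fraction Fraction of waveforms to keep, in (0, 1]. Default 0.05.
#' @param window Spectral window, see [power_spectrum()].
#' @return List with `frequencies`, `mean_power`, `sd_power`, `selected`
#'   (indices of the selected waveforms in flattened raster order).
#' @export
top_percentile_spectra <- function(scan, fraction = 0.05, window = "rect") {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  m <- scan_matrix(scan)
  n <- nrow(m)
  if (n < 20L) stop("need at least 20 waveforms")
  peaks <- apply(abs(m), 1, max)
  k <- max(1L, floor(fraction * n))
  sel <- order(peaks, decreasing = TRUE)[seq_len(k)]
  dt <- scan_dt(scan)
  sp <- lapply(sel, function(i) power_spectrum(waveform(m[i, ], dt), window)$power)
  P <- do.call(rbind, sp)
  f <- power_spectrum(waveform(m[sel[1], ], dt), window)$frequencies
  list(frequencies = f, mean_power = colMeans(P),
       sd_power = apply(P, 2, stats::sd), selected = sel)
}

# Waveform matrix (one row per raster position) from scan-like objects.
scan_matrix <- function(scan) {
  if (inherits(scan, "pa_simresult")) {
    if (is.null(scan$scan)) stop("simulation result carries no plane recording")
    a <- scan$scan
  } else if (inherits(scan, "pa_scan")) a <- scan$pressure
  else a <- scan
  d <- dim(a)
  if (length(d) == 3L) a <- array(a, c(d[1] * d[2], d[3])) else a <- as.matrix(a)
  a
}

scan_dt <- function(scan) {
  if (inherits(scan, "pa_simresult")) scan$dt
  else if (inherits(scan, "pa_scan")) scan$dt
  else stop("cannot infer dt; supply a pa_scan")
}
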