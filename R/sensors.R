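#' Fabry-Perot etalon specification
#'
#' Optical description of a two-mirror cavity: spacer thickness, refractive
#' index and mirror (intensity) reflectivities, with the interrogation
#' wavelength band.
#'
#' @param spacer_thickness_L Spacer thickness in metres.
#' @param refractive_index_n Spacer refractive index (>= 1).
#' @param R1,R2 Mirror intensity reflectivities, in (0, 1).
#' @param band Length-2 interrogation wavelength band in metres.
#' @return An object of class `etalon_spec`.
#' @export
etalon_spec <- function(spacer_thickness_L, refractive_index_n = 1.52,
                        R1 = 0.949, R2 = 0.97,
                        band = c(1530e-9, 1625e-9)) {
  stopifnot(spacer_thickness_L > 0, refractive_index_n >= 1,
            R1 >= 0, R1 < 1, R2 >= 0, R2 < 1)
  structure(list(L = spacer_thickness_L, n = refractive_index_n,
                 R1 = R1, R2 = R2, band = band),
            class = "etalon_spec")
}

#' Interferometer transfer function (ITF)
#'
#' Normalised reflected intensity of a two-mirror cavity versus interrogation
#' wavelength (Airy reflectance). The cavity round-trip phase is
#' `phi = 4 pi n L / lambda`; resonances appear as dips in reflection.
#'
#' @param etalon An [etalon_spec()].
#' @param wavelengths Wavelength grid in metres; must resolve the fringes
#'   (at least 20 samples per free spectral range).
#' @return List of class `pa_itf` with `wavelengths` and `intensity`.
#' @export
itf <- function(etalon, wavelengths) {
  wavelengths <- sort(wavelengths)
  lam_c <- stats::median(wavelengths)
  fsr <- lam_c^2 / (2 * etalon$n * etalon$L)
  if (stats::median(diff(wavelengths)) > fsr / 20)
    stop(sprintf("unresolved fringe: need sample spacing <= FSR/20 = %.3g m; use a finer grid",
                 fsr / 20))
  r1 <- sqrt(etalon$R1); r2 <- sqrt(etalon$R2)
  phi <- 4 * pi * etalon$n * etalon$L / wavelengths
  e <- exp(1i * phi)
  r <- r1 - (1 - r1^2) * r2 * e / (1 - r1 * r2 * e)
  structure(list(wavelengths = wavelengths, intensity = Mod(r)^2,
                 etalon = etalon),
            class = "pa_itf")
}

#' Metrics of a measured or modelled ITF
#'
#' Characterises the fringes of an interferometer transfer function:
#' full-width half-maximum of the deepest fringe (by linear interpolation at
#' half depth), fringe visibility `(Imax - Imin) / (Imax + Imin)`, free
#' spectral range (mean fringe spacing), and quality factor
#' `Q = lambda_fringe / FWHM`.
#'
#' @param x A `pa_itf`, or a wavelength vector when `intensity` is given.
#' @param intensity Reflected intensity matching `x`.
#' @return List of class `itf_metrics`: `fwhm`, `fringe_visibility`,
#'   `free_spectral_range`, `q_factor` (and the fringe wavelengths).
#' @export
itf_metrics <- function(x, intensity = NULL) {
  if (inherits(x, "pa_itf")) { wl <- x$wavelengths; I <- x$intensity }
  else { wl <- x; I <- intensity }
  n <- length(I)
  rng <- diff(range(I))
  i_min <- which(I[2:(n - 1)] < I[1:(n - 2)] & I[2:(n - 1)] <= I[3:n]) + 1L
  if (rng > 0) i_min <- i_min[(max(I) - I[i_min]) > 0.5 * rng]
  if (length(i_min) < 2L) stop("fewer than two minima in the supplied band")
  Imax <- max(I)
  deepest <- i_min[which.min(I[i_min])]
  half <- (Imax + I[deepest]) / 2
  left <- deepest; while (left > 1L && I[left] < half) left <- left - 1L
  right <- deepest; while (right < n && I[right] < half) right <- right + 1L
  wl_l <- interp_cross(wl[left], wl[left + 1L], I[left], I[left + 1L], half)
  wl_r <- interp_cross(wl[right - 1L], wl[right], I[right - 1L], I[right], half)
  fwhm <- wl_r - wl_l
  lam0 <- wl[deepest]
  structure(list(fwhm = fwhm,
                 fringe_visibility = (Imax - min(I)) / (Imax + min(I)),
                 free_spectral_range = mean(diff(wl[i_min])),
                 q_factor = lam0 / fwhm,
                 fringe_wavelengths = wl[i_min]),
            class = "itf_metrics")
}

interp_cross <- function(x0, x1, y0, y1, y) {
  if (y1 == y0) return(x0)
  x0 + (y - y0) * (x1 - x0) / (y1 - y0)
}

#' @export
print.itf_metrics <- function(x, ...) {
  cat(sprintf("<itf_metrics> FWHM %.3g pm, visibility %.3f, FSR %.3g nm, Q %.3g\n",
              x$fwhm * 1e12, x$fringe_visibility,
              x$free_spectral_range * 1e9, x$q_factor))
  invisible(x)
}

#' Spacer thickness from the free spectral range
#'
#' Inverts `FSR = lambda^2 / (2 n L)`.
#'
#' @param fsr Free spectral range in metres (wavelength units).
#' @param n Spacer refractive index.
#' @param lambda_center Band-centre wavelength in metres.
#' @return Physical thickness L in metres.
#' @export
thickness_from_fsr <- function(fsr, n, lambda_center) {
  stopifnot(fsr > 0)
  lambda_center^2 / (2 * n * fsr)
}

# ---- layered acoustic models ------------------------------------------------

#' Acoustic film stack
#'
#' One finite-thickness spacer layer between two half-spaces: the `front`
#' medium carrying the incident wave (water for an immersed sensor) and the
#' `backing` substrate. Layer absorption may be given as an alpha0 prefactor
#' (dB/cm/MHz^2).
#'
#' @param backing,spacer,front `pa_material` objects.
#' @param thickness Spacer thickness in metres.
#' @return An object of class `film_stack`.
#' @export
film_stack <- function(backing, spacer, front, thickness) {
  stopifnot(thickness > 0)
  structure(list(backing = backing, spacer = spacer, front = front,
                 thickness = thickness),
            class = "film_stack")
}

#' Plane-wave transmission through a single layer between half-spaces
#'
#' Transfer-matrix pressure transmission coefficient for normal incidence
#' from the front half-space, through the spacer, into the backing
#' half-space. Layer absorption (alpha0 f^2 power law) enters through a
#' complex layer wavenumber. At `f = m c_layer / (2 thickness)` the layer is
#' acoustically transparent up to the front/backing impedance step.
#'
#' @param stack A [film_stack()].
#' @param frequency Frequencies in Hz (vector).
#' @return Complex pressure transmission coefficients.
#' @export
layer_transmission <- function(stack, frequency) {
  Z1 <- acoustic_impedance(stack$front)
  Z2 <- acoustic_impedance(stack$spacer)
  Z3 <- acoustic_impedance(stack$backing)
  L <- stack$thickness
  w <- 2 * pi * frequency
  alpha <- alpha0_db_to_np(stack$spacer$alpha0) * w^2  # Np/m
  k2 <- w / stack$spacer$sound_speed - 1i * alpha      # matrix phase convention
  cs <- cos(k2 * L); sn <- sin(k2 * L)
  2 / (cs * (1 + Z1 / Z3) + 1i * sn * (Z2 / Z3 + Z1 / Z2))
}

#' Plane-wave reflection from a single layer between half-spaces
#'
#' @rdname layer_transmission
#' @export
layer_reflection <- function(stack, frequency) {
  Z2 <- acoustic_impedance(stack$spacer)
  Z3 <- acoustic_impedance(stack$backing)
  L <- stack$thickness
  w <- 2 * pi * frequency
  alpha <- alpha0_db_to_np(stack$spacer$alpha0) * w^2
  k2 <- w / stack$spacer$sound_speed - 1i * alpha
  cs <- cos(k2 * L); sn <- sin(k2 * L)
  Tt <- layer_transmission(stack, frequency)
  Tt * (cs + 1i * Z2 * sn / Z3) - 1
}

#' Acoustic frequency response of a Fabry-Perot film sensor
#'
#' Normalised acoustic sensitivity `M(f)` of an interferometric film sensor:
#' the magnitude of the mean harmonic stress across the spacer for a normally
#' incident unit plane wave from the front medium, computed from the
#' transfer-matrix field inside the spacer and normalised so `M(0) = 1`. The
#' optical read-out integrates strain across the cavity, which is
#' proportional to this mean stress. Also reports the -3 dB bandwidth and the
#' first response minimum (cut-off).
#'
#' @param stack A [film_stack()].
#' @param frequencies Frequencies in Hz (ascending vector).
#' @return List of class `film_response`: `frequencies`, `sensitivity`
#'   (normalised), `f_3db` (Hz), `f_first_min` (Hz or `NA`).
#' @export
film_frequency_response <- function(stack, frequencies) {
  stopifnot(stack$thickness > 0)
  f <- sort(frequencies)
  m <- Mod(film_mean_stress(stack, pmax(f, 1)))
  m0 <- Mod(film_mean_stress(stack, 1))  # dc limit at 1 Hz
  M <- m / m0
  below <- which(M < 1 / sqrt(2))
  f_3db <- if (length(below)) {
    i <- below[1]
    if (i > 1L) interp_cross(f[i - 1L], f[i], M[i - 1L], M[i], 1 / sqrt(2)) else f[1]
  } else NA_real_
  n <- length(M)
  mins <- which(M[2:(n - 1)] < M[1:(n - 2)] & M[2:(n - 1)] <= M[3:n]) + 1L
  structure(list(frequencies = f, sensitivity = M, f_3db = f_3db,
                 f_first_min = if (length(mins)) f[mins[1]] else NA_real_),
            class = "film_response")
}

# Complex mean pressure over the spacer for unit incidence from the front.
film_mean_stress <- function(stack, f) {
  Z2 <- acoustic_impedance(stack$spacer)
  Z3 <- acoustic_impedance(stack$backing)
  L <- stack$thickness
  k2 <- 2 * pi * f / stack$spacer$sound_speed
  Tt <- layer_transmission(stack, f)
  e <- exp(1i * k2 * L)
  A <- Tt * (1 + Z2 / Z3) / (2 * e)
  B <- Tt * (1 - Z2 / Z3) * e / 2
  (A * (e - 1) - B * (1 / e - 1)) / (1i * k2 * L)
}

#' @export
print.film_response <- function(x, ...) {
  cat(sprintf("<film_response> -3 dB at %.3g MHz, first minimum at %.3g MHz\n",
              x$f_3db / 1e6, x$f_first_min / 1e6))
  invisible(x)
}

# ---- piezoelectric sensors --------------------------------------------------

#' Piezoelectric transducer specification
#'
#' @param center_frequency Centre frequency in Hz.
#' @param fractional_bandwidth_minus6db Fractional -6 dB bandwidth (0..2).
#' @param element_diameter Active element diameter in metres.
#' @return An object of class `piezo_spec`.
#' @export
piezo_spec <- function(center_frequency, fractional_bandwidth_minus6db = 0.65,
                       element_diameter = 25.4e-3) {
  stopifnot(center_frequency > 0,
            fractional_bandwidth_minus6db > 0, fractional_bandwidth_minus6db < 2,
            element_diameter > 0)
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth_minus6db,
                 element_diameter = element_diameter),
            class = "piezo_spec")
}

#' Band-pass frequency response of a resonant piezoelectric transducer
#'
#' Gaussian band-pass centred at the transducer's centre frequency whose
#' -6 dB (half-amplitude) full width equals the fractional bandwidth times
#' the centre frequency. Resonant ceramics are effectively blind near dc:
#' for a 1 MHz, 65 % transducer `M(0) < 0.01`.
#'
#' @param spec A [piezo_spec()].
#' @param frequencies Frequencies in Hz.
#' @return Normalised amplitude sensitivity (1 at the centre frequency).
#' @export
piezo_response <- function(spec, frequencies) {
  fc <- spec$center_frequency
  sigma <- (spec$fractional_bandwidth / 2) * fc / sqrt(2 * log(2))
  exp(-(frequencies - fc)^2 / (2 * sigma^2))
}

#' Low-pass frequency response of a broadband PVDF transducer
#'
#' Flat from dc with a fourth-order Butterworth roll-off; the -6 dB
#' (half-amplitude) point defaults to 20 MHz.
#'
#' @param frequencies Frequencies in Hz.
#' @param f_6db -6 dB frequency in Hz.
#' @param order Butterworth order.
#' @return Normalised amplitude sensitivity.
#' @export
pvdf_response <- function(frequencies, f_6db = 20e6, order = 4) {
  f0 <- f_6db / 3^(1 / (2 * order))
  1 / sqrt(1 + (frequencies / f0)^(2 * order))
}

#' Apply a sensor frequency response to a waveform
#'
#' Filters a pressure waveform with a sensor's amplitude response in the
#' frequency domain (zero phase).
#'
#' @param w A [waveform()].
#' @param response Function mapping frequency (Hz) to amplitude sensitivity,
#'   e.g. `function(f) piezo_response(spec, f)`.
#' @return Filtered [waveform()].
#' @export
apply_sensor_response <- function(w, response) {
  n <- length(w$samples)
  f <- abs(fft_wavenumbers(n, w$dt)) / (2 * pi)
  X <- stats::fft(w$samples) * response(f)
  waveform(Re(stats::fft(X, inverse = TRUE)) / n, w$dt, w$t0)
}

# ---- finite aperture --------------------------------------------------------

#' Spatially average a planar field over a finite circular element
#'
#' Unweighted mean of all raster waveforms whose position lies inside the
#' element disk, emulating the output of a large single-element transducer
#' pressed against the scan plane. Heterogeneous (aberrated) fields partially
#' cancel under this average, unlike at a point detector.
#'
#' @param scan A [scan_set()] or a `pa_simresult` holding a plane recording
#'   (then `dx` must be supplied).
#' @param element_diameter Element diameter in metres.
#' @param center Element centre in metres (defaults to the aperture centre).
#' @param dx Raster pitch in metres when `scan` is a simulation result.
#' @return A [waveform()] of the averaged trace.
#' @export
aperture_average <- function(scan, element_diameter, center = NULL, dx = NULL) {
  if (inherits(scan, "pa_scan")) { a <- scan$pressure; dx <- scan$dx; dt <- scan$dt }
  else if (inherits(scan, "pa_simresult")) {
    if (is.null(scan$scan)) stop("simulation result carries no plane recording")
    a <- scan$scan; dt <- scan$dt
    if (is.null(dx)) dx <- scan$spacing
  } else stop("scan must be a pa_scan or pa_simresult")
  d <- dim(a)
  r <- element_diameter / 2
  if (length(d) == 2L) {
    y <- (seq_len(d[1]) - (d[1] + 1) / 2) * dx
    if (!is.null(center)) y <- y - center[1]
    if (r > max(abs(y)) + dx / 2) stop("element footprint exceeds the scan aperture")
    sel <- abs(y) <= r
    tr <- colMeans(a[sel, , drop = FALSE])
  } else {
    y <- (seq_len(d[1]) - (d[1] + 1) / 2) * dx
    z <- (seq_len(d[2]) - (d[2] + 1) / 2) * dx
    if (!is.null(center)) { y <- y - center[1]; z <- z - center[2] }
    if (r > min(max(abs(y)), max(abs(z))) + dx / 2)
      stop("element footprint exceeds the scan aperture")
    mask <- outer(y, z, function(a_, b_) sqrt(a_^2 + b_^2)) <= r
    m <- array(a, c(d[1] * d[2], d[3]))
    tr <- colMeans(m[as.vector(mask), , drop = FALSE])
  }
  waveform(tr, dt)
}

# ---- noise-equivalent pressure ----------------------------------------------

#' Estimate noise-equivalent pressure from a detector noise trace
#'
#' NEP is the standard deviation of the band-limited noise referred to
#' pressure through the sensitivity calibration; the spectral density is
#' `NEP / sqrt(bandwidth)`. The trace is low-pass filtered to the stated
#' measurement bandwidth (the sensor's modelled -3 dB bandwidth) before
#' taking the standard deviation.
#'
#' @param noise_trace A [waveform()] of detector noise (no signal), in
#'   detector units.
#' @param calibration Sensitivity calibration: detector units per Pa.
#' @param bandwidth Measurement bandwidth in Hz.
#' @return List of class `nep_result`: `nep` (Pa), `nep_density`
#'   (Pa / sqrt(Hz)), `measurement_bandwidth` (Hz).
#' @export
estimate_nep <- function(noise_trace, calibration, bandwidth) {
  if (calibration == 0) stop("zero sensitivity calibration")
  n <- length(noise_trace$samples)
  if (n * noise_trace$dt <= 10 / bandwidth)
    stop("noise trace shorter than 10 / bandwidth")
  x <- noise_trace$samples
  nyq <- 1 / (2 * noise_trace$dt)
  if (bandwidth < nyq) {
    bf <- signal::butter(4, bandwidth / nyq, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  nep <- stats::sd(x) / abs(calibration)
  structure(list(nep = nep, nep_density = nep / sqrt(bandwidth),
                 measurement_bandwidth = bandwidth),
            class = "nep_result")
}

#' @export
print.nep_result <- function(x, ...) {
  cat(sprintf("<nep_result> NEP %.3g Pa (%.3g mPa/sqrt(Hz)) over %.3g MHz\n",
              x$nep, x$nep_density * 1e3, x$measurement_bandwidth / 1e6))
  invisible(x)
}

#' Modelled NEP versus resonator thickness (design trend)
#'
#' Design-stage model of how the noise-equivalent pressure of an
#' interferometric film sensor scales with spacer thickness: the acoustic
#' phase sensitivity grows linearly with L while the detection bandwidth
#' (from [film_frequency_response()]) shrinks as 1/L, so
#' `NEP(L) = noise_density / (s0 L) * sqrt(f3dB(L))` decreases
#' monotonically with L. Absolute values depend on the interrogation system
#' through `phase_noise_density` and `phase_sensitivity`; the trend does not.
#'
#' @param L_values Spacer thicknesses in metres.
#' @param spacer,backing,front Materials for the film model.
#' @param phase_noise_density Interrogation phase noise, rad / sqrt(Hz).
#' @param phase_sensitivity Acoustic phase sensitivity per unit pressure and
#'   thickness, rad / (Pa m).
#' @return data.frame with `L`, `bandwidth_hz`, `nep_pa`.
#' @export
nep_design_curve <- function(L_values,
                             spacer = pa_materials()$spacer,
                             backing = pa_materials()$cop,
                             front = pa_materials()$water,
                             phase_noise_density = 1e-3,
                             phase_sensitivity = 20) {
  bw <- vapply(L_values, function(L) {
    st <- film_stack(backing, spacer, front, L)
    fr <- film_frequency_response(st, seq(1e4, 0.8 * spacer$sound_speed / L, length.out = 2000))
    fr$f_3db
  }, numeric(1))
  nep <- phase_noise_density / (phase_sensitivity * L_values) * sqrt(bw)
  data.frame(L = L_values, bandwidth_hz = bw, nep_pa = nep)
}
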