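---
title: "Modelling transcranial photoacoustic sensing: waves, skull phantoms, sensors and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcranial photoacoustic sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pacranial)
```

## The problem

Photoacoustic (PA) imaging of the human brain through the intact skull is
limited by cranial bone: the porous diploe layer between the two cortical
tables scatters and absorbs ultrasound strongly and frequency-dependently,
so that transcranial PA signals are confined to low acoustic frequencies
(roughly below 2 MHz for thick frontal bone) and reconstructed images lose
resolution and contrast. Quantifying these losses, and matching an
ultrasound sensor's frequency response and noise floor to the surviving
band, is a modelling problem with four coupled parts, which this package
implements:

1. **Skull phantoms** (`skull_spec()`, `generate_skull_slab()`): synthetic
   three-layer bone slabs with a statistically controlled porous diploe.
2. **Wave propagation** (`run_forward()`): a k-space pseudospectral
   time-domain solver for longitudinal waves in heterogeneous lossy media.
3. **Sensor models** (`itf()`, `film_frequency_response()`,
   `piezo_response()`, `estimate_nep()`): interferometric film sensors
   (planar Fabry-Perot, plano-concave resonators), piezoelectric
   transducers, finite apertures and noise-equivalent pressure.
4. **Image formation** (`reconstruct_planar()`): FFT reconstruction of
   initial-pressure volumes from planar raster scans, with a sound-speed
   sweep for the heuristic homogeneous-speed choice.

`water_reference_study()`, `skull_insertion_loss_study()`,
`site_band_edge_study()` and `transcranial_imaging_study()` assemble these
into the standard in-silico experiments; `run_experiment()` orchestrates
them from configuration files.

## Acoustic model and solver

The solver integrates the first-order linear acoustics system

$$\partial_t \mathbf{u} = -\tfrac{1}{\rho_0}\nabla p,\qquad
  \partial_t \rho_d = -\rho_0\, \partial_d u_d,\qquad
  p = c_0^2\Big(\textstyle\sum_d \rho_d - \tau\,\rho_0 \nabla\cdot\mathbf{u}\Big),$$

on staggered spatial grids with spectral (FFT) derivatives, a k-space
correction factor $\kappa = \mathrm{sinc}(c_{\mathrm{ref}} |k| \Delta t/2)$
that makes leapfrog time stepping exact for homogeneous media at the
reference speed, and a split-field perfectly matched layer (PML, default 16
grid points, quartic absorption profile) on all outer boundaries. Shear
waves are not modelled; bone is treated as a fluid with elevated impedance,
which is appropriate near normal incidence.

Acoustic absorption follows a frequency-squared power law,
$\alpha = \alpha_0 f^2$ with $\alpha_0$ in dB/cm/MHz².  For exponent 2 the
power-law loss operator reduces to a term proportional to the local
divergence of particle velocity (the fractional Laplacian becomes the
ordinary Laplacian and the dispersion correction vanishes identically), so
absorption costs no extra FFTs. The unit conversion is
$\alpha[\mathrm{Np/m}] = \alpha_0 \times 100 / 8.686 \times (f/\mathrm{MHz})^2$
(`alpha0_db_to_np()`).

Two numerical properties matter in practice and are pinned by tests:

* **Loss-term accuracy is CFL-limited.** The loss term is evaluated at
  collocation times, so its error grows like $\alpha d\,(\omega\Delta
  t)^2$. At the default CFL of 0.3 the $f^2$ law is reproduced closely at
  low frequency but departs near the grid's maximum frequency; quantitative
  absorption studies run at CFL $\approx$ 0.03. Separately, the model
  equation's own dispersion relation $k = (\omega/c)(1 - i\omega\tau)^{-1/2}$
  departs from the pure $f^2$ law by more than 2 % above $\sim$0.7 of the
  grid limit at bone-like $\alpha d$, so the pure law is only asserted below
  0.6 of the grid limit.
* **The grid limit is $f_{\max} = \min(c)/(2\Delta x)$** (two points per
  wavelength): 5.92 MHz for water on a 125 µm grid
  (`max_supported_frequency()`).

### Axisymmetric grids

The disk-source/on-axis-sensor transmission geometry is axisymmetric. The
package propagates such media on a mirrored, cell-centred radial domain:
the half-plane $(x, r\ge 0)$ is reflected about the axis, radial positions
sit at $r = \pm(j+\tfrac12)\Delta x$ so the coordinate singularity never
falls on a grid point, radial derivatives are spectral on the mirrored
domain (pressure even, radial velocity odd), and the cylindrical divergence
term $u_r/r$ is evaluated pointwise. The on-axis value is obtained by
quadratic extrapolation from the two innermost radial cells. This
construction was validated against a brute-force quadrature of the analytic
axisymmetric k-space solution for the smoothed disk source (band edges
agree within a few percent at reduced scale; see `test-solver.R`).

Initial pressure sources are Blackman-smoothed in the spatial frequency
domain (`smooth_source()`), the standard anti-aliasing treatment for
single-voxel broadband sources; smoothing is what limits the upper band
edge of the simulated reference spectrum.

## Skull phantom generator

Cranial bone is modelled as two solid cortical tables enclosing a porous
diploe. The diploe microstructure is a Gaussian random field smoothed with
an isotropic Gaussian kernel of correlation length $\ell_c$ (default
0.5 mm) and thresholded at the quantile equal to the requested porosity, so
the realized water fraction matches the request to within counting noise
(tested at ±0.03). Site presets are midpoints of reported thickness ranges:
temporal 1.0 mm (0.4 mm tables, porosity 0.2), occipital 5.0 mm (1.0 mm
tables, 0.4), frontal 7.5 mm (1.5 mm tables, 0.5). The porosities are
calibration parameters of the synthetic model — no measured microstructure
statistics stand behind them — and are exposed in `skull_spec()`.

What the generator reproduces: layered cortical/trabecular structure,
blob-like pores of controllable size and volume fraction, seeded
reproducibility (identical spec + seed gives bit-identical maps).
What it does not: anisotropic trabecular alignment, multi-scale pore-size
distributions, cortical-thickness gradients, curvature of real calvaria.
Tests passing on these phantoms therefore validate the *pipeline physics*,
not fidelity to any individual skull.

**Dimensionality matters.** The porous diploe scatters in 3D; reduced
representations bias the measured insertion loss. An axisymmetric random
field makes ring-shaped pores whose near-axis structure is effectively
stratified, producing coherent transmission combs instead of broadband
scattering loss; a planar-2D field (cylindrical pores) scatters more
realistically but still under-represents 3D multiple scattering and shows
large seed-to-seed spread. The insertion-loss study therefore runs the bone
arm on a reduced 3D grid (250 µm spacing, 12 mm lateral aperture, the full
3 cm source-sensor path), where the simulated frontal-bone loss is close to
ex-vivo-calibrated reference values (about −20 dB at 1 MHz, steepening at
several dB/MHz). The water-only reference band edges are computed
axisymmetrically at 125 µm, the exact reduction for that homogeneous
geometry. A shorter source-sensor distance was rejected because the sensor
then sits in the slab's near field and the measured loss changes by several
dB.

Two estimator choices stabilise the insertion-loss summary against the
speckle of the scattered transcranial field. First, the reported loss is
the per-frequency mean of per-position loss spectra over a 5 × 5 grid of
receive points spanning about 3 mm around the axis — the standard
multi-waveform treatment for transmission measurements — and optionally
over several phantom realizations (the site preset describes a
microstructure ensemble, and single realizations scatter by several dB at
any one frequency); the quoted loss "at 1 MHz" is likewise the mean of the
averaged loss spectrum over a 0.9–1.1 MHz window rather than one
interpolated bin. Second, on the scaled 250 µm grid the least-squares
loss slope is fitted from 0.5 MHz up to 0.6 of the grid frequency limit
(1.78 MHz) rather than to 2.5 MHz: beyond that band the reference spectrum
is more than 20 dB below its peak and the transcranial arm reaches its own
scattered-field floor, so the ratio flattens and then reverses — an
artefact of the scaled measurement, not of the bone. At full 125 µm scale
the same rule reproduces the conventional 0.5–2.5 MHz fit window.

## Spectral analysis

Spectra are one-sided periodograms (rectangular window by default — the
records are compact pulses; Hann is available), Parseval-consistent with
the time-domain mean square. Insertion loss is
$10\log_{10}(P_\mathrm{test}/P_\mathrm{ref})$, reported negative for
attenuation, with a validity band where the reference power stays 20 dB
above its own noise floor (estimated as the median reference power in the
top 20 % of frequencies); this truncation prevents the ratio from blowing
up outside the excited band. Band edges interpolate dB values linearly
between bins; the −6 dB edges are the outermost crossings. The loss slope
is an ordinary least-squares fit of loss against frequency in MHz over
0.5–2.5 MHz. Waveform conditioning for sensor comparisons uses a zero-phase
second-order Butterworth band-pass (10 kHz–3 MHz) followed by
normalisation to the standard deviation of a pre-arrival noise segment, so
compared traces are in SNR units. Whole-scan spectral summaries average the
spectra of the top 5 % of waveforms by peak amplitude, mean and standard
deviation per frequency; averaging is per-waveform-then-summarise (the
alternative, ratio-then-average, is available by computing insertion losses
individually).

## Sensor models

**Optics.** The interferometer transfer function of a two-mirror cavity is
the Airy reflectance with round-trip phase $4\pi n L/\lambda$; its metrics
(FWHM by interpolation at half depth, visibility, free spectral range,
$Q = \lambda/\mathrm{FWHM}$) are validated against a brute-force phasor sum
of 200 partial reflections, and $L = \lambda^2/(2 n\,\mathrm{FSR})$ inverts
the FSR to physical thickness.

**Acoustics.** The film sensor's acoustic response is the mean harmonic
stress across the spacer for a unit plane wave incident from the front
medium, computed from the transfer-matrix field (incident water half-space,
finite spacer, substrate half-space), normalised to unity at dc. For
matched impedances it reduces exactly to $|\mathrm{sinc}(\pi f L/c)|$ with
first null at $c/L$, and the −3 dB bandwidth scales as $1/L$ (both
tested). With the package's default materials (parylene C spacer
$c = 2200$ m/s, $\rho = 1290$ kg/m³; COP substrate $c = 2440$ m/s,
$\rho = 1010$ kg/m³; cured spacer polymer $c = 2500$ m/s,
$\rho = 1200$ kg/m³) the model predicts −3 dB bandwidths of about 57 MHz
for a 20 µm parylene film and 2.7 MHz for a 493 µm resonator spacer.
Published characterisations of comparable devices report narrower bands
(around 36 MHz and 2 MHz respectively) — values this three-medium model
reproduces only with a much stiffer effective backing (a rigid backing
gives 35 MHz and 1.6 MHz). The discrepancy is a genuine sensitivity of the
planar model: real sensors carry hard dielectric mirror stacks and
curvature that the three-medium idealisation omits. The package reports
what the stated model computes rather than rescaling materials to match
published figures; all material parameters are overridable.

Piezoelectric transducers are modelled as Gaussian band-passes whose −6 dB
full width equals the fractional bandwidth times the centre frequency
(65 % default) — such resonant elements are effectively blind near dc
($M(0) < 0.01$ at 1 MHz centre) — and the broadband PVDF element as a
fourth-order Butterworth low-pass with −6 dB at 20 MHz (only the −6 dB
point is physically anchored; the roll-off shape is a modelling choice).
Finite apertures average the raster waveforms inside the element disk
without weighting, which is where heterogeneous transcranial wavefronts
cancel. NEP is the standard deviation of band-limited noise referred to
pressure, with density $\mathrm{NEP}/\sqrt{B}$; the band-limit convention
is the sensor's modelled −3 dB bandwidth. The design-trend model
`nep_design_curve()` combines phase sensitivity $\propto L$ with bandwidth
$\propto 1/L$, giving NEP strictly decreasing with thickness; its absolute
scale depends on interrogation-system constants and is not calibrated.

## Reconstruction

Planar-sensor data $p(x, y, t)$ are mapped to the initial pressure by the
Fourier-shell relation: FFT over lateral position and (evenly extended)
time, remapping $\omega \to k_z$ on $\omega = c\sqrt{k_x^2+k_y^2+k_z^2}$
with complex linear interpolation and the Jacobian weight $c k_z/\omega$
(which tends to 1 at the dc bin — a limit that must be special-cased, or
laterally uniform fields lose their mean), Hermitian completion, inverse
FFT, and a factor 2 for the half-space support. Plane-layer fields
round-trip to machine precision; structured fields lose amplitude to
interpolation and finite recording windows (the forward projector
`project_planar()` plus reconstruction round trip is accurate to
$\sim$10–20 % in amplitude, position-exact). The reconstruction assumes a
homogeneous sound speed by design — the point of the transcranial study is
precisely that this simple heuristic degrades gracefully.

`sweep_sound_speed()` scores candidate speeds with a focus metric. The
default is peak coherence: $\max |p_0|$ evaluated with 8-fold Fourier
upsampling along depth on the strongest columns, so the score is
insensitive to where the focus lands relative to the voxel grid; coherent
summation is maximised when the assumed speed matches the medium, and on
analytic water scans the optimum lands within 1 % of 1480 m/s provided the
recording window captures the steep-angle arrivals (truncated windows bias
the optimum low). A histogram-entropy score was evaluated and retained as
an option (`method = "entropy"`), but it is dominated by axial-rescaling
and limited-view arc structure for point-like targets and does not localise
the true speed; it is not the default for that reason.

## Problem sizes

The bundled studies are sized for a single CPU: axisymmetric water
reference 288 × 128 cells at 125 µm (about a thousand time steps);
reduced-3D insertion loss 168 × 48 × 48 at 250 µm (a thousand steps per
arm); planar-2D imaging studies 150–200 × 192 at 125 µm. Full-scale 3D
grids (364³ at 125 µm) are supported by the same code paths but are not run
by the test suite.

## Known limitations

* Longitudinal waves only; shear conversion in bone is absorbed into the
  effective attenuation.
* The synthetic diploe is statistically, not anatomically, realistic; its
  porosity presets are calibration knobs.
* The film-sensor acoustic model is planar and three-medium; mirror stacks,
  dome curvature and reverberation within it are not modelled.
* Reconstruction assumes a homogeneous sound speed; no aberration
  correction from the known phantom map is attempted.
* The loss term's accuracy degrades near the grid frequency limit unless
  the time step is reduced well below the stability limit.
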