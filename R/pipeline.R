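#' Experiment configuration
#'
#' Validates and normalises the configuration of an in-silico experiment.
#' Configurations may be built in code or loaded from YAML with
#' [load_experiment_config()].
#'
#' @param experiment One of `"insertion_loss_sim"`, `"tomography_planar"`,
#'   `"tomography_tube"`, `"sensor_comparison"`, `"sensor_design"`.
#' @param phantom `NULL` (water path) or a [skull_spec()] / preset site name.
#' @param seed Integer seed; fanned out to per-stage seeds.
#' @param output_dir Output directory (created on demand); `NULL` keeps all
#'   results in memory.
#' @param grid_spacing Voxel spacing in metres.
#' @param source_sensor_distance Source-to-sensor distance in metres.
#' @param source_diameter Source diameter in metres.
#' @param n_steps,cfl,pml_size Solver settings (see [simulation_config()]).
#' @param scaled Logical: use reduced desk-scale geometry defaults.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment,
                              phantom = NULL,
                              seed = 1L,
                              output_dir = NULL,
                              grid_spacing = 125e-6,
                              source_sensor_distance = 30e-3,
                              source_diameter = 5e-3,
                              n_steps = NULL, cfl = 0.3, pml_size = 16,
                              scaled = TRUE) {
  experiments <- c("insertion_loss_sim", "tomography_planar", "tomography_tube",
                   "sensor_comparison", "sensor_design")
  if (!experiment %in% experiments)
    stop("unknown experiment; offending keys: experiment = '", experiment,
         "'. Valid: ", paste(experiments, collapse = ", "))
  if (is.character(phantom)) phantom <- skull_spec(phantom, seed = seed)
  if (!is.null(phantom) && !inherits(phantom, "skull_spec"))
    stop("offending keys: phantom (need NULL, a site name, or a skull_spec)")
  structure(list(experiment = experiment, phantom = phantom,
                 seed = as.integer(seed), output_dir = output_dir,
                 grid_spacing = grid_spacing,
                 source_sensor_distance = source_sensor_distance,
                 source_diameter = source_diameter,
                 n_steps = n_steps, cfl = cfl, pml_size = pml_size,
                 scaled = isTRUE(scaled)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file with the fields of [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom) && is.list(y$phantom))
    y$phantom <- do.call(skull_spec, y$phantom)
  do.call(experiment_config, y)
}

# Deterministic per-stage seed fan-out from one experiment seed.
stage_seed <- function(seed, stage) {
  stages <- c("phantom", "noise", "scan", "misc")
  (as.integer(seed) * 1009L + 97L * match(stage, stages)) %% 2147483647L
}

#' Build the simulation scene of the transmission experiments
#'
#' Axisymmetric (x, r) medium with the source disk near one end, an optional
#' skull slab midway, and an on-axis point sensor at the stated distance.
#' Internal geometry shared by [run_experiment()] and the acceptance checks.
#'
#' @param phantom `NULL` or a [skull_spec()].
#' @param grid_spacing Voxel spacing, m.
#' @param distance Source-to-sensor distance, m.
#' @param source_diameter Source diameter, m.
#' @param radial_extent Radial half-aperture of the domain, m.
#' @param pml_size PML thickness, voxels.
#' @return List with `medium`, `source`, `sensors`, and index bookkeeping.
#' @export
transmission_scene <- function(phantom = NULL, grid_spacing = 125e-6,
                               distance = 30e-3, source_diameter = 5e-3,
                               radial_extent = 6e-3, pml_size = 16) {
  n_dist <- round(distance / grid_spacing)
  ix_src <- pml_size + 5L
  ix_sen <- ix_src + n_dist
  nx <- ix_sen + 8L + pml_size
  nr <- round(radial_extent / grid_spacing) + pml_size
  water <- pa_materials()$water
  if (is.null(phantom)) {
    med <- homogeneous_medium(c(nx, nr), grid_spacing, water, axisymmetric = TRUE)
  } else {
    med <- generate_skull_slab(phantom, grid_spacing,
                               lateral_extent = nr * grid_spacing * 1e3,
                               axial_extent = nx * grid_spacing * 1e3,
                               slab_center = (ix_src + n_dist / 2) * grid_spacing * 1e3,
                               ndims = 2, axisymmetric = TRUE)
  }
  list(medium = med,
       source = source_disk(med, ix_src, source_diameter),
       sensors = sensor_axis(ix_sen),
       ix_source = ix_src, ix_sensor = ix_sen, nx = nx, nr = nr)
}

#' Run an in-silico experiment end to end
#'
#' Orchestrates the package's four experiment families from a single
#' configuration: skull insertion loss from disk-source transmission runs;
#' planar-target and tube-target tomography with FFT reconstruction; the
#' sensor comparison on a simulated transcranial field; and the sensor design
#' curves (film responses and modelled NEP trend). Results are returned as a
#' bundle; when `output_dir` is set, CSV/TIFF outputs and a JSON manifest
#' with content checksums are written.
#'
#' @param config An [experiment_config()].
#' @return A result bundle (list), invisibly including the manifest.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  res <- switch(config$experiment,
    insertion_loss_sim = exp_insertion_loss(config),
    tomography_planar  = exp_tomography(config, target = "plane"),
    tomography_tube    = exp_tomography(config, target = "tube"),
    sensor_comparison  = exp_sensor_comparison(config),
    sensor_design      = exp_sensor_design(config))
  res$config <- config
  if (!is.null(config$output_dir)) res$manifest <- write_bundle(res, config)
  invisible(res)
}

exp_insertion_loss <- function(config) {
  ph <- config$phantom
  if (is.null(ph)) {
    # water-only control: test arm identical to the reference arm
    sc <- transmission_scene(NULL, config$grid_spacing,
                             config$source_sensor_distance,
                             config$source_diameter,
                             pml_size = config$pml_size)
    dt <- config$cfl * config$grid_spacing / 1480
    n_steps <- config$n_steps
    if (is.null(n_steps))
      n_steps <- ceiling((config$source_sensor_distance / 1480 * 1.18) / dt)
    cfg <- simulation_config(dt = dt, n_steps = n_steps,
                             pml_size = config$pml_size)
    ref <- result_waveform(run_forward(sc$medium, sc$source, sc$sensors, cfg))
    il <- insertion_loss(ref, ref)
    return(list(reference = ref, transcranial = ref, il = il,
                ref_band = suppressWarnings(band_edges(power_spectrum(ref))),
                il_1mhz = il_at(il, 1e6), slope_db_per_mhz = 0))
  }
  ph$seed <- stage_seed(config$seed, "phantom")
  wr <- water_reference_study(config$grid_spacing,
                              config$source_sensor_distance,
                              config$source_diameter, cfl = config$cfl)
  st <- skull_insertion_loss_study(ph, seed = ph$seed,
                                   distance = config$source_sensor_distance,
                                   cfl = config$cfl)
  list(reference = st$reference, transcranial = st$transcranial, il = st$il,
       ref_band = wr$band, il_1mhz = st$il_1mhz,
       slope_db_per_mhz = st$slope_db_per_mhz)
}

exp_tomography <- function(config, target = c("plane", "tube")) {
  target <- match.arg(target)
  dxg <- config$grid_spacing
  dist <- if (config$scaled) min(config$source_sensor_distance, 12e-3) else
    config$source_sensor_distance
  nlat <- if (config$scaled) 96L else 256L
  pml <- config$pml_size
  nx <- round(dist / dxg) + 14L + 2L * pml
  ph <- config$phantom
  if (!is.null(ph)) ph$seed <- stage_seed(config$seed, "phantom")
  ix_src <- nx - pml - 6L
  med <- if (is.null(ph))
    homogeneous_medium(c(nx, nlat), dxg) else
    generate_skull_slab(ph, dxg, lateral_extent = nlat * dxg * 1e3,
                        axial_extent = nx * dxg * 1e3,
                        slab_center = (pml + 8L + round(dist / dxg) / 2) * dxg * 1e3,
                        ndims = 2)
  p0 <- if (target == "plane")
    source_disk(med, ix_src, diameter = if (config$scaled) 5e-3 else 5e-3)
  else source_tube(med, ix_src, inner_diameter = 2e-3)
  cmax <- max(med$sound_speed)
  dt <- config$cfl * dxg / cmax
  n_steps <- config$n_steps
  if (is.null(n_steps)) n_steps <- ceiling((dist / 1480 * 1.5) / dt)
  cfg <- simulation_config(dt = dt, n_steps = n_steps, pml_size = pml)
  sim <- run_forward(med, p0, sensor_plane(pml + 2L), cfg)
  scan <- scan_set(sim$scan, dxg, sim$dt)
  vol <- reconstruct_planar(scan, 1480)
  list(scan = scan, volume = vol,
       mip = render(vol, "mip", axis = 2L),
       slice = render(vol, "slice", axis = 1L))
}

#' Tube-shaped absorber source
#'
#' Initial pressure emulating a liquid-filled tube of given inner diameter,
#' its axis perpendicular to the acoustic axis (a filled circle in a 2D
#' cross-sectional grid; a cylinder in 3D).
#'
#' @param medium A `pa_medium`.
#' @param x_index Axial voxel index of the tube centre.
#' @param inner_diameter Inner diameter in metres.
#' @param amplitude Initial pressure, Pa.
#' @return Initial pressure array.
#' @export
source_tube <- function(medium, x_index, inner_diameter = 2e-3, amplitude = 1) {
  d <- dim(medium$sound_speed)
  dx <- medium$spacing
  r <- inner_diameter / 2
  p0 <- array(0, d)
  xs <- (seq_len(d[1]) - x_index) * dx
  if (length(d) == 2L) {
    yc <- (d[2] + 1) / 2
    ys <- (seq_len(d[2]) - yc) * dx
    p0[outer(xs^2, ys^2, `+`) <= r^2] <- amplitude
  } else {
    yc <- (d[2] + 1) / 2
    ys <- (seq_len(d[2]) - yc) * dx
    mask2 <- outer(xs^2, ys^2, `+`) <= r^2   # tube axis along dim 3
    for (iz in seq_len(d[3])) p0[, , iz][mask2] <- amplitude
  }
  p0
}

exp_sensor_comparison <- function(config) {
  # transcranial planar field at desk scale, then sensor-specific detection
  ph <- config$phantom
  if (is.null(ph)) ph <- skull_spec("frontal")
  ph$seed <- stage_seed(config$seed, "phantom")
  tom <- exp_tomography(modifyList_cfg(config, phantom = ph), target = "plane")
  scan <- tom$scan
  nt <- dim(scan$pressure)[2]
  noise_range <- c(1L, max(2L, round(nt * 0.08)))
  sensors <- list(
    pzt_500k = function(f) piezo_response(piezo_spec(0.5e6), f),
    pzt_1m   = function(f) piezo_response(piezo_spec(1e6), f),
    pvdf     = function(f) pvdf_response(f),
    pfp      = function(f) {
      st <- film_stack(pa_materials()$cop, pa_materials()$parylene,
                       pa_materials()$water, 20e-6)
      Mod(film_mean_stress(st, pmax(f, 1))) / Mod(film_mean_stress(st, 1))
    },
    pcor     = function(f) {
      st <- film_stack(pa_materials()$cop, pa_materials()$spacer,
                       pa_materials()$water, 493e-6)
      Mod(film_mean_stress(st, pmax(f, 1))) / Mod(film_mean_stress(st, 1))
    })
  apertures <- c(pzt_500k = 25.4e-3, pzt_1m = 25.4e-3, pvdf = 19.2e-3,
                 pfp = 0, pcor = 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stage_seed(config$seed, "noise"))
  out <- lapply(names(sensors), function(nm) {
    ap <- apertures[[nm]]
    aperture_m <- dim(scan$pressure)[1] * scan$dx
    w <- if (ap > 0) aperture_average(scan, min(ap, aperture_m * 0.9))
         else waveform(scan$pressure[round(dim(scan$pressure)[1] / 2), ], scan$dt)
    w <- apply_sensor_response(w, sensors[[nm]])
    w$samples <- w$samples + stats::rnorm(length(w$samples),
                                          sd = max(abs(w$samples)) * 1e-3 + 1e-12)
    wn <- filter_and_normalize(w, noise_range)
    list(waveform = wn, peak_snr = max(abs(wn$samples)))
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  names(out) <- names(sensors)
  ranking <- sort(vapply(out, `[[`, numeric(1), "peak_snr"), decreasing = TRUE)
  list(sensors = out, ranking = ranking, scan = scan)
}

modifyList_cfg <- function(config, ...) {
  upd <- list(...)
  for (nm in names(upd)) config[[nm]] <- upd[[nm]]
  config
}

exp_sensor_design <- function(config) {
  mats <- pa_materials()
  Ls <- seq(100e-6, 500e-6, by = 50e-6)
  curve <- nep_design_curve(Ls)
  pfp <- film_frequency_response(
    film_stack(mats$cop, mats$parylene, mats$water, 20e-6),
    seq(1e4, 150e6, length.out = 4000))
  pcor <- film_frequency_response(
    film_stack(mats$cop, mats$spacer, mats$water, 493e-6),
    seq(1e4, 8e6, length.out = 4000))
  f <- seq(0, 5e6, length.out = 1000)
  list(nep_curve = curve, pfp = pfp, pcor = pcor,
       piezo = data.frame(f = f,
                          pzt_500k = piezo_response(piezo_spec(0.5e6), f),
                          pzt_1m = piezo_response(piezo_spec(1e6), f),
                          pvdf = pvdf_response(f)))
}

# Write bundle outputs + JSON manifest with md5 checksums of each file.
write_bundle <- function(res, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files[[length(files) + 1L]] <<- p
  }
  if (!is.null(res$il))
    put_csv(data.frame(frequency_hz = res$il$frequencies,
                       loss_db = res$il$loss_db, valid = res$il$valid),
            "insertion_loss.csv")
  if (!is.null(res$reference))
    put_csv(data.frame(t = waveform_time(res$reference),
                       reference = res$reference$samples,
                       transcranial = res$transcranial$samples),
            "waveforms.csv")
  if (!is.null(res$volume)) {
    p <- file.path(config$output_dir, "reconstruction.tif")
    write_volume(res$volume$p0, p)
    files[[length(files) + 1L]] <- p
  }
  if (!is.null(res$nep_curve)) put_csv(res$nep_curve, "nep_design_curve.csv")
  if (!is.null(res$ranking))
    put_csv(data.frame(sensor = names(res$ranking), peak_snr = res$ranking),
            "sensor_ranking.csv")
  manifest <- list(
    experiment = config$experiment, seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = lapply(files, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Generate the small fixture bundle used by examples and tests
#'
#' Writes reduced-size synthetic inputs: phantom medium maps for the three
#' site presets (TIFF stacks), a water-reference on-axis waveform (CSV), a
#' Gaussian noise trace (CSV), a modelled ITF curve (CSV), and a JSON
#' manifest listing every file with its checksum. Regeneration with the same
#' seed reproduces the checksums.
#'
#' @param output_dir Output directory.
#' @param seed Integer seed.
#' @return Manifest list, invisibly.
#' @export
make_fixtures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (site in c("temporal", "occipital", "frontal")) {
    ph <- skull_spec(site, seed = stage_seed(seed, "phantom"))
    med <- generate_skull_slab(ph, 125e-6, lateral_extent = 8, ndims = 3,
                               axial_extent = ph$total_thickness + 2)
    p <- file.path(output_dir, paste0("phantom_", site, ".tif"))
    write_volume(med, p)
    files <- c(files, p)
  }
  sc <- transmission_scene(NULL, 250e-6, distance = 10e-3, radial_extent = 4e-3)
  cfg <- simulation_config(n_steps = 450L)
  ref <- result_waveform(run_forward(sc$medium, sc$source, sc$sensors, cfg))
  p <- file.path(output_dir, "water_reference.csv")
  utils::write.csv(data.frame(t = waveform_time(ref), p = ref$samples), p,
                   row.names = FALSE)
  files <- c(files, p)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stage_seed(seed, "noise"))
  noise <- stats::rnorm(4096)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p <- file.path(output_dir, "noise_trace.csv")
  utils::write.csv(data.frame(t = seq_along(noise) * 1e-8, v = noise), p,
                   row.names = FALSE)
  files <- c(files, p)
  et <- etalon_spec(493e-6)
  wl <- seq(1578e-9, 1582e-9, by = 2e-12)
  curve <- itf(et, wl)
  p <- file.path(output_dir, "itf_curve.csv")
  utils::write.csv(data.frame(wavelength_m = curve$wavelengths,
                              intensity = curve$intensity), p,
                   row.names = FALSE)
  files <- c(files, p)
  manifest <- list(seed = seed,
                   files = lapply(files, function(f)
                     list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
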