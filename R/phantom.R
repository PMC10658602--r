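#' Synthetic cranial bone slab specification
#'
#' Describes a three-layer bone slab: two solid cortical tables enclosing a
#' porous diploe layer. The diploe is a binary bone/water microstructure
#' obtained by thresholding a smoothed Gaussian random field, controlled by a
#' porosity (water fraction) and an isotropic correlation length.
#'
#' @param site One of `"temporal"`, `"occipital"`, `"frontal"`, or `"custom"`.
#'   Named sites fill the remaining arguments with preset values (see
#'   [skull_site_presets()]); explicit arguments override the preset.
#' @param total_thickness Total slab thickness in mm.
#' @param cortical_table_thickness Thickness of each of the two solid cortical
#'   tables, mm. `2 * cortical_table_thickness <= total_thickness`.
#' @param porosity Fraction of diploe voxels assigned water, in `[0, 1]`.
#' @param pore_correlation_length Correlation length of the diploe
#'   microstructure, mm.
#' @param seed Integer RNG seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return An object of class `skull_spec`.
#' @export
skull_spec <- function(site = "custom", total_thickness = NULL,
                       cortical_table_thickness = NULL, porosity = NULL,
                       pore_correlation_length = 0.5, seed = 1L) {
  presets <- skull_site_presets()
  if (site %in% names(presets)) {
    p <- presets[[site]]
    if (is.null(total_thickness)) total_thickness <- p$total_thickness
    if (is.null(cortical_table_thickness)) cortical_table_thickness <- p$cortical_table_thickness
    if (is.null(porosity)) porosity <- p$porosity
  }
  stopifnot(is.numeric(total_thickness), total_thickness > 0,
            is.numeric(cortical_table_thickness), cortical_table_thickness >= 0,
            2 * cortical_table_thickness <= total_thickness)
  if (porosity < 0 || porosity > 1) stop("porosity must lie in [0, 1]")
  structure(list(site = site, total_thickness = total_thickness,
                 cortical_table_thickness = cortical_table_thickness,
                 porosity = porosity,
                 pore_correlation_length = pore_correlation_length,
                 seed = as.integer(seed)),
            class = "skull_spec")
}

#' Skull site presets
#'
#' Midpoints of the reported thickness ranges for the three measurement sites:
#' temporal bone is thinnest and least cancellous (0.5-1.5 mm reported range),
#' frontal bone thickest and most porous (6-9 mm). Porosities are calibration
#' parameters of the synthetic model, not measured values.
#'
#' @return Named list of preset parameter lists (thicknesses in mm).
#' @export
skull_site_presets <- function() {
  list(
    temporal  = list(total_thickness = 1.0, cortical_table_thickness = 0.4, porosity = 0.2),
    occipital = list(total_thickness = 5.0, cortical_table_thickness = 1.0, porosity = 0.4),
    frontal   = list(total_thickness = 7.5, cortical_table_thickness = 1.5, porosity = 0.5)
  )
}

#' @export
print.skull_spec <- function(x, ...) {
  cat(sprintf("<skull_spec: %s> %g mm total, 2 x %g mm cortical tables, porosity %g, l_c %g mm, seed %d\n",
              x$site, x$total_thickness, x$cortical_table_thickness,
              x$porosity, x$pore_correlation_length, x$seed))
  invisible(x)
}

# Gaussian random field smoothed with an isotropic Gaussian kernel of standard
# deviation sigma_vox (in voxels), computed spectrally with periodic wrap.
smoothed_random_field <- function(dims, sigma_vox) {
  z <- array(stats::rnorm(prod(dims)), dims)
  if (sigma_vox <= 0) return(z)
  w <- lapply(seq_along(dims), function(d) {
    k <- fft_wavenumbers(dims[d], 1)
    exp(-0.5 * (k * sigma_vox)^2)
  })
  W <- Reduce(function(a, d) sweep_dim(a, d, w[[d]]),
              seq_along(dims), array(1, dims))
  Re(stats::fft(stats::fft(z) * W, inverse = TRUE)) / prod(dims)
}

#' Generate a synthetic cranial bone slab medium map
#'
#' Builds a three-layer slab normal to the acoustic axis (dimension 1): two
#' solid cortical tables of bone, separated by a diploe layer in which voxels
#' are assigned water with probability equal to the requested porosity. The
#' diploe microstructure is a Gaussian random field smoothed with an isotropic
#' kernel of the requested correlation length and thresholded at the quantile
#' matching the porosity, which reproduces blob-like cancellous structure.
#' All surrounding voxels are water.
#'
#' @param spec A [skull_spec()].
#' @param grid_spacing Voxel spacing in metres.
#' @param lateral_extent Lateral extent in mm. For `axisymmetric = TRUE` this
#'   is the radial extent of the (x, r) half-plane.
#' @param axial_extent Axial (x) extent in mm; defaults to the slab thickness
#'   plus 4 mm of water margin.
#' @param slab_center Axial position of the slab centre in mm; defaults to the
#'   grid centre.
#' @param ndims 1, 2 or 3 grid dimensions.
#' @param axisymmetric Mark the map as an (x, r) half-plane (`ndims = 2`).
#' @param bone_props,water_props Material properties.
#' @return A `pa_medium`; `meta` records the spec, seed, and the diploe and
#'   slab voxel index ranges along x (`diploe_range`, `slab_range`).
#' @export
generate_skull_slab <- function(spec, grid_spacing, lateral_extent,
                                axial_extent = NULL, slab_center = NULL,
                                ndims = 3, axisymmetric = FALSE,
                                bone_props = pa_materials()$bone,
                                water_props = pa_materials()$water) {
  stopifnot(inherits(spec, "skull_spec"))
  if (spec$porosity < 0 || spec$porosity > 1) stop("porosity must lie in [0, 1]")
  mm <- 1e-3
  if (is.null(axial_extent)) axial_extent <- spec$total_thickness + 4
  n_thick <- round(spec$total_thickness * mm / grid_spacing)
  if (n_thick < 2) stop("unresolvable slab: thickness spans fewer than 2 voxels")
  n_table <- round(spec$cortical_table_thickness * mm / grid_spacing)
  if (2 * n_table > n_thick) n_table <- floor(n_thick / 2)
  nx <- max(round(axial_extent * mm / grid_spacing), n_thick)
  nl <- max(round(lateral_extent * mm / grid_spacing), 1L)
  dims <- switch(as.character(ndims), "1" = nx, "2" = c(nx, nl), c(nx, nl, nl))
  if (is.null(slab_center)) slab_center <- nx * grid_spacing / mm / 2
  i0 <- round(slab_center * mm / grid_spacing - n_thick / 2) + 1L
  i0 <- max(1L, min(i0, nx - n_thick + 1L))
  i1 <- i0 + n_thick - 1L
  bone <- array(FALSE, dims)
  slab_idx <- seq.int(i0, i1)
  assign_x <- function(a, idx, value) {
    if (ndims == 1) a[idx] <- value
    else if (ndims == 2) a[idx, ] <- value
    else a[idx, , ] <- value
    a
  }
  bone <- assign_x(bone, slab_idx, TRUE)
  di0 <- i0 + n_table; di1 <- i1 - n_table
  if (di1 >= di0 && spec$porosity > 0) {
    ddims <- c(di1 - di0 + 1L, dims[-1])
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    g <- smoothed_random_field(ddims, spec$pore_correlation_length * mm / grid_spacing)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    thr <- stats::quantile(g, spec$porosity, names = FALSE)
    pores <- g <= thr
    if (ndims == 1) bone[di0:di1][pores] <- FALSE
    else if (ndims == 2) bone[di0:di1, ][pores] <- FALSE
    else bone[di0:di1, , ][pores] <- FALSE
  }
  medium_map(ifelse(bone, bone_props$sound_speed, water_props$sound_speed),
             ifelse(bone, bone_props$density, water_props$density),
             ifelse(bone, bone_props$alpha0, water_props$alpha0),
             grid_spacing, axisymmetric = axisymmetric,
             meta = list(spec = spec, seed = spec$seed,
                         slab_range = c(i0, i1),
                         diploe_range = if (di1 >= di0) c(di0, di1) else NULL))
}

#' Realized diploe porosity of a generated slab
#'
#' Water-voxel fraction inside the diploe layer, by voxel counting.
#'
#' @param medium A `pa_medium` from [generate_skull_slab()].
#' @return Fraction in `[0, 1]`.
#' @export
realized_porosity <- function(medium) {
  rng <- medium$meta$diploe_range
  if (is.null(rng)) return(0)
  1 - bone_volume_fraction(medium, x_range = rng)
}
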