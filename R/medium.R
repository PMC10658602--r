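#' Voxelized acoustic medium map
#'
#' The simulation's world: per-voxel sound speed, density and absorption
#' prefactor on a regular isotropic grid. Dimension 1 is the acoustic axis x.
#' For axisymmetric media the array holds the (x, r) half-plane, r >= 0, and
#' the solver mirrors it about the axis internally.
#'
#' @param sound_speed,density,alpha0 Numeric arrays of identical shape
#'   (1D vector, 2D matrix or 3D array). Units m/s, kg/m^3, dB/cm/MHz^2.
#' @param spacing Isotropic voxel spacing in metres.
#' @param axisymmetric Logical; interpret dimension 2 as radius.
#' @param meta Optional list of provenance attributes (seed, spec, ...).
#' @return An object of class `pa_medium`.
#' @export
medium_map <- function(sound_speed, density, alpha0 = NULL, spacing,
                       axisymmetric = FALSE, meta = list()) {
  sound_speed <- as.array(sound_speed)
  density <- as.array(density)
  if (is.null(alpha0)) alpha0 <- array(0, dim(sound_speed)) else alpha0 <- as.array(alpha0)
  stopifnot(identical(dim(sound_speed), dim(density)),
            identical(dim(sound_speed), dim(alpha0)),
            is.numeric(spacing), length(spacing) == 1L, spacing > 0,
            all(is.finite(sound_speed)), all(sound_speed > 0),
            all(is.finite(density)), all(density > 0),
            all(alpha0 >= 0))
  structure(list(sound_speed = sound_speed, density = density, alpha0 = alpha0,
                 spacing = spacing, axisymmetric = isTRUE(axisymmetric),
                 meta = meta),
            class = "pa_medium")
}

#' @export
print.pa_medium <- function(x, ...) {
  d <- dim(x$sound_speed)
  cat(sprintf("<pa_medium> %s voxels @ %g um%s\n",
              paste(d, collapse = " x "), x$spacing * 1e6,
              if (x$axisymmetric) " (axisymmetric half-plane)" else ""))
  cat(sprintf("  c:     %g .. %g m/s\n", min(x$sound_speed), max(x$sound_speed)))
  cat(sprintf("  rho:   %g .. %g kg/m^3\n", min(x$density), max(x$density)))
  cat(sprintf("  alpha0:%g .. %g dB/cm/MHz^2\n", min(x$alpha0), max(x$alpha0)))
  invisible(x)
}

#' Homogeneous medium map
#'
#' @param dims Integer vector of grid dimensions.
#' @param spacing Voxel spacing in metres.
#' @param material A `pa_material` filling the whole grid.
#' @param axisymmetric Logical, see [medium_map()].
#' @return A `pa_medium`.
#' @export
homogeneous_medium <- function(dims, spacing, material = pa_materials()$water,
                               axisymmetric = FALSE) {
  medium_map(array(material$sound_speed, dims),
             array(material$density, dims),
             array(material$alpha0, dims),
             spacing, axisymmetric = axisymmetric)
}

#' Maximum frequency supported by a medium's grid
#'
#' The spectral grid resolves two grid points per wavelength, so the maximum
#' supported frequency is min(c) / (2 * spacing). On a 125 um grid containing
#' water this evaluates to 5.92 MHz.
#'
#' @param medium A `pa_medium`.
#' @return Frequency in Hz.
#' @export
max_supported_frequency <- function(medium) {
  stopifnot(inherits(medium, "pa_medium"), length(medium$sound_speed) >= 1L)
  min(medium$sound_speed) / (2 * medium$spacing)
}

#' Bone volume fraction of a medium map
#'
#' Fraction of voxels carrying the bone density, optionally restricted to an
#' index range along the acoustic axis (e.g. the diploe region recorded in
#' `meta$diploe_range` by [generate_skull_slab()]).
#'
#' @param medium A `pa_medium`.
#' @param bone_density Density identifying bone voxels (kg/m^3).
#' @param x_range Optional length-2 integer range along dimension 1.
#' @return Fraction in `[0, 1]`.
#' @export
bone_volume_fraction <- function(medium, bone_density = pa_materials()$bone$density,
                                 x_range = NULL) {
  rho <- medium$density
  if (!is.null(x_range)) {
    idx <- seq.int(x_range[1], x_range[2])
    rho <- if (length(dim(rho)) == 1L) rho[idx, drop = FALSE]
           else if (length(dim(rho)) == 2L) rho[idx, , drop = FALSE]
           else rho[idx, , , drop = FALSE]
  }
  mean(abs(rho - bone_density) < 1e-9)
}

#' Load a binary segmentation volume as a medium map
#'
#' Reads a binary bone segmentation (multi-page TIFF stack, NIfTI-1 volume, or
#' an in-memory array) and maps nonzero voxels to `bone_props`, zero voxels to
#' `water_props`. Voxel spacing is taken from the NIfTI header when available,
#' otherwise it must be supplied.
#'
#' @param volume Path to a `.tif`/`.tiff` stack or `.nii`/`.nii.gz` file, or
#'   a numeric array of 0/1 labels.
#' @param bone_props,water_props `pa_material` objects.
#' @param spacing Voxel spacing in metres; required for TIFF and array input.
#' @return A `pa_medium`.
#' @export
load_segmentation <- function(volume, bone_props = pa_materials()$bone,
                              water_props = pa_materials()$water,
                              spacing = NULL) {
  src <- "array"
  if (is.character(volume)) {
    src <- volume
    if (grepl("\\.nii(\\.gz)?$", volume, ignore.case = TRUE)) {
      img <- RNifti::readNifti(volume)
      if (is.null(spacing)) {
        pix <- RNifti::pixdim(img)
        if (length(pix) < 1L || any(pix[1] <= 0))
          stop("missing voxel spacing: NIfTI header has no usable pixdim and none was supplied")
        if (length(unique(round(pix[seq_len(min(3, length(pix)))], 12))) != 1L)
          stop("anisotropic NIfTI spacing; supply `spacing` explicitly")
        spacing <- pix[1]
      }
      volume <- as.array(img)
    } else if (grepl("\\.tiff?$", volume, ignore.case = TRUE)) {
      pages <- tiff::readTIFF(volume, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      volume <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    } else stop("unrecognised volume file type: ", volume)
  }
  if (is.null(spacing))
    stop("missing voxel spacing: supply `spacing` (metres) for this input")
  volume <- as.array(volume)
  rounded <- round(volume)
  if (max(abs(volume - rounded)) < 1e-6) volume <- rounded  # file-format jitter
  labels <- sort(unique(as.vector(volume)))
  if (!all(labels %in% c(0, 1)))
    stop("non-binary segmentation volume; distinct labels: ",
         paste(utils::head(labels, 10), collapse = ", "))
  bone <- volume == 1
  medium_map(ifelse(bone, bone_props$sound_speed, water_props$sound_speed),
             ifelse(bone, bone_props$density, water_props$density),
             ifelse(bone, bone_props$alpha0, water_props$alpha0),
             spacing, meta = list(source = src))
}

#' Write a medium map (or any volume array) as a TIFF stack or NIfTI volume
#'
#' TIFF output stores one 32-bit float page per x-slice; NIfTI output stores
#' the array with the voxel spacing in the header.
#'
#' @param x A `pa_medium` (its sound-speed field is written) or numeric array.
#' @param path Output file; format chosen from the extension.
#' @param field For `pa_medium` input, which field to write.
#' @param spacing Spacing in metres (taken from the medium when omitted).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, field = c("sound_speed", "density", "alpha0"),
                         spacing = NULL) {
  if (inherits(x, "pa_medium")) {
    field <- match.arg(field)
    spacing <- x$spacing
    x <- x[[field]]
  }
  x <- as.array(x)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(x)
    if (!is.null(spacing)) {
      n <- length(dim(x))
      RNifti::pixdim(img) <- rep(spacing, n)
    }
    RNifti::writeNifti(img, path)
  } else {
    rng <- range(x)
    scl <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
    if (length(dim(scl)) == 2L) scl <- array(scl, c(dim(scl), 1L))
    pages <- lapply(seq_len(dim(scl)[3]), function(i) scl[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}
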