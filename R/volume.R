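#' Density and label volume containers
#'
#' A `density_volume` wraps a 3D numeric array of grayscale densities with
#' its voxel size in nanometres, an origin offset and the cryo-ET contrast
#' convention flag (`structure_low = TRUE` means protein/membrane density is
#' *lower*-valued than background, as in reconstructed tomograms). A
#' `label_volume` wraps an integer array of the same shape marking the
#' boundaries the segmentation needs: 0 background, 1 active-zone (AZ)
#' membrane, 2 non-AZ plasma membrane, 3 postsynaptic/excluded, vesicles
#' >= 10. Detected segments, when exported, use ids >= 1000.
#'
#' Voxel coordinates throughout the package are 1-based array indices in
#' axis order (x, y, z), with z the beam axis; nanometres appear only in
#' reported quantities.
#'
#' @param values 3D numeric array.
#' @param voxel_size_nm Isotropic voxel size in nm (> 0).
#' @param origin Numeric length-3 origin offset in voxels. Default `c(0,0,0)`.
#' @param structure_low Contrast convention flag; `TRUE` (default) for
#'   cryo-ET style maps where structure is dark (low values).
#' @return A `density_volume` or `label_volume` object.
#' @examples
#' v <- density_volume(array(rnorm(8^3), c(8, 8, 8)), voxel_size_nm = 1.4)
#' dim(v$values)
#' @export
density_volume <- function(values, voxel_size_nm, origin = c(0, 0, 0),
                           structure_low = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("`values` must be a 3D array (not a 3D volume otherwise)")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    abort("`voxel_size_nm` must be a single positive number")
  if (any(!is.finite(values)))
    abort("density values must be finite")
  structure(
    list(values = values, voxel_size_nm = as.numeric(voxel_size_nm),
         origin = as.numeric(origin), structure_low = isTRUE(structure_low)),
    class = "density_volume"
  )
}

#' @rdname density_volume
#' @export
label_volume <- function(values, voxel_size_nm, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("`values` must be a 3D array (not a 3D volume otherwise)")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    abort("`voxel_size_nm` must be a single positive number")
  storage.mode(values) <- "integer"
  if (anyNA(values)) abort("label values must be non-missing integers")
  structure(
    list(values = values, voxel_size_nm = as.numeric(voxel_size_nm),
         origin = as.numeric(origin)),
    class = "label_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.4g nm/voxel, %s\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              if (x$structure_low) "structure-low contrast" else "structure-high contrast"))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$values)
  ids <- sort(unique(as.vector(x$values)))
  cat(sprintf("<label_volume> %d x %d x %d voxels, %.4g nm/voxel, ids: %s\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              paste(head(ids, 12), collapse = " ")))
  invisible(x)
}

# shared shape/voxel-size compatibility check
check_aligned <- function(density, labels) {
  if (!identical(dim(density$values), dim(labels$values)))
    abort("density and label volumes have different shapes")
  if (abs(density$voxel_size_nm - labels$voxel_size_nm) >
      1e-6 * density$voxel_size_nm)
    abort("density and label volumes have different voxel sizes")
  invisible(TRUE)
}

# linear index <-> (x,y,z) helpers, 1-based
vox_xyz <- function(idx, dims) {
  arrayInd(as.integer(idx), .dim = dims)
}
xyz_vox <- function(xyz, dims) {
  as.numeric((xyz[, 3] - 1) * dims[1] * dims[2] + (xyz[, 2] - 1) * dims[1] + xyz[, 1])
}
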