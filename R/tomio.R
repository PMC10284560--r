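#' Read an MRC2014 volume
#'
#' Minimal, strict MRC2014 I/O. Densities are stored as 32-bit floats
#' (mode 2); label volumes as 16-bit signed integers (mode 1). Voxel size is
#' taken from the cell dimensions over the sampling grid and converted from
#' Angstrom to nm; anisotropic voxel sizes (beyond 0.1% relative spread) and
#' non-3D data are rejected rather than guessed at.
#'
#' @param path Path to an MRC file.
#' @param structure_low Contrast convention to record on the returned
#'   [density_volume()].
#' @return [read_mrc()] returns a [density_volume()];
#'   [write_mrc()] invisibly returns `path`.
#' @examples
#' v <- density_volume(array(rnorm(4^3), c(4, 4, 4)), 1.4)
#' f <- tempfile(fileext = ".mrc")
#' write_mrc(v, f)
#' v2 <- read_mrc(f)
#' all.equal(v$values, v2$values)
#' @export
read_mrc <- function(path, structure_low = TRUE) {
  raw <- read_mrc_raw(path)
  density_volume(raw$values, voxel_size_nm = raw$voxel_size_nm,
                 origin = raw$origin, structure_low = structure_low)
}

read_mrc_raw <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 208)
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    abort(sprintf("malformed MRC header in %s: missing MAP tag", path))
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_num[11:13]
  nsymbt <- hdr_int[24]
  if (any(c(nx, ny, nz) <= 0)) abort("malformed MRC header: non-positive dimensions")
  if (nz < 2L || ny < 2L || nx < 2L)
    abort(sprintf("%s is not a 3D volume (dimensions %d x %d x %d)", path, nx, ny, nz))
  vox_ang <- cella / c(mx, my, mz)
  if (any(!is.finite(vox_ang)) || any(vox_ang <= 0))
    abort("malformed MRC header: invalid cell/grid size")
  if ((max(vox_ang) - min(vox_ang)) / mean(vox_ang) > 1e-3)
    abort(sprintf("anisotropic voxel size (%s Angstrom) not supported",
                  paste(sprintf("%.4g", vox_ang), collapse = " x ")))
  n <- as.double(nx) * ny * nz
  seek(con, 1024 + nsymbt)
  values <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")),
    abort(sprintf("unsupported MRC mode %d", mode))
  )
  if (length(values) != n) abort(sprintf("truncated MRC data in %s", path))
  list(values = array(values, c(nx, ny, nz)),
       voxel_size_nm = mean(vox_ang) / 10,
       origin = hdr_num[50:52], mode = mode)
}

#' @param vol A [density_volume()] (for [write_mrc()]) or [label_volume()]
#'   (for [write_labels()]).
#' @rdname read_mrc
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  write_mrc_raw(vol$values, vol$voxel_size_nm, vol$origin, path, mode = 2L)
  invisible(path)
}

write_mrc_raw <- function(values, voxel_size_nm, origin, path, mode) {
  d <- dim(values)
  vox_ang <- voxel_size_nm * 10
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wn <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(mode)
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wn(d * vox_ang)            # cella
  wn(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  v <- as.vector(values)
  wn(c(min(v), max(v), mean(v)))
  wi(c(0, 0))                # ispg, nsymbt
  wi(rep(0L, 25))            # extra (words 25-49)
  wn(origin)                 # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wn(sd(v))
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  if (mode == 2L) {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else if (mode == 1L) {
    if (max(abs(v)) > 32767) abort("label ids exceed 16-bit range")
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else abort("unsupported write mode")
  invisible(path)
}

#' Read or write an integer label volume
#'
#' Labels follow the package's reserved-id scheme (see [label_volume()]).
#' An optional `id_map` renumbers ids on input (e.g. `c("5" = 1)` maps a
#' hand-segmentation id 5 onto the AZ-membrane id 1); ids absent from the
#' map are kept and reported, never silently dropped.
#'
#' @inheritParams read_mrc
#' @param id_map Named integer vector mapping file ids (names) to pipeline
#'   ids (values); `NULL` keeps ids as stored.
#' @param density Optional companion [density_volume()]; shape and voxel
#'   size must agree or the read is rejected.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, id_map = NULL, density = NULL) {
  raw <- read_mrc_raw(path)
  vals <- raw$values
  if (any(vals != round(vals)))
    abort(sprintf("%s contains non-integer label values", path))
  storage.mode(vals) <- "integer"
  if (!is.null(id_map)) {
    if (is.null(names(id_map)) || any(names(id_map) == ""))
      abort("`id_map` must be a named vector (names = file ids)")
    if (anyDuplicated(names(id_map)))
      abort(sprintf("id %s appears more than once in `id_map`",
                    names(id_map)[duplicated(names(id_map))][1]))
    old <- as.integer(names(id_map))
    present <- sort(unique(as.vector(vals)))
    unmapped <- setdiff(present, c(old, .LABEL_BACKGROUND))
    if (length(unmapped))
      warn(sprintf("label ids not in `id_map`, kept as-is: %s",
                   paste(unmapped, collapse = ", ")))
    out <- vals
    for (k in seq_along(old)) out[vals == old[k]] <- as.integer(id_map[[k]])
    vals <- out
  }
  lab <- label_volume(vals, voxel_size_nm = raw$voxel_size_nm, origin = raw$origin)
  if (!is.null(density)) check_aligned(density, lab)
  lab
}

#' @rdname read_labels
#' @export
write_labels <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_mrc_raw(vol$values, vol$voxel_size_nm, vol$origin, path, mode = 1L)
  invisible(path)
}

#' Write the pipeline's result tables
#'
#' Persists the per-vesicle, per-segment, per-synapse and per-comparison
#' tables as CSV with a fixed, versioned column order, plus a JSON manifest
#' (schema version, configuration, seeds) for provenance. Rerunning on
#' identical inputs produces byte-identical files.
#'
#' @param results Named list with any of `vesicles`, `segments`, `synapses`,
#'   `comparisons` (tibbles) and an optional `manifest` list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  schemas <- list(
    vesicles = c("synapse_id", "vesicle_id", "center_x", "center_y", "center_z",
                 "radius_nm", "distance_nm", "n_tethers", "n_connectors",
                 "tethered", "multiply_tethered", "state", "distance_class"),
    segments = c("synapse_id", "segment_id", "kind", "validity_threshold",
                 "n_voxels", "length_nm", "boundary_a", "boundary_b"),
    synapses = c("synapse_id", "condition", "orientation_deg", "az_area_nm2",
                 "n_vesicles", "n_proximal", "n_tethers", "n_connectors",
                 "surface_concentration_um2"),
    comparisons = c("variable", "group_a", "group_b", "test", "statistic",
                    "p_value", "stars", "n_a", "n_b", "flag")
  )
  paths <- character(0)
  for (nm in names(schemas)) {
    tab <- results[[nm]]
    cols <- schemas[[nm]]
    if (is.null(tab)) tab <- tibble::as_tibble(setNames(
      rep(list(vector("logical", 0)), length(cols)), cols))
    missing_cols <- setdiff(cols, names(tab))
    for (mc in missing_cols) tab[[mc]] <- NA
    tab <- tab[, cols, drop = FALSE]
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  manifest <- results$manifest %||% list()
  manifest$schema_version <- .RESULT_SCHEMA_VERSION
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
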