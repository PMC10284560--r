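#' Extend a traced equatorial contour to a sphere
#'
#' Vesicles are delineated by tracing the maximum-diameter profile in one
#' grid plane; a least-squares circle fit (Kasa) of the traced voxels gives
#' the centre and radius, and the sphere is the set of voxels within that
#' radius of the centre.
#'
#' @param contour n x 3 matrix of traced voxel coordinates (1-based, all in
#'   one grid plane).
#' @param dims Volume shape (3 integers) used to enumerate sphere voxels.
#' @param voxel_size_nm Voxel size, nm.
#' @return List with `center` (voxel coordinates), `radius_nm`, and
#'   `voxels` (1-based linear indices of the filled sphere).
#' @export
disk_to_sphere <- function(contour, dims, voxel_size_nm) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 6) abort("degenerate contour: fewer than 6 voxels")
  vr <- apply(contour, 2, function(v) diff(range(v)))
  plane_axis <- which.min(vr)
  if (vr[plane_axis] > 0)
    abort("contour does not lie in a single grid plane")
  ip <- setdiff(1:3, plane_axis)
  x <- contour[, ip[1]]; y <- contour[, ip[2]]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit) || qr(A)$rank < 3)
    abort("degenerate contour: collinear trace")
  cx <- fit[1]; cy <- fit[2]
  r <- sqrt(fit[3] + cx^2 + cy^2)
  center <- numeric(3)
  center[ip] <- c(cx, cy)
  center[plane_axis] <- contour[1, plane_axis]
  # enumerate sphere voxels in a bounding box
  lo <- pmax(1L, floor(center - r)); hi <- pmin(dims, ceiling(center + r))
  grid <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  dd <- sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2 + (grid$z - center[3])^2)
  keep <- as.matrix(grid[dd <= r, , drop = FALSE])
  list(center = center, radius_nm = r * voxel_size_nm,
       voxels = sort(xyz_vox(keep, dims)))
}

#' Vesicle morphometrics from a label volume
#'
#' Measures every vesicle (label ids >= 10): centroid, sphere-equivalent
#' radius, and the edge-to-edge distance to the AZ membrane, defined as the
#' minimal voxel-centre to voxel-centre distance between vesicle and AZ
#' voxels minus one voxel (so face-adjacent surfaces score 0), clamped at
#' zero. Distances are classified into the tethering states.
#'
#' @param labels A [label_volume()].
#' @param region An `az_region` from [analysis_region()] (carries the AZ
#'   distance map).
#' @param state_bounds Left-closed state interval bounds in nm
#'   (default `c(5, 10)`: states `<5`, `5-10`, `>=10`).
#' @return Tibble with one row per vesicle: `vesicle_id`, `center_x/y/z`
#'   (voxels), `radius_nm`, `distance_nm`, `state`.
#' @export
vesicle_table <- function(labels, region, state_bounds = c(5, 10)) {
  stopifnot(inherits(labels, "label_volume"), inherits(region, "az_region"))
  vs <- labels$voxel_size_nm
  ids <- sort(unique(as.vector(labels$values)))
  ids <- ids[ids >= .LABEL_VESICLE_MIN]
  rows <- purrr::map(ids, function(id) {
    idx <- which(labels$values == id)
    xyz <- vox_xyz(idx, dim(labels$values))
    m <- min(region$dist_vox[idx])
    tibble(vesicle_id = as.integer(id),
           center_x = mean(xyz[, 1]), center_y = mean(xyz[, 2]),
           center_z = mean(xyz[, 3]),
           radius_nm = (3 * length(idx) / (4 * pi))^(1 / 3) * vs,
           distance_nm = max(0, m - 1) * vs)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    return(tibble(vesicle_id = integer(0), center_x = numeric(0),
                  center_y = numeric(0), center_z = numeric(0),
                  radius_nm = numeric(0), distance_nm = numeric(0),
                  state = character(0)))
  out$state <- classify_state(out$distance_nm, state_bounds)
  out
}

#' Edge-to-edge distance from one vesicle to the AZ membrane
#'
#' @param vesicle_voxels 1-based linear indices of the vesicle sphere.
#' @param region An `az_region` (AZ distance map).
#' @return Distance in nm; 0 when the sphere touches the membrane.
#' @export
distance_to_az <- function(vesicle_voxels, region) {
  if (!length(vesicle_voxels)) abort("empty vesicle voxel set")
  m <- min(region$dist_vox[vesicle_voxels])
  max(0, m - 1) * region$voxel_size_nm
}

#' Geodesic segment lengths
#'
#' Fills the `length_nm` column of a segment table: the minimal geodesic
#' path length through the segment's voxel set (26-neighbour steps with
#' Euclidean weights 1, sqrt(2), sqrt(3) voxels) between any contact voxel
#' of one boundary and any contact voxel of the other. Curvature therefore
#' contributes to the length; a straight rod's length approximates its
#' span, and a segment whose two contact sets share a voxel has length 0.
#'
#' @param segments Segment tibble from [connectivity_segmentation()].
#' @param dims Volume shape.
#' @param voxel_size_nm Voxel size, nm.
#' @return The segment tibble with `length_nm` filled.
#' @export
measure_segments <- function(segments, dims, voxel_size_nm) {
  if (!nrow(segments)) return(segments)
  segments$length_nm <- purrr::pmap_dbl(
    segments[, c("voxels", "contacts_a", "contacts_b")],
    function(voxels, contacts_a, contacts_b) {
      L <- cpp_geodesic_min(voxels, as.integer(dims), contacts_a, contacts_b)
      if (!is.finite(L))
        abort("internal error: contact sets disconnected within a segment")
      L * voxel_size_nm
    })
  segments
}

#' Classify tether lengths and vesicle states
#'
#' Both classifications use left-closed, right-open intervals.
#' [classify_tether()] bins lengths into `<6 nm` (short), `6-12 nm`
#' (intermediate), `12-24 nm` (long), and `>=24 nm` ("extra", retained in
#' totals); [classify_state()] bins AZ distances into the SNAP25-dependent
#' (`<5 nm`), intermediate (`5-10 nm`) and Munc13-independent (`>=10 nm`)
#' tethering states.
#'
#' @param length_nm,distance_nm Numeric vectors, nm.
#' @param bounds Increasing interval bounds (defaults `c(6, 12, 24)` and
#'   `c(5, 10)`).
#' @return Character vector of class labels.
#' @examples
#' classify_tether(c(5.5, 6, 30))
#' classify_state(c(4, 7, 10))
#' @export
classify_tether <- function(length_nm, bounds = c(6, 12, 24)) {
  stopifnot(all(diff(bounds) > 0), all(length_nm >= 0))
  as.character(cut(length_nm, breaks = c(0, bounds, Inf), right = FALSE,
                   labels = c("short", "intermediate", "long", "extra")))
}

#' @rdname classify_tether
#' @export
classify_state <- function(distance_nm, bounds = c(5, 10)) {
  stopifnot(all(diff(bounds) > 0), all(distance_nm >= 0))
  as.character(cut(distance_nm, breaks = c(0, bounds, Inf), right = FALSE,
                   labels = c("SNAP25-dependent", "intermediate",
                              "Munc13-independent")))
}

#' Per-vesicle tether and connector counts
#'
#' Each tether increments exactly one vesicle; each connector increments
#' both of its vesicles. Derived flags: `tethered` (>= 1 tether) and
#' `multiply_tethered` (>= 3 tethers).
#'
#' @param vesicles Vesicle tibble ([vesicle_table()]).
#' @param segments Measured segment tibble.
#' @return The vesicle tibble with `n_tethers`, `n_connectors`, `tethered`,
#'   `multiply_tethered` added.
#' @export
count_bridges <- function(vesicles, segments) {
  teth <- segments[segments$kind == "tether", ]
  conn <- segments[segments$kind == "connector", ]
  ves_of_tether <- pmax(teth$boundary_a, teth$boundary_b)  # the non-AZ id
  nt <- table(factor(ves_of_tether, levels = vesicles$vesicle_id))
  nc <- table(factor(c(conn$boundary_a, conn$boundary_b),
                     levels = vesicles$vesicle_id))
  vesicles$n_tethers <- as.integer(nt)
  vesicles$n_connectors <- as.integer(nc)
  vesicles$tethered <- vesicles$n_tethers >= 1L
  vesicles$multiply_tethered <- vesicles$n_tethers >= 3L
  vesicles
}

#' Layer occupancy profile of the presynaptic cytoplasm
#'
#' Divides the cytoplasm (vesicles included) into 1-voxel-thick layers by
#' distance to the AZ membrane and measures the fraction of each layer's
#' volume occupied by vesicles, plus aggregates over the proximal /
#' intermediate / distal zones. Voxel counts are integers and conserve
#' exactly: summed vesicle-occupied counts equal the total vesicle voxels
#' within the analysis range.
#'
#' @param labels A [label_volume()].
#' @param region An `az_region` built with `include_vesicles = TRUE`.
#' @param zones Zone bounds in nm, default `c(45, 75, 250)` (proximal
#'   `<45`, intermediate `45-75`, distal `75-250`; left-closed).
#' @return A `layer_profile` object: tibbles `layers` (per 1-voxel layer:
#'   interval, voxel count, vesicle-occupied count, fraction `phi`) and
#'   `zones`.
#' @export
layer_profile <- function(labels, region, zones = c(45, 75, 250)) {
  stopifnot(inherits(labels, "label_volume"), inherits(region, "az_region"))
  vs <- labels$voxel_size_nm
  sel <- which(region$mask)
  dv <- region$dist_vox[sel]
  is_sv <- labels$values[sel] >= .LABEL_VESICLE_MIN
  layer <- ceiling(dv - 1e-9)           # layer k: distance in ((k-1), k] voxels
  kmax <- max(layer)
  lt <- tibble(layer = seq_len(kmax),
               dist_lo_nm = (seq_len(kmax) - 1) * vs,
               dist_hi_nm = seq_len(kmax) * vs)
  cnt <- tabulate(layer, nbins = kmax)
  occ <- tabulate(layer[is_sv], nbins = kmax)
  lt$n_voxels <- cnt
  lt$n_sv <- occ
  lt$phi <- ifelse(cnt > 0, occ / cnt, 0)
  dn <- dv * vs
  zone <- cut(dn, breaks = c(0, zones), right = FALSE,
              labels = c("proximal", "intermediate", "distal"),
              include.lowest = TRUE)
  zt <- tibble(zone = levels(zone)) |>
    dplyr::mutate(
      n_voxels = as.integer(table(zone)[.data$zone]),
      n_sv = purrr::map_int(.data$zone, function(z)
        sum(is_sv[!is.na(zone) & zone == z])),
      phi = ifelse(.data$n_voxels > 0, .data$n_sv / .data$n_voxels, 0))
  structure(list(layers = lt, zones = zt, voxel_size_nm = vs),
            class = "layer_profile")
}

#' Surface concentration of proximal vesicles
#'
#' Number of vesicles in the proximal zone divided by the AZ membrane
#' surface area, reported per square micrometre.
#'
#' @param n_proximal Count of proximal-zone vesicles.
#' @param az_area_nm2 AZ membrane area in nm^2 (> 0).
#' @return Concentration per um^2.
#' @export
surface_concentration <- function(n_proximal, az_area_nm2) {
  if (!is.numeric(az_area_nm2) || az_area_nm2 <= 0)
    abort("`az_area_nm2` must be > 0")
  n_proximal / az_area_nm2 * 1e6
}

#' AZ membrane surface area
#'
#' Estimates the area of the AZ membrane label as a normal-weighted count
#' of exposed voxel faces: each face between an AZ voxel and a non-AZ voxel
#' contributes `voxel_area / (|nx| + |ny| + |nz|)`, where `n` is the local
#' unit normal from the gradient of a Gaussian-smoothed mask. The weighted
#' sum is halved because a thin membrane sheet exposes two faces per unit
#' of midline area. This is exact for axis-aligned sheets and consistent
#' for oblique and curved ones; plain face counting with the stereological
#' 2/3 factor is available as `method = "face_count"`.
#'
#' @param labels A [label_volume()].
#' @param method `"weighted_faces"` (default) or `"face_count"`.
#' @return Area in nm^2.
#' @export
az_area <- function(labels, method = c("weighted_faces", "face_count")) {
  method <- match.arg(method)
  stopifnot(inherits(labels, "label_volume"))
  vs <- labels$voxel_size_nm
  mask_full <- labels$values == .LABEL_AZ
  if (!any(mask_full)) abort("empty AZ membrane label (id 1)")
  idx <- which(mask_full, arr.ind = TRUE)
  pad <- 4L
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(dim(mask_full), apply(idx, 2, max) + pad)
  m <- mask_full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(m)
  faces <- 0
  weighted <- 0
  sm <- array(cpp_smooth3(as.numeric(m), d, 1.5), d)
  grad <- function(a, axis) {
    # central differences with replicated edges
    n <- dim(a)[axis]
    ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
    switch(axis,
           (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) / 2,
           (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) / 2,
           (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) / 2)
  }
  gx <- grad(sm, 1); gy <- grad(sm, 2); gz <- grad(sm, 3)
  gnorm <- sqrt(gx^2 + gy^2 + gz^2)
  wt <- (abs(gx) + abs(gy) + abs(gz)) / pmax(gnorm, 1e-12)
  w_voxel <- ifelse(gnorm > 1e-6, 1 / wt, 1)   # degenerate normal: weight 1
  shift <- function(a, axis, by) {
    out <- array(FALSE, dim(a))
    n <- dim(a)[axis]
    if (by == 1) {
      switch(axis,
             out[2:n, , ] <- a[1:(n - 1), , ],
             out[, 2:n, ] <- a[, 1:(n - 1), ],
             out[, , 2:n] <- a[, , 1:(n - 1)])
    } else {
      switch(axis,
             out[1:(n - 1), , ] <- a[2:n, , ],
             out[, 1:(n - 1), ] <- a[, 2:n, ],
             out[, , 1:(n - 1)] <- a[, , 2:n])
    }
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L)) {
    # face between a mask voxel and a non-mask neighbour at offset `by`
    exposed <- m & !shift(m, axis, -by)
    faces <- faces + sum(exposed)
    weighted <- weighted + sum(w_voxel[exposed])
  }
  area <- if (method == "weighted_faces") weighted * vs^2 / 2
  else faces * vs^2 * (2 / 3) / 2
  area
}

#' Minimal inter-region span of an atomic model
#'
#' Reads an atomic-coordinate file (PDB or mmCIF, via bio3d) and returns
#' the minimal inter-atomic distance between two residue-range selections
#' in nm — e.g. between a membrane-binding C2B domain and the C-terminal
#' end of a MUN domain, which sets the membrane-to-membrane span a
#' tether-forming molecule can bridge.
#'
#' @param path Coordinate file path (`.pdb` or `.cif`).
#' @param sel_a,sel_b Lists with elements `resno` (integer vector of
#'   residue numbers) and optionally `chain`.
#' @return Span in nm.
#' @export
model_span <- function(path, sel_a, sel_b) {
  pdb <- tryCatch({
    if (grepl("\\.cif$", path, ignore.case = TRUE)) bio3d::read.cif(path)
    else bio3d::read.pdb(path)
  }, error = function(e) abort(sprintf("unparsable coordinate file: %s", conditionMessage(e))))
  pick <- function(sel) {
    s <- do.call(bio3d::atom.select,
                 c(list(pdb, "protein"), sel[intersect(names(sel), c("resno", "chain", "elety"))]))
    m <- matrix(pdb$xyz[s$xyz], ncol = 3, byrow = TRUE)
    if (!nrow(m)) abort("empty atom selection")
    m
  }
  a <- pick(sel_a); b <- pick(sel_b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2))) / 10
}

#' Synthetic Munc13 C1C2BMUN-like coordinates
#'
#' Constructs a synthetic stand-in for an elongated priming-factor model: a
#' gently curved rod of CA pseudo-atoms about 16 nm long (MUN-like, chain
#' A, residues 101-420) flanked by a compact C2B-like domain cluster
#' (residues 1-60) offset laterally near the rod's N-terminal end, plus a
#' small C1-like cluster. The construction is deterministic and mirrors
#' the published domain architecture of the Munc13 core fragment; it is
#' synthetic and is not a deposited structure.
#'
#' @param path Output PDB path.
#' @return `path`, invisibly; attributes `sel_c2b` and `sel_mun_cterm`
#'   give the selections delimiting the C2B cluster and the rod's
#'   C-terminal end for [model_span()].
#' @export
synthetic_munc13_model <- function(path = tempfile(fileext = ".pdb")) {
  # rod: 320 residues along a shallow arc from x = 0 to x = 160 Angstrom
  t <- seq(0, 1, length.out = 320)
  rod <- cbind(160 * t, 12 * sin(pi * t), 0)
  # C2B-like cluster: compact ball of radius ~12 A centred 25 A off the rod N-end
  th <- seq(0, 19 * pi, length.out = 60)
  ball <- cbind(10 + 10 * cos(th) * sqrt(1 - (seq(-0.9, 0.9, length.out = 60))^2),
                -25 + 10 * sin(th) * sqrt(1 - (seq(-0.9, 0.9, length.out = 60))^2),
                10 * seq(-0.9, 0.9, length.out = 60))
  # C1-like cluster near the N-terminal end, above the rod
  th2 <- seq(0, 9 * pi, length.out = 30)
  c1 <- cbind(5 + 8 * cos(th2), 20 + 8 * sin(th2), 4 * sin(th2 / 3))
  coords <- rbind(ball, rod, c1)
  resno <- c(seq_len(60), 100 + seq_len(320), 500 + seq_len(30))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), resno, coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "END"), path)
  attr(path, "sel_c2b") <- list(resno = 1:60, chain = "A")
  attr(path, "sel_mun_cterm") <- list(resno = 411:420, chain = "A")
  invisible(path)
}

#' Can a segment accommodate a model of a given span?
#'
#' Geometric feasibility screen: `TRUE` when a geodesic path of length at
#' least `span_nm` exists within the segment's voxel set between its two
#' contact sets (the longest shortest-path placement over all contact-voxel
#' pairs). Curvature counts, so an L-shaped tether whose chord is shorter
#' than the span can still accommodate the model. Any voxel path has a
#' cross-section of at least one voxel. This is a screen, not a rigid-body
#' fit: it makes no claim of agreement with full grayscale fitting.
#'
#' @param segment One-row segment tibble (or list) with `voxels`,
#'   `contacts_a`, `contacts_b`.
#' @param span_nm Required span, nm.
#' @param dims Volume shape.
#' @param voxel_size_nm Voxel size, nm.
#' @return Logical.
#' @export
tether_accommodates <- function(segment, span_nm, dims, voxel_size_nm) {
  L <- cpp_geodesic_max(segment$voxels[[1]], as.integer(dims),
                        segment$contacts_a[[1]], segment$contacts_b[[1]])
  is.finite(L) && L * voxel_size_nm >= span_nm
}
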