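#' Specify a ground-truthed synthetic tomogram phantom
#'
#' Builds a validated specification for a tomogram-like test volume: a
#' membrane slab carrying a central active-zone (AZ) patch, spherical
#' vesicles held at prescribed edge-to-edge distances above the AZ, and
#' curved rod-like density bridges (tethers to the AZ, connectors between
#' vesicles) rasterized as tubes swept along polylines. Bridges exist only
#' in the grayscale density, as in real tomograms; the label volume carries
#' boundaries only (membranes and vesicle spheres).
#'
#' The geometry lives in continuous nm coordinates where voxel `i` (1-based)
#' is centred at `(i - 0.5) * voxel_size_nm`. The membrane slab spans
#' `z` in `[membrane_z_nm, membrane_z_nm + membrane_thickness_nm)`; the
#' presynaptic cytoplasm is above it, the space below is labelled
#' postsynaptic/excluded. Tether AZ attachments sit in the first cytoplasmic
#' voxel layer above the slab.
#'
#' @param volume_shape Integer length-3 volume shape in voxels (x, y, z).
#' @param voxel_size_nm Voxel size in nm.
#' @param vesicles Tibble/data frame with columns `x_nm`, `y_nm` (lateral
#'   centre), `radius_nm`, `distance_nm` (edge-to-edge distance to the AZ
#'   surface). The vesicle centre height is derived from `distance_nm`.
#' @param tethers Data frame with columns `vesicle` (row index into
#'   `vesicles`), `shape` (`"straight"` or `"semicircle"`), `az_dx_nm`,
#'   `az_dy_nm` (lateral offset of the AZ attachment from the vesicle
#'   axis), `bulge_axis` (`"x"` or `"y"`, for arcs) and `radius_nm` (rod
#'   radius). May be `NULL`.
#' @param connectors Data frame with columns `vesicle_a`, `vesicle_b`
#'   (row indices) and `radius_nm`. May be `NULL`.
#' @param membrane_thickness_nm Lipid bilayer thickness.
#' @param membrane_z_nm Height of the lower slab face.
#' @param az_extent_nm Lateral edge length of the square AZ patch (centred).
#' @param density_fg,density_bg Foreground (structure) and background
#'   density values; `density_fg < density_bg` per the cryo-ET
#'   structure-low convention.
#' @param noise_sigma Additive Gaussian noise sigma, in units of the
#'   background-foreground contrast. Default 0.5 (SNR 2), typical of
#'   4x-binned phase-plate reconstructions.
#' @param wedge_halfangle_deg Half-range of the simulated tilt series in
#'   degrees (the missing wedge spans the unsampled remainder); 0 disables
#'   wedge filtering.
#' @param seed RNG seed used for the noise.
#' @return A `phantom_spec` object with resolved attachment points,
#'   waypoint polylines and derived vesicle centres.
#' @examples
#' spec <- phantom_spec(
#'   volume_shape = c(48, 48, 48), voxel_size_nm = 1.4,
#'   vesicles = tibble::tibble(x_nm = 33, y_nm = 33, radius_nm = 15,
#'                             distance_nm = 8),
#'   tethers = tibble::tibble(vesicle = 1, shape = "straight",
#'                            az_dx_nm = 0, az_dy_nm = 0,
#'                            bulge_axis = "x", radius_nm = 2.1),
#'   noise_sigma = 0)
#' ph <- generate_phantom(spec)
#' ph$ground_truth$vesicles
#' @export
phantom_spec <- function(volume_shape, voxel_size_nm,
                         vesicles,
                         tethers = NULL,
                         connectors = NULL,
                         membrane_thickness_nm = 4.2,
                         membrane_z_nm = 14,
                         az_extent_nm = NULL,
                         density_fg = 0, density_bg = 1,
                         noise_sigma = 0.5,
                         wedge_halfangle_deg = 0,
                         seed = 1L) {
  vs <- voxel_size_nm
  if (!is.numeric(vs) || vs <= 0) abort("`voxel_size_nm` must be > 0")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    abort("`volume_shape` must be 3 integers >= 8")
  if (density_fg >= density_bg)
    abort("structure-low contrast requires density_fg < density_bg")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  vesicles <- tibble::as_tibble(vesicles)
  need <- c("x_nm", "y_nm", "radius_nm", "distance_nm")
  if (!all(need %in% names(vesicles)))
    abort(paste("`vesicles` needs columns", paste(need, collapse = ", ")))
  if (any(vesicles$distance_nm < 0)) abort("vesicle distances must be >= 0")
  if (any(vesicles$radius_nm <= 0)) abort("vesicle radii must be > 0")
  ext <- volume_shape * vs
  if (is.null(az_extent_nm)) az_extent_nm <- 0.9 * min(ext[1:2])

  # derived geometry: top membrane voxel layer and attachment plane
  z_top <- membrane_z_nm + membrane_thickness_nm       # slab upper face (nm)
  kz <- (seq_len(volume_shape[3]) - 0.5) * vs
  mem_k <- which(kz >= membrane_z_nm & kz < z_top)
  if (!length(mem_k)) abort("membrane slab contains no voxel layer")
  z_mem_top <- kz[max(mem_k)]            # centre of top membrane voxel layer
  z_attach <- z_mem_top + vs             # first cytoplasmic voxel layer

  vesicles$id <- .LABEL_VESICLE_MIN + seq_len(nrow(vesicles)) - 1L
  vesicles$z_nm <- z_attach + vesicles$distance_nm + vesicles$radius_nm

  # vesicle-vesicle and vesicle-slab intersection checks
  n <- nrow(vesicles)
  if (n > 1) {
    cen <- as.matrix(vesicles[, c("x_nm", "y_nm", "z_nm")])
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (sqrt(sum((cen[i, ] - cen[j, ])^2)) <=
          vesicles$radius_nm[i] + vesicles$radius_nm[j])
        abort(sprintf("vesicles %d and %d overlap", vesicles$id[i], vesicles$id[j]))
    }
  }
  bad <- which(vesicles$z_nm - vesicles$radius_nm <= z_top - vs / 2)
  if (length(bad))
    abort(sprintf("vesicle %d intersects the membrane slab", vesicles$id[bad[1]]))

  spec <- structure(list(
    volume_shape = volume_shape, voxel_size_nm = vs,
    membrane_thickness_nm = membrane_thickness_nm,
    membrane_z_nm = membrane_z_nm, az_extent_nm = az_extent_nm,
    density_fg = density_fg, density_bg = density_bg,
    noise_sigma = noise_sigma, wedge_halfangle_deg = wedge_halfangle_deg,
    seed = as.integer(seed), z_attach_nm = z_attach, z_mem_top_nm = z_mem_top,
    vesicles = vesicles, tethers = NULL, connectors = NULL
  ), class = "phantom_spec")

  spec$tethers <- resolve_tethers(spec, tethers)
  spec$connectors <- resolve_connectors(spec, connectors)
  validate_bridge_endpoints(spec)
  spec
}

# polyline arc length (nm)
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

resolve_tethers <- function(spec, tethers) {
  if (is.null(tethers) || nrow(tethers) == 0) return(NULL)
  tethers <- tibble::as_tibble(tethers)
  if (!"shape" %in% names(tethers)) tethers$shape <- "straight"
  if (!"az_dx_nm" %in% names(tethers)) tethers$az_dx_nm <- 0
  if (!"az_dy_nm" %in% names(tethers)) tethers$az_dy_nm <- 0
  if (!"bulge_axis" %in% names(tethers)) tethers$bulge_axis <- "x"
  if (any(tethers$radius_nm < spec$voxel_size_nm))
    abort("bridge rod radius must be at least 1 voxel")
  ves <- spec$vesicles
  purrr::pmap(tethers, function(vesicle, shape, az_dx_nm, az_dy_nm,
                                bulge_axis, radius_nm, ...) {
    v <- ves[vesicle, ]
    cen <- c(v$x_nm, v$y_nm, v$z_nm)
    att_az <- c(v$x_nm + az_dx_nm, v$y_nm + az_dy_nm, spec$z_attach_nm)
    u <- att_az - cen; u <- u / sqrt(sum(u^2))
    att_sv <- cen + v$radius_nm * u
    bulge <- if (bulge_axis == "x") c(1, 0, 0) else c(0, 1, 0)
    wp <- switch(shape,
      semicircle = semicircle_waypoints(att_sv, att_az, bulge = bulge),
      arc = arc_waypoints(att_sv, att_az, bulge = bulge, sagitta_frac = 0.25),
      rbind(att_sv, att_az))
    list(vesicle = ves$id[vesicle], attach_sv = att_sv, attach_az = att_az,
         waypoints = wp, radius_nm = radius_nm,
         length_nm = polyline_length(wp), kind = "tether")
  })
}

# exact semicircular arc between p and q bulging along `bulge`
semicircle_waypoints <- function(p, q, bulge = c(1, 0, 0), n = 65) {
  m <- (p + q) / 2
  chord <- q - p
  r <- sqrt(sum(chord^2)) / 2
  e1 <- chord / (2 * r)
  b <- bulge - sum(bulge * e1) * e1
  if (sqrt(sum(b^2)) < 1e-9) abort("bulge direction parallel to the chord")
  e2 <- b / sqrt(sum(b^2))
  th <- seq(0, pi, length.out = n)
  t(vapply(th, function(a) m - r * cos(a) * e1 + r * sin(a) * e2, numeric(3)))
}

# shallow circular arc between p and q with sagitta = sagitta_frac * chord,
# bulging along `bulge`; total turning stays moderate so the minimal
# geodesic through a rasterized tube tracks the centreline arc length
arc_waypoints <- function(p, q, bulge = c(1, 0, 0), sagitta_frac = 0.25,
                          n = 65) {
  m <- (p + q) / 2
  chord <- q - p
  c2 <- sqrt(sum(chord^2)) / 2
  e1 <- chord / (2 * c2)
  b <- bulge - sum(bulge * e1) * e1
  if (sqrt(sum(b^2)) < 1e-9) abort("bulge direction parallel to the chord")
  e2 <- b / sqrt(sum(b^2))
  s <- sagitta_frac * 2 * c2
  R <- (c2^2 + s^2) / (2 * s)
  alpha <- asin(c2 / R)
  o <- m - (R - s) * e2
  th <- seq(-alpha, alpha, length.out = n)
  t(vapply(th, function(a) o + R * (sin(a) * e1 + cos(a) * e2), numeric(3)))
}

resolve_connectors <- function(spec, connectors) {
  if (is.null(connectors) || nrow(connectors) == 0) return(NULL)
  connectors <- tibble::as_tibble(connectors)
  if (any(connectors$radius_nm < spec$voxel_size_nm))
    abort("bridge rod radius must be at least 1 voxel")
  ves <- spec$vesicles
  purrr::pmap(connectors, function(vesicle_a, vesicle_b, radius_nm, ...) {
    va <- ves[vesicle_a, ]; vb <- ves[vesicle_b, ]
    ca <- c(va$x_nm, va$y_nm, va$z_nm); cb <- c(vb$x_nm, vb$y_nm, vb$z_nm)
    u <- (cb - ca) / sqrt(sum((cb - ca)^2))
    att_a <- ca + va$radius_nm * u
    att_b <- cb - vb$radius_nm * u
    wp <- rbind(att_a, att_b)
    list(vesicle_a = ves$id[vesicle_a], vesicle_b = ves$id[vesicle_b],
         attach_a = att_a, attach_b = att_b, waypoints = wp,
         radius_nm = radius_nm, length_nm = polyline_length(wp),
         kind = "connector")
  })
}

validate_bridge_endpoints <- function(spec) {
  vs <- spec$voxel_size_nm
  ves <- spec$vesicles
  on_sphere <- function(p, id) {
    v <- ves[ves$id == id, ]
    abs(sqrt(sum((p - c(v$x_nm, v$y_nm, v$z_nm))^2)) - v$radius_nm) <= vs
  }
  half <- spec$az_extent_nm / 2
  cx <- spec$volume_shape[1] * vs / 2; cy <- spec$volume_shape[2] * vs / 2
  on_az <- function(p) {
    abs(p[3] - spec$z_attach_nm) <= vs &&
      abs(p[1] - cx) <= half + vs && abs(p[2] - cy) <= half + vs
  }
  for (te in spec$tethers) {
    if (!on_sphere(te$attach_sv, te$vesicle))
      abort(sprintf("tether endpoint not on the surface of vesicle %d", te$vesicle))
    if (!on_az(te$attach_az))
      abort("tether endpoint not on the AZ membrane surface")
  }
  for (co in spec$connectors) {
    if (!on_sphere(co$attach_a, co$vesicle_a) || !on_sphere(co$attach_b, co$vesicle_b))
      abort(sprintf("connector endpoint not on the surface of vesicle %d/%d",
                    co$vesicle_a, co$vesicle_b))
  }
  invisible(TRUE)
}

#' Generate a phantom volume with ground truth
#'
#' Rasterizes a [phantom_spec()] into a grayscale [density_volume()]
#' (membranes, vesicle shells and bridges at the foreground value, before
#' noise), a boundary-only [label_volume()], and a ground-truth table pair
#' (planted vesicles and bridges with true polyline arc lengths). Identical
#' specs, including the seed, give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `density`, `labels`, `ground_truth` (list of
#'   tibbles `vesicles` and `bridges`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$volume_shape
  vs <- spec$voxel_size_nm
  xs <- (seq_len(d[1]) - 0.5) * vs
  ys <- (seq_len(d[2]) - 0.5) * vs
  zs <- (seq_len(d[3]) - 0.5) * vs

  dens <- array(spec$density_bg, d)
  labs <- array(0L, d)

  # membrane slab + postsynaptic side
  z_lo <- spec$membrane_z_nm
  z_hi <- z_lo + spec$membrane_thickness_nm
  mem_k <- which(zs >= z_lo & zs < z_hi)
  post_k <- which(zs < z_lo)
  half <- spec$az_extent_nm / 2
  cx <- d[1] * vs / 2; cy <- d[2] * vs / 2
  in_patch <- outer(abs(xs - cx) <= half, abs(ys - cy) <= half, "&")
  for (k in mem_k) {
    labs[, , k] <- ifelse(in_patch, .LABEL_AZ, .LABEL_PLASMA)
    dens[, , k] <- spec$density_fg
  }
  for (k in post_k) labs[, , k] <- .LABEL_EXCLUDED

  # vesicles: filled spheres in labels, shells in density
  shell <- spec$membrane_thickness_nm
  for (i in seq_len(nrow(spec$vesicles))) {
    v <- spec$vesicles[i, ]
    ix <- which(abs(xs - v$x_nm) <= v$radius_nm + vs)
    iy <- which(abs(ys - v$y_nm) <= v$radius_nm + vs)
    iz <- which(abs(zs - v$z_nm) <= v$radius_nm + vs)
    if (!length(ix) || !length(iy) || !length(iz))
      abort(sprintf("vesicle %d lies outside the volume", v$id))
    dd <- sqrt(outer(outer((xs[ix] - v$x_nm)^2, (ys[iy] - v$y_nm)^2, "+"),
                     (zs[iz] - v$z_nm)^2, "+"))
    inside <- dd <= v$radius_nm
    labsub <- labs[ix, iy, iz, drop = FALSE]
    labsub[inside] <- as.integer(v$id)
    labs[ix, iy, iz] <- labsub
    densub <- dens[ix, iy, iz, drop = FALSE]
    densub[inside & dd >= v$radius_nm - shell] <- spec$density_fg
    dens[ix, iy, iz] <- densub
  }

  # bridges: tubes around waypoint polylines (density only)
  for (br in c(spec$tethers, spec$connectors))
    dens <- rasterize_tube(dens, br$waypoints, br$radius_nm, spec, xs, ys, zs)

  gt_ves <- tibble(
    vesicle_id = spec$vesicles$id,
    x_nm = spec$vesicles$x_nm, y_nm = spec$vesicles$y_nm,
    z_nm = spec$vesicles$z_nm,
    radius_nm = spec$vesicles$radius_nm,
    distance_nm = spec$vesicles$distance_nm
  )
  bridges <- c(spec$tethers, spec$connectors)
  gt_br <- if (length(bridges)) tibble(
    bridge_id = seq_along(bridges),
    kind = purrr::map_chr(bridges, "kind"),
    vesicle_a = purrr::map_int(bridges, function(b)
      as.integer(b$vesicle %||% b$vesicle_a)),
    vesicle_b = purrr::map_int(bridges, function(b)
      if (identical(b$kind, "connector")) as.integer(b$vesicle_b) else NA_integer_),
    length_nm = purrr::map_dbl(bridges, "length_nm"),
    rod_radius_nm = purrr::map_dbl(bridges, "radius_nm")
  ) else tibble(bridge_id = integer(0), kind = character(0),
                vesicle_a = integer(0), vesicle_b = integer(0),
                length_nm = numeric(0), rod_radius_nm = numeric(0))

  density <- density_volume(dens, vs, structure_low = TRUE)
  if (spec$noise_sigma > 0) {
    sigma_abs <- spec$noise_sigma * (spec$density_bg - spec$density_fg)
    density <- add_noise(density, sigma_abs, seed = spec$seed)
  }
  if (spec$wedge_halfangle_deg > 0 && spec$wedge_halfangle_deg < 90)
    density <- apply_missing_wedge(density, spec$wedge_halfangle_deg)

  list(density = density,
       labels = label_volume(labs, vs),
       ground_truth = list(vesicles = gt_ves, bridges = gt_br))
}

# mark tube voxels (min distance to the polyline <= rod radius) as foreground
rasterize_tube <- function(dens, wp, rod_nm, spec, xs, ys, zs) {
  pad <- rod_nm + spec$voxel_size_nm
  ix <- which(xs >= min(wp[, 1]) - pad & xs <= max(wp[, 1]) + pad)
  iy <- which(ys >= min(wp[, 2]) - pad & ys <= max(wp[, 2]) + pad)
  iz <- which(zs >= min(wp[, 3]) - pad & zs <= max(wp[, 3]) + pad)
  if (!length(ix) || !length(iy) || !length(iz)) return(dens)
  pts <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(wp) - 1)) {
    a <- wp[s, ]; b <- wp[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
                            (pts[, 3] - a[3]) * ab[3]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dz <- pts[, 3] - (a[3] + t * ab[3])
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy + dz * dz))
  }
  sub <- dens[ix, iy, iz, drop = FALSE]
  sub[array(dmin <= rod_nm, dim(sub))] <- spec$density_fg
  dens[ix, iy, iz] <- sub
  dens
}

#' Add seeded Gaussian noise to a density volume
#'
#' @param vol A [density_volume()].
#' @param sigma Noise standard deviation (same units as the density values).
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return A [density_volume()] with `vol + N(0, sigma^2)` values;
#'   `sigma = 0` returns the input unchanged.
#' @export
add_noise <- function(vol, sigma, seed = 1L) {
  stopifnot(inherits(vol, "density_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    abort("`sigma` must be a single number >= 0")
  if (sigma == 0) return(vol)
  noisy <- vol
  noisy$values <- vol$values + local_seed(seed, array(rnorm(length(vol$values),
                                                            sd = sigma),
                                                      dim(vol$values)))
  noisy
}

# evaluate `code` under `set.seed(seed)` and restore the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Apply a missing-wedge Fourier filter
#'
#' Emulates the anisotropic resolution of limited-tilt tomography: Fourier
#' coefficients in the unsampled wedge are zeroed and the volume is
#' transformed back. With tilt axis `y` and beam axis `z`, a tilt series
#' covering +/- `halfangle_deg` samples every spatial frequency whose
#' direction in the x-z plane lies within `halfangle_deg` of the x axis;
#' the rest (the wedge around the z axis) is removed, elongating features
#' along z. `halfangle_deg` of 90 or more means full coverage and returns
#' the volume unchanged.
#'
#' @param vol A [density_volume()].
#' @param halfangle_deg Half-range of the sampled tilt series, degrees, in
#'   (0, 90].
#' @param tilt_axis `"x"` or `"y"`.
#' @return Filtered [density_volume()] (real-valued; total energy never
#'   increases).
#' @export
apply_missing_wedge <- function(vol, halfangle_deg, tilt_axis = "y") {
  stopifnot(inherits(vol, "density_volume"))
  if (!is.numeric(halfangle_deg) || length(halfangle_deg) != 1L ||
      is.na(halfangle_deg) || halfangle_deg <= 0)
    abort("`halfangle_deg` must be a single number in (0, 90]")
  if (!tilt_axis %in% c("x", "y")) abort("degenerate tilt axis")
  if (halfangle_deg >= 90 - 1e-9) return(vol)
  d <- dim(vol$values)
  freqs <- function(n) {
    k <- c(0:floor(n / 2), if (n > 1) -(ceiling(n / 2) - 1):-1) / n
    k[seq_len(n)]
  }
  kx <- freqs(d[1]); ky <- freqs(d[2]); kz <- freqs(d[3])
  # angle from the in-plane axis perpendicular to the tilt axis
  ang <- atan2(abs(rep(kz, each = d[1] * d[2])),
               abs(if (tilt_axis == "y")
                 rep(kx, times = d[2] * d[3])
                 else rep(rep(ky, each = d[1]), times = d[3]))) * 180 / pi
  keep <- array(ang <= halfangle_deg, d)
  ft <- fft(vol$values)
  ft[!keep] <- 0
  out <- vol
  out$values <- Re(fft(ft, inverse = TRUE)) / prod(d)
  out
}

#' Canonical study phantoms
#'
#' [example_phantom_spec()] is the package's reference recovery target: a
#' 128^3 volume at 1.4 nm/voxel holding six vesicles at AZ distances of 3
#' to 18 nm, eight tethers (one semicircular, so chord < span < geodesic)
#' and four connectors, noiseless by default so planted structures are the
#' only density. [noisy_phantom_spec()] is a smaller (64^3) two-vesicle
#' variant with noise at the default SNR, used for noise-robustness
#' properties.
#'
#' @param noise_sigma Noise level in contrast units.
#' @param seed RNG seed for the noise realization.
#' @return A [phantom_spec()].
#' @export
example_phantom_spec <- function(noise_sigma = 0, seed = 1L) {
  vesicles <- tibble(
    x_nm = c(30, 90, 150, 30, 90, 150),
    y_nm = c(45, 45, 45, 135, 135, 135),
    radius_nm = 20,
    distance_nm = c(3, 6, 9, 12, 15, 18))
  tethers <- tibble(
    vesicle   = c(1, 1, 2, 3, 4, 4, 5, 6),
    shape     = c("straight", "straight", "straight", "straight",
                  "straight", "straight", "arc", "straight"),
    az_dx_nm  = c(0, 14, 0, 0, 0, -14, 0, 0),
    az_dy_nm  = c(0, 0, 0, 0, 0, 0, 0, 6),
    bulge_axis = "x",
    radius_nm = c(2.1, 2.1, 2.1, 2.1, 2.1, 2.1, 1.4, 2.1))
  connectors <- tibble(
    vesicle_a = c(1, 2, 4, 5),
    vesicle_b = c(2, 3, 5, 6),
    radius_nm = 2.1)
  phantom_spec(volume_shape = c(128, 128, 128), voxel_size_nm = 1.4,
               vesicles = vesicles, tethers = tethers,
               connectors = connectors, az_extent_nm = 160,
               noise_sigma = noise_sigma, seed = seed)
}

#' @rdname example_phantom_spec
#' @export
noisy_phantom_spec <- function(noise_sigma = 0.5, seed = 1L) {
  vesicles <- tibble(
    x_nm = c(28, 62), y_nm = c(45, 45), radius_nm = 16,
    distance_nm = c(5, 12))
  tethers <- tibble(
    vesicle = c(1, 2), shape = "straight",
    az_dx_nm = 0, az_dy_nm = 0, bulge_axis = "x", radius_nm = 2.5)
  connectors <- tibble(vesicle_a = 1, vesicle_b = 2, radius_nm = 2.5)
  phantom_spec(volume_shape = c(64, 64, 64), voxel_size_nm = 1.4,
               vesicles = vesicles, tethers = tethers,
               connectors = connectors, az_extent_nm = 76,
               noise_sigma = noise_sigma, seed = seed)
}
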