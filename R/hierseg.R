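#' Delimit the presynaptic analysis region
#'
#' The analysis region is the presynaptic cytoplasm within a maximal
#' Euclidean distance of the AZ membrane (250 nm in the default
#' configuration), excluding every boundary voxel (membranes, vesicles,
#' postsynaptic side). The exact Euclidean distance map to the AZ membrane
#' is computed once and carried along for reuse by the distance and layer
#' measurements.
#'
#' @param labels A [label_volume()] with a nonempty AZ membrane (id 1).
#' @param max_dist_nm Maximal distance from the AZ membrane, nm.
#' @param include_vesicles If `TRUE`, vesicle voxels (ids >= 10) are part
#'   of the region (used by the layer-occupancy analysis, which measures
#'   the fraction of cytoplasmic volume occupied by vesicles); membranes
#'   and the postsynaptic side are always excluded.
#' @return An `az_region` object: logical `mask` array, numeric `dist_vox`
#'   array (distance to the nearest AZ voxel centre, voxel units), and the
#'   voxel size.
#' @export
analysis_region <- function(labels, max_dist_nm, include_vesicles = FALSE) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$values)
  az <- labels$values == .LABEL_AZ
  if (!any(az)) abort("empty AZ membrane label (id 1)")
  dist_vox <- array(cpp_edt(as.vector(az), d), d)
  vs <- labels$voxel_size_nm
  allowed <- labels$values == .LABEL_BACKGROUND
  if (include_vesicles)
    allowed <- allowed | labels$values >= .LABEL_VESICLE_MIN
  mask <- allowed & dist_vox > 0 & dist_vox * vs <= max_dist_nm
  structure(list(mask = mask, dist_vox = dist_vox, voxel_size_nm = vs,
                 max_dist_nm = max_dist_nm),
            class = "az_region")
}

#' Build a grayscale threshold schedule
#'
#' Either an explicit, strictly increasing list of absolute thresholds, or
#' a quantile ladder over the analysis region's density values (the
#' default: 24 evenly spaced quantiles between probabilities 0.02 and 0.5,
#' which is invariant to the volume's contrast scaling). At least two
#' thresholds are required.
#'
#' @param density A [density_volume()].
#' @param region An `az_region` from [analysis_region()] (required for the
#'   quantile rule).
#' @param k Number of thresholds in the quantile ladder.
#' @param probs Length-2 probability range of the ladder.
#' @param absolute Optional explicit numeric thresholds (overrides the
#'   quantile rule).
#' @return Sorted numeric vector of thresholds, class `threshold_schedule`.
#' @export
threshold_schedule <- function(density = NULL, region = NULL, k = 24,
                               probs = c(0.02, 0.5), absolute = NULL) {
  if (!is.null(absolute)) {
    tt <- as.numeric(absolute)
    if (length(tt) < 2L || any(diff(tt) <= 0))
      abort("thresholds must be strictly increasing, K >= 2")
    return(structure(tt, class = "threshold_schedule"))
  }
  stopifnot(inherits(density, "density_volume"), inherits(region, "az_region"))
  vals <- density$values[region$mask]
  tt <- unname(quantile(vals, probs = seq(probs[1], probs[2], length.out = k)))
  tt <- unique(tt)
  if (length(tt) < 2L)
    abort("quantile ladder degenerates to < 2 distinct thresholds; supply `absolute`")
  structure(tt, class = "threshold_schedule")
}

#' Classify a boundary-contact signature
#'
#' A segment linking exactly one vesicle to the AZ membrane is a tether; a
#' segment linking exactly two vesicles and no membrane is a connector.
#' Everything else (a single boundary, three or more boundaries, or a
#' vesicle linked only to non-AZ membrane) is rejected rather than split.
#'
#' @param boundaries Integer vector of contacted boundary label ids.
#' @return `"tether"`, `"connector"` or `"rejected"`.
#' @examples
#' classify_segment(c(12, 1))   # tether
#' classify_segment(c(12, 13))  # connector
#' classify_segment(c(12, 13, 1))  # rejected
#' @export
classify_segment <- function(boundaries) {
  s <- sort(unique(as.integer(boundaries)))
  ves <- s[s >= .LABEL_VESICLE_MIN]
  if (length(s) == 2L && .LABEL_AZ %in% s && length(ves) == 1L) return("tether")
  if (length(s) == 2L && length(ves) == 2L) return("connector")
  "rejected"
}

#' Hierarchical connectivity segmentation
#'
#' Detects tethers and connectors as connected clusters of dense voxels
#' linking two boundaries. Foreground at threshold `t` is the set of region
#' voxels with density `<= t` (structure-low contrast); 26-connected
#' components are computed at every threshold of the schedule in ascending
#' order; a component is valid when its boundary-contact signature (26-
#' adjacency to label voxels) classifies as tether or connector, and every
#' reported segment is the component at the *lowest* threshold at which it
#' is valid — its "core". Components at higher thresholds that contain an
#' already-reported core are represented by that core alone, so reported
#' segments are mutually disjoint.
#'
#' @param density A [density_volume()] (structure-low contrast).
#' @param labels The aligned [label_volume()].
#' @param region An `az_region` from [analysis_region()].
#' @param schedule A [threshold_schedule()].
#' @return A tibble with one row per segment: `segment_id`, `kind`,
#'   `validity_threshold`, `n_voxels`, `boundary_a`, `boundary_b`, and
#'   list-columns `voxels` (1-based linear indices), `contacts_a`,
#'   `contacts_b` (contact voxel indices adjacent to each boundary).
#'   `length_nm` is `NA` until filled by [measure_segments()].
#' @export
connectivity_segmentation <- function(density, labels, region, schedule) {
  stopifnot(inherits(density, "density_volume"), inherits(labels, "label_volume"),
            inherits(region, "az_region"))
  check_aligned(density, labels)
  if (!density$structure_low)
    abort("density contrast convention is not structure-low; segmentation thresholds from below")
  if (!any(region$mask)) abort("empty analysis region")
  d <- dim(density$values)
  vals <- density$values[region$mask]
  rng <- range(vals)
  if (rng[1] == rng[2]) return(empty_segments())   # uniform region: no structure
  tt <- as.numeric(schedule)
  if (max(tt) < rng[1] || min(tt) > rng[2])
    abort(sprintf(
      "threshold schedule [%.4g, %.4g] lies outside the region density range [%.4g, %.4g]",
      min(tt), max(tt), rng[1], rng[2]))

  reported <- array(FALSE, d)
  out <- list()
  seg_id <- 0L
  labvec <- as.vector(labels$values)
  for (t in tt) {
    fg <- region$mask & density$values <= t
    if (!any(fg)) next
    complab <- cpp_label_mask(as.vector(fg), d)
    contacts <- cpp_component_contacts(complab, labvec, d)
    if (!nrow(contacts)) next
    sig <- split(contacts, contacts$component)
    for (cc in sig) {
      kind <- classify_segment(cc$boundary)
      if (kind == "rejected") next
      comp <- cc$component[1]
      vox <- which(complab == comp)
      if (any(reported[vox])) next   # already represented by a lower core
      seg_id <- seg_id + 1L
      reported[vox] <- TRUE
      bids <- sort(unique(cc$boundary))
      out[[seg_id]] <- list(
        segment_id = seg_id, kind = kind, validity_threshold = t,
        n_voxels = length(vox),
        boundary_a = bids[1], boundary_b = bids[2],
        voxels = as.numeric(vox),
        contacts_a = as.numeric(sort(unique(cc$voxel[cc$boundary == bids[1]]))),
        contacts_b = as.numeric(sort(unique(cc$voxel[cc$boundary == bids[2]])))
      )
    }
  }
  if (!length(out)) return(empty_segments())
  tibble(
    segment_id = purrr::map_int(out, "segment_id"),
    kind = purrr::map_chr(out, "kind"),
    validity_threshold = purrr::map_dbl(out, "validity_threshold"),
    n_voxels = purrr::map_int(out, "n_voxels"),
    boundary_a = purrr::map_int(out, function(x) as.integer(x$boundary_a)),
    boundary_b = purrr::map_int(out, function(x) as.integer(x$boundary_b)),
    voxels = purrr::map(out, "voxels"),
    contacts_a = purrr::map(out, "contacts_a"),
    contacts_b = purrr::map(out, "contacts_b"),
    length_nm = NA_real_
  )
}

empty_segments <- function() {
  tibble(segment_id = integer(0), kind = character(0),
         validity_threshold = numeric(0), n_voxels = integer(0),
         boundary_a = integer(0), boundary_b = integer(0),
         voxels = list(), contacts_a = list(), contacts_b = list(),
         length_nm = numeric(0))
}

#' Export detected segments as a label volume
#'
#' Writes each segment's voxels into an integer volume for visualization,
#' using ids from the reserved segment range (>= 1000).
#'
#' @param segments Segment tibble from [connectivity_segmentation()].
#' @param labels The boundary [label_volume()] the segments were detected
#'   against (supplies shape and voxel size).
#' @return A [label_volume()] containing boundaries plus segments.
#' @export
segment_labels <- function(segments, labels) {
  vals <- labels$values
  for (i in seq_len(nrow(segments)))
    vals[segments$voxels[[i]]] <- .LABEL_SEGMENT_MIN + segments$segment_id[i] - 1L
  label_volume(vals, labels$voxel_size_nm, labels$origin)
}
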