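#' Pipeline configuration
#'
#' Collects the analysis parameters with the field's standard defaults:
#' zones at 45/75/250 nm, tether length classes at 6/12/24 nm, tethering
#' states at 5/10 nm, a 250 nm analysis range, and the segmentation
#' threshold schedule (quantile ladder unless absolute thresholds are
#' given). All bound vectors must be strictly increasing.
#'
#' @param zones_nm Proximal/intermediate/distal zone bounds.
#' @param tether_bounds_nm Tether length class bounds.
#' @param state_bounds_nm Tethering-state distance bounds.
#' @param analysis_range_nm Maximal distance from the AZ membrane.
#' @param schedule_k,schedule_probs Quantile-ladder parameters.
#' @param schedule_absolute Optional absolute threshold list.
#' @param orientation_tolerance_deg Tolerance for
#'   [equalize_orientation()].
#' @param welch Use Welch's t test in comparisons.
#' @param seed Base RNG seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(zones_nm = c(45, 75, 250),
                       tether_bounds_nm = c(6, 12, 24),
                       state_bounds_nm = c(5, 10),
                       analysis_range_nm = 250,
                       schedule_k = 24, schedule_probs = c(0.02, 0.5),
                       schedule_absolute = NULL,
                       orientation_tolerance_deg = 5,
                       welch = FALSE,
                       seed = 1L) {
  for (b in list(zones_nm, tether_bounds_nm, state_bounds_nm))
    if (any(diff(b) <= 0)) abort("bounds must be strictly increasing")
  structure(list(zones_nm = zones_nm, tether_bounds_nm = tether_bounds_nm,
                 state_bounds_nm = state_bounds_nm,
                 analysis_range_nm = analysis_range_nm,
                 schedule_k = schedule_k, schedule_probs = schedule_probs,
                 schedule_absolute = schedule_absolute,
                 orientation_tolerance_deg = orientation_tolerance_deg,
                 welch = isTRUE(welch), seed = as.integer(seed)),
            class = "run_config")
}

#' Analyse one synapse volume
#'
#' Runs the fixed stage order — analysis region, hierarchical connectivity
#' segmentation, segment classification, geodesic lengths, vesicle
#' distances, bridge counts, layer profile, AZ area and surface
#' concentration — and returns every stage's table. Reruns on identical
#' input are bit-for-bit reproducible.
#'
#' @param density A [density_volume()].
#' @param labels The aligned [label_volume()].
#' @param config A [run_config()].
#' @param synapse_id Identifier recorded in every table.
#' @param condition Condition label.
#' @param orientation_deg Synapse orientation angle (membrane normal vs the
#'   x axis, degrees).
#' @return An `svt_synapse` list: `vesicles`, `segments`, `layers`,
#'   `synapse` (one-row summary).
#' @export
run_synapse <- function(density, labels, config = run_config(),
                        synapse_id = "syn1", condition = NA_character_,
                        orientation_deg = NA_real_) {
  check_aligned(density, labels)
  region <- analysis_region(labels, config$analysis_range_nm)
  sched <- threshold_schedule(density, region, k = config$schedule_k,
                              probs = config$schedule_probs,
                              absolute = config$schedule_absolute)
  segments <- connectivity_segmentation(density, labels, region, sched)
  segments <- measure_segments(segments, dim(density$values),
                               density$voxel_size_nm)
  if (nrow(segments))
    segments$tether_class <- ifelse(
      segments$kind == "tether",
      classify_tether(segments$length_nm, config$tether_bounds_nm),
      NA_character_)
  vesicles <- vesicle_table(labels, region, config$state_bounds_nm)
  vesicles <- count_bridges(vesicles, segments)
  vesicles$distance_class <- vesicles$state
  region_sv <- analysis_region(labels, config$analysis_range_nm,
                               include_vesicles = TRUE)
  layers <- layer_profile(labels, region_sv, config$zones_nm)
  area <- az_area(labels)
  n_prox <- sum(vesicles$distance_nm < config$zones_nm[1])
  syn <- tibble(
    synapse_id = synapse_id, condition = condition,
    orientation_deg = orientation_deg, az_area_nm2 = area,
    n_vesicles = nrow(vesicles), n_proximal = n_prox,
    n_tethers = sum(segments$kind == "tether"),
    n_connectors = sum(segments$kind == "connector"),
    surface_concentration_um2 = surface_concentration(n_prox, area))
  vesicles <- dplyr::mutate(vesicles, synapse_id = synapse_id,
                            .before = 1)
  segments <- dplyr::mutate(segments, synapse_id = synapse_id, .before = 1)
  structure(list(vesicles = vesicles, segments = segments, layers = layers,
                 synapse = syn, config = config),
            class = "svt_synapse")
}

#' Run a multi-synapse, multi-condition study
#'
#' Pools per-synapse results across conditions, equalizes mean synapse
#' orientations before any tether/connector analysis (removed synapses are
#' dropped from bridge-related variables only; distance and layer analyses
#' keep all synapses), aggregates, and runs the planned comparisons.
#'
#' @param synapses List of `svt_synapse` results (with condition and
#'   orientation set).
#' @param design A [comparison_design()]; `NULL` builds a default design
#'   comparing every consecutive condition pair on the standard variables
#'   (SV distance: t; fraction of proximal SVs < 10 nm: chi-squared;
#'   tether length: t; tethers and connectors per vesicle: Kruskal-Wallis).
#' @param config A [run_config()].
#' @return An `svt_study` list: `comparisons`, `vesicles`, `segments`,
#'   `synapses`, `removals`, `manifest`.
#' @export
run_study <- function(synapses, design = NULL, config = run_config()) {
  stopifnot(length(synapses) > 0)
  syn_tbl <- dplyr::bind_rows(purrr::map(synapses, "synapse"))
  ves <- dplyr::bind_rows(purrr::map(synapses, "vesicles"))
  seg <- dplyr::bind_rows(purrr::map(synapses, "segments"))
  ves <- dplyr::left_join(ves,
                          syn_tbl[, c("synapse_id", "condition")],
                          by = "synapse_id", suffix = c("", ".syn"))
  seg <- dplyr::left_join(seg, syn_tbl[, c("synapse_id", "condition")],
                          by = "synapse_id", suffix = c("", ".syn"))

  eq <- if (all(is.finite(syn_tbl$orientation_deg))) {
    equalize_orientation(syn_tbl, config$orientation_tolerance_deg)
  } else list(kept = syn_tbl, removed = syn_tbl[0, ], converged = TRUE)
  bridge_ok <- eq$kept$synapse_id
  seg_eq <- seg[seg$synapse_id %in% bridge_ok, ]
  ves_bridge <- ves[ves$synapse_id %in% bridge_ok, ]

  conditions <- unique(syn_tbl$condition)
  if (is.null(design) && length(conditions) >= 2) {
    prs <- tibble(group_a = conditions[-length(conditions)],
                  group_b = conditions[-1])
    pairs <- dplyr::bind_rows(
      dplyr::mutate(prs, variable = "sv_distance_nm", test = "t"),
      dplyr::mutate(prs, variable = "sv_within_10nm", test = "chisq"),
      dplyr::mutate(prs, variable = "tether_length_nm", test = "t"),
      dplyr::mutate(prs, variable = "n_tethers", test = "kruskal"),
      dplyr::mutate(prs, variable = "n_connectors", test = "kruskal"))
    design <- comparison_design(pairs, welch = config$welch)
  }
  prox <- ves[ves$distance_nm < config$zones_nm[1], ]
  long <- dplyr::bind_rows(
    tibble(variable = "sv_distance_nm", group = prox$condition,
           value = prox$distance_nm),
    tibble(variable = "sv_within_10nm", group = prox$condition,
           value = as.numeric(prox$distance_nm < 10)),
    if (nrow(seg_eq)) tibble(
      variable = "tether_length_nm",
      group = seg_eq$condition[seg_eq$kind == "tether"],
      value = seg_eq$length_nm[seg_eq$kind == "tether"]),
    tibble(variable = "n_tethers",
           group = ves_bridge$condition, value = ves_bridge$n_tethers),
    tibble(variable = "n_connectors",
           group = ves_bridge$condition, value = ves_bridge$n_connectors))
  comparisons <- if (!is.null(design)) {
    keep <- purrr::pmap_lgl(design$pairs, function(variable, group_a, group_b, ...) {
      sum(long$variable == variable & long$group == group_a) > 0 &&
        sum(long$variable == variable & long$group == group_b) > 0
    })
    design$pairs <- design$pairs[keep, ]
    if (nrow(design$pairs)) compare_groups(long, design) else NULL
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("svtether")),
    schema_version = .RESULT_SCHEMA_VERSION,
    config = unclass(config),
    conditions = conditions,
    removed_synapses = eq$removed$synapse_id)
  structure(list(comparisons = comparisons, vesicles = ves, segments = seg,
                 synapses = syn_tbl, removals = eq$removed,
                 manifest = manifest),
            class = "svt_study")
}
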