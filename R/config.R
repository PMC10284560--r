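#' Read a phantom spec or run configuration from a YAML file
#'
#' Key/value configuration mirrors the constructor arguments one-to-one.
#' A phantom file holds the scalar fields of [phantom_spec()] plus
#' `vesicles`, `tethers` and `connectors` as lists of records; a run file
#' holds the fields of [run_config()]. Unknown keys are rejected so typos
#' never pass silently.
#'
#' ```yaml
#' # phantom.yml
#' volume_shape: [64, 64, 64]
#' voxel_size_nm: 1.4
#' noise_sigma: 0.5
#' vesicles:
#'   - {x_nm: 28, y_nm: 45, radius_nm: 16, distance_nm: 5}
#' tethers:
#'   - {vesicle: 1, shape: straight, az_dx_nm: 0, az_dy_nm: 0,
#'      bulge_axis: x, radius_nm: 2.5}
#' ```
#'
#' @param path YAML file path.
#' @return [read_phantom_spec()] returns a [phantom_spec()];
#'   [read_run_config()] a [run_config()].
#' @export
read_phantom_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- function(x) if (is.null(x)) NULL else dplyr::bind_rows(x)
  known <- union(names(formals(phantom_spec)), character(0))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    abort(paste("unknown phantom config keys:", paste(bad, collapse = ", ")))
  cfg$vesicles <- tab(cfg$vesicles)
  cfg$tethers <- tab(cfg$tethers)
  cfg$connectors <- tab(cfg$connectors)
  cfg$volume_shape <- as.integer(unlist(cfg$volume_shape))
  do.call(phantom_spec, cfg)
}

#' @rdname read_phantom_spec
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    abort(paste("unknown run config keys:", paste(bad, collapse = ", ")))
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  do.call(run_config, cfg)
}
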