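#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summary methods for pipeline results
#'
#' `tidy()` on a comparison table returns it as a plain tibble; on a study
#' it returns the comparison table; on a CDF object the regions of steep
#' increase. `glance()` on a study gives one-row totals.
#'
#' @param x An `svt_comparisons`, `svt_study` or `svt_cdf` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy svt_comparisons
#' @export
tidy.svt_comparisons <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "svt_comparisons")
  tibble::as_tibble(out)
}

#' @rdname tidy.svt_comparisons
#' @method tidy svt_study
#' @export
tidy.svt_study <- function(x, ...) {
  if (is.null(x$comparisons)) return(tibble())
  tidy(x$comparisons)
}

#' @rdname tidy.svt_comparisons
#' @method tidy svt_cdf
#' @export
tidy.svt_cdf <- function(x, ...) x$regions

#' @rdname tidy.svt_comparisons
#' @method glance svt_study
#' @export
glance.svt_study <- function(x, ...) {
  tibble(n_synapses = nrow(x$synapses),
         n_conditions = length(unique(x$synapses$condition)),
         n_vesicles = nrow(x$vesicles),
         n_tethers = sum(x$segments$kind == "tether"),
         n_connectors = sum(x$segments$kind == "connector"),
         n_removed = nrow(x$removals),
         n_comparisons = if (is.null(x$comparisons)) 0L else nrow(x$comparisons))
}

#' Plot a layer occupancy profile
#'
#' Vesicle-occupied volume fraction per 1-voxel layer against distance to
#' the AZ membrane, with the zone bounds marked.
#'
#' @param x A `layer_profile`.
#' @param zones_nm Zone bounds to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_layer_profile <- function(x, zones_nm = c(45, 75, 250), ...) {
  stopifnot(inherits(x, "layer_profile"))
  df <- x$layers
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$dist_lo_nm + .data$dist_hi_nm) / 2,
                                   y = .data$phi)) +
    ggplot2::geom_col(width = x$voxel_size_nm, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = zones_nm, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "distance to AZ membrane (nm)",
                  y = "volume fraction occupied by SVs") +
    ggplot2::theme_minimal()
}

#' @rdname plot_layer_profile
#' @method autoplot layer_profile
#' @export
autoplot.layer_profile <- function(x, ...) plot_layer_profile(x, ...)

#' Plot an empirical CDF with its inflection regions
#'
#' @param x An `svt_cdf` from [cdf_and_inflection()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot svt_cdf
#' @export
autoplot.svt_cdf <- function(x, ...) {
  df <- tibble(grid = x$grid, cdf = x$cdf)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$grid, .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "value (nm)", y = "cumulative fraction") +
    ggplot2::theme_minimal()
  if (is.finite(x$inflection_nm))
    p <- p + ggplot2::geom_vline(xintercept = x$inflection_nm,
                                 linetype = "dashed", colour = "firebrick")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
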