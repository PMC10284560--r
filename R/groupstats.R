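#' Aggregate a variable within experimental groups
#'
#' Per-structure variables (per-vesicle distances, per-tether lengths, ...)
#' are pooled across the synapses of a group; per-synapse fraction
#' variables are summarized as the mean of synapse means with the SEM
#' between synapse means. With a single observation the SEM is undefined
#' and reported as `NA`, never as 0.
#'
#' @param data Tibble of observations.
#' @param value Column (tidy-eval) holding the variable.
#' @param group Column (tidy-eval) holding the group/condition label.
#' @return Tibble with `group`, `n`, `mean`, `sem`.
#' @examples
#' aggregate_groups(tibble::tibble(g = c("a", "a"), f = c(0.4, 0.6)), f, g)
#' @export
aggregate_groups <- function(data, value, group) {
  data |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sem = ifelse(dplyr::n() >= 2,
                   sd({{ value }}) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop")
}

#' Define the planned comparison design
#'
#' Statistical testing is restricted to a configured set of planned,
#' orthogonal pairs — no all-versus-all expansion, and consequently no
#' multiple-testing correction. Each row names the variable, the two
#' groups, and the test matched to the variable kind: `"t"` for
#' continuous approximately normal values, `"kruskal"` for per-vesicle
#' counts and other non-normal values, `"chisq"` for frequencies, and
#' `"pearson"` for associations. All tests are two-tailed.
#'
#' @param pairs Tibble with columns `variable`, `group_a`, `group_b`,
#'   `test`.
#' @param welch Use Welch's unequal-variance t test instead of Student's.
#' @return A `comparison_design` object.
#' @export
comparison_design <- function(pairs, welch = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("variable", "group_a", "group_b", "test")
  if (!all(need %in% names(pairs)))
    abort(paste("`pairs` needs columns", paste(need, collapse = ", ")))
  bad <- setdiff(unique(pairs$test), c("t", "kruskal", "chisq", "pearson"))
  if (length(bad)) abort(paste("unknown test:", paste(bad, collapse = ", ")))
  structure(list(pairs = pairs, welch = isTRUE(welch), two_tailed = TRUE),
            class = "comparison_design")
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "ns")
}

#' Compare two groups on one variable
#'
#' Two-sample tests as configured in the [comparison_design()]: Student's
#' (or Welch's) t test, the Kruskal-Wallis rank test (kept for two groups),
#' or the Pearson chi-squared test without continuity correction for
#' binary frequency variables. Degenerate inputs are handled explicitly:
#' zero variance in both groups yields p = 1 with a warning for the t test;
#' chi-squared results with an expected cell below 5 (or 1) carry a flag.
#'
#' @param a,b Numeric (or logical, for `"chisq"`) observation vectors.
#' @param test `"t"`, `"kruskal"` or `"chisq"`.
#' @param welch Welch t test flag.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `stars`,
#'   `n_a`, `n_b`, `flag`.
#' @export
compare_pair <- function(a, b, test = c("t", "kruskal", "chisq"),
                         welch = FALSE) {
  test <- match.arg(test)
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  flag <- NA_character_
  if (test == "t") {
    if (sd(a) == 0 && sd(b) == 0) {
      warn("zero variance in both groups; reporting p = 1")
      stat <- 0; p <- 1
    } else {
      ht <- t.test(a, b, var.equal = !welch)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else if (test == "kruskal") {
    if (length(unique(c(a, b))) == 1L) {
      warn("all observations identical; reporting p = 1")
      stat <- 0; p <- 1
    } else {
      ht <- kruskal.test(list(a, b))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
    if (any(ht$expected < 1)) {
      warn("chi-squared expected cell < 1")
      flag <- "expected<1"
    } else if (any(ht$expected < 5)) flag <- "expected<5"
  }
  tibble(test = test, statistic = stat, p_value = p, stars = p_stars(p),
         n_a = length(a), n_b = length(b), flag = flag)
}

#' @rdname compare_pair
#' @param x,y Paired numeric vectors for the Pearson association test.
#' @export
correlate_pair <- function(x, y) {
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(test = "pearson", statistic = unname(ht$estimate),
         p_value = ht$p.value, stars = p_stars(ht$p.value),
         n_a = sum(complete.cases(x, y)), n_b = sum(complete.cases(x, y)),
         flag = NA_character_)
}

#' Run every planned comparison of a design
#'
#' @param data Long tibble with one row per structure/synapse observation
#'   and columns `variable` (name), `group`, `value`.
#' @param design A [comparison_design()].
#' @return `svt_comparisons` tibble: design columns plus test results.
#' @export
compare_groups <- function(data, design) {
  stopifnot(inherits(design, "comparison_design"))
  res <- purrr::pmap(design$pairs, function(variable, group_a, group_b, test) {
    a <- data$value[data$variable == variable & data$group == group_a]
    b <- data$value[data$variable == variable & data$group == group_b]
    if (test == "chisq") { a <- as.logical(a); b <- as.logical(b) }
    dplyr::bind_cols(
      tibble(variable = variable, group_a = group_a, group_b = group_b),
      compare_pair(a, b, test, welch = design$welch))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("svt_comparisons", class(out))
  out
}

#' Empirical CDF and its inflection points
#'
#' Computes the empirical cumulative distribution of a sample, smooths it
#' with a fixed-bandwidth moving average, and locates the regions of steep
#' increase: maximal contiguous intervals where the smoothed derivative
#' exceeds half its maximum. Each region's midpoint is an inflection point;
#' the midpoint of the longest region is the primary one. For a flat
#' (uniform-like) derivative — when the above-half-maximum region covers
#' most of the data range — no inflection is reported rather than an
#' arbitrary midpoint.
#'
#' @param values Numeric sample (nm).
#' @param bandwidth_nm Moving-average bandwidth, nm (default 1).
#' @param flat_fraction Fraction of the data range above which the steep
#'   region is considered flat (default 0.75).
#' @return An `svt_cdf` object: `grid`, `cdf`, `deriv`, tibble `regions`
#'   (`lo`, `hi`, `midpoint`), and `inflection_nm` (`NA` when flat).
#' @export
cdf_and_inflection <- function(values, bandwidth_nm = 1, flat_fraction = 0.75) {
  values <- values[is.finite(values)]
  if (length(values) < 5) abort("need at least 5 values")
  h <- bandwidth_nm / 4
  grid <- seq(min(values) - bandwidth_nm, max(values) + bandwidth_nm, by = h)
  F <- stats::ecdf(values)(grid)
  w <- max(3L, 2L * floor(bandwidth_nm / (2 * h)) + 1L)   # odd window
  Fs <- stats::filter(F, rep(1 / w, w), sides = 2)
  Fs[is.na(Fs)] <- F[is.na(Fs)]
  deriv <- c(NA, diff(Fs) / h)
  deriv[1] <- deriv[2]
  steep <- deriv > max(deriv, na.rm = TRUE) / 2
  steep[is.na(steep)] <- FALSE
  r <- rle(as.vector(steep))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- tibble(
    lo = grid[starts[r$values]], hi = grid[ends[r$values]]) |>
    dplyr::mutate(midpoint = (.data$lo + .data$hi) / 2,
                  width = .data$hi - .data$lo)
  rng <- diff(range(values))
  flat <- sum(regions$width) >= flat_fraction * rng
  inflection <- if (flat || !nrow(regions)) NA_real_
  else regions$midpoint[which.max(regions$width)]
  structure(list(grid = grid, cdf = F, deriv = as.numeric(deriv),
                 regions = regions, inflection_nm = inflection,
                 bandwidth_nm = bandwidth_nm, flat = flat),
            class = "svt_cdf")
}

#' Equalize mean synapse orientations across conditions
#'
#' Synapse orientation (the angle of the membrane normal to the x axis)
#' determines how the missing wedge intersects tethers and connectors. To
#' prevent an orientation bias between conditions, synapses are removed one
#' at a time — always the one with the most extreme angle relative to the
#' grand mean, from the group whose mean deviates most — until all pairwise
#' group-mean differences are within the tolerance. The removal order is
#' logged; the procedure is deterministic and invariant to input row order.
#'
#' @param synapses Tibble with columns `synapse_id`, `condition`,
#'   `orientation_deg` (in `[-90, 90]`).
#' @param tolerance_deg Maximal allowed pairwise difference of group mean
#'   angles (default 5).
#' @return List with `kept` (tibble), `removed` (tibble with removal
#'   `order`), and `converged` (logical).
#' @export
equalize_orientation <- function(synapses, tolerance_deg = 5) {
  synapses <- tibble::as_tibble(synapses)
  need <- c("synapse_id", "condition", "orientation_deg")
  if (!all(need %in% names(synapses)))
    abort(paste("`synapses` needs columns", paste(need, collapse = ", ")))
  if (any(abs(synapses$orientation_deg) > 90))
    abort("orientation angles must lie in [-90, 90] degrees")
  cur <- dplyr::arrange(synapses, .data$condition, .data$synapse_id)
  removed <- cur[0, ]
  ord <- integer(0)
  repeat {
    gm <- cur |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(m = mean(.data$orientation_deg), n = dplyr::n(),
                       .groups = "drop")
    if (nrow(gm) < 2) break
    spread <- max(gm$m) - min(gm$m)
    if (spread <= tolerance_deg) break
    grand <- mean(gm$m)
    gm$dev <- abs(gm$m - grand)
    # tie-break: the group holding the globally most extreme synapse, so
    # removal follows "from the most extreme angle" order
    gm$extreme <- vapply(gm$condition, function(g)
      max(abs(cur$orientation_deg[cur$condition == g] - grand)), numeric(1))
    worst <- gm$condition[order(-gm$dev, -gm$extreme, gm$condition)][1]
    pool <- cur[cur$condition == worst, ]
    if (nrow(pool) <= 1)
      abort(sprintf(
        "cannot equalize orientations: group '%s' would be emptied (spread %.2f deg > tolerance)",
        worst, spread))
    ext <- pool[order(-abs(pool$orientation_deg - grand), pool$synapse_id), ][1, ]
    cur <- cur[cur$synapse_id != ext$synapse_id, ]
    removed <- dplyr::bind_rows(removed, ext)
    ord <- c(ord, nrow(removed))
  }
  removed$order <- seq_len(nrow(removed))
  list(kept = cur, removed = removed, converged = TRUE)
}

#' Normalized histogram of a morphometric variable
#'
#' Counts and probabilities over left-closed bins; default bin edges follow
#' the tethering-state distance classes. Probabilities sum to 1 for a
#' nonempty sample.
#'
#' @param values Numeric sample.
#' @param breaks Increasing bin edges; values beyond the last edge fall in
#'   a final open bin.
#' @return Tibble `bin`, `lo`, `hi`, `count`, `probability`.
#' @export
bridge_histogram <- function(values, breaks = c(0, 5, 10)) {
  edges <- unique(c(breaks, Inf))
  cuts <- cut(values, breaks = edges, right = FALSE)
  cnt <- as.integer(table(cuts))
  tibble(bin = levels(cuts),
         lo = edges[-length(edges)], hi = edges[-1],
         count = cnt,
         probability = if (length(values)) cnt / length(values) else 0)
}

#' Simulate per-vesicle AZ distances for a condition
#'
#' Draws vesicle-to-AZ distances from a truncated normal centred on the
#' condition's characteristic peak — around 6 nm for conditions with intact
#' Munc13-dependent tethering, around 16 nm for tethering-deficient
#' conditions.
#'
#' @param n Number of vesicles.
#' @param peak_nm Peak position (nm).
#' @param sd_nm Spread (nm).
#' @param seed RNG seed.
#' @return Numeric vector of nonnegative distances.
#' @export
simulate_sv_distances <- function(n, peak_nm, sd_nm = 3, seed = 1L) {
  local_seed(seed, {
    out <- rnorm(n, peak_nm, sd_nm)
    while (any(out < 0)) out[out < 0] <- rnorm(sum(out < 0), peak_nm, sd_nm)
    out
  })
}
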