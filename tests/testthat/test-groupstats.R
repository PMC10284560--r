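test_that("group aggregation: mean, SEM, and NA for a single synapse", {
  two <- aggregate_groups(tibble::tibble(g = "a", f = c(0.4, 0.6)), f, g)
  expect_equal(two$mean, 0.5)
  expect_equal(two$sem, 0.1)
  one <- aggregate_groups(tibble::tibble(g = "a", f = 0.5), f, g)
  expect_true(is.na(one$sem))
  expect_equal(one$mean, 0.5)
  # pooling conserves counts
  pooled <- aggregate_groups(
    tibble::tibble(g = rep(c("a", "b"), c(7, 5)), v = rnorm(12)), v, g)
  expect_identical(sum(pooled$n), 12L)
})

test_that("chi-squared matches the closed form sum((O-E)^2/E)", {
  # contingency [[80,20],[15,85]], hand calculation
  O <- rbind(c(80, 20), c(15, 85))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat_hand <- sum((O - E)^2 / E)
  p_hand <- stats::pchisq(stat_hand, df = 1, lower.tail = FALSE)
  a <- rep(c(TRUE, FALSE), c(80, 20))
  b <- rep(c(TRUE, FALSE), c(15, 85))
  res <- compare_pair(a, b, "chisq")
  expect_equal(res$statistic, stat_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  expect_identical(res$stars, "***")
})

test_that("Student t matches the textbook pooled-variance formula", {
  a <- c(4.1, 5.2, 6.3, 5.8)
  b <- c(7.4, 8.1, 6.9)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = n1 + n2 - 2)
  res <- compare_pair(a, b, "t")
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the rank-sum closed form (no ties)", {
  a <- c(1.1, 3.4, 5.6, 9.1)
  b <- c(2.2, 4.5, 7.7)
  r <- rank(c(a, b))
  N <- length(r)
  Ra <- sum(r[1:4]); Rb <- sum(r[5:7])
  H <- 12 / (N * (N + 1)) * (Ra^2 / 4 + Rb^2 / 3) - 3 * (N + 1)
  p_hand <- stats::pchisq(H, df = 1, lower.tail = FALSE)
  res <- compare_pair(a, b, "kruskal")
  expect_equal(res$statistic, H, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
})

test_that("identical groups and degenerate variance give p = 1", {
  a <- c(1, 2, 3, 4)
  expect_equal(compare_pair(a, a, "t")$p_value, 1)
  expect_equal(compare_pair(a, a, "kruskal")$p_value, 1)
  expect_warning(res <- compare_pair(rep(2, 4), rep(2, 5), "t"),
                 "zero variance")
  expect_equal(res$p_value, 1)
  expect_error(compare_pair(numeric(0), a, "t"), "nonempty")
})

test_that("Pearson association is exact for linear data", {
  x <- 1:10
  res <- correlate_pair(x, 2 * x + 3)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-10)
})

test_that("compare_groups runs the configured planned pairs only", {
  set.seed(9)
  dat <- tibble::tibble(
    variable = "d",
    group = rep(c("ko", "wt", "other"), each = 30),
    value = c(rnorm(30, 16, 3), rnorm(30, 6, 2), rnorm(30, 6, 2)))
  des <- comparison_design(tibble::tibble(
    variable = "d", group_a = "ko", group_b = "wt", test = "t"))
  out <- compare_groups(dat, des)
  expect_identical(nrow(out), 1L)       # no all-vs-all expansion
  expect_lt(out$p_value, 0.001)
  expect_identical(out$stars, "***")
  expect_s3_class(tidy(out), "tbl_df")
  expect_error(comparison_design(tibble::tibble(
    variable = "d", group_a = "a", group_b = "b", test = "anova")),
    "unknown test")
})

test_that("CDF inflection sits at the centre of a logistic sample", {
  x <- local({set.seed(31); stats::rlogis(4000, location = 8, scale = 0.8)})
  cdf <- cdf_and_inflection(x, bandwidth_nm = 1)
  expect_lt(abs(cdf$inflection_nm - 8), 1)
  expect_s3_class(tidy(cdf), "tbl_df")
})

test_that("a uniform sample reports no inflection instead of a midpoint", {
  u <- local({set.seed(5); stats::runif(3000, 0, 40)})
  cdf <- cdf_and_inflection(u, bandwidth_nm = 1)
  expect_true(is.na(cdf$inflection_nm))
  expect_true(cdf$flat)
})

test_that("a bimodal sample yields one steep region per mode", {
  x <- local({set.seed(7); c(rnorm(800, 6, 1), rnorm(800, 16, 1))})
  cdf <- cdf_and_inflection(x, bandwidth_nm = 1)
  mids <- cdf$regions$midpoint[order(-cdf$regions$width)][1:2]
  expect_true(any(abs(mids - 6) < 2))
  expect_true(any(abs(mids - 16) < 2))
})

test_that("orientation equalization follows the most-extreme-first rule", {
  syn <- tibble::tibble(
    synapse_id = paste0("s", 1:5),
    condition = c("g1", "g1", "g1", "g2", "g2"),
    orientation_deg = c(0, 10, 50, 5, 15))
  res <- equalize_orientation(syn, tolerance_deg = 5)
  expect_identical(res$removed$synapse_id, "s3")   # the 50-degree synapse
  expect_identical(nrow(res$kept), 4L)

  # already within tolerance: nothing removed
  ok <- tibble::tibble(synapse_id = paste0("s", 1:4),
                       condition = rep(c("a", "b"), 2),
                       orientation_deg = c(10, 12, 11, 9))
  expect_identical(nrow(equalize_orientation(ok, 5)$removed), 0L)

  # permutation invariance
  shuffled <- syn[c(4, 2, 5, 1, 3), ]
  expect_identical(equalize_orientation(shuffled, 5)$removed$synapse_id, "s3")

  # a single-synapse group is never emptied
  lone <- tibble::tibble(synapse_id = c("a1", "b1"),
                         condition = c("a", "b"),
                         orientation_deg = c(-60, 60))
  expect_error(equalize_orientation(lone, 5), "emptied")
  expect_error(equalize_orientation(
    dplyr::mutate(lone, orientation_deg = c(120, 0))), "\\[-90, 90\\]")
})

test_that("histograms normalize to probability 1 with state bin edges", {
  h <- bridge_histogram(c(4, 7, 16))
  expect_identical(h$count, c(1L, 1L, 1L))
  expect_equal(sum(h$probability), 1)
  h0 <- bridge_histogram(numeric(0))
  expect_true(all(h0$count == 0L))
})

test_that("simulated distance conditions separate at the <10 nm fraction", {
  near <- simulate_sv_distances(300, peak_nm = 6, sd_nm = 2.5, seed = 1)
  far <- simulate_sv_distances(300, peak_nm = 16, sd_nm = 4, seed = 2)
  expect_true(all(near >= 0) && all(far >= 0))
  res <- compare_pair(near < 10, far < 10, "chisq")
  expect_lt(res$p_value, 0.001)
  # identical generator, different seeds: no systematic difference
  same <- compare_pair(simulate_sv_distances(300, 10, 4, seed = 3) < 10,
                       simulate_sv_distances(300, 10, 4, seed = 4) < 10,
                       "chisq")
  expect_gt(same$p_value, 0.001)
})
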