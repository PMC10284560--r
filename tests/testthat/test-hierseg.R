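test_that("analysis region is the presynaptic shell around the AZ membrane", {
  labs <- array(0L, c(24, 24, 24))
  labs[, , 10] <- 1L            # membrane plane at z = 10, voxel 1 nm
  for (k in 1:9) labs[, , k] <- 3L  # postsynaptic side
  lv <- label_volume(labs, 1)
  reg <- analysis_region(lv, 5)
  zz <- unique(which(reg$mask, arr.ind = TRUE)[, 3])
  expect_identical(sort(zz), 11:15)
  # boundary voxels are never part of the region
  expect_false(any(reg$mask[labs != 0L]))
  expect_identical(sum(analysis_region(lv, 0)$mask), 0L)
  empty <- label_volume(array(0L, c(8, 8, 8)), 1)
  expect_error(analysis_region(empty, 250), "empty AZ")
})

test_that("vesicles join the region only when requested", {
  ph <- generate_phantom(noisy_phantom_spec(noise_sigma = 0))
  r0 <- analysis_region(ph$labels, 250)
  r1 <- analysis_region(ph$labels, 250, include_vesicles = TRUE)
  sv <- ph$labels$values >= 10L
  expect_false(any(r0$mask[sv]))
  expect_true(all(r1$mask[sv & r1$dist_vox * 1.4 <= 250 & r1$dist_vox > 0]))
})

test_that("foreground grows monotonically along the schedule", {
  set.seed(8)
  dens <- array(runif(12^3), c(12, 12, 12))
  tt <- c(0.2, 0.4, 0.6, 0.8)
  for (i in seq_len(length(tt) - 1)) {
    expect_true(all(which(dens <= tt[i]) %in% which(dens <= tt[i + 1])))
  }
})

test_that("contact signatures classify to tether, connector, or rejected", {
  expect_identical(classify_segment(c(12, 1)), "tether")
  expect_identical(classify_segment(c(1, 12)), "tether")
  expect_identical(classify_segment(c(12, 13)), "connector")
  expect_identical(classify_segment(c(12, 13, 1)), "rejected")
  expect_identical(classify_segment(c(12, 2)), "rejected")
  expect_identical(classify_segment(12), "rejected")
  expect_identical(classify_segment(integer(0)), "rejected")
})

test_that("a hand-built gradient rod yields its core at the lowest valid threshold", {
  # membrane plane, vesicle blob, and a rod whose density increases
  # radially: the 1-voxel core links the boundaries at the low threshold
  dims <- c(9, 9, 9)
  labs <- array(0L, dims)
  labs[, , 1] <- 1L
  labs[4:6, 4:6, 8:9] <- 10L
  dens <- array(1, dims)
  dens[5, 5, 2:7] <- 0.1            # core
  dens[4, 5, 2:7] <- 0.5            # sheath (also valid at high threshold)
  dv <- density_volume(dens, 1)
  lv <- label_volume(labs, 1)
  reg <- analysis_region(lv, 250)
  segs <- connectivity_segmentation(dv, lv, reg,
                                    threshold_schedule(absolute = c(0.2, 0.6, 0.9)))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$kind, "tether")
  expect_equal(segs$validity_threshold, 0.2)
  expect_identical(segs$n_voxels, 6L)   # the core only, not the sheath
  o <- oracle_segmentation(dens, labs, reg$mask, c(0.2, 0.6, 0.9))
  expect_identical(canonical_segments(segs)[[1]]$voxels,
                   canonical_segments(o)[[1]]$voxels)
})

test_that("segmentation equals the exhaustive per-threshold oracle on random grids", {
  for (s in 1:8) {
    sc <- random_scene(seed = 100 + s)
    reg <- analysis_region(sc$labels, 250)
    tt <- unname(quantile(sc$density$values[reg$mask], c(0.3, 0.5, 0.7, 0.85)))
    segs <- connectivity_segmentation(sc$density, sc$labels, reg,
                                      threshold_schedule(absolute = tt))
    o <- oracle_segmentation(sc$density$values, sc$labels$values, reg$mask, tt)
    a <- canonical_segments(segs); b <- canonical_segments(o)
    expect_identical(length(a), length(b))
    for (i in seq_along(a)) {
      expect_identical(a[[i]]$voxels, b[[i]]$voxels)
      expect_identical(a[[i]]$kind, b[[i]]$kind)
      expect_equal(a[[i]]$validity_threshold, b[[i]]$validity_threshold)
      expect_identical(a[[i]]$contacts_a, b[[i]]$contacts_a)
      expect_identical(a[[i]]$contacts_b, b[[i]]$contacts_b)
    }
  }
})

test_that("noiseless phantom bridges are recovered exactly, with matching contacts", {
  ph <- generate_phantom(noisy_phantom_spec(noise_sigma = 0))
  reg <- analysis_region(ph$labels, 250)
  segs <- connectivity_segmentation(
    ph$density, ph$labels, reg,
    threshold_schedule(absolute = c(0.25, 0.5, 0.75)))
  expect_identical(sum(segs$kind == "tether"), 2L)
  expect_identical(sum(segs$kind == "connector"), 1L)
  gt <- ph$ground_truth$bridges
  teth <- segs[segs$kind == "tether", ]
  expect_setequal(pmax(teth$boundary_a, teth$boundary_b),
                  gt$vesicle_a[gt$kind == "tether"])
  conn <- segs[segs$kind == "connector", ]
  expect_identical(sort(c(conn$boundary_a, conn$boundary_b)),
                   sort(c(gt$vesicle_a[gt$kind == "connector"],
                          gt$vesicle_b[gt$kind == "connector"])))
})

test_that("adding a threshold below every density leaves segments unchanged", {
  ph <- generate_phantom(noisy_phantom_spec(seed = 21))
  reg <- analysis_region(ph$labels, 250)
  base <- threshold_schedule(ph$density, reg, k = 8)
  low <- min(ph$density$values) - 1
  ext <- threshold_schedule(absolute = c(low, as.numeric(base)))
  s1 <- connectivity_segmentation(ph$density, ph$labels, reg, base)
  s2 <- connectivity_segmentation(ph$density, ph$labels, reg, ext)
  a <- canonical_segments(s1); b <- canonical_segments(s2)
  expect_identical(length(a), length(b))
  for (i in seq_along(a)) expect_identical(a[[i]]$voxels, b[[i]]$voxels)
})

test_that("degenerate inputs are rejected with diagnostics", {
  ph <- generate_phantom(noisy_phantom_spec(noise_sigma = 0))
  reg <- analysis_region(ph$labels, 250)
  expect_error(
    connectivity_segmentation(ph$density, ph$labels, reg,
                              threshold_schedule(absolute = c(5, 6))),
    "outside the region density range")
  expect_error(threshold_schedule(absolute = c(0.5, 0.4)), "increasing")
  expect_error(threshold_schedule(absolute = 0.5), "increasing|K >= 2")
  hi <- density_volume(ph$density$values, 1.4, structure_low = FALSE)
  expect_error(
    connectivity_segmentation(hi, ph$labels, reg,
                              threshold_schedule(absolute = c(0.2, 0.5))),
    "structure-low")
})
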