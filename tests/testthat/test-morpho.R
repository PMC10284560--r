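diag_nm <- sqrt(3) * 1.4

test_that("circle fit recovers a digital circle and rejects degenerate traces", {
  dims <- c(40, 40, 40)
  th <- seq(0, 2 * pi, length.out = 72)[-72]
  contour <- unique(cbind(round(20 + 10 * cos(th)), round(20 + 10 * sin(th)), 20))
  fit <- disk_to_sphere(contour, dims, voxel_size_nm = 1)
  expect_equal(fit$center[1:2], c(20, 20), tolerance = 0.2)
  expect_equal(fit$radius_nm, 10, tolerance = 0.5)
  expect_gt(length(fit$voxels), 0)

  set.seed(2)
  jit <- contour + cbind(sample(-1:1, nrow(contour), TRUE),
                         sample(-1:1, nrow(contour), TRUE), 0)
  fitj <- disk_to_sphere(jit, dims, 1)
  expect_equal(fitj$radius_nm, 10, tolerance = 1)

  expect_error(disk_to_sphere(cbind(1:10, 1:10, 5), dims, 1), "collinear")
  expect_error(disk_to_sphere(contour[1:4, ], dims, 1), "fewer than 6")
})

test_that("planted AZ distances are recovered within one voxel diagonal", {
  spec <- phantom_spec(c(64, 64, 64), 1.4,
                       vesicles = tibble::tibble(
                         x_nm = c(20, 50, 74), y_nm = 45, radius_nm = 11,
                         distance_nm = c(4, 8, 16)),
                       noise_sigma = 0)
  ph <- generate_phantom(spec)
  reg <- analysis_region(ph$labels, 250)
  ves <- vesicle_table(ph$labels, reg)
  expect_identical(nrow(ves), 3L)
  expect_true(all(abs(ves$distance_nm - c(4, 8, 16)) < diag_nm))
  # a sphere overlapping the membrane-adjacent layer scores 0
  touching <- phantom_spec(c(48, 48, 48), 1.4,
                           vesicles = tibble::tibble(x_nm = 33, y_nm = 33,
                                                     radius_nm = 10,
                                                     distance_nm = 0),
                           noise_sigma = 0)
  pht <- generate_phantom(touching)
  regt <- analysis_region(pht$labels, 250)
  expect_lt(distance_to_az(which(pht$labels$values == 10L), regt), diag_nm)
})

test_that("a straight rod's geodesic length equals the Dijkstra oracle and the gap rule", {
  # rod across a 10-voxel gap: contact-centre to contact-centre = 9 voxels
  dims <- c(11, 11, 13)
  labs <- array(0L, dims)
  labs[, , 1] <- 1L
  labs[4:8, 4:8, 12:13] <- 10L
  dens <- array(1, dims)
  dens[6, 6, 2:11] <- 0
  lv <- label_volume(labs, 1)
  dv <- density_volume(dens, 1)
  reg <- analysis_region(lv, 250)
  segs <- connectivity_segmentation(dv, lv, reg,
                                    threshold_schedule(absolute = c(0.3, 0.6)))
  segs <- measure_segments(segs, dims, 1)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$length_nm, 9)
  o <- oracle_geodesic(segs$voxels[[1]], dims,
                       segs$contacts_a[[1]], segs$contacts_b[[1]])
  expect_equal(segs$length_nm, o, tolerance = 1e-9)
})

test_that("a shared contact voxel gives length zero", {
  seg <- tibble::tibble(voxels = list(c(5)), contacts_a = list(c(5)),
                        contacts_b = list(c(5)))
  out <- measure_segments(
    dplyr::mutate(seg, segment_id = 1L, kind = "tether"), c(4, 4, 4), 1.4)
  expect_identical(out$length_nm, 0)
})

test_that("curved tether length includes curvature: chord < span < geodesic", {
  spec <- phantom_spec(c(64, 64, 64), 1.4,
                       vesicles = tibble::tibble(x_nm = 40, y_nm = 45,
                                                 radius_nm = 16,
                                                 distance_nm = 12),
                       tethers = tibble::tibble(vesicle = 1,
                                                shape = "arc",
                                                az_dx_nm = 0, az_dy_nm = 0,
                                                bulge_axis = "x",
                                                radius_nm = 1.4),
                       noise_sigma = 0)
  ph <- generate_phantom(spec)
  reg <- analysis_region(ph$labels, 250)
  segs <- measure_segments(
    connectivity_segmentation(ph$density, ph$labels, reg,
                              threshold_schedule(absolute = c(0.3, 0.6))),
    c(64, 64, 64), 1.4)
  expect_identical(nrow(segs), 1L)
  arc <- ph$ground_truth$bridges$length_nm
  expect_gt(arc, 12)                         # planted: chord < arc
  expect_lt(abs(segs$length_nm - arc), max(diag_nm, 0.1 * arc))
  expect_gt(segs$length_nm, 12)              # strictly above the chord
})

test_that("geodesic lengths match the igraph oracle on every phantom segment", {
  ph <- generate_phantom(noisy_phantom_spec(noise_sigma = 0))
  reg <- analysis_region(ph$labels, 250)
  segs <- measure_segments(
    connectivity_segmentation(ph$density, ph$labels, reg,
                              threshold_schedule(absolute = c(0.3, 0.6))),
    c(64, 64, 64), 1.4)
  for (i in seq_len(nrow(segs))) {
    o <- oracle_geodesic(segs$voxels[[i]], c(64, 64, 64),
                         segs$contacts_a[[i]], segs$contacts_b[[i]])
    expect_equal(segs$length_nm[i], o * 1.4, tolerance = 1e-9)
  }
})

test_that("length and state classifications use left-closed printed intervals", {
  expect_identical(classify_tether(c(5.5, 6, 11.99, 12, 23.9, 24, 30)),
                   c("short", "intermediate", "intermediate", "long",
                     "long", "extra", "extra"))
  expect_identical(classify_state(c(0, 4, 5, 7, 9.99, 10, 40)),
                   c("SNAP25-dependent", "SNAP25-dependent", "intermediate",
                     "intermediate", "intermediate", "Munc13-independent",
                     "Munc13-independent"))
})

test_that("bridge counts: tethers hit one vesicle, connectors two", {
  ves <- tibble::tibble(vesicle_id = c(10L, 11L, 12L))
  seg <- tibble::tibble(
    kind = c("tether", "tether", "tether", "connector"),
    boundary_a = c(1L, 1L, 1L, 10L),
    boundary_b = c(10L, 10L, 10L, 11L))
  out <- count_bridges(ves, seg)
  expect_identical(out$n_tethers, c(3L, 0L, 0L))
  expect_identical(out$n_connectors, c(1L, 1L, 0L))
  expect_identical(out$multiply_tethered, c(TRUE, FALSE, FALSE))
  expect_identical(out$tethered, c(TRUE, FALSE, FALSE))
  none <- count_bridges(ves, seg[0, ])
  expect_true(all(none$n_tethers == 0L) && all(none$n_connectors == 0L))
})

test_that("layer occupancy conserves vesicle voxels exactly", {
  spec <- phantom_spec(c(64, 64, 64), 1.4,
                       vesicles = tibble::tibble(
                         x_nm = c(25, 60), y_nm = 45, radius_nm = 12,
                         distance_nm = c(5, 40)),   # second straddles 45 nm
                       noise_sigma = 0)
  ph <- generate_phantom(spec)
  reg <- analysis_region(ph$labels, 250, include_vesicles = TRUE)
  lp <- layer_profile(ph$labels, reg)
  in_range <- reg$mask & ph$labels$values >= 10L
  expect_identical(sum(lp$layers$n_sv), sum(in_range))
  expect_identical(sum(lp$zones$n_sv), sum(in_range))
  expect_true(all(lp$layers$phi >= 0 & lp$layers$phi <= 1))
  # straddling sphere splits across proximal and intermediate
  expect_gt(lp$zones$n_sv[lp$zones$zone == "proximal"], 0)
  expect_gt(lp$zones$n_sv[lp$zones$zone == "intermediate"], 0)
  # no vesicles -> phi = 0 everywhere
  empty <- phantom_spec(c(32, 32, 32), 1.4,
                        vesicles = tibble::tibble(x_nm = numeric(0),
                                                  y_nm = numeric(0),
                                                  radius_nm = numeric(0),
                                                  distance_nm = numeric(0)),
                        noise_sigma = 0)
  phe <- generate_phantom(empty)
  lpe <- layer_profile(phe$labels,
                       analysis_region(phe$labels, 250, include_vesicles = TRUE))
  expect_true(all(lpe$layers$phi == 0))
})

test_that("surface concentration converts counts per area to per square micron", {
  expect_equal(surface_concentration(5, 0.05 * 1e6), 100)
  expect_equal(surface_concentration(0, 1e4), 0)
  expect_error(surface_concentration(1, 0), "> 0")
})

test_that("AZ area estimator is accurate for plane and spherical cap", {
  ph <- generate_phantom(noisy_phantom_spec(noise_sigma = 0))
  a <- az_area(ph$labels)
  expect_lt(abs(a - 76^2) / 76^2, 0.05)
  af <- az_area(ph$labels, method = "face_count")
  expect_gt(af, 0)

  # spherical cap: 1-voxel shell, opening angle 60 deg, area 2*pi*R*h
  dims <- c(64, 64, 64)
  g <- expand.grid(x = 1:64, y = 1:64, z = 1:64)
  R <- 20
  r <- sqrt((g$x - 32)^2 + (g$y - 32)^2 + (g$z - 20)^2)
  cap <- r >= R - 0.5 & r <= R + 0.5 & (g$z - 20) >= R * cos(pi / 3)
  labs <- array(0L, dims)
  labs[as.matrix(g[cap, ])] <- 1L
  lv <- label_volume(labs, 1)
  h <- R * (1 - cos(pi / 3))
  expect_lt(abs(az_area(lv) - 2 * pi * R * h) / (2 * pi * R * h), 0.1)

  one <- array(0L, c(8, 8, 8)); one[4, 4, 4] <- 1L
  expect_gt(az_area(label_volume(one, 1.4)), 0)
})

test_that("model span is the minimal inter-selection atom distance in nm", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      13.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_equal(model_span(f, list(resno = 1), list(resno = 2)), 1.3,
               tolerance = 1e-9)
  expect_equal(model_span(f, list(resno = 1:2), list(resno = 1:2)), 0)
  expect_error(model_span(f, list(resno = 99), list(resno = 2)), "empty")
  expect_error(model_span(tempfile(fileext = ".pdb"),
                          list(resno = 1), list(resno = 2)), "unparsable")
})

test_that("synthetic priming-factor stand-in spans at least 13 nm (synthetic model)", {
  f <- synthetic_munc13_model(withr::local_tempfile(fileext = ".pdb"))
  span <- model_span(f, attr(f, "sel_c2b"), attr(f, "sel_mun_cterm"))
  # brute-force oracle straight from the PDB text
  txt <- readLines(f)
  txt <- txt[startsWith(txt, "ATOM")]
  resno <- as.integer(substr(txt, 23, 26))
  xyz <- cbind(as.numeric(substr(txt, 31, 38)), as.numeric(substr(txt, 39, 46)),
               as.numeric(substr(txt, 47, 54)))
  a <- xyz[resno %in% 1:60, , drop = FALSE]
  b <- xyz[resno %in% 411:420, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(a))) best <- min(best, sqrt(colSums((t(b) - a[i, ])^2)))
  expect_equal(span, best / 10, tolerance = 1e-9)
  expect_gte(span, 13.0)
})

test_that("the accommodation screen honours geodesic span, not chord", {
  # straight 5-voxel tether: too short for a 13 nm model at 1.4 nm voxels
  straight <- tibble::tibble(voxels = list(as.numeric(1:5)),
                             contacts_a = list(1), contacts_b = list(5))
  expect_false(tether_accommodates(straight, 13, c(100, 1, 1), 1.4))
  # L-shaped path: 6 + 6 voxels, geodesic ~ 14.6 nm, chord ~ 8.9 nm
  dims <- c(12, 12, 3)
  arm1 <- cbind(1:7, 1, 2)
  arm2 <- cbind(7, 2:7, 2)
  vox <- xyz_to_linear(rbind(arm1, arm2), dims)
  lshape <- tibble::tibble(voxels = list(vox),
                           contacts_a = list(vox[1]),
                           contacts_b = list(vox[length(vox)]))
  chord_nm <- sqrt(sum((arm1[1, ] - arm2[nrow(arm2), ])^2)) * 1.4
  expect_lt(chord_nm, 13)
  expect_true(tether_accommodates(lshape, 13, dims, 1.4))
})

test_that("every tether is at least as long as its vesicle's AZ distance", {
  ph <- generate_phantom(example_phantom_spec())
  reg <- analysis_region(ph$labels, 250)
  segs <- measure_segments(
    connectivity_segmentation(ph$density, ph$labels, reg,
                              threshold_schedule(absolute = c(0.3, 0.6))),
    c(128, 128, 128), 1.4)
  ves <- vesicle_table(ph$labels, reg)
  teth <- segs[segs$kind == "tether", ]
  vid <- pmax(teth$boundary_a, teth$boundary_b)
  d <- ves$distance_nm[match(vid, ves$vesicle_id)]
  expect_true(all(teth$length_nm >= d - diag_nm))
})
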