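# Independent oracles used across the suite.
#
# oracle_segmentation(): exhaustive per-threshold reference for the
# hierarchical connectivity segmentation. Written independently of the
# package implementation: components come from igraph over an explicitly
# constructed 26-adjacency edge list, signatures from a plain R neighbour
# scan, and the lowest-valid-threshold selection rule is applied literally.
#
# oracle_geodesic(): igraph shortest path over the segment's voxel graph
# with Euclidean edge weights, as a reference for the Dijkstra in src/.

neighbour_offsets_r <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# all 26-adjacent index pairs within `idx` (1-based linear indices)
adjacency_pairs <- function(idx, dims) {
  xyz <- arrayInd(idx, .dim = dims)
  key <- (xyz[, 3] - 1) * dims[1] * dims[2] + (xyz[, 2] - 1) * dims[1] + xyz[, 1]
  inset <- new.env(hash = TRUE)
  for (k in key) assign(as.character(k), TRUE, envir = inset)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(neighbour_offsets_r))) {
    off <- neighbour_offsets_r[r, ]
    nb <- cbind(xyz[, 1] + off[1], xyz[, 2] + off[2], xyz[, 3] + off[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nbkey <- (nb[, 3] - 1) * dims[1] * dims[2] + (nb[, 2] - 1) * dims[1] + nb[, 1]
    present <- ok
    present[ok] <- vapply(as.character(nbkey[ok]),
                          function(k) exists(k, envir = inset), logical(1))
    keep <- present & key < nbkey        # each undirected edge once
    from <- c(from, key[keep]); to <- c(to, nbkey[keep])
    w <- c(w, rep(sqrt(sum(off^2)), sum(keep)))
  }
  list(from = from, to = to, weight = w)
}

oracle_components <- function(idx, dims) {
  if (!length(idx)) return(list())
  ed <- adjacency_pairs(idx, dims)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  mem <- igraph::components(g)$membership
  split(as.numeric(names(mem)), mem)
}

# boundary contacts of a voxel set: list(boundary id -> contact voxels)
oracle_contacts <- function(vox, labels, dims) {
  xyz <- arrayInd(as.integer(vox), .dim = dims)
  out <- list()
  for (r in seq_len(nrow(neighbour_offsets_r))) {
    off <- neighbour_offsets_r[r, ]
    nb <- cbind(xyz[, 1] + off[1], xyz[, 2] + off[2], xyz[, 3] + off[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nbidx <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    b <- labels[nbidx]
    hit <- b > 0
    if (!any(hit)) next
    for (i in which(hit)) {
      id <- as.character(b[i])
      out[[id]] <- c(out[[id]], vox[ok][i])
    }
  }
  lapply(out, function(v) sort(unique(v)))
}

oracle_classify <- function(bids) {
  s <- sort(unique(as.integer(bids)))
  ves <- s[s >= 10]
  if (length(s) == 2 && 1 %in% s && length(ves) == 1) return("tether")
  if (length(s) == 2 && length(ves) == 2) return("connector")
  "rejected"
}

oracle_segmentation <- function(density, labels, region_mask, thresholds) {
  dims <- dim(density)
  labvec <- as.vector(labels)
  reported <- rep(FALSE, length(labvec))
  segs <- list()
  for (t in sort(thresholds)) {
    fg <- which(region_mask & density <= t)
    comps <- oracle_components(fg, dims)
    # deterministic order: by smallest voxel index
    comps <- comps[order(vapply(comps, min, numeric(1)))]
    for (vox in comps) {
      ct <- oracle_contacts(vox, labvec, dims)
      kind <- oracle_classify(names(ct))
      if (kind == "rejected") next
      if (any(reported[vox])) next
      reported[vox] <- TRUE
      bids <- sort(as.integer(names(ct)))
      segs[[length(segs) + 1]] <- list(
        kind = kind, validity_threshold = t, voxels = sort(vox),
        boundary_a = bids[1], boundary_b = bids[2],
        contacts_a = ct[[as.character(bids[1])]],
        contacts_b = ct[[as.character(bids[2])]])
    }
  }
  segs
}

# canonical form for comparing segment sets regardless of discovery order
canonical_segments <- function(segs) {
  if (is.data.frame(segs)) {
    segs <- purrr::pmap(segs[, c("kind", "validity_threshold", "voxels",
                                 "boundary_a", "boundary_b",
                                 "contacts_a", "contacts_b")], list)
    segs <- lapply(segs, function(s) {
      s$voxels <- sort(as.numeric(s$voxels))
      s$contacts_a <- sort(as.numeric(s$contacts_a))
      s$contacts_b <- sort(as.numeric(s$contacts_b))
      s$boundary_a <- as.integer(s$boundary_a)
      s$boundary_b <- as.integer(s$boundary_b)
      s
    })
  } else {
    segs <- lapply(segs, function(s) {
      s$voxels <- sort(as.numeric(s$voxels))
      s$contacts_a <- sort(as.numeric(s$contacts_a))
      s$contacts_b <- sort(as.numeric(s$contacts_b))
      s
    })
  }
  ord <- order(vapply(segs, function(s) s$validity_threshold, numeric(1)),
               vapply(segs, function(s) min(s$voxels), numeric(1)))
  segs[ord]
}

oracle_geodesic <- function(vox, dims, src, dst) {
  ed <- adjacency_pairs(as.integer(vox), dims)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to),
               weight = ed$weight),
    directed = FALSE, vertices = data.frame(name = as.character(vox)))
  d <- igraph::distances(g, v = as.character(src), to = as.character(dst),
                         weights = igraph::E(g)$weight)
  min(d)
}

# random boundary scene for oracle-equivalence tests: a membrane sheet at
# the bottom (AZ patch + plasma membrane) and two small vesicle blobs
random_scene <- function(dims = c(10, 10, 10), seed = 1) {
  set.seed(seed)
  labs <- array(0L, dims)
  labs[, , 1] <- 2L
  labs[3:8, 3:8, 1] <- 1L
  ball <- function(cx, cy, cz, r) {
    g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                     z = seq_len(dims[3]))
    which((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= r^2)
  }
  labs[ball(3, 3, 7, 2)] <- 10L
  labs[ball(8, 8, 6, 2)] <- 11L
  dens <- array(runif(prod(dims)), dims)
  list(density = density_volume(dens, 1), labels = label_volume(labs, 1))
}

xyz_to_linear <- function(xyz, dims) {
  as.numeric((xyz[, 3] - 1) * dims[1] * dims[2] + (xyz[, 2] - 1) * dims[1] + xyz[, 1])
}
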