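#' Construct a 10-node tetrahedral mesh object
#'
#' Validates and wraps a quadratic tetrahedral mesh. Node convention per
#' element: corners 1-4 followed by mid-edge nodes on edges
#' (1,2),(2,3),(3,1),(1,4),(2,4),(3,4) (the C3D10 / VTK quadratic-tet order).
#' Construction enforces positive corner Jacobians, mid-edge nodes at edge
#' midpoints (to 1e-6 of the edge length), full node usage and region
#' coverage.
#'
#' @param nodes N x 3 matrix of coordinates (mm).
#' @param conn M x 10 integer connectivity (1-based).
#' @param region Character vector (length M) of `"diaphysis"` /
#'   `"ossifying_epiphysis"`, or a single value recycled.
#' @param landmarks Optional [landmark_set()] carried with the mesh.
#' @return Object of class `tet_mesh10`.
#' @export
tet_mesh10 <- function(nodes, conn, region = "diaphysis", landmarks = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(conn) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(conn) == 10)
  if (length(region) == 1) region <- rep(region, nrow(conn))
  stopifnot(length(region) == nrow(conn), all(region %in% .region_levels))
  dets <- cpp_corner_jacobians(nodes, conn)
  if (any(dets <= 0))
    stop(sprintf("non-positive corner Jacobian in element(s) %s",
                 paste(utils::head(which(dets <= 0), 5), collapse = ", ")))
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in 1:6) {
    pa <- nodes[conn[, ed[e, 1]], , drop = FALSE]
    pb <- nodes[conn[, ed[e, 2]], , drop = FALSE]
    pm <- nodes[conn[, 4 + e], , drop = FALSE]
    elen <- sqrt(rowSums((pa - pb)^2))
    dev <- sqrt(rowSums((pm - (pa + pb) / 2)^2))
    if (any(dev > 1e-6 * elen))
      stop("mid-edge node(s) displaced from edge midpoints at construction")
  }
  if (length(setdiff(seq_len(nrow(nodes)), unique(as.vector(conn)))) > 0)
    stop("mesh contains unreferenced nodes")
  structure(list(nodes = nodes, conn = conn, region = region,
                 landmarks = landmarks),
            class = "tet_mesh10")
}

#' @export
print.tet_mesh10 <- function(x, ...) {
  cat(sprintf("tet_mesh10: %d nodes, %d 10-node tetrahedra\n",
              nrow(x$nodes), nrow(x$conn)))
  print(table(x$region))
  invisible(x)
}

#' Promote a linear tetrahedral mesh to quadratic
#'
#' Inserts one shared node per unique edge at the edge midpoint, yielding
#' node counts of corners plus unique edges.
#'
#' @param nodes N x 3 corner coordinates.
#' @param conn M x 4 corner connectivity.
#' @param region,landmarks Passed through to [tet_mesh10()].
#' @return A `tet_mesh10`.
#' @export
promote_to_quadratic <- function(nodes, conn, region = "diaphysis",
                                 landmarks = NULL) {
  nodes <- as.matrix(nodes)
  conn <- as.matrix(conn)
  if (ncol(conn) == 10)
    stop("mesh is already quadratic; refusing to promote again")
  stopifnot(ncol(conn) == 4)
  if (any(apply(conn, 1, anyDuplicated) > 0))
    stop("element(s) with duplicate corner nodes")
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  M <- nrow(conn)
  ia <- ib <- matrix(0L, M, 6)
  for (e in 1:6) {
    ia[, e] <- pmin(conn[, ed[e, 1]], conn[, ed[e, 2]])
    ib[, e] <- pmax(conn[, ed[e, 1]], conn[, ed[e, 2]])
  }
  key <- as.numeric(ia) * (nrow(nodes) + 1) + as.numeric(ib)
  uk <- unique(key)
  mid_id <- match(key, uk)                 # edge index per (element, edge)
  first <- match(uk, key)
  mids <- (nodes[as.vector(ia)[first], , drop = FALSE] +
           nodes[as.vector(ib)[first], , drop = FALSE]) / 2
  conn10 <- cbind(conn, matrix(nrow(nodes) + mid_id, M, 6))
  tet_mesh10(rbind(nodes, mids), conn10, region, landmarks)
}

# count fine voxels matching a predicate within each coarse block
.block_counts <- function(arr, k, nc) {
  dim(arr) <- c(k[1], nc[1], k[2], nc[2], k[3], nc[3])
  arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  dim(arr) <- c(prod(k), prod(nc))
  array(colSums(arr), nc)
}

# Kuhn subdivision of a unit cube into 6 conforming tetrahedra; rows give
# corner offsets as indices into the 8 cube vertices ordered by (dx,dy,dz)
# binary code dx + 2 dy + 4 dz + 1.
.kuhn_paths <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(apply(perms, 1, function(p) {
    off <- c(0, 0, 0)
    verts <- 1L
    for (step in p) {
      off[step] <- 1
      verts <- c(verts, off[1] + 2 * off[2] + 4 * off[3] + 1L)
    }
    verts
  }))
})

#' Mesh the non-background domain of a labelled voxel image
#'
#' Builds a conforming 10-node tetrahedral mesh of the labelled domain by a
#' structured lattice method: the image is partitioned into cubic blocks of
#' edge close to `target_edge`, blocks at least half filled with
#' non-background voxels are kept, each block is split into six Kuhn
#' tetrahedra (face-conforming across blocks), and the linear mesh is
#' promoted to quadratic. Element regions come from the majority voxel label
#' within each block; ties favour the ossifying epiphysis.
#'
#' @param image A `voxel_image`.
#' @param target_edge Target element edge length (mm).
#' @param landmarks Optional landmark set to carry on the mesh.
#' @param min_fill Minimum non-background voxel fraction to keep a block.
#' @return A `tet_mesh10`.
#' @export
mesh_from_labels <- function(image, target_edge, landmarks = NULL,
                             min_fill = 0.5) {
  stopifnot(inherits(image, "voxel_image"))
  lab <- image$labels
  if (!any(lab != .label_codes[["background"]]))
    stop("image has no non-background voxels to mesh")
  sp <- image$spacing
  k <- pmax(1L, as.integer(round(target_edge / sp)))
  d <- dim(lab)
  nc <- ceiling(d / k)
  pad <- nc * k
  if (any(pad > d)) {
    full <- array(.label_codes[["background"]], pad)
    full[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- lab
    lab <- full
  }
  cdia <- .block_counts((lab == .label_codes[["cortical"]]) +
                        (lab == .label_codes[["trabecular"]]), k, nc)
  cepi <- .block_counts((lab == .label_codes[["ossifying_epiphysis"]]) + 0, k, nc)
  nonbg <- cdia + cepi
  keep <- which(nonbg >= min_fill * prod(k))
  if (length(keep) == 0) stop("no blocks meet the fill threshold")
  kc <- arrayInd(keep, nc) - 1L            # 0-based block indices
  region <- ifelse(cepi[keep] >= cdia[keep], .region_levels[2], .region_levels[1])

  # lattice corner ids
  npl <- nc + 1L
  corner_id <- function(i, j, kk) 1 + i + npl[1] * (j + npl[2] * kk)
  offs <- cbind(dx = c(0, 1, 0, 1, 0, 1, 0, 1),
                dy = c(0, 0, 1, 1, 0, 0, 1, 1),
                dz = c(0, 0, 0, 0, 1, 1, 1, 1))
  ids8 <- sapply(1:8, function(v)
    corner_id(kc[, 1] + offs[v, 1], kc[, 2] + offs[v, 2], kc[, 3] + offs[v, 3]))
  ids8 <- matrix(ids8, nrow = nrow(kc))
  conn4 <- do.call(rbind, lapply(1:6, function(t4)
    ids8[, .kuhn_paths[t4, ], drop = FALSE]))
  region6 <- rep(region, times = 6)
  used <- sort(unique(as.vector(conn4)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  conn4 <- matrix(remap[conn4], nrow = nrow(conn4))
  gi <- arrayInd(used, npl) - 1L
  nodes <- cbind(image$origin[1] + gi[, 1] * k[1] * sp[1],
                 image$origin[2] + gi[, 2] * k[2] * sp[2],
                 image$origin[3] + gi[, 3] * k[3] * sp[3])
  # orient: swap last two corners where the corner Jacobian is negative
  x0 <- nodes[conn4[, 1], ]
  a1 <- nodes[conn4[, 2], ] - x0
  a2 <- nodes[conn4[, 3], ] - x0
  a3 <- nodes[conn4[, 4], ] - x0
  dets <- a1[, 1] * (a2[, 2] * a3[, 3] - a2[, 3] * a3[, 2]) -
    a1[, 2] * (a2[, 1] * a3[, 3] - a2[, 3] * a3[, 1]) +
    a1[, 3] * (a2[, 1] * a3[, 2] - a2[, 2] * a3[, 1])
  neg <- dets < 0
  if (any(neg)) conn4[neg, c(3, 4)] <- conn4[neg, c(4, 3)]
  mesh <- promote_to_quadratic(nodes, conn4, region6, landmarks)
  vol_mesh <- sum(element_volume(mesh))
  vol_lab <- sum(image$labels != .label_codes[["background"]]) * prod(sp)
  if (abs(vol_mesh - vol_lab) > 0.03 * vol_lab)
    warning(sprintf("mesh volume %.1f mm^3 deviates from labelled volume %.1f mm^3 by more than 3%%",
                    vol_mesh, vol_lab))
  mesh
}

#' Element volumes by quadrature
#'
#' Integrates |J| over each element; equals the closed-form corner-tet volume
#' when mid-edge nodes sit at midpoints, and remains valid for curved
#' elements.
#'
#' @param mesh A `tet_mesh10`.
#' @param elems Element indices (default all).
#' @param rule Quadrature rule, see [tet10_rule()].
#' @return Numeric vector of volumes (mm^3).
#' @export
element_volume <- function(mesh, elems = NULL, rule = tet10_rule(4)) {
  conn <- if (is.null(elems)) mesh$conn else mesh$conn[elems, , drop = FALSE]
  as.numeric(cpp_tet10_volumes(mesh$nodes, conn, rule$points, rule$weights))
}

#' Element centroids (corner average)
#' @param mesh A `tet_mesh10`.
#' @return M x 3 matrix.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$conn[, 1], ] + mesh$nodes[mesh$conn[, 2], ] +
   mesh$nodes[mesh$conn[, 3], ] + mesh$nodes[mesh$conn[, 4], ]) / 4
}

#' Mesh summary statistics
#'
#' Counts, volumes, Jacobian and edge-length ranges; serialisable to JSON for
#' reporting.
#'
#' @param mesh A `tet_mesh10`.
#' @return A list.
#' @export
mesh_statistics <- function(mesh) {
  vol <- element_volume(mesh)
  dets <- cpp_corner_jacobians(mesh$nodes, mesh$conn)
  e1 <- mesh$nodes[mesh$conn[, 1], ] - mesh$nodes[mesh$conn[, 2], ]
  elen <- sqrt(rowSums(e1^2))
  list(n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$conn),
       regions = as.list(table(mesh$region)),
       total_volume_mm3 = sum(vol),
       min_corner_jacobian = min(dets),
       edge_length_mm = c(min = min(elen), median = stats::median(elen),
                          max = max(elen)))
}

#' Boundary faces of a mesh
#'
#' Faces (quadratic triangles) that belong to exactly one element.
#'
#' @param mesh A `tet_mesh10`.
#' @return Integer matrix, one row per boundary face: three corner nodes
#'   followed by the three mid-edge nodes.
#' @export
boundary_faces <- function(mesh) {
  lf <- rbind(c(1, 2, 3, 5, 6, 7),
              c(1, 2, 4, 5, 9, 8),
              c(2, 3, 4, 6, 10, 9),
              c(3, 1, 4, 7, 8, 10))
  faces <- do.call(rbind, lapply(1:4, function(fi) mesh$conn[, lf[fi, ]]))
  key <- apply(faces[, 1:3, drop = FALSE], 1, function(v)
    paste(sort(v), collapse = "-"))
  once <- names(which(table(key) == 1))
  faces[key %in% once, , drop = FALSE]
}

#' Consistent nodal forces of a uniform surface traction
#'
#' Integrates a constant traction vector over the given boundary faces with
#' the quadratic (T6) consistent load vector: for straight-sided faces the
#' corner nodes receive zero and each mid-edge node one third of the face
#' load.
#'
#' @param mesh A `tet_mesh10`.
#' @param faces Face matrix as returned by [boundary_faces()] (possibly
#'   filtered to the loaded surface).
#' @param traction Traction vector (N/mm^2).
#' @return N x 3 matrix of nodal forces (mostly zero rows).
#' @export
traction_forces <- function(mesh, faces, traction) {
  f <- matrix(0, nrow(mesh$nodes), 3)
  for (r in seq_len(nrow(faces))) {
    p <- mesh$nodes[faces[r, 1:3], , drop = FALSE]
    a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]
    area <- 0.5 * sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])^2))
    for (mnode in faces[r, 4:6])
      f[mnode, ] <- f[mnode, ] + area / 3 * traction
  }
  f
}

#' Extract a subset of elements as a new mesh
#'
#' Keeps the selected elements, drops unreferenced nodes and renumbers the
#' connectivity. The node mapping (old id of each new node) is attached as
#' attribute `node_map`.
#'
#' @param mesh A `tet_mesh10`.
#' @param elems Logical or integer element selection.
#' @return A `tet_mesh10` with attribute `node_map`.
#' @export
subset_mesh <- function(mesh, elems) {
  if (is.logical(elems)) elems <- which(elems)
  conn <- mesh$conn[elems, , drop = FALSE]
  used <- sort(unique(as.vector(conn)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  out <- tet_mesh10(mesh$nodes[used, , drop = FALSE],
                    matrix(remap[conn], nrow = nrow(conn)),
                    mesh$region[elems], mesh$landmarks)
  attr(out, "node_map") <- used
  out
}

#' Uniform (congruent) mesh refinement
#'
#' Splits every 10-node tetrahedron into eight children through its mid-edge
#' nodes (four corner tetrahedra plus four from the inner octahedron) and
#' re-promotes the result to quadratic. The refined mesh covers exactly the
#' same domain, which makes it suitable for convergence and stability
#' studies.
#'
#' @param mesh A `tet_mesh10`.
#' @return A `tet_mesh10` with 8x the elements.
#' @export
refine_uniform <- function(mesh) {
  ch <- rbind(c(1, 5, 7, 8), c(5, 2, 6, 9), c(7, 6, 3, 10), c(8, 9, 10, 4),
              c(7, 9, 5, 6), c(7, 9, 6, 10), c(7, 9, 10, 8), c(7, 9, 8, 5))
  conn4 <- do.call(rbind, lapply(1:8, function(i) mesh$conn[, ch[i, ]]))
  conn4 <- .orient_tets(mesh$nodes, conn4)
  region <- rep(mesh$region, times = 8)
  # drop mid-node coordinates duplicated nowhere: all nodes still referenced
  promote_to_quadratic(mesh$nodes, conn4, region, mesh$landmarks)
}
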