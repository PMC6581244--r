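# Structured benchmark meshes: a box split into Kuhn tetrahedra and an
# extruded polygonal cylinder. Both produce conforming linear meshes that are
# promoted to quadratic.

#' Structured tetrahedral box mesh
#'
#' @param lengths Box edge lengths (mm), length 3.
#' @param n Cell counts per direction, length 3.
#' @param origin Corner of the box.
#' @param region Region tag for all elements.
#' @return A `tet_mesh10`.
#' @export
tet_mesh_box <- function(lengths, n, origin = c(0, 0, 0),
                         region = "diaphysis") {
  n <- as.integer(n)
  npl <- n + 1L
  gi <- as.matrix(expand.grid(i = 0:n[1], j = 0:n[2], k = 0:n[3]))
  nodes <- cbind(origin[1] + gi[, 1] * lengths[1] / n[1],
                 origin[2] + gi[, 2] * lengths[2] / n[2],
                 origin[3] + gi[, 3] * lengths[3] / n[3])
  cid <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1),
                               k = 0:(n[3] - 1)))
  corner_id <- function(i, j, k) 1 + i + npl[1] * (j + npl[2] * k)
  offs <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  ids8 <- sapply(1:8, function(v)
    corner_id(cid[, 1] + offs[v, 1], cid[, 2] + offs[v, 2], cid[, 3] + offs[v, 3]))
  ids8 <- matrix(ids8, nrow = nrow(cid))
  conn4 <- do.call(rbind, lapply(1:6, function(t4) ids8[, .kuhn_paths[t4, ]]))
  conn4 <- .orient_tets(nodes, conn4)
  promote_to_quadratic(nodes, conn4, region)
}

.orient_tets <- function(nodes, conn4) {
  x0 <- nodes[conn4[, 1], , drop = FALSE]
  a1 <- nodes[conn4[, 2], , drop = FALSE] - x0
  a2 <- nodes[conn4[, 3], , drop = FALSE] - x0
  a3 <- nodes[conn4[, 4], , drop = FALSE] - x0
  dets <- a1[, 1] * (a2[, 2] * a3[, 3] - a2[, 3] * a3[, 2]) -
    a1[, 2] * (a2[, 1] * a3[, 3] - a2[, 3] * a3[, 1]) +
    a1[, 3] * (a2[, 1] * a3[, 2] - a2[, 2] * a3[, 1])
  neg <- dets < 0
  if (any(neg)) conn4[neg, c(3, 4)] <- conn4[neg, c(4, 3)]
  conn4
}

# split triangular prisms (rows: bottom v1 v2 v3, top v4 v5 v6) into 3 tets
# each, with quad-face diagonals through the globally smallest node id so
# neighbouring prisms tetrahedralise their shared faces identically
.split_prisms <- function(P) {
  out <- matrix(0L, 3 * nrow(P), 4)
  for (r in seq_len(nrow(P))) {
    v <- P[r, ]
    m <- which.min(v)
    if (m > 3) v <- v[c(4, 5, 6, 1, 2, 3)]
    m <- which.min(v[1:3])
    if (m == 2) v <- v[c(2, 3, 1, 5, 6, 4)]
    if (m == 3) v <- v[c(3, 1, 2, 6, 4, 5)]
    # quad face (v2,v3,v6,v5): diagonal through its smallest vertex
    if (min(v[2], v[6]) < min(v[3], v[5])) {
      tets <- rbind(c(v[1], v[2], v[3], v[6]),
                    c(v[1], v[2], v[6], v[5]),
                    c(v[1], v[5], v[6], v[4]))
    } else {
      tets <- rbind(c(v[1], v[2], v[3], v[5]),
                    c(v[1], v[3], v[6], v[5]),
                    c(v[1], v[5], v[6], v[4]))
    }
    out[(3 * r - 2):(3 * r), ] <- tets
  }
  out
}

#' Structured tetrahedral cylinder mesh
#'
#' Extruded polygonal disc along the x-axis. With `area_matched = TRUE`
#' (default) the polygon radius is inflated so the cross-sectional area
#' equals that of the true circle, which makes section constants (area, polar
#' and bending second moments) second-order accurate in 1/`n_theta` — the
#' appropriate geometry for torsion and bending verification against
#' closed-form circular-shaft solutions.
#'
#' @param radius,length Cylinder radius and length (mm); axis along +x from
#'   the origin.
#' @param n_theta Vertices around the circumference.
#' @param n_r Rings between centre and surface.
#' @param n_z Axial layers.
#' @param area_matched Match polygon area to the circle area.
#' @param region Region tag for all elements.
#' @return A `tet_mesh10`.
#' @export
tet_mesh_cylinder <- function(radius, length, n_theta = 24, n_r = 6,
                              n_z = 18, area_matched = TRUE,
                              region = "diaphysis") {
  a <- if (area_matched)
    radius * sqrt(2 * pi / (n_theta * sin(2 * pi / n_theta))) else radius
  # disc nodes: centre, then rings
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  disc <- rbind(c(0, 0),
                do.call(rbind, lapply(1:n_r, function(k)
                  cbind(a * k / n_r * cos(th), a * k / n_r * sin(th)))))
  ndisc <- nrow(disc)
  ring_id <- function(k, i) {             # k ring 1..n_r, i 1..n_theta cyclic
    i <- ((i - 1) %% n_theta) + 1
    1 + (k - 1) * n_theta + i
  }
  tris <- do.call(rbind, lapply(1:n_theta, function(i)
    c(1, ring_id(1, i), ring_id(1, i + 1))))
  if (n_r > 1) {
    for (k in 1:(n_r - 1)) {
      for (i in 1:n_theta) {
        q <- c(ring_id(k, i), ring_id(k + 1, i),
               ring_id(k + 1, i + 1), ring_id(k, i + 1))
        # split quad along the diagonal through its smallest node id
        if (min(q[1], q[3]) < min(q[2], q[4])) {
          tris <- rbind(tris, c(q[1], q[2], q[3]), c(q[1], q[3], q[4]))
        } else {
          tris <- rbind(tris, c(q[1], q[2], q[4]), c(q[2], q[3], q[4]))
        }
      }
    }
  }
  xs <- length * (0:n_z) / n_z
  nodes <- do.call(rbind, lapply(xs, function(x)
    cbind(x, disc[, 1], disc[, 2])))
  prisms <- do.call(rbind, lapply(1:n_z, function(l) {
    base <- (l - 1) * ndisc
    cbind(base + tris, base + ndisc + tris)
  }))
  conn4 <- .split_prisms(prisms)
  conn4 <- .orient_tets(nodes, conn4)
  promote_to_quadratic(nodes, conn4, region)
}
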