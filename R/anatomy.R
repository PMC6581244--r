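#' Anatomical coordinate frame of a long-bone mesh
#'
#' Constructs the femoral frame from two diaphyseal cross-sections: the
#' shaft is sliced at 25% and 75% of its axial extent, the volume-weighted
#' slab centroids are computed, and the X axis is the unit vector from the
#' proximal to the distal centroid. Y is the component of the medial hint
#' orthogonal to X; Z = X x Y points anteriorly. Using two interior shaft
#' centroids (rather than bone end points) minimises the implicit bending
#' moment that anatomical asymmetry would otherwise introduce under axial
#' load.
#'
#' @param mesh A `tet_mesh10` with a non-empty diaphysis region. Landmarks
#'   supply the proximal/distal orientation and the medial hint; meshes
#'   without landmarks fall back to +x distal, +y medial.
#' @param slab_thickness Half-width (mm) of the smooth slab window used for
#'   the cross-sections; default one element layer (twice the median corner
#'   edge length).
#' @param fractions Axial stations of the two sections (proximal, distal).
#' @return Object of class `anatomical_frame`: `origin`, unit vectors `X`,
#'   `Y`, `Z` and the rotation matrix `R = [X Y Z]`.
#' @export
build_frame <- function(mesh, slab_thickness = NULL,
                        fractions = c(0.25, 0.75)) {
  dia <- which(mesh$region == "diaphysis")
  if (length(dia) == 0) stop("mesh has no diaphysis elements")
  cen <- element_centroids(mesh)[dia, , drop = FALSE]
  vol <- element_volume(mesh, dia)
  # provisional axis: dominant principal direction of the shaft
  cbar <- colSums(cen * vol) / sum(vol)
  cc <- sweep(cen, 2, cbar)
  ax <- eigen(crossprod(cc * sqrt(vol)))$vectors[, 1]
  lm <- mesh$landmarks
  distal_hint <- if (!is.null(lm)) lm$point2 - lm$point1 else c(1, 0, 0)
  if (sum(ax * distal_hint) < 0) ax <- -ax
  t_ax <- as.numeric(cc %*% ax)
  if (is.null(slab_thickness)) {
    e1 <- mesh$nodes[mesh$conn[dia, 1], ] - mesh$nodes[mesh$conn[dia, 2], ]
    slab_thickness <- 2 * stats::median(sqrt(rowSums(e1^2)))
  }
  tmin <- min(t_ax); tmax <- max(t_ax)
  # smooth (cos^2) slab window: insensitive to which elements straddle the
  # slab edge, so the recovered axis is stable under mesh refinement
  centroid_at <- function(fr) {
    t0 <- tmin + fr * (tmax - tmin)
    w <- ifelse(abs(t_ax - t0) < slab_thickness,
                cos(pi * (t_ax - t0) / (2 * slab_thickness))^2, 0)
    if (sum(w > 0) < 10)
      stop(sprintf("degenerate cross-section at %.0f%%: only %d elements intersected",
                   100 * fr, sum(w > 0)))
    colSums(cen * (w * vol)) / sum(w * vol)
  }
  c_prox <- centroid_at(fractions[1])
  c_dist <- centroid_at(fractions[2])
  X <- c_dist - c_prox
  X <- X / sqrt(sum(X^2))
  medial <- if (!is.null(lm)) lm$medial_direction else c(0, 1, 0)
  Y <- medial - sum(medial * X) * X
  ny <- sqrt(sum(Y^2))
  if (ny < 1e-8) stop("medial hint parallel to the shaft axis")
  Y <- Y / ny
  Z <- c(X[2] * Y[3] - X[3] * Y[2],
         X[3] * Y[1] - X[1] * Y[3],
         X[1] * Y[2] - X[2] * Y[1])
  R <- cbind(X = X, Y = Y, Z = Z)
  stopifnot(max(abs(crossprod(R) - diag(3))) < 1e-10)
  structure(list(origin = (c_prox + c_dist) / 2, X = X, Y = Y, Z = Z, R = R),
            class = "anatomical_frame")
}

# minimum-norm nodal force set with prescribed resultant force and moment
# about ref_point: F = A' (A A')^{-1} b
.distribute_load <- function(positions, ref_point, force, moment) {
  n <- nrow(positions)
  r <- sweep(positions, 2, ref_point)
  A <- matrix(0, 6, 3 * n)
  for (k in 1:3) A[k, seq(k, 3 * n, by = 3)] <- 1
  A[4, seq(2, 3 * n, by = 3)] <- -r[, 3]
  A[4, seq(3, 3 * n, by = 3)] <- r[, 2]
  A[5, seq(1, 3 * n, by = 3)] <- r[, 3]
  A[5, seq(3, 3 * n, by = 3)] <- -r[, 1]
  A[6, seq(1, 3 * n, by = 3)] <- -r[, 2]
  A[6, seq(2, 3 * n, by = 3)] <- r[, 1]
  b <- c(force, moment)
  lam <- solve(A %*% t(A), b)
  matrix(as.numeric(t(A) %*% lam), ncol = 3, byrow = TRUE)
}

#' Build one of the standard load cases
#'
#' Torsion applies a pure moment (default 2000 N mm = 2 kN mm) about the
#' frame X axis through Point 1 as a statically equivalent, zero-net-force
#' set of nodal forces on the patch of nodes around Point 1; axial cases
#' apply a force (default 200 N) along the named frame axis at Point 1. The
#' patch around Point 2 is fully fixed. Nodal forces are the minimum-norm
#' set reproducing the requested resultant exactly, which for a disc-like
#' patch coincides with the classical linear traction distributions.
#'
#' @param mesh A `tet_mesh10` with landmarks (or supply `load_point` /
#'   `fix_point`).
#' @param frame An [build_frame()] result.
#' @param kind `"torsion"`, `"axial_X"`, `"axial_Y"` or `"axial_Z"`.
#' @param magnitude Load magnitude (N mm for torsion, N for axial); defaults
#'   2000 N mm and 200 N.
#' @param patch_radius Radius (mm) of the loaded node patch around Point 1.
#' @param fixed_radius Radius (mm) of the fixed node patch around Point 2.
#' @param load_point,fix_point Override the landmark points (mm).
#' @return A [boundary_conditions()] object.
#' @export
make_load_case <- function(mesh, frame,
                           kind = c("torsion", "axial_X", "axial_Y", "axial_Z"),
                           magnitude = NULL, patch_radius = 3,
                           fixed_radius = 8,
                           load_point = NULL, fix_point = NULL) {
  kind <- match.arg(kind)
  lm <- mesh$landmarks
  if (is.null(load_point)) {
    if (is.null(lm)) stop("mesh has no landmarks; supply load_point")
    load_point <- lm$point1
  }
  if (is.null(fix_point)) {
    if (is.null(lm)) stop("mesh has no landmarks; supply fix_point")
    fix_point <- lm$point2
  }
  d1 <- sqrt(colSums((t(mesh$nodes) - load_point)^2))
  d2 <- sqrt(colSums((t(mesh$nodes) - fix_point)^2))
  loaded <- which(d1 <= patch_radius)
  fixed <- which(d2 <= fixed_radius)
  if (length(loaded) < 3)
    stop("fewer than 3 nodes in the loaded patch; increase patch_radius")
  if (length(fixed) < 3)
    stop("fewer than 3 nodes in the fixed patch; increase fixed_radius")
  fixed <- setdiff(fixed, loaded)
  if (is.null(magnitude))
    magnitude <- if (kind == "torsion") 2000 else 200
  if (kind == "torsion") {
    force <- c(0, 0, 0)
    moment <- magnitude * frame$X
  } else {
    axis <- switch(kind, axial_X = frame$X, axial_Y = frame$Y,
                   axial_Z = frame$Z)
    force <- magnitude * axis
    moment <- c(0, 0, 0)
  }
  forces <- .distribute_load(mesh$nodes[loaded, , drop = FALSE], load_point,
                             force, moment)
  boundary_conditions(fixed, loaded, forces,
                      info = list(kind = kind, magnitude = magnitude,
                                  load_point = load_point,
                                  fix_point = fix_point, frame = frame))
}

#' Resultant force and moment of a load set
#'
#' Sums nodal forces and their moments about a reference point; used to
#' verify static equivalence of generated load cases.
#'
#' @param mesh A `tet_mesh10`.
#' @param bcs A `boundary_conditions` object.
#' @param ref_point Moment reference (mm).
#' @return List with `force` (N) and `moment` (N mm).
#' @export
load_resultant <- function(mesh, bcs, ref_point) {
  if (length(bcs$loaded_nodes) == 0)
    return(list(force = c(0, 0, 0), moment = c(0, 0, 0)))
  r <- sweep(mesh$nodes[bcs$loaded_nodes, , drop = FALSE], 2, ref_point)
  Fm <- bcs$forces
  list(force = colSums(Fm),
       moment = colSums(cbind(r[, 2] * Fm[, 3] - r[, 3] * Fm[, 2],
                              r[, 3] * Fm[, 1] - r[, 1] * Fm[, 3],
                              r[, 1] * Fm[, 2] - r[, 2] * Fm[, 1])))
}
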