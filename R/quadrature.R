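#' Quadrature rules on the reference tetrahedron
#'
#' Returns symmetric Gauss rules on the reference tetrahedron
#' \eqn{\{(r,s,t): r,s,t \ge 0, r+s+t \le 1\}}. Weights sum to the reference
#' volume 1/6. The 4-point rule is exact for polynomials of total degree 2
#' (sufficient for the stiffness of straight-sided quadratic tetrahedra); the
#' 5-point rule is exact to degree 3 and carries the classical negative centre
#' weight.
#'
#' @param n Number of points, 4 (default) or 5.
#' @return List with `points` (n x 3 matrix of (r,s,t)) and `weights`.
#' @export
tet10_rule <- function(n = 4) {
  if (n == 4) {
    a <- 0.5854101966249685
    b <- 0.1381966011250105
    pts <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
    w <- rep(1 / 24, 4)
  } else if (n == 5) {
    pts <- rbind(c(1/4, 1/4, 1/4),
                 c(1/2, 1/6, 1/6), c(1/6, 1/2, 1/6),
                 c(1/6, 1/6, 1/2), c(1/6, 1/6, 1/6))
    w <- c(-2/15, rep(3/40, 4)) # degree-3 rule, weights sum to 1/6
  } else {
    stop("supported rules: n = 4 or n = 5")
  }
  structure(list(points = pts, weights = w), class = "tet_quadrature")
}

#' Shape functions of the 10-node tetrahedron
#'
#' Evaluates the quadratic Lagrange shape functions and their parent-space
#' gradients at points of the reference tetrahedron. Node order: corners
#' 1-4, then mid-edge nodes on edges (1,2),(2,3),(3,1),(1,4),(2,4),(3,4).
#'
#' @param points m x 3 matrix of (r,s,t) reference coordinates.
#' @return List with `N` (m x 10) and `dN` (m x 10 x 3 array of d/d(r,s,t)).
#' @export
tet10_shape <- function(points) {
  points <- matrix(points, ncol = 3)
  m <- nrow(points)
  r <- points[, 1]; s <- points[, 2]; t <- points[, 3]
  L <- cbind(1 - r - s - t, r, s, t)
  dL <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  N <- matrix(0, m, 10)
  dN <- array(0, c(m, 10, 3))
  for (i in 1:4) {
    N[, i] <- L[, i] * (2 * L[, i] - 1)
    for (k in 1:3) dN[, i, k] <- (4 * L[, i] - 1) * dL[i, k]
  }
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in 1:6) {
    i <- ed[e, 1]; j <- ed[e, 2]
    N[, 4 + e] <- 4 * L[, i] * L[, j]
    for (k in 1:3) dN[, 4 + e, k] <- 4 * (L[, i] * dL[j, k] + L[, j] * dL[i, k])
  }
  list(N = N, dN = dN)
}

#' Map reference points into a TET10 element
#'
#' @param Xe 10 x 3 node coordinates of one element.
#' @param points m x 3 reference coordinates.
#' @return m x 3 physical coordinates.
#' @keywords internal
tet10_map <- function(Xe, points) {
  sh <- tet10_shape(points)
  sh$N %*% Xe
}
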