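# Assembly, static solves and verification against closed-form mechanics.

# independent element-stiffness oracle: separately coded shape gradients,
# composite integration (4-point rule on the 8 midpoint sub-tetrahedra),
# exact for the quadratic integrand of a straight-sided element
oracle_ke <- function(Xe, E, nu) {
  dshape <- function(r, s, t) {
    L <- c(1 - r - s - t, r, s, t)
    dL <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    dN <- matrix(0, 10, 3)
    for (i in 1:4) dN[i, ] <- (4 * L[i] - 1) * dL[i, ]
    ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    for (e in 1:6) {
      i <- ed[e, 1]; j <- ed[e, 2]
      dN[4 + e, ] <- 4 * (L[i] * dL[j, ] + L[j] * dL[i, ])
    }
    dN
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  msub <- function(i, j) (corners[i, ] + corners[j, ]) / 2
  subtets <- list()
  v <- corners
  m12 <- msub(1, 2); m13 <- msub(1, 3); m14 <- msub(1, 4)
  m23 <- msub(2, 3); m24 <- msub(2, 4); m34 <- msub(3, 4)
  subtets <- list(rbind(v[1, ], m12, m13, m14), rbind(m12, v[2, ], m23, m24),
                  rbind(m13, m23, v[3, ], m34), rbind(m14, m24, m34, v[4, ]),
                  rbind(m12, m13, m14, m24), rbind(m12, m13, m23, m24),
                  rbind(m13, m14, m24, m34), rbind(m13, m23, m24, m34))
  a <- 0.5854101966249685; b <- 0.1381966011250105
  bary <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
  bary <- cbind(1 - rowSums(bary), bary)
  ke <- matrix(0, 30, 30)
  for (S in subtets) {
    vol_ref <- abs(det(rbind(S[2, ] - S[1, ], S[3, ] - S[1, ],
                             S[4, ] - S[1, ]))) / 6
    for (q in 1:4) {
      p <- as.numeric(bary[q, ] %*% S)
      dN <- dshape(p[1], p[2], p[3])
      A <- t(Xe) %*% dN
      dNdx <- dN %*% solve(A)
      B <- matrix(0, 6, 30)
      for (aN in 1:10) {
        c0 <- 3 * (aN - 1)
        B[1, c0 + 1] <- dNdx[aN, 1]; B[2, c0 + 2] <- dNdx[aN, 2]
        B[3, c0 + 3] <- dNdx[aN, 3]
        B[4, c0 + 1] <- dNdx[aN, 2]; B[4, c0 + 2] <- dNdx[aN, 1]
        B[5, c0 + 2] <- dNdx[aN, 3]; B[5, c0 + 3] <- dNdx[aN, 2]
        B[6, c0 + 1] <- dNdx[aN, 3]; B[6, c0 + 3] <- dNdx[aN, 1]
      }
      ke <- ke + (vol_ref / 4) * det(A) * t(B) %*% D %*% B
    }
  }
  ke
}

test_that("element stiffness matches an independent integration oracle", {
  nodes <- rbind(c(0, 0, 0), c(1.1, 0.1, 0), c(-0.1, 0.9, 0.05),
                 c(0.2, 0.1, 1.2))
  m <- promote_to_quadratic(nodes, matrix(1:4, 1))
  mats <- uniform_mats(m, E = 1, nu = 0)
  K <- as.matrix(assemble_linear(m, mats))
  ke <- oracle_ke(m$nodes[m$conn[1, ], ], 1, 0)
  # same node order, so global = local here
  expect_lt(max(abs(K - ke)) / max(abs(ke)), 1e-12)
  # and for a Poisson material
  mats2 <- uniform_mats(m, E = 2500, nu = 0.33)
  K2 <- as.matrix(assemble_linear(m, mats2))
  ke2 <- oracle_ke(m$nodes[m$conn[1, ], ], 2500, 0.33)
  expect_lt(max(abs(K2 - ke2)) / max(abs(ke2)), 1e-12)
})

test_that("stiffness annihilates rigid-body modes", {
  m <- distorted_box()
  K <- assemble_linear(m, uniform_mats(m))
  nK <- max(abs(K))
  N <- nrow(m$nodes)
  u_t <- rep(c(1, -2, 0.5), N)
  expect_lt(max(abs(K %*% u_t)), 1e-10 * nK)
  rot <- cbind(-m$nodes[, 2], m$nodes[, 1], 0)
  expect_lt(max(abs(K %*% as.vector(t(rot)))), 1e-10 * nK)
})

test_that("linear and quadratic patch tests pass", {
  m <- distorted_box()
  nu <- 0.3
  mats <- uniform_mats(m, E = 1000, nu = nu)
  bnd <- box_boundary_nodes(m)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 2e-4, -5e-4, 3e-4, -1e-4, 3e-4, 4e-4), 3)
  uex <- m$nodes %*% A
  sol <- solve_static(m, mats, boundary_conditions(bnd, fixed_values = uex[bnd, ]))
  expect_lt(max(abs(sol$u - uex)) / max(abs(uex)), 1e-10)
  # quadratic equilibrium field: pure bending about z
  k <- 1e-3
  x <- m$nodes[, 1]; y <- m$nodes[, 2]; z <- m$nodes[, 3]
  uex2 <- cbind(k * x * y, -k / 2 * (x^2 + nu * (y^2 - z^2)), -k * nu * y * z)
  sol2 <- solve_static(m, mats, boundary_conditions(bnd, fixed_values = uex2[bnd, ]))
  expect_lt(max(abs(sol2$u - uex2)) / max(abs(uex2)), 1e-10)
})

test_that("linearised response scales exactly with the load", {
  tb <- cylinder_torsion(12, 3, 10)
  bcs2 <- tb$sol$bcs
  bcs2$forces <- bcs2$forces * 3.7
  sol2 <- solve_static(tb$mesh, uniform_mats(tb$mesh, tb$E, tb$nu), bcs2)
  expect_lt(max(abs(sol2$u - 3.7 * tb$sol$u)) / max(abs(sol2$u)), 1e-10)
  expect_lt(max(abs(sol2$principal - 3.7 * tb$sol$principal)) /
              max(abs(sol2$principal)), 1e-10)
})

test_that("solution is frame invariant", {
  tb <- cylinder_torsion(10, 3, 8)
  th <- 0.61; ps <- 0.32
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(ps), -sin(ps)), c(0, sin(ps), cos(ps)))
  m2 <- tb$mesh
  m2$nodes <- tb$mesh$nodes %*% t(R)
  bcs2 <- tb$sol$bcs
  bcs2$forces <- tb$sol$bcs$forces %*% t(R)
  sol2 <- solve_static(m2, uniform_mats(m2, tb$E, tb$nu), bcs2)
  expect_lt(max(abs(sol2$principal - tb$sol$principal)) /
              max(abs(tb$sol$principal)), 1e-9)
  expect_lt(max(abs(sol2$u - tb$sol$u %*% t(R))) / max(abs(sol2$u)), 1e-9)
})

test_that("torsion of a cylinder matches Saint-Venant within 2%", {
  errs <- vapply(list(c(8, 2, 8), c(12, 3, 12), c(16, 4, 16)), function(p)
    torsion_field_error(cylinder_torsion(p[1], p[2], p[3])), numeric(1))
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))        # monotone convergence
})

test_that("cantilever tip deflection matches Timoshenko theory within 3%", {
  E <- 2000; nu <- 0.3; R <- 4; L <- 40; P <- 10
  cy <- tet_mesh_cylinder(R, L, 16, 4, 16)
  fixed <- which(abs(cy$nodes[, 1]) < 1e-9)
  loaded <- which(abs(cy$nodes[, 1] - L) < 1e-9)
  Fm <- min_norm_load(cy$nodes[loaded, , drop = FALSE], c(L, 0, 0),
                      c(0, P, 0), c(0, 0, 0))
  sol <- solve_static(cy, uniform_mats(cy, E, nu),
                      boundary_conditions(fixed, loaded, Fm))
  tip <- mean(sol$u[loaded, 2])
  G <- E / (2 * (1 + nu)); I <- pi * R^4 / 4; A <- pi * R^2
  kap <- 6 * (1 + nu) / (7 + 6 * nu)
  delta <- P * L^3 / (3 * E * I) + P * L / (kap * G * A)
  expect_lt(abs(tip - delta) / delta, 0.03)
})

test_that("principal strains are sorted eigenvalues", {
  expect_equal(principal_strains(c(0.01, 0, -0.01, 0, 0, 0)),
               c(0.01, 0, -0.01))
  # pure shear gamma = 0.02
  expect_equal(principal_strains(c(0, 0, 0, 0.02, 0, 0)),
               c(0.01, 0, -0.01), tolerance = 1e-14)
  set.seed(5)
  for (i in 1:20) {
    S <- matrix(rnorm(9), 3); S <- (S + t(S)) / 2
    v <- c(S[1, 1], S[2, 2], S[3, 3], 2 * S[1, 2], 2 * S[2, 3], 2 * S[1, 3])
    expect_equal(principal_strains(v),
                 sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE),
                 tolerance = 1e-12)
    # rotation invariance
    qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
    Sr <- qr_ %*% S %*% t(qr_)
    expect_equal(principal_strains(Sr), principal_strains(S),
                 tolerance = 1e-12)
  }
})

test_that("hyperelastic solve agrees with linear elasticity at small strain", {
  m <- tet_mesh_box(c(10, 2, 2), c(5, 2, 2), region = "ossifying_epiphysis")
  mats <- uniform_mats(m, E = 100, nu = 0.3, kind = "neo_hookean_poro")
  fixed <- which(abs(m$nodes[, 1]) < 1e-9)
  bf <- boundary_faces(m)
  topf <- bf[apply(bf, 1, function(fc) all(abs(m$nodes[fc, 1] - 10) < 1e-9)), ]
  fm <- traction_forces(m, topf, c(0.01, 0, 0))
  loaded <- which(rowSums(abs(fm)) > 0)
  bcs <- boundary_conditions(fixed, loaded, fm[loaded, ])
  sh <- solve_static(m, mats, bcs, mode = "hyperelastic",
                     control = list(n_steps = 2))
  expect_true(sh$converged)
  sl <- solve_static(m, mats, bcs)
  expect_lt(abs(max(sh$principal[, 1]) - max(sl$principal[, 1])) /
              max(sl$principal[, 1]), 1e-3)
  # moderate stretch still converges and reports iterations
  fm2 <- traction_forces(m, topf, c(5, 0, 0))
  bcs2 <- boundary_conditions(fixed, loaded, fm2[loaded, ])
  sh2 <- solve_static(m, mats, bcs2, mode = "hyperelastic")
  expect_true(sh2$converged)
  expect_gt(sh2$newton_iterations, 0)
})

test_that("under-constrained systems are diagnosed", {
  m <- tet_mesh_box(c(1, 1, 1), c(1, 1, 1))
  mats <- uniform_mats(m)
  expect_error(suppressWarnings(
    solve_static(m, mats, boundary_conditions(integer(0)))),
    "singular|constrain")
})
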