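#' Boundary conditions for a static solve
#'
#' Fixed nodes are constrained in all three displacement components. Loads
#' are per-node force vectors on the loaded set, normally produced by
#' [make_load_case()]. Alternatively a rigid coupling can be given: the
#' listed nodes move as a rigid body whose reference point carries a resultant
#' force and moment (the kinematic-coupling idiom of commercial FE codes).
#'
#' @param fixed_nodes Integer node ids, fully fixed.
#' @param loaded_nodes Integer node ids carrying `forces`.
#' @param forces Matrix (length(loaded_nodes) x 3) of nodal forces (N).
#' @param rigid Optional list `list(nodes, ref_point, force, moment)`.
#' @param fixed_dofs Additional single-component constraints, as global dof
#'   indices (dof of node n, component k, is `3 (n-1) + k`); always held at
#'   zero. Used e.g. for laterally confined consolidation columns.
#' @param fixed_values Optional matrix (length(fixed_nodes) x 3) of
#'   prescribed displacements at the fixed nodes (default zero); supported
#'   in linearised mode.
#' @param info Optional metadata (load-case description).
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(fixed_nodes, loaded_nodes = integer(0),
                                forces = NULL, rigid = NULL,
                                fixed_dofs = integer(0), fixed_values = NULL,
                                info = list()) {
  fixed_nodes <- as.integer(fixed_nodes)
  loaded_nodes <- as.integer(loaded_nodes)
  if (length(intersect(fixed_nodes, loaded_nodes)) > 0)
    stop("fixed and loaded node sets must be disjoint")
  if (length(loaded_nodes) > 0) {
    forces <- matrix(forces, ncol = 3)
    stopifnot(nrow(forces) == length(loaded_nodes))
  }
  if (!is.null(fixed_values)) {
    fixed_values <- matrix(fixed_values, ncol = 3)
    stopifnot(nrow(fixed_values) == length(fixed_nodes))
  }
  if (!is.null(rigid) && length(intersect(fixed_nodes, rigid$nodes)) > 0)
    stop("fixed and rigidly coupled node sets must be disjoint")
  structure(list(fixed_nodes = fixed_nodes, loaded_nodes = loaded_nodes,
                 forces = forces, rigid = rigid,
                 fixed_dofs = as.integer(fixed_dofs),
                 fixed_values = fixed_values, info = info),
            class = "boundary_conditions")
}

# all constrained dofs of a boundary_conditions object
.constrained_dofs <- function(bcs) {
  union(.node_dofs(bcs$fixed_nodes), bcs$fixed_dofs)
}

# prescribed displacement vector (zero except fixed_values)
.prescribed_u <- function(n_dof, bcs) {
  u <- numeric(n_dof)
  if (!is.null(bcs$fixed_values))
    u[.node_dofs(bcs$fixed_nodes)] <- as.vector(t(bcs$fixed_values))
  u
}

.node_dofs <- function(nodes) {
  as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
}

#' Assemble the global linear-elastic stiffness matrix
#'
#' Symmetric sparse stiffness of the whole mesh with every element treated
#' as (linearised) isotropic elastic; Neo-Hookean records contribute their
#' small-strain moduli recovered from `(C10, D1)`. Before constraints the
#' operator is positive semi-definite with the six rigid-body null modes.
#'
#' @param mesh A `tet_mesh10`.
#' @param materials A `material_field` (one record per element).
#' @param rule Quadrature rule.
#' @return A `dsCMatrix` of dimension 3N x 3N.
#' @export
assemble_linear <- function(mesh, materials, rule = tet10_rule(4)) {
  stopifnot(length(materials$E) == nrow(mesh$conn))
  pr <- .linearised_props(materials)
  tr <- cpp_tet10_stiffness(mesh$nodes, mesh$conn, pr$E, pr$nu,
                            rule$points, rule$weights)
  n <- 3 * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n),
                       symmetric = TRUE)
}

# external force vector from boundary conditions
.external_force <- function(n_dof, bcs) {
  f <- numeric(n_dof)
  if (length(bcs$loaded_nodes) > 0) {
    f[.node_dofs(bcs$loaded_nodes)] <- as.vector(t(bcs$forces))
  }
  f
}

# rigid-coupling transformation: u = T q with q = [u_free ; u0 (3) ; theta (3)]
.rigid_transform <- function(n_dof, free_dofs, rigid) {
  nodes <- rigid$nodes
  r <- sweep(rigid$coords, 2, rigid$ref_point)
  nq <- length(free_dofs) + 6
  # free part
  ti <- free_dofs
  tj <- seq_along(free_dofs)
  tx <- rep(1, length(free_dofs))
  m0 <- length(free_dofs)
  for (k in 1:3) {                        # u0 columns
    ti <- c(ti, 3 * (nodes - 1) + k)
    tj <- c(tj, rep(m0 + k, length(nodes)))
    tx <- c(tx, rep(1, length(nodes)))
  }
  # theta columns: u = theta x r -> u_x = th_y r_z - th_z r_y, etc.
  comp <- list(cbind(0 * r[, 1], r[, 3], -r[, 2]),
               cbind(-r[, 3], 0 * r[, 1], r[, 1]),
               cbind(r[, 2], -r[, 1], 0 * r[, 1]))
  for (k in 1:3) {
    for (j in 1:3) {
      ti <- c(ti, 3 * (nodes - 1) + k)
      tj <- c(tj, rep(m0 + 3 + j, length(nodes)))
      tx <- c(tx, comp[[k]][, j])
    }
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_dof, nq))
}

#' Solve the static problem
#'
#' Linearised mode solves the small-strain elastic system in one sparse
#' Cholesky factorisation, treating Neo-Hookean elements through their
#' recovered small-strain moduli. Hyperelastic mode keeps diaphysis elements
#' linear and solves the Neo-Hookean elements by Newton iteration on the
#' total-Lagrangian residual, with incremental load application.
#'
#' @param mesh A `tet_mesh10`.
#' @param materials A `material_field`.
#' @param bcs A [boundary_conditions()] object.
#' @param mode `"linearised"` or `"hyperelastic"`.
#' @param rule Quadrature rule.
#' @param control Newton controls: `tol` (relative residual), `maxit`
#'   (iterations per load step), `n_steps` (load increments).
#' @return Object of class `solution_field`: nodal displacements `u` (N x 3,
#'   mm), volume-averaged element strain tensors `strain` (M x 6 Voigt,
#'   engineering shears), sorted principal strains `principal` (M x 3),
#'   `converged`, `newton_iterations`, and the inputs for downstream
#'   post-processing.
#' @export
solve_static <- function(mesh, materials, bcs,
                         mode = c("linearised", "hyperelastic"),
                         rule = tet10_rule(4),
                         control = list(tol = 1e-8, maxit = 30, n_steps = 5)) {
  mode <- match.arg(mode)
  n_dof <- 3 * nrow(mesh$nodes)
  f <- .external_force(n_dof, bcs)
  fixed <- .constrained_dofs(bcs)
  if (mode == "linearised") {
    K <- assemble_linear(mesh, materials, rule)
    if (is.null(bcs$rigid)) {
      free <- setdiff(seq_len(n_dof), fixed)
      u <- .prescribed_u(n_dof, bcs)
      rhs <- f[free]
      if (any(u != 0))
        rhs <- rhs - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
      Kff <- Matrix::forceSymmetric(K[free, free])
      ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE),
                     error = function(e)
                       stop("stiffness singular after constraints; check that the fixed set removes all rigid-body modes"))
      u[free] <- as.numeric(Matrix::solve(ch, rhs))
    } else {
      rg <- bcs$rigid
      rg$coords <- mesh$nodes[rg$nodes, , drop = FALSE]
      free <- setdiff(seq_len(n_dof), union(fixed, .node_dofs(rg$nodes)))
      T <- .rigid_transform(n_dof, free, rg)
      Khat <- Matrix::forceSymmetric(Matrix::t(T) %*% K %*% T)
      fhat <- as.numeric(Matrix::t(T) %*% f)
      m0 <- length(free)
      fhat[m0 + 1:3] <- fhat[m0 + 1:3] + rg$force
      fhat[m0 + 4:6] <- fhat[m0 + 4:6] + rg$moment
      ch <- Matrix::Cholesky(Khat, LDL = FALSE, super = TRUE)
      q <- as.numeric(Matrix::solve(ch, fhat))
      u <- as.numeric(T %*% q)
    }
    st <- cpp_tet10_strains(mesh$nodes, mesh$conn, u, rule$points, rule$weights)
    return(structure(list(mesh = mesh, materials = materials, bcs = bcs,
                          u = matrix(u, ncol = 3, byrow = TRUE),
                          strain = st$strain, principal = st$principal,
                          converged = TRUE, newton_iterations = 0L,
                          mode = mode),
                     class = "solution_field"))
  }
  # hyperelastic: linear part assembled once, NH part re-linearised
  if (!is.null(bcs$rigid))
    stop("rigid coupling is only supported in linearised mode")
  if (!is.null(bcs$fixed_values) && any(bcs$fixed_values != 0))
    stop("prescribed non-zero displacements are only supported in linearised mode")
  is_nh <- materials$kind == "neo_hookean_poro"
  ctrl <- utils::modifyList(list(tol = 1e-8, maxit = 30, n_steps = 5), control)
  free <- setdiff(seq_len(n_dof), fixed)
  K_lin <- NULL
  if (any(!is_nh)) {
    tr <- cpp_tet10_stiffness(mesh$nodes, mesh$conn[!is_nh, , drop = FALSE],
                              materials$E[!is_nh], materials$nu[!is_nh],
                              rule$points, rule$weights)
    K_lin <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                  dims = c(n_dof, n_dof), symmetric = TRUE)
  }
  conn_nh <- mesh$conn[is_nh, , drop = FALSE]
  C10 <- materials$C10[is_nh]
  D1 <- materials$D1[is_nh]
  u <- numeric(n_dof)
  it_total <- 0L
  converged <- TRUE
  for (s in seq_len(ctrl$n_steps)) {
    fs <- f * (s / ctrl$n_steps)
    ok <- FALSE
    for (it in seq_len(ctrl$maxit)) {
      nh <- cpp_nh_assemble(mesh$nodes, conn_nh, u, C10, D1,
                            rule$points, rule$weights, TRUE)
      res <- nh$fint - fs
      if (!is.null(K_lin)) res <- res + as.numeric(K_lin %*% u)
      rnorm <- sqrt(sum(res[free]^2))
      fnorm <- max(sqrt(sum(fs[free]^2)), 1e-12)
      if (rnorm <= ctrl$tol * fnorm) { ok <- TRUE; break }
      Kt <- Matrix::sparseMatrix(i = nh$i, j = nh$j, x = nh$x,
                                 dims = c(n_dof, n_dof))
      Kt <- (Kt + Matrix::t(Kt)) / 2
      if (!is.null(K_lin)) Kt <- Kt + K_lin
      du <- numeric(n_dof)
      du[free] <- as.numeric(Matrix::solve(Kt[free, free], -res[free]))
      u <- u + du
      it_total <- it_total + 1L
    }
    if (!ok) { converged <- FALSE; break }
  }
  if (!converged)
    warning("Newton iteration did not converge; partial result returned")
  st <- cpp_tet10_strains(mesh$nodes, mesh$conn, u, rule$points, rule$weights)
  structure(list(mesh = mesh, materials = materials, bcs = bcs,
                 u = matrix(u, ncol = 3, byrow = TRUE),
                 strain = st$strain, principal = st$principal,
                 converged = converged, newton_iterations = it_total,
                 mode = mode),
            class = "solution_field")
}

#' Principal strains of a symmetric strain tensor
#'
#' Sorted (descending) eigenvalues. Accepts a length-6 Voigt vector
#' (xx, yy, zz, gxy, gyz, gzx; engineering shears), a 3 x 3 symmetric
#' tensor, or an M x 6 matrix of Voigt rows.
#'
#' @param strain Strain tensor(s).
#' @return Length-3 vector, or M x 3 matrix for matrix input.
#' @export
principal_strains <- function(strain) {
  one <- function(v) {
    Tm <- matrix(c(v[1], v[4] / 2, v[6] / 2,
                   v[4] / 2, v[2], v[5] / 2,
                   v[6] / 2, v[5] / 2, v[3]), 3, 3)
    sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }
  if (is.matrix(strain) && all(dim(strain) == c(3, 3))) {
    return(sort(eigen((strain + t(strain)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values, decreasing = TRUE))
  }
  if (is.matrix(strain)) return(t(apply(strain, 1, one)))
  one(strain)
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf("solution_field (%s): %d nodes, %d elements\n", x$mode,
              nrow(x$u), nrow(x$strain)))
  cat(sprintf("  max |u| = %.4g mm, principal strain range [%.3g, %.3g]\n",
              max(sqrt(rowSums(x$u^2))), min(x$principal), max(x$principal)))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}
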