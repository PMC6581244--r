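#' Transient linear poroelastic solve (u-p formulation)
#'
#' Solves small-strain Biot consolidation with incompressible constituents:
#' quadratic displacement interpolation, linear (corner-node) pore pressure
#' (the stable Taylor-Hood pairing) and backward-Euler time stepping. The
#' load is applied at t = 0+ and the initial state is the undrained
#' (incompressible) response; as t grows with drained boundaries the solution
#' approaches the drained static solve.
#'
#' Only elements whose material record is `neo_hookean_poro` carry pore
#' pressure; other elements are solid elastic and impermeable. The solid
#' skeleton is treated through its linearised moduli.
#'
#' @param mesh A `tet_mesh10`.
#' @param materials A `material_field`; poro elements must have positive
#'   permeability (mm^4/(N s) in the consistent mm-N-s system).
#' @param bcs A [boundary_conditions()] object (displacement BCs and loads).
#' @param time_steps Strictly increasing positive solution times (s).
#' @param drained_nodes Node ids where the pore pressure is prescribed zero
#'   (free-draining boundary).
#' @param rule Quadrature rule.
#' @return Object of class `poro_solution`: `times` (with the undrained
#'   instant 0 prepended), `u` (list of N x 3 displacement matrices),
#'   `p` (list of pressure vectors over pressure-carrying corner nodes),
#'   `pressure_nodes`, and the final-state element strains.
#' @export
solve_poroelastic <- function(mesh, materials, bcs, time_steps,
                              drained_nodes = integer(0),
                              rule = tet10_rule(4)) {
  stopifnot(length(time_steps) >= 1)
  if (any(diff(c(0, time_steps)) <= 0))
    stop("time steps must be strictly increasing and positive (zero or negative time step)")
  is_poro <- materials$kind == "neo_hookean_poro"
  if (!any(is_poro)) stop("no poroelastic elements in the material field")
  perm <- materials$permeability[is_poro]
  if (any(!is.finite(perm)) || any(perm <= 0))
    stop("non-positive permeability on poroelastic element(s)")
  n_node <- nrow(mesh$nodes)
  n_dof <- 3 * n_node
  K <- assemble_linear(mesh, materials, rule)
  f <- .external_force(n_dof, bcs)
  fixed <- .constrained_dofs(bcs)
  free <- setdiff(seq_len(n_dof), fixed)

  conn_p <- mesh$conn[is_poro, , drop = FALSE]
  pnodes <- setdiff(sort(unique(as.vector(conn_p[, 1:4]))), drained_nodes)
  pmap <- integer(n_node)
  pmap[pnodes] <- seq_along(pnodes)
  np <- length(pnodes)
  pm <- cpp_poro_mats(mesh$nodes, conn_p, perm, pmap, rule$points, rule$weights)
  Q <- Matrix::sparseMatrix(i = pm$qi, j = pm$qj, x = pm$qx,
                            dims = c(n_dof, np))
  H <- Matrix::sparseMatrix(i = pm$hi, j = pm$hj, x = pm$hx,
                            dims = c(np, np))
  Qf <- Q[free, , drop = FALSE]
  Kff <- K[free, free]

  solve_step <- function(dt, u_prev_free) {
    A <- rbind(cbind(Kff, -Qf),
               cbind(Matrix::t(-Qf), -dt * H))
    rhs <- c(f[free], -as.numeric(Matrix::t(Qf) %*% u_prev_free))
    sol <- as.numeric(Matrix::solve(A, rhs))
    list(u = sol[seq_along(free)], p = sol[length(free) + seq_len(np)])
  }
  # undrained instant: dt = 0 enforces incompressibility weakly
  st0 <- solve_step(0, numeric(length(free)))
  times <- c(0, time_steps)
  us <- vector("list", length(times))
  ps <- vector("list", length(times))
  pack_u <- function(uf) {
    u <- numeric(n_dof)
    u[free] <- uf
    matrix(u, ncol = 3, byrow = TRUE)
  }
  us[[1]] <- pack_u(st0$u)
  ps[[1]] <- st0$p
  u_prev <- st0$u
  for (i in seq_along(time_steps)) {
    dt <- times[i + 1] - times[i]
    st <- solve_step(dt, u_prev)
    us[[i + 1]] <- pack_u(st$u)
    ps[[i + 1]] <- st$p
    u_prev <- st$u
  }
  uend <- numeric(n_dof)
  uend[free] <- u_prev
  stend <- cpp_tet10_strains(mesh$nodes, mesh$conn, uend,
                             rule$points, rule$weights)
  structure(list(times = times, u = us, p = ps, pressure_nodes = pnodes,
                 strain = stend$strain, principal = stend$principal,
                 mesh = mesh, materials = materials, bcs = bcs),
            class = "poro_solution")
}
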