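# Shared fixtures, built once per test run. The femur models are the study
# conditions of the whole analysis; building them in one place keeps every
# test on identical inputs.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

femur_model <- function(which = "4mo", target_edge = 2.5) {
  fixture(paste0("femur_", which), function() {
    ph <- generate_femur(femur_preset(which))
    mesh <- mesh_from_labels(ph$image, target_edge, landmarks = ph$landmarks)
    mats <- build_material_field(ph$image, mesh)
    frame <- build_frame(mesh)
    bcs <- make_load_case(mesh, frame, "torsion")
    sol <- solve_static(mesh, mats, bcs)
    list(ph = ph, mesh = mesh, mats = mats, frame = frame, bcs = bcs,
         sol = sol)
  })
}

# bone-only companion model sharing the diaphysis geometry, torque applied
# over the free proximal end face
bone_only_model <- function(which = "4mo", target_edge = 2.5,
                            patch_radius = 9) {
  fixture(paste0("bone_", which), function() {
    fm <- femur_model(which, target_edge)
    img_b <- bone_only_image(fm$ph$image)
    mesh_b <- suppressWarnings(mesh_from_labels(img_b, target_edge))
    xmin <- min(mesh_b$nodes[, 1])
    endn <- mesh_b$nodes[mesh_b$nodes[, 1] < xmin + target_edge, , drop = FALSE]
    mesh_b$landmarks <- landmark_set(
      c(xmin, mean(endn[, 2]), mean(endn[, 3])), fm$ph$landmarks$point2)
    frame_b <- build_frame(mesh_b)
    bcs_b <- make_load_case(mesh_b, frame_b, "torsion",
                            patch_radius = patch_radius)
    mats_b <- build_material_field(img_b, mesh_b)
    sol_b <- solve_static(mesh_b, mats_b, bcs_b)
    list(mesh = mesh_b, mats = mats_b, frame = frame_b, bcs = bcs_b,
         sol = sol_b)
  })
}

# uniform-material cylinder under an end couple (Saint-Venant benchmark)
cylinder_torsion <- function(n_theta, n_r, n_z, radius = 5, len = 50,
                             E = 1000, nu = 0.3, torque = 2000) {
  cy <- tet_mesh_cylinder(radius, len, n_theta, n_r, n_z)
  fixed <- which(abs(cy$nodes[, 1]) < 1e-9)
  loaded <- which(abs(cy$nodes[, 1] - len) < 1e-9)
  Fm <- min_norm_load(cy$nodes[loaded, , drop = FALSE], c(len, 0, 0),
                      c(0, 0, 0), c(torque, 0, 0))
  bcs <- boundary_conditions(fixed, loaded, Fm, info = list(magnitude = torque))
  mats <- material_field("linear_elastic", E = rep(E, nrow(cy$conn)),
                         nu = rep(nu, nrow(cy$conn)))
  sol <- solve_static(cy, mats, bcs)
  list(mesh = cy, sol = sol, E = E, nu = nu, torque = torque,
       radius = radius, len = len)
}

min_norm_load <- function(positions, ref, force, moment) {
  infantfem:::.distribute_load(positions, ref, force, moment)
}

# worst-case relative error of surface strains against the circular-shaft
# closed form, evaluated at element centroid radii over the mid span
torsion_field_error <- function(tb) {
  G <- tb$E / (2 * (1 + tb$nu))
  J <- pi * tb$radius^4 / 2
  cen <- element_centroids(tb$mesh)
  rho <- sqrt(cen[, 2]^2 + cen[, 3]^2)
  mid <- cen[, 1] > 0.3 * tb$len & cen[, 1] < 0.7 * tb$len
  pred <- tb$torque * rho[mid] / (G * J) / 2
  max(abs(tb$sol$principal[mid, 1] - pred) / max(pred))
}

# distorted unit-ish box mesh for patch tests (interior corners perturbed,
# mid-edge nodes re-inserted at midpoints)
distorted_box <- function(seed = 42) {
  fixture("distorted_box", function() {
    m0 <- tet_mesh_box(c(2, 1, 1), c(4, 3, 3))
    nc <- max(m0$conn[, 1:4])
    corners <- m0$nodes[1:nc, ]
    inner <- corners[, 1] > 1e-9 & corners[, 1] < 2 - 1e-9 &
      corners[, 2] > 1e-9 & corners[, 2] < 1 - 1e-9 &
      corners[, 3] > 1e-9 & corners[, 3] < 1 - 1e-9
    set.seed(seed)
    corners[inner, ] <- corners[inner, ] +
      matrix(runif(sum(inner) * 3, -0.04, 0.04), ncol = 3)
    promote_to_quadratic(corners, m0$conn[, 1:4])
  })
}

box_boundary_nodes <- function(mesh, lx = 2, ly = 1, lz = 1) {
  which(mesh$nodes[, 1] < 1e-9 | mesh$nodes[, 1] > lx - 1e-9 |
        mesh$nodes[, 2] < 1e-9 | mesh$nodes[, 2] > ly - 1e-9 |
        mesh$nodes[, 3] < 1e-9 | mesh$nodes[, 3] > lz - 1e-9)
}

uniform_mats <- function(mesh, E = 1000, nu = 0.3,
                         kind = "linear_elastic", ...) {
  material_field(kind, E = rep(E, nrow(mesh$conn)),
                 nu = rep(nu, nrow(mesh$conn)), ...)
}

terzaghi_fixture <- function() {
  fixture("terzaghi", function() {
    H <- 10; E <- 10; nu <- 0.2; k <- 0.00455
    m <- tet_mesh_box(c(H, 1, 1), c(40, 1, 1), region = "ossifying_epiphysis")
    mats <- uniform_mats(m, E, nu, kind = "neo_hookean_poro",
                         permeability = k)
    bot <- which(abs(m$nodes[, 1] - H) < 1e-9)
    lateral <- as.vector(vapply(seq_len(nrow(m$nodes)),
                                function(n) c(3 * n - 1, 3 * n), numeric(2)))
    bf <- boundary_faces(m)
    topf <- bf[apply(bf, 1, function(fc) all(abs(m$nodes[fc, 1]) < 1e-9)), ]
    fmat <- traction_forces(m, topf, c(1, 0, 0))
    loaded <- which(rowSums(abs(fmat)) > 0)
    bcs <- boundary_conditions(integer(0), loaded, fmat[loaded, ],
                               fixed_dofs = c(3 * (bot - 1) + 1, lateral))
    drained <- which(abs(m$nodes[, 1]) < 1e-9)
    Eoed <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
    cv <- k * Eoed
    Treport <- exp(seq(log(0.02), log(1.5), length.out = 20))
    treport <- Treport * H^2 / cv
    tgrid <- sort(unique(c(exp(seq(log(min(treport) / 50),
                                   log(max(treport)), length.out = 160)),
                           treport)))
    ps <- solve_poroelastic(m, mats, bcs, tgrid, drained_nodes = drained)
    list(m = m, mats = mats, bcs = bcs, ps = ps, H = H, cv = cv,
         Treport = Treport, treport = treport,
         top = which(abs(m$nodes[, 1]) < 1e-9), E = E, nu = nu)
  })
}

terzaghi_series <- function(Tv) {
  vapply(Tv, function(T) {
    m <- pi * (2 * (0:300) + 1) / 2
    1 - sum(2 / m^2 * exp(-m^2 * T))
  }, numeric(1))
}
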