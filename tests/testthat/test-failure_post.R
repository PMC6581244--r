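# Strain-limit failure criterion and the epiphysis-effect comparison.

test_that("strain extrema behave on degenerate and imposed fields", {
  tb <- cylinder_torsion(10, 3, 8)
  bcs0 <- tb$sol$bcs
  bcs0$forces <- bcs0$forces * 0
  sol0 <- solve_static(tb$mesh, uniform_mats(tb$mesh, tb$E, tb$nu), bcs0)
  ex <- strain_extrema(sol0)
  expect_equal(ex$max_tensile, 0, tolerance = 1e-12)
  expect_equal(ex$min_compressive, 0, tolerance = 1e-12)
  expect_error(strain_extrema(tb$sol, logical(0)), "empty")
  # imposed homogeneous uniaxial strain on a single element
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m1 <- promote_to_quadratic(nodes, matrix(1:4, 1))
  fake <- structure(list(mesh = m1,
                         principal = matrix(c(0.01, 0, 0), 1),
                         strain = matrix(c(0.01, 0, 0, 0, 0, 0), 1),
                         bcs = boundary_conditions(1L, info = list(magnitude = 1)),
                         converged = TRUE), class = "solution_field")
  expect_equal(strain_extrema(fake)$max_tensile, 0.01)
})

test_that("torsion failure initiates at the outer surface", {
  tb <- cylinder_torsion(12, 3, 12)
  fr <- load_to_fail(tb$sol, failure_criterion(region_mask = "all"),
                     applied_load = tb$torque)
  cen <- element_centroids(tb$mesh)
  rho <- sqrt(cen[fr$limiting_element, 2]^2 + cen[fr$limiting_element, 3]^2)
  expect_gt(rho, 0.8 * tb$radius)
})

test_that("linear scaling identities hold exactly", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m1 <- promote_to_quadratic(nodes, matrix(1:4, 1))
  crit <- failure_criterion(region_mask = "all")
  mk <- function(e1, e3) structure(
    list(mesh = m1, principal = matrix(c(e1, 0, e3), 1),
         bcs = boundary_conditions(1L, info = list(magnitude = 2000)),
         converged = TRUE), class = "solution_field")
  # max principal strain exactly at the tensile limit: capacity = probe
  expect_equal(load_to_fail(mk(0.0073, 0), crit)$load_to_fail, 2000)
  # double the limit strain: capacity halves
  r <- load_to_fail(mk(0.0146, -1e-4), crit)
  expect_equal(r$load_to_fail, 1000)
  expect_identical(r$limiting_mode, "tension")
  # compression-limited case
  rc <- load_to_fail(mk(1e-4, -0.0208), crit)
  expect_equal(rc$load_to_fail, 1000)
  expect_identical(rc$limiting_mode, "compression")
  expect_false(rc$tension_first)
  # zero strain flags infinite capacity
  expect_warning(ri <- load_to_fail(mk(0, 0), crit), "infinite")
  expect_equal(ri$load_to_fail, Inf)
})

test_that("capacity is independent of the probe load", {
  fm <- femur_model("4mo")
  crit <- failure_criterion(boundary_buffer = 16)
  b1 <- make_load_case(fm$mesh, fm$frame, "torsion", magnitude = 2000)
  b2 <- make_load_case(fm$mesh, fm$frame, "torsion", magnitude = 517)
  f1 <- load_to_fail(solve_static(fm$mesh, fm$mats, b1), crit)
  f2 <- load_to_fail(solve_static(fm$mesh, fm$mats, b2), crit)
  expect_lt(abs(f1$load_to_fail - f2$load_to_fail) / f1$load_to_fail, 1e-8)
})

test_that("enlarging the mask never increases the capacity", {
  fm <- femur_model("4mo")
  f_dia <- load_to_fail(fm$sol, failure_criterion())
  f_all <- load_to_fail(fm$sol, failure_criterion(region_mask = "all"))
  expect_lte(f_all$load_to_fail, f_dia$load_to_fail)
})

test_that("the tension-first flag reports the governing mode", {
  fm <- femur_model("4mo")
  fr <- load_to_fail(fm$sol, failure_criterion(boundary_buffer = 16))
  expect_identical(fr$tension_first,
                   fr$max_tensile_strain / 0.0073 >=
                     fr$max_compressive_strain / 0.0104)
  # on the phantom under torsion the shaft fails first in tension
  expect_true(fr$tension_first)
})

test_that("hyperelastic bisection agrees with linear scaling at small strain", {
  m <- tet_mesh_box(c(10, 2, 2), c(4, 2, 2), region = "ossifying_epiphysis")
  mats <- uniform_mats(m, E = 500, nu = 0.2, kind = "neo_hookean_poro")
  fixed <- which(abs(m$nodes[, 1]) < 1e-9)
  bf <- boundary_faces(m)
  topf <- bf[apply(bf, 1, function(fc) all(abs(m$nodes[fc, 1] - 10) < 1e-9)), ]
  fm <- traction_forces(m, topf, c(1, 0, 0))
  loaded <- which(rowSums(abs(fm)) > 0)
  bcs <- boundary_conditions(fixed, loaded, fm[loaded, ],
                             info = list(magnitude = 4))
  crit <- failure_criterion(region_mask = "all")
  lin <- load_to_fail(solve_static(m, mats, bcs), crit)
  hyp <- load_to_fail_hyperelastic(m, mats, bcs, crit,
                                   control = list(n_steps = 1))
  expect_lt(abs(hyp$load_to_fail - lin$load_to_fail) / lin$load_to_fail, 0.02)
})

test_that("the epiphysis effect report compares compatible models", {
  fm <- femur_model("4mo")
  bm <- bone_only_model("4mo")
  crit <- failure_criterion(boundary_buffer = 16)
  rep <- epiphysis_effect_report(fm$sol, bm$sol, crit)
  expect_true(is.finite(rep$ratio))
  expect_equal(nrow(rep$profile), 20)
  expect_gt(rep$transition_max_e1, rep$shaft_median_e1)
  # half a shaft is not a compatible comparison model
  cen <- element_centroids(fm$mesh)
  half <- subset_mesh(fm$mesh, fm$mesh$region == "diaphysis" &
                        cen[, 1] < 60)
  fake <- fm$sol
  fake$mesh <- half
  fake$principal <- fm$sol$principal[fm$mesh$region == "diaphysis" &
                                       cen[, 1] < 60, , drop = FALSE]
  expect_error(epiphysis_effect_report(fm$sol, fake, crit), "incompatible")
})

test_that("utilisation field flags the limiting element at 1", {
  fm <- femur_model("4mo")
  crit <- failure_criterion(boundary_buffer = 16)
  fr <- load_to_fail(fm$sol, crit)
  util <- utilisation_field(fm$sol, crit)
  mask <- criterion_mask(fm$mesh, crit, fm$sol$bcs)
  scale <- fr$load_to_fail / fr$applied_load
  expect_equal(max(util[mask]) * scale, 1, tolerance = 1e-9)
})
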