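# Quadratic tetrahedra: shape functions, quadrature, promotion, meshing and
# file round trips.

test_that("quadrature rules integrate quadratics exactly", {
  for (n in c(4, 5)) {
    r <- tet10_rule(n)
    expect_equal(sum(r$weights), 1 / 6, tolerance = 1e-15)
    x <- r$points[, 1]; y <- r$points[, 2]
    expect_equal(sum(r$weights * x^2), 1 / 60, tolerance = 1e-14)
    expect_equal(sum(r$weights * x * y), 1 / 120, tolerance = 1e-14)
  }
})

test_that("shape functions partition unity and are nodal", {
  set.seed(7)
  # random points inside the reference tetrahedron
  p <- matrix(runif(300), ncol = 3)
  p <- p[rowSums(p) < 1, , drop = FALSE]
  while (nrow(p) < 100) {
    q <- matrix(runif(300), ncol = 3)
    p <- rbind(p, q[rowSums(q) < 1, , drop = FALSE])
  }
  p <- p[1:100, ]
  sh <- tet10_shape(p)
  expect_lt(max(abs(rowSums(sh$N) - 1)), 1e-12)
  expect_lt(max(abs(apply(sh$dN, c(1, 3), sum))), 1e-12)
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(.5, 0, 0), c(.5, .5, 0), c(0, .5, 0),
                 c(0, 0, .5), c(.5, 0, .5), c(0, .5, .5))
  expect_equal(tet10_shape(nodes)$N, diag(10), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("promotion inserts one shared node per unique edge", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m1 <- promote_to_quadratic(nodes, matrix(1:4, 1))
  expect_equal(nrow(m1$nodes), 10)
  # two tets sharing a face: 5 corners + 9 unique edges
  nodes2 <- rbind(nodes, c(1, 1, 1))
  conn2 <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  m2 <- promote_to_quadratic(nodes2, conn2)
  expect_equal(nrow(m2$nodes), 14)
  expect_error(promote_to_quadratic(m2$nodes, m2$conn), "already quadratic")
  expect_error(promote_to_quadratic(nodes, matrix(c(1, 2, 3, 3), 1)),
               "duplicate")
})

test_that("element volumes match closed forms and a Monte-Carlo oracle", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- promote_to_quadratic(nodes, matrix(1:4, 1))
  expect_equal(element_volume(m), 1 / 6, tolerance = 1e-14)
  m2 <- m; m2$nodes <- m$nodes * 2
  expect_equal(element_volume(m2), 8 / 6, tolerance = 1e-13)
  # curved element: displace one mid-edge node, integrate |J| by dense
  # Monte-Carlo over the reference tetrahedron as the oracle
  mc <- m
  mc$nodes[5, ] <- mc$nodes[5, ] + c(0, 0.06, 0.04)
  v_quad <- element_volume(mc, rule = tet10_rule(5))
  set.seed(11)
  p <- matrix(runif(6e5), ncol = 3)
  p <- p[rowSums(p) < 1, , drop = FALSE]
  sh <- tet10_shape(p)
  detj <- vapply(seq_len(nrow(p)), function(i) {
    A <- t(mc$nodes[mc$conn[1, ], ]) %*% sh$dN[i, , ]
    det(A)
  }, numeric(1))
  v_mc <- mean(detj) / 6
  expect_lt(abs(v_quad - v_mc) / v_mc, 0.005)
})

test_that("element volumes sum to the domain volume", {
  m <- tet_mesh_box(c(2, 1, 3), c(3, 2, 4))
  expect_equal(sum(element_volume(m)), 6, tolerance = 1e-12)
  expect_equal(sum(element_volume(distorted_box())), 2, tolerance = 1e-10)
})

test_that("label meshing honours volume, orientation and region majority", {
  n <- 20L
  lab <- array(1L, c(n, n, n))
  img <- structure(list(intensities = array(1000, dim(lab)), labels = lab,
                        spacing = rep(1 / n, 3), origin = c(0, 0, 0)),
                   class = "voxel_image")
  mesh <- mesh_from_labels(img, 0.5)
  expect_lt(abs(sum(element_volume(mesh)) - 1), 0.03)
  expect_true(all(infantfem:::cpp_corner_jacobians(mesh$nodes, mesh$conn) > 0))
  expect_true(all(mesh$region == "diaphysis"))
  # half the cube epiphysis: ties (exact 50/50 blocks) go to the epiphysis
  lab2 <- lab
  lab2[, , 1:(n / 2)] <- 3L
  img2 <- img; img2$labels <- lab2
  mesh2 <- mesh_from_labels(img2, 0.5)
  cen <- element_centroids(mesh2)
  expect_true(all(mesh2$region[cen[, 3] < 0.5] == "ossifying_epiphysis"))
  expect_true(all(mesh2$region[cen[, 3] > 0.5] == "diaphysis"))
  # empty image is rejected
  img0 <- img; img0$labels <- array(0L, dim(lab))
  expect_error(mesh_from_labels(img0, 0.5), "no non-background")
})

test_that("preset femur mesh volume tracks the labelled volume", {
  fm <- femur_model("4mo")
  vol_mesh <- sum(element_volume(fm$mesh))
  vol_lab <- sum(fm$ph$image$labels != 0) * prod(fm$ph$image$spacing)
  expect_lt(abs(vol_mesh - vol_lab) / vol_lab, 0.03)
  expect_lt(abs(vol_mesh / 1000 - 13.13) / 13.13, 0.03)
})

test_that("meshes round-trip through VTU and INP", {
  m <- tet_mesh_box(c(2, 1, 1), c(2, 1, 1))
  m$region[1:3] <- "ossifying_epiphysis"
  td <- withr::local_tempdir()
  for (ext in c("vtu", "inp")) {
    f <- file.path(td, paste0("m.", ext))
    write_mesh(m, f)
    m2 <- read_mesh(f)
    expect_lt(max(abs(m$nodes - m2$nodes)) / max(abs(m$nodes)), 1e-9)
    expect_identical(m$conn, m2$conn)
    expect_identical(m$region, m2$region)
  }
  expect_error(write_mesh(m, file.path(td, "m.stl")), "unsupported")
})

test_that("INP export follows the C3D10 node ordering convention", {
  # hand-built element with distinguishable coordinates
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  m <- promote_to_quadratic(nodes, matrix(1:4, 1))
  td <- withr::local_tempdir()
  f <- file.path(td, "e.inp")
  write_mesh(m, f)
  lines <- readLines(f)
  eline <- lines[grep("^1, ", lines)[2]]   # element record (node 1 line is first)
  ids <- as.integer(strsplit(eline, ",")[[1]])[-1]
  expect_equal(length(ids), 10)
  # mid-side nodes 5..10 must be midpoints of edges (1,2),(2,3),(3,1),(1,4),(2,4),(3,4)
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in 1:6) {
    expected <- (m$nodes[ids[ed[e, 1]], ] + m$nodes[ids[ed[e, 2]], ]) / 2
    expect_equal(unname(m$nodes[ids[4 + e], ]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("uniform refinement preserves the domain", {
  m <- tet_mesh_box(c(1, 1, 1), c(2, 2, 2))
  mr <- refine_uniform(m)
  expect_equal(nrow(mr$conn), 8 * nrow(m$conn))
  expect_equal(sum(element_volume(mr)), 1, tolerance = 1e-12)
})

test_that("mesh statistics report counts and quality", {
  m <- tet_mesh_box(c(1, 1, 1), c(2, 2, 2))
  st <- mesh_statistics(m)
  expect_equal(st$n_elements, 48)
  expect_gt(st$min_corner_jacobian, 0)
  expect_equal(st$total_volume_mm3, 1, tolerance = 1e-12)
})
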