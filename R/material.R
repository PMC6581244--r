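#' Intensity-to-modulus calibration law
#'
#' Affine HU-to-density step followed by a power-law density-to-modulus step,
#' \eqn{\rho = a + b\,HU} (g/cm^3) and \eqn{E = c\,\rho^d} (MPa), with the
#' element-averaged modulus clamped to `[clamp_min, clamp_max]`. The default
#' coefficients are the package's documented placeholder for a QCT
#' calibration convention: chosen once so that the preset phantoms span the
#' modulus range reported for infant femora (about 0.46-17.8 GPa, cortical
#' peak 16-18 GPa, ossifying region 0.46-0.60 GPa).
#'
#' @param a,b Affine HU-to-density coefficients (g/cm^3, g/cm^3 per HU).
#' @param c,d Power-law density-to-modulus coefficients (MPa, exponent).
#' @param clamp_min,clamp_max Bounds applied to the element-averaged modulus
#'   (MPa).
#' @param hu_average_first If `TRUE`, average HU over the element before
#'   applying the law (sensitivity variant); the default applies the law
#'   pointwise and then averages, i.e. the integrated-average ordering.
#' @return Object of class `calibration_law`.
#' @export
calibration_law <- function(a = 0, b = 0.001, c = 6850, d = 1.49,
                            clamp_min = 460, clamp_max = 20000,
                            hu_average_first = FALSE) {
  stopifnot(b > 0, c > 0, d > 0, clamp_min < clamp_max)
  structure(list(hu_to_density = c(a = a, b = b),
                 density_to_modulus = c(c = c, d = d),
                 clamp_min = clamp_min, clamp_max = clamp_max,
                 hu_average_first = hu_average_first),
            class = "calibration_law")
}

# trilinear interpolation of image intensities at points (n x 3, mm);
# coordinates are clamped to the voxel-centre lattice at the border
.interp_hu <- function(image, pts) {
  d <- dim(image$intensities)
  for (k in 1:3) {
    lo <- image$origin[k]
    hi <- image$origin[k] + d[k] * image$spacing[k]
    if (any(pts[, k] < lo - 1e-9) || any(pts[, k] > hi + 1e-9))
      stop("sample point outside image bounds")
  }
  u <- sweep(sweep(pts, 2, image$origin), 2, image$spacing, "/") - 0.5
  i0 <- matrix(pmin(pmax(floor(u), 0),
                    matrix(d - 2, nrow(u), 3, byrow = TRUE)), ncol = 3)
  f <- pmin(pmax(u - i0, 0), 1)
  idx <- function(di) {
    1 + (i0[, 1] + di[1]) + d[1] * ((i0[, 2] + di[2]) + d[2] * (i0[, 3] + di[3]))
  }
  v <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    v <- v + wgt * image$intensities[idx(c(dx, dy, dz))]
  }
  v
}

# reference-tetrahedron sample points from `level` midpoint subdivisions,
# 4-point rule per sub-tetrahedron; equal weights (sub-tets have equal volume)
.ref_sample_points <- function(level = 2) {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tets <- list(corners)
  subdiv <- function(X) {
    m <- function(i, j) (X[i, ] + X[j, ]) / 2
    v <- X
    m12 <- m(1, 2); m13 <- m(1, 3); m14 <- m(1, 4)
    m23 <- m(2, 3); m24 <- m(2, 4); m34 <- m(3, 4)
    list(rbind(v[1, ], m12, m13, m14), rbind(m12, v[2, ], m23, m24),
         rbind(m13, m23, v[3, ], m34), rbind(m14, m24, m34, v[4, ]),
         rbind(m12, m13, m14, m24), rbind(m12, m13, m23, m24),
         rbind(m13, m14, m24, m34), rbind(m13, m23, m24, m34))
  }
  for (l in seq_len(level)) tets <- unlist(lapply(tets, subdiv), recursive = FALSE)
  q <- tet10_rule(4)$points
  bq <- cbind(1 - rowSums(q), q)
  do.call(rbind, lapply(tets, function(X) bq %*% X))
}

#' Element-averaged Young's modulus from a voxel image
#'
#' Computes, for each element, the volume average of the pointwise modulus
#' \eqn{E(HU(x))} over the element (law applied pointwise to the trilinearly
#' interpolated intensity field, then averaged — the integrated-average
#' ordering), clamped to the law's bounds.
#'
#' @param image A `voxel_image`.
#' @param mesh A `tet_mesh10` embedded in the image (mm coordinates).
#' @param law A [calibration_law()].
#' @param elems Element indices (default all).
#' @param level Midpoint-subdivision depth controlling sample density
#'   (4 x 8^level points per element; the default 2 gives 256).
#' @return Vector of moduli (MPa).
#' @export
element_modulus <- function(image, mesh, law = calibration_law(),
                            elems = NULL, level = 2) {
  stopifnot(inherits(image, "voxel_image"), inherits(mesh, "tet_mesh10"),
            inherits(law, "calibration_law"))
  if (is.null(elems)) elems <- seq_len(nrow(mesh$conn))
  ref <- .ref_sample_points(level)
  Nt <- t(tet10_shape(ref)$N)              # 10 x P
  P <- ncol(Nt)
  ab <- law$hu_to_density
  cd <- law$density_to_modulus
  E <- numeric(length(elems))
  chunk <- max(1L, as.integer(2e6 / P))    # bounded working memory
  for (start in seq(1, length(elems), by = chunk)) {
    sel <- elems[start:min(start + chunk - 1, length(elems))]
    conn <- mesh$conn[sel, , drop = FALSE]
    M <- nrow(conn)
    pts <- matrix(0, M * P, 3)
    for (k in 1:3) {
      Xk <- matrix(mesh$nodes[conn, k], M, 10)
      pts[, k] <- as.vector(t(Xk %*% Nt))  # element-major blocks of P
    }
    hu <- tryCatch(.interp_hu(image, pts), error = function(e)
      stop("element sample outside image bounds (elements ",
           paste(utils::head(sel, 3), collapse = ","), " ...)"))
    Ec <- if (law$hu_average_first) {
      hu_bar <- colMeans(matrix(hu, P, M))
      cd[1] * pmax(ab[1] + ab[2] * hu_bar, 0)^cd[2]
    } else {
      colMeans(matrix(cd[1] * pmax(ab[1] + ab[2] * hu, 0)^cd[2], P, M))
    }
    E[start:(start + M - 1)] <- Ec
  }
  unname(pmin(pmax(E, law$clamp_min), law$clamp_max))
}

#' Neo-Hookean parameters from Young's modulus
#'
#' For the compressible Neo-Hookean strain energy
#' \eqn{W = C_{10}(\bar I_1 - 3) + (1/D_1)(J-1)^2}, the parameters follow
#' from the small-strain modulus and Poisson's ratio as
#' \eqn{C_{10} = E / (4(1+\nu))} and \eqn{D_1 = 6(1-2\nu)/E}.
#'
#' @param E Young's modulus (MPa), vectorised.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return List with components `C10` (MPa) and `D1` (1/MPa).
#' @examples
#' neo_hookean_from_modulus(601.63, 0.20) # C10 = 125.34, D1 = 0.0060
#' @export
neo_hookean_from_modulus <- function(E, nu) {
  if (any(E <= 0)) stop("E must be positive")
  if (any(nu < 0 | nu >= 0.5))
    stop("nu must lie in [0, 0.5): D1 is undefined at the incompressible limit")
  list(C10 = E / (4 * (1 + nu)), D1 = 6 * (1 - 2 * nu) / E)
}

#' Recover (E, nu) from Neo-Hookean parameters
#'
#' Inverse of [neo_hookean_from_modulus()]; used by the linearised solver
#' mode to treat Neo-Hookean elements as small-strain linear elastic.
#'
#' @param C10,D1 Neo-Hookean parameters (MPa, 1/MPa), vectorised.
#' @return List with components `E` and `nu`.
#' @export
modulus_from_neo_hookean <- function(C10, D1) {
  q <- 4 * C10 * D1
  nu <- (6 - q) / (q + 12)
  list(E = 4 * C10 * (1 + nu), nu = nu)
}

#' Build the per-element material field
#'
#' Diaphysis elements become isotropic linear elastic with the image-derived
#' element modulus and `nu_bone`; ossifying-epiphysis elements become
#' Neo-Hookean poroelastic, with `C10`/`D1` derived from their own
#' image-derived modulus (the ossifying region is transitional tissue whose
#' stiffness is still estimated from the scan) plus literature poroelastic
#' constants.
#'
#' @param image,mesh,law,level As in [element_modulus()].
#' @param nu_bone Poisson's ratio of the mineralised diaphysis.
#' @param nu_epiphysis Poisson's ratio of the ossifying region.
#' @param permeability Hydraulic permeability of the ossifying region, in
#'   consistent mm-N-s units (mm^4/(N s)); stored as configured.
#' @param void_ratio Pore void ratio of the ossifying region.
#' @return Object of class `material_field`: per-element vectors `kind`,
#'   `E`, `nu`, `C10`, `D1`, `permeability`, `void_ratio`.
#' @export
build_material_field <- function(image, mesh, law = calibration_law(),
                                 nu_bone = 0.3, nu_epiphysis = 0.2,
                                 permeability = 0.00455, void_ratio = 4.50,
                                 level = 2) {
  E <- element_modulus(image, mesh, law, level = level)
  if (any(!is.finite(E))) stop("non-finite element modulus")
  material_field(
    kind = ifelse(mesh$region == "ossifying_epiphysis",
                  "neo_hookean_poro", "linear_elastic"),
    E = E,
    nu = ifelse(mesh$region == "ossifying_epiphysis", nu_epiphysis, nu_bone),
    permeability = permeability, void_ratio = void_ratio)
}

#' Construct a material field directly
#'
#' Lower-level constructor used both by [build_material_field()] and by
#' verification models with hand-set properties. Neo-Hookean parameters are
#' always derived from `(E, nu)`, so the stored record satisfies the
#' parameter relations exactly.
#'
#' @param kind `"linear_elastic"` or `"neo_hookean_poro"`, recycled.
#' @param E,nu Per-element modulus (MPa) and Poisson ratio, recycled.
#' @param permeability,void_ratio Poroelastic constants for
#'   `neo_hookean_poro` records.
#' @return Object of class `material_field`.
#' @export
material_field <- function(kind, E, nu, permeability = 0.00455,
                           void_ratio = 4.50) {
  n <- max(length(kind), length(E), length(nu))
  kind <- rep_len(kind, n); E <- rep_len(E, n); nu <- rep_len(nu, n)
  stopifnot(all(kind %in% c("linear_elastic", "neo_hookean_poro")),
            all(E > 0), all(nu >= 0 & nu < 0.5), all(permeability > 0))
  is_nh <- kind == "neo_hookean_poro"
  C10 <- D1 <- rep(NA_real_, n)
  if (any(is_nh)) {
    nh <- neo_hookean_from_modulus(E[is_nh], nu[is_nh])
    C10[is_nh] <- nh$C10
    D1[is_nh] <- nh$D1
  }
  structure(list(kind = kind, E = E, nu = nu, C10 = C10, D1 = D1,
                 permeability = ifelse(is_nh, rep_len(permeability, n), NA_real_),
                 void_ratio = ifelse(is_nh, rep_len(void_ratio, n), NA_real_)),
            class = "material_field")
}

# per-element (E, nu) for the linearised solver: linear records as stored,
# Neo-Hookean records recovered from (C10, D1)
.linearised_props <- function(materials) {
  E <- materials$E
  nu <- materials$nu
  is_nh <- materials$kind == "neo_hookean_poro"
  if (any(is_nh)) {
    rec <- modulus_from_neo_hookean(materials$C10[is_nh], materials$D1[is_nh])
    E[is_nh] <- rec$E
    nu[is_nh] <- rec$nu
  }
  list(E = E, nu = nu)
}

#' Scale the stiffness of selected elements
#'
#' Multiplies the modulus of the selected elements by `factor`, updating the
#' Neo-Hookean parameters consistently (C10 scales with E, D1 inversely).
#' Used for the degenerate-epiphysis limits (factor towards infinity
#' approaches a rigid epiphysis, towards zero a mechanically absent one).
#'
#' @param materials A `material_field`.
#' @param elems Logical or integer element selection.
#' @param factor Positive stiffness multiplier.
#' @return The modified `material_field`.
#' @export
scale_stiffness <- function(materials, elems, factor) {
  stopifnot(factor > 0)
  materials$E[elems] <- materials$E[elems] * factor
  materials$C10[elems] <- materials$C10[elems] * factor
  materials$D1[elems] <- materials$D1[elems] / factor
  materials
}
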