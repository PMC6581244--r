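#' Parameter set for the synthetic infant femur phantom
#'
#' Describes a parametric infant femur: a (possibly bowed) hollow cylindrical
#' diaphysis of cortical bone around a trabecular core, with a hemi-ellipsoidal
#' ossifying proximal epiphysis attached at the metaphyseal plane. Lengths and
#' semi-axes are in cm, voxel spacing in mm, intensities in Hounsfield-like
#' units (HU), matching the conventions of the printed morphometry these
#' phantoms emulate.
#'
#' @param length_prox_dist Proximal-distal length of the whole bone (cm).
#' @param shaft_outer_radius Outer radius of the diaphysis (cm), or `NULL` to
#'   derive it from `total_volume_target`.
#' @param shaft_cortical_thickness Cortical shell thickness (cm).
#' @param neck_shaft_angle Angle between neck/epiphysis axis and shaft (deg);
#'   infant femora are valgus, around 140-150 degrees.
#' @param anteversion_angle Rotation of the neck axis about the shaft towards
#'   anterior (deg).
#' @param epiphysis_semi_axes Semi-axes (cm) of the epiphyseal ellipsoid:
#'   first along the neck axis, the others transverse. The labelled epiphysis
#'   is the proximal half of this ellipsoid (cut at the metaphyseal plane), so
#'   its volume is \eqn{(2/3)\pi abc}.
#' @param epiphysis_volume_target Optional target epiphysis volume (cm^3);
#'   when given, the semi-axes are scaled isotropically to match it exactly.
#' @param total_volume_target Optional target total labelled volume (cm^3);
#'   used to derive the shaft radius when `shaft_outer_radius` is `NULL`.
#' @param shaft_bow Anterior bow of the shaft axis at mid-shaft (cm); the bow
#'   profile is a half-sine vanishing at both shaft ends, so labelled volumes
#'   are unaffected.
#' @param voxel_spacing Voxel spacing (mm), length-1 or length-3.
#' @param hu_cortical_peak,hu_trabecular,hu_epiphysis,hu_background Region
#'   intensities (HU). The background default of 100 HU represents the soft
#'   tissue a post-mortem limb scan embeds the femur in.
#' @param transition_width Width (mm) of the linear metaphyseal HU ramp from
#'   epiphyseal to diaphyseal intensity.
#' @param noise_sd Standard deviation of i.i.d. Gaussian HU noise added to
#'   non-background voxels.
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `femur_params`.
#' @seealso [femur_preset()], [generate_femur()]
#' @export
femur_params <- function(length_prox_dist,
                         shaft_outer_radius = NULL,
                         shaft_cortical_thickness = 0.2,
                         neck_shaft_angle = 145,
                         anteversion_angle = 30,
                         epiphysis_semi_axes = c(0.9, 0.81, 0.81),
                         epiphysis_volume_target = NULL,
                         total_volume_target = NULL,
                         shaft_bow = 0.18,
                         voxel_spacing = 0.8,
                         hu_cortical_peak = 1860,
                         hu_trabecular = 360,
                         hu_epiphysis = 190,
                         hu_background = 100,
                         transition_width = 3,
                         noise_sd = 30,
                         seed = 20190618) {
  if (length(voxel_spacing) == 1) voxel_spacing <- rep(voxel_spacing, 3)
  stopifnot(length_prox_dist > 0, all(voxel_spacing > 0),
            transition_width >= 0, noise_sd >= 0,
            length(epiphysis_semi_axes) == 3, all(epiphysis_semi_axes > 0),
            shaft_cortical_thickness > 0)
  if (!is.null(shaft_outer_radius) &&
      shaft_cortical_thickness >= shaft_outer_radius)
    stop("cortical thickness must be smaller than the shaft outer radius")
  if (is.null(shaft_outer_radius) && is.null(total_volume_target))
    stop("give either shaft_outer_radius or total_volume_target")
  if (!is.null(epiphysis_volume_target)) {
    v0 <- 2 / 3 * pi * prod(epiphysis_semi_axes)
    epiphysis_semi_axes <- epiphysis_semi_axes *
      (epiphysis_volume_target / v0)^(1 / 3)
  }
  structure(list(
    length_prox_dist = length_prox_dist,
    shaft_outer_radius = shaft_outer_radius,
    shaft_cortical_thickness = shaft_cortical_thickness,
    neck_shaft_angle = neck_shaft_angle,
    anteversion_angle = anteversion_angle,
    epiphysis_semi_axes = epiphysis_semi_axes,
    epiphysis_volume_target = epiphysis_volume_target,
    total_volume_target = total_volume_target,
    shaft_bow = shaft_bow,
    voxel_spacing = voxel_spacing,
    hu_cortical_peak = hu_cortical_peak,
    hu_trabecular = hu_trabecular,
    hu_epiphysis = hu_epiphysis,
    hu_background = hu_background,
    transition_width = transition_width,
    noise_sd = noise_sd,
    seed = seed
  ), class = "femur_params")
}

#' Preset phantoms for the two developmental stages
#'
#' Two parameterisations reproducing the printed femoral morphometry of a
#' 4-month-old and a 7-month-old infant: proximal-distal lengths 10.55 and
#' 13.28 cm, proximal epiphysis volumes 1.24 and 7.91 cm^3, total bone
#' volumes 13.13 and 30.79 cm^3. Shaft radius, cortical thickness, neck
#' angle and bow are not constrained by those measurements; the presets use
#' plausible infant values (cortical shell 2.0/2.4 mm, neck-shaft angle 145
#' degrees, mild anterior bow).
#'
#' @param which `"4mo"` or `"7mo"`.
#' @param ... Overrides passed on to [femur_params()].
#' @return A `femur_params` object.
#' @export
femur_preset <- function(which = c("4mo", "7mo"), ...) {
  which <- match.arg(which)
  base <- if (which == "4mo") {
    list(length_prox_dist = 10.55,
         epiphysis_semi_axes = c(0.90, 0.81, 0.81),
         epiphysis_volume_target = 1.24,
         total_volume_target = 13.13,
         shaft_cortical_thickness = 0.20,
         seed = 404L)
  } else {
    list(length_prox_dist = 13.28,
         epiphysis_semi_axes = c(1.65, 1.51, 1.51),
         epiphysis_volume_target = 7.91,
         total_volume_target = 30.79,
         shaft_cortical_thickness = 0.24,
         seed = 707L)
  }
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(femur_params, base)
}

#' Landmark set accompanying a phantom or mesh
#'
#' @param point1 Proximal ossification centre (mm), load application point.
#' @param point2 Distal fixation point on the diaphyseal axis (mm).
#' @param medial_direction,anterior_direction Unit hint vectors; must be
#'   orthogonal.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(point1, point2, medial_direction = c(0, 1, 0),
                         anterior_direction = c(0, 0, 1)) {
  m <- medial_direction / sqrt(sum(medial_direction^2))
  a <- anterior_direction / sqrt(sum(anterior_direction^2))
  if (abs(sum(m * a)) > 1e-9)
    stop("medial and anterior hint vectors must be orthogonal")
  structure(list(point1 = as.numeric(point1), point2 = as.numeric(point2),
                 medial_direction = m, anterior_direction = a),
            class = "landmark_set")
}

.voxel_image <- function(intensities, labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(identical(dim(intensities), dim(labels)))
  if (!all(labels %in% .label_codes))
    stop("labels contain codes outside the supported set")
  structure(list(intensities = intensities, labels = labels,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "voxel_image")
}

# voxel-centre coordinate vectors (mm) of an image
.voxel_axes <- function(image) {
  d <- dim(image$labels)
  lapply(1:3, function(k)
    image$origin[k] + (seq_len(d[k]) - 0.5) * image$spacing[k])
}

# rotation sending the ellipsoid frame into image space; columns are the
# neck axis and two transverse directions
.neck_frame <- function(neck_shaft_angle, anteversion_angle) {
  th <- (180 - neck_shaft_angle) * pi / 180
  al <- anteversion_angle * pi / 180
  u <- c(-cos(th), sin(th) * cos(al), sin(th) * sin(al))
  v0 <- c(0, -sin(al), cos(al))          # orthogonal to u by construction
  v <- v0 - sum(v0 * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, v, w)
}

#' Generate a synthetic infant femur phantom
#'
#' Builds the voxel image (intensities plus region labels) and the landmark
#' set of a parametric infant femur. The diaphysis is a hollow cylinder of
#' cortical label around a trabecular core, the proximal epiphysis is the
#' proximal half of an ellipsoid cut at the metaphyseal plane (so its
#' labelled volume is analytically \eqn{(2/3)\pi abc}), and intensities ramp
#' linearly over `transition_width` mm from epiphyseal to diaphyseal HU at
#' the metaphysis. Only the proximal ossifying region is generated; labels
#' end at the distal diaphysis.
#'
#' @param params A [femur_params()] object.
#' @return Object of class `femur_phantom`: a list with `image`
#'   (class `voxel_image`), `landmarks` (class `landmark_set`) and `params`.
#' @examples
#' ph <- generate_femur(femur_preset("4mo", voxel_spacing = 1.6))
#' voxel_volume_of_label(ph$image, "ossifying_epiphysis")
#' @export
generate_femur <- function(params) {
  stopifnot(inherits(params, "femur_params"))
  p <- params
  sp <- p$voxel_spacing
  L <- p$length_prox_dist * 10
  tw_cort <- p$shaft_cortical_thickness * 10
  if (tw_cort < 2 * max(sp))
    stop(sprintf(paste0("voxel spacing too coarse to resolve the cortical ",
                        "shell: %.2f mm across fewer than 2 voxels of %.2f mm"),
                 tw_cort, max(sp)))
  axes <- p$epiphysis_semi_axes * 10      # mm
  a <- axes[1]; b <- axes[2]; cc <- axes[3]
  R <- .neck_frame(p$neck_shaft_angle, p$anteversion_angle)
  Mel <- R %*% diag(axes^2) %*% t(R)      # ellipsoid shape matrix
  ext <- sqrt(diag(Mel))                  # half-extent along each image axis
  Ls <- L - ext[1]
  if (Ls <= 0) stop("epiphysis longer than the whole bone")
  v_epi <- 2 / 3 * pi * a * b * cc
  r_out <- if (!is.null(p$shaft_outer_radius)) p$shaft_outer_radius * 10 else
    sqrt((p$total_volume_target * 1000 - v_epi) / (pi * Ls))
  if (r_out <= tw_cort)
    stop("derived shaft radius smaller than the cortical thickness")
  bow <- p$shaft_bow * 10
  # epiphysis centre: on the cut plane, offset along the transverse part of
  # the neck axis (head sits medially/anteriorly off the shaft axis)
  off2 <- c(R[2, 1], R[3, 1])
  off2 <- if (sum(off2^2) > 1e-12) 0.3 * b * off2 / sqrt(sum(off2^2)) else c(0, 0)

  margin <- 3 * max(sp)
  # snap the metaphyseal cut plane to a voxel boundary so the half-ellipsoid
  # volume is not biased by plane-position quantisation
  x_cut <- round((margin + ext[1]) / sp[1]) * sp[1]
  # snap the distal end plane too, then derive the shaft radius from the
  # snapped length so the volume target is met exactly
  Ls <- round((x_cut + Ls) / sp[1]) * sp[1] - x_cut
  if (is.null(p$shaft_outer_radius))
    r_out <- sqrt((p$total_volume_target * 1000 - v_epi) / (pi * Ls))
  hy <- max(r_out, abs(off2[1]) + ext[2]) + margin
  hz <- max(r_out + bow, abs(off2[2]) + ext[3]) + margin
  dims <- c(ceiling((L + 2 * margin) / sp[1]),
            ceiling(2 * hy / sp[2]), ceiling(2 * hz / sp[3]))
  xv <- (seq_len(dims[1]) - 0.5) * sp[1]
  yv <- (seq_len(dims[2]) - 0.5) * sp[2]
  zv <- (seq_len(dims[3]) - 0.5) * sp[3]
  yc <- dims[2] * sp[2] / 2
  zc <- dims[3] * sp[3] / 2
  X <- array(xv, dims)
  Y <- array(rep(yv, each = dims[1]), dims)
  Z <- array(rep(zv, each = dims[1] * dims[2]), dims)

  xi <- pmin(pmax((X - x_cut) / Ls, 0), 1)
  # bow mostly anterior with a small lateral component, so the shaft axis
  # sweeps both transverse grid directions (no standing aliasing pattern)
  bow_dir <- c(0.5, 0.866)
  yax <- yc + bow * bow_dir[1] * sin(pi * xi)
  zax <- zc + bow * bow_dir[2] * sin(pi * xi)
  d2 <- (Y - yax)^2 + (Z - zax)^2
  in_shaft <- X >= x_cut & X <= x_cut + Ls & d2 <= r_out^2
  ctr <- c(x_cut, yc + off2[1], zc + off2[2])
  Q <- cbind(as.vector(X) - ctr[1], as.vector(Y) - ctr[2], as.vector(Z) - ctr[3]) %*% R
  in_epi <- array((Q[, 1] / a)^2 + (Q[, 2] / b)^2 + (Q[, 3] / cc)^2 <= 1, dims) &
    X <= x_cut

  labels <- array(.label_codes[["background"]], dims)
  labels[in_shaft & d2 >= (r_out - tw_cort)^2] <- .label_codes[["cortical"]]
  labels[in_shaft & d2 < (r_out - tw_cort)^2] <- .label_codes[["trabecular"]]
  labels[in_epi] <- .label_codes[["ossifying_epiphysis"]]

  hu <- array(p$hu_background, dims)
  hu[labels == .label_codes[["cortical"]]] <- p$hu_cortical_peak
  hu[labels == .label_codes[["trabecular"]]] <- p$hu_trabecular
  hu[labels == .label_codes[["ossifying_epiphysis"]]] <- p$hu_epiphysis
  if (p$transition_width > 0) {
    ramp <- in_shaft & X <= x_cut + p$transition_width
    f <- (X[ramp] - x_cut) / p$transition_width
    hu[ramp] <- p$hu_epiphysis + f * (hu[ramp] - p$hu_epiphysis)
  }
  if (p$noise_sd > 0) {
    nb <- labels != .label_codes[["background"]]
    hu[nb] <- hu[nb] + .with_seed(p$seed, rnorm(sum(nb), sd = p$noise_sd))
  }

  image <- .voxel_image(hu, labels, sp)
  epi_idx <- which(labels == .label_codes[["ossifying_epiphysis"]])
  p1 <- c(mean(X[epi_idx]), mean(Y[epi_idx]), mean(Z[epi_idx]))
  x2 <- x_cut + Ls - 4
  xi2 <- (x2 - x_cut) / Ls
  p2 <- c(x2, yc + bow * bow_dir[1] * sin(pi * xi2),
          zc + bow * bow_dir[2] * sin(pi * xi2))
  lm <- landmark_set(p1, p2)
  structure(list(image = image, landmarks = lm, params = p),
            class = "femur_phantom")
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Volume of one labelled region
#'
#' Counts voxels carrying a label and converts to cm^3.
#'
#' @param image A `voxel_image`.
#' @param label Label name (see [label_codes()]) or integer code.
#' @return Volume in cm^3; zero with a warning when the label is absent.
#' @export
voxel_volume_of_label <- function(image, label) {
  stopifnot(inherits(image, "voxel_image"))
  code <- if (is.character(label)) .label_codes[[label]] else as.integer(label)
  n <- sum(image$labels == code)
  if (n == 0) warning(sprintf("label %s absent from image", label))
  n * prod(image$spacing) / 1000
}

#' Simple cylinder test image
#'
#' Solid cylinder of a single label along the image x-axis, optionally bent
#' mid-shaft by `bend_deg` in the x-y plane. Used for frame-construction and
#' meshing benchmarks.
#'
#' @param radius_mm,length_mm Cylinder dimensions (mm).
#' @param spacing Voxel spacing (mm, scalar or triple).
#' @param hu Intensity of cylinder voxels.
#' @param bend_deg Bend angle of the distal half (degrees, about z).
#' @param label Region label for cylinder voxels (default cortical).
#' @return A `voxel_image`.
#' @export
synthetic_cylinder_image <- function(radius_mm, length_mm, spacing = 1,
                                     hu = 1500, bend_deg = 0,
                                     label = "cortical") {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  margin <- 3 * max(spacing)
  half <- length_mm / 2
  th <- bend_deg * pi / 180
  ymax <- half * sin(th) + radius_mm
  dims <- c(ceiling((length_mm + 2 * margin) / spacing[1]),
            ceiling((2 * radius_mm + 2 * margin + max(0, ymax - radius_mm)) / spacing[2]),
            ceiling((2 * radius_mm + 2 * margin) / spacing[3]))
  xv <- (seq_len(dims[1]) - 0.5) * spacing[1]
  yv <- (seq_len(dims[2]) - 0.5) * spacing[2]
  zv <- (seq_len(dims[3]) - 0.5) * spacing[3]
  x0 <- margin; yc <- margin + radius_mm; zc <- dims[3] * spacing[3] / 2
  X <- array(xv, dims)
  Y <- array(rep(yv, each = dims[1]), dims)
  Z <- array(rep(zv, each = dims[1] * dims[2]), dims)
  # axis: straight to mid-length, then rotated by bend_deg in x-y;
  # distal inclusion tests distance to the rotated axis segment
  t2 <- ((X - (x0 + half)) * cos(th) + (Y - yc) * sin(th))
  d2 <- (Y - yc)^2 + (Z - zc)^2
  d2b <- ((X - (x0 + half)) - t2 * cos(th))^2 +
    ((Y - yc) - t2 * sin(th))^2 + (Z - zc)^2
  inside <- (X >= x0 & (X - x0) <= half & d2 <= radius_mm^2) |
    (t2 >= 0 & t2 <= half & d2b <= radius_mm^2)
  labels <- array(.label_codes[["background"]], dims)
  labels[inside] <- .label_codes[[label]]
  hu_arr <- array(0, dims)
  hu_arr[inside] <- hu
  .voxel_image(hu_arr, labels, spacing)
}

#' Write a phantom to NIfTI plus JSON sidecar
#'
#' Writes `<prefix>_hu.nii.gz`, `<prefix>_labels.nii.gz` and
#' `<prefix>.json` (spacing, origin, landmarks, parameters, seed).
#'
#' @param phantom A `femur_phantom`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "femur_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- phantom$image
  f_hu <- file.path(dir, paste0(prefix, "_hu.nii.gz"))
  f_lab <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  f_js <- file.path(dir, paste0(prefix, ".json"))
  ni <- RNifti::asNifti(img$intensities, pixdim = img$spacing)
  RNifti::writeNifti(ni, f_hu)
  nl <- RNifti::asNifti(array(as.integer(img$labels), dim(img$labels)),
                        pixdim = img$spacing)
  RNifti::writeNifti(nl, f_lab)
  side <- list(spacing = img$spacing, origin = img$origin,
               landmarks = unclass(phantom$landmarks),
               params = unclass(phantom$params))
  jsonlite::write_json(side, f_js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(f_hu, f_lab, f_js))
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory holding the files.
#' @param prefix File name prefix used when writing.
#' @return A `femur_phantom`.
#' @export
read_phantom <- function(dir, prefix = "phantom") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  hu_n <- RNifti::readNifti(file.path(dir, paste0(prefix, "_hu.nii.gz")))
  lab_n <- RNifti::readNifti(file.path(dir, paste0(prefix, "_labels.nii.gz")))
  img <- .voxel_image(array(as.numeric(hu_n), dim(hu_n)),
                      array(as.integer(lab_n), dim(lab_n)),
                      side$spacing, side$origin)
  lm <- landmark_set(side$landmarks$point1, side$landmarks$point2,
                     side$landmarks$medial_direction,
                     side$landmarks$anterior_direction)
  prm <- side$params
  structure(list(image = img, landmarks = lm, params = prm),
            class = "femur_phantom")
}

#' Remove the ossifying epiphysis from a labelled image
#'
#' Relabels epiphysis voxels as background (intensities untouched), giving
#' the bone-only geometry used in shaft-only models.
#'
#' @param image A `voxel_image`.
#' @return A `voxel_image`.
#' @export
bone_only_image <- function(image) {
  image$labels[image$labels == .label_codes[["ossifying_epiphysis"]]] <-
    .label_codes[["background"]]
  image
}
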