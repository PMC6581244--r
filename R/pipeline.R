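#' Pipeline run configuration
#'
#' Plain-list configuration for the end-to-end analysis (phantom, mesh,
#' materials, frame and load cases, solve, failure). Serialises to and from
#' YAML with round-trip identity; every run writes the resolved
#' configuration beside its outputs.
#'
#' @param preset `"4mo"` or `"7mo"`, or `NULL` when `params` is given.
#' @param params Optional list of [femur_params()] arguments overriding the
#'   preset.
#' @param voxel_spacing Phantom voxel spacing (mm).
#' @param target_edge Mesh target edge length (mm).
#' @param cases Load cases to run (`"torsion"`, `"axial_X"`, `"axial_Y"`,
#'   `"axial_Z"`).
#' @param mode Solver mode (`"linearised"` or `"hyperelastic"`).
#' @param law Calibration-law coefficients as a list (see
#'   [calibration_law()]).
#' @param nu_bone,nu_epiphysis Poisson ratios.
#' @param tensile_limit,compressive_limit Failure strain limits.
#' @param boundary_buffer Saint-Venant buffer (mm) for the capacity mask
#'   (about one shaft diameter; see [failure_criterion()]).
#' @param out_dir Output directory.
#' @param seed Integer seed (also seeds the phantom).
#' @return Object of class `run_config` (a plain list).
#' @export
run_config <- function(preset = "4mo", params = NULL, voxel_spacing = 0.8,
                       target_edge = 2.5,
                       cases = "torsion",
                       mode = "linearised",
                       law = list(), nu_bone = 0.3, nu_epiphysis = 0.2,
                       tensile_limit = 0.0073, compressive_limit = 0.0104,
                       boundary_buffer = 16,
                       out_dir = "infantfem_run", seed = 1) {
  cfg <- list(preset = preset, params = params, voxel_spacing = voxel_spacing,
              target_edge = target_edge, cases = cases, mode = mode,
              law = law, nu_bone = nu_bone, nu_epiphysis = nu_epiphysis,
              tensile_limit = tensile_limit,
              compressive_limit = compressive_limit,
              boundary_buffer = boundary_buffer,
              out_dir = out_dir, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full analysis pipeline
#'
#' Executes phantom generation, meshing, material mapping, the configured
#' load-case solves and failure post-processing, writing all artefacts and a
#' manifest (files, MD5 checksums, stage wall times, versions) into
#' `config$out_dir`. Outputs are deterministic for a fixed seed in
#' linearised mode.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_run_config(config, file.path(out, "config.yaml"))
  files <- character(0)
  stages <- list()

  s1 <- .stage("phantom", {
    pargs <- c(list(voxel_spacing = config$voxel_spacing, seed = config$seed),
               config$params)
    params <- do.call(femur_preset, c(list(which = config$preset), pargs))
    phantom <- generate_femur(params)
    write_phantom(phantom, out, "phantom")
    phantom
  })
  phantom <- s1$value
  stages$phantom <- s1$elapsed
  files <- c(files, file.path(out, c("phantom_hu.nii.gz", "phantom_labels.nii.gz",
                                     "phantom.json")))

  s2 <- .stage("mesh", {
    mesh <- mesh_from_labels(phantom$image, config$target_edge,
                             landmarks = phantom$landmarks)
    write_mesh(mesh, file.path(out, "mesh.vtu"))
    jsonlite::write_json(mesh_statistics(mesh), file.path(out, "mesh_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    mesh
  })
  mesh <- s2$value
  stages$mesh <- s2$elapsed
  files <- c(files, file.path(out, c("mesh.vtu", "mesh_stats.json")))

  s3 <- .stage("materials", {
    law <- do.call(calibration_law, config$law)
    mats <- build_material_field(phantom$image, mesh, law,
                                 nu_bone = config$nu_bone,
                                 nu_epiphysis = config$nu_epiphysis)
    write_mesh(mesh, file.path(out, "materials.vtu"),
               cell_data = list(E = mats$E,
                                C10 = ifelse(is.na(mats$C10), 0, mats$C10),
                                D1 = ifelse(is.na(mats$D1), 0, mats$D1)))
    mats
  })
  mats <- s3$value
  stages$materials <- s3$elapsed
  files <- c(files, file.path(out, "materials.vtu"))

  criterion <- failure_criterion(config$tensile_limit, config$compressive_limit,
                                 boundary_buffer = config$boundary_buffer)
  s4 <- .stage("solve", {
    frame <- build_frame(mesh)
    sols <- list()
    for (case in config$cases) {
      bcs <- make_load_case(mesh, frame, case)
      sol <- solve_static(mesh, mats, bcs, mode = config$mode)
      write_mesh(mesh, file.path(out, paste0("solution_", case, ".vtu")),
                 cell_data = list(e1 = sol$principal[, 1],
                                  e3 = sol$principal[, 3],
                                  utilisation = utilisation_field(sol, criterion)),
                 point_data = list(displacement = sol$u))
      sols[[case]] <- sol
    }
    sols
  })
  sols <- s4$value
  stages$solve <- s4$elapsed
  files <- c(files, file.path(out, paste0("solution_", config$cases, ".vtu")))

  s5 <- .stage("failure", {
    rep <- lapply(sols, function(sol) {
      fr <- load_to_fail(sol, criterion)
      list(kind = sol$bcs$info$kind,
           applied_load = fr$applied_load,
           load_to_fail = fr$load_to_fail,
           limiting_mode = fr$limiting_mode,
           limiting_element = fr$limiting_element,
           max_tensile_strain = fr$max_tensile_strain,
           max_compressive_strain = fr$max_compressive_strain,
           tension_first = fr$tension_first)
    })
    jsonlite::write_json(rep, file.path(out, "failure_report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  stages$failure <- s5$elapsed
  files <- c(files, file.path(out, "failure_report.json"))

  files <- c(files, file.path(out, "config.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("infantfem")),
    r_version = R.version.string,
    seed = config$seed,
    stages = lapply(stages, function(t) list(elapsed_s = t)),
    files = lapply(setNames(files, basename(files)), function(fp)
      list(path = fp, md5 = unname(tools::md5sum(fp)))),
    failure = s5$value)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
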