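#' Default pipeline configuration
#'
#' One nested configuration drives the whole pipeline (synthesis, correction,
#' evaluation). Defaults reproduce the package's reference synthetic
#' experiment: a 128^3 / 1 mm phantom with 23 beads, a midsagittal retraction
#' corridor opened 7.0 mm to the right and 6.3 mm to the left, a 14 mm blade
#' tracked by a noisy, partially occluded scan, 5 mm hexahedral elements and
#' 3 kPa / 0.45 tissue elasticity.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global integer seed; every stochastic stage derives its seed
#'   from it.
#' @return a nested list (class `pipeline_config`).
#' @export
default_config <- function(out_dir = "retractx_out", seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = list(grid_shape = c(128L, 128L, 128L), voxel_size_mm = c(1, 1, 1),
                   ellipsoid_semiaxes_mm = c(55, 45, 40), n_beads = 23L,
                   bead_diameter_mm = 1.5, background_intensity = 0,
                   tissue_intensity = 100, bead_intensity = 1000,
                   smooth_sigma_mm = 2),
    crack = list(depth_mm = 25, width_mm = 100),
    truth = list(d_right_mm = 7.0, d_left_mm = 6.3, decay_radius_mm = 35,
                 front_taper_mm = 10),
    retractor = list(width_mm = 14, length_mm = 25, thickness_mm = 2,
                     pitch_mm = 2),
    lrs = list(keep_fraction = 0.6, noise_sd_mm = 0.3,
               occluded_patch_fraction = 0.3, surface_pitch_mm = 1),
    mesh = list(element_size_mm = 5, occupancy_threshold = 0.5),
    material = list(E_pa = 3000, nu = 0.45),
    cpd = list(beta = 2, lambda = 3, w = NULL, max_iter = 200, tol = 1e-8),
    icp = list(trim = 0.7, residual_threshold = 10),
    bc = list(zero_axis = 3, zero_max_mm = NULL),
    warp = list(background_intensity = 0, interp = "trilinear"),
    eval = list(n_slices = 19L, axis = 3L, canny_sigma = 1.0,
                canny_low = 0.1, canny_high = 0.2)
  ), class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#' @param path YAML file.
#' @param config a `pipeline_config`.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()), yaml::read_yaml(path))
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$out_dir))
  ph <- config$phantom
  stopifnot(length(ph$grid_shape) == 3, all(ph$grid_shape > 0),
            ph$n_beads >= 0, config$truth$decay_radius_mm > 0,
            config$material$E_pa > 0, config$material$nu < 0.5,
            config$eval$n_slices >= 1)
  config
}

cfg_phantom_spec <- function(config) {
  ph <- config$phantom
  phantom_spec(grid_shape = ph$grid_shape, voxel_size_mm = ph$voxel_size_mm,
               ellipsoid_semiaxes_mm = ph$ellipsoid_semiaxes_mm,
               n_beads = ph$n_beads, bead_diameter_mm = ph$bead_diameter_mm,
               background_intensity = ph$background_intensity,
               tissue_intensity = ph$tissue_intensity,
               bead_intensity = ph$bead_intensity,
               smooth_sigma_mm = ph$smooth_sigma_mm, seed = config$seed)
}

cfg_retractor <- function(config) {
  r <- config$retractor
  retractor_model(r$width_mm, r$length_mm, r$thickness_mm, r$pitch_mm)
}

stage_log <- function(stage, t0) {
  message(sprintf("[retractx] %-22s %7.2f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Generate the synthetic phantom bundle
#'
#' Writes every input the correction stage needs: pre/post volumes (NIfTI),
#' tissue label, bead tables (CSV), probe points, the simulated scanner
#' cloud (PLY + CSV), crack and truth parameters (YAML), a resolved copy of
#' the configuration, and a checksum manifest.
#'
#' @param config a [default_config()]-style configuration.
#' @return invisibly, a list of generated objects and file paths.
#' @export
run_synth <- function(config = default_config()) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  t0 <- proc.time()[3]
  spec <- cfg_phantom_spec(config)
  ph <- generate_phantom_volume(spec)
  crack <- default_phantom_crack(spec, depth_mm = config$crack$depth_mm,
                                 width_mm = config$crack$width_mm)
  tr <- config$truth
  field <- analytic_retraction_field(crack, tr$d_right_mm, tr$d_left_mm,
                                     tr$decay_radius_mm, tr$front_taper_mm)
  post <- apply_field_to_volume(ph$volume, field, crack, ph$beads,
                                background_intensity = spec$background_intensity)
  stage_log("synth: phantom+field", t0)

  model <- cfg_retractor(config)
  probe <- simulate_probe_points(crack, model)
  # the scanner samples the physical surface finer than the template pitch
  dense_model <- retractor_model(model$width, model$length, model$thickness,
                                 pitch_mm = config$lrs$surface_pitch_mm)
  surf <- build_retractor_cloud(probe, dense_model)
  # deformed blade faces: tissue displacement minus one blade thickness along
  # the face normal (the scanner sees the inner face, not the tissue contact)
  disp <- matrix(0, nrow(surf$points), 3)
  for (s in c(1, -1)) {
    rows <- surf$face == s
    disp[rows, ] <- evaluate_field(field, surf$points[rows, , drop = FALSE],
                                   side = if (s > 0) "+" else "-")
  }
  post_surface <- point_cloud(surf$points + disp -
                                model$thickness * surf$normals,
                              normals = surf$normals, face = surf$face)
  lrs <- simulate_lrs_cloud(post_surface,
                            keep_fraction = config$lrs$keep_fraction,
                            noise_sd_mm = config$lrs$noise_sd_mm,
                            occluded_patch_fraction = config$lrs$occluded_patch_fraction,
                            seed = config$seed + 1L)
  stage_log("synth: tracking inputs", t0)

  write_volume(ph$volume, file.path(od, "pre.nii.gz"))
  write_volume(ph$label, file.path(od, "label.nii.gz"))
  write_volume(post$volume, file.path(od, "post.nii.gz"))
  files <- c("pre.nii.gz", "label.nii.gz", "post.nii.gz")
  if (nrow(ph$beads) > 0) {
    utils::write.csv(ph$beads, file.path(od, "beads_pre.csv"), row.names = FALSE)
    utils::write.csv(post$beads, file.path(od, "beads_post.csv"), row.names = FALSE)
    files <- c(files, "beads_pre.csv", "beads_post.csv")
  }
  utils::write.csv(data.frame(x = probe[, 1], y = probe[, 2], z = probe[, 3]),
                   file.path(od, "probe_points.csv"), row.names = FALSE)
  write_cloud_ply(lrs, file.path(od, "lrs_cloud.ply"))
  write_cloud_csv(lrs, file.path(od, "lrs_cloud.csv"))
  write_crack_yaml(crack, file.path(od, "crack.yaml"))
  yaml::write_yaml(config$truth, file.path(od, "truth.yaml"))
  write_config(config, file.path(od, "config_resolved.yaml"))
  files <- c(files, "probe_points.csv", "lrs_cloud.ply", "lrs_cloud.csv",
             "crack.yaml", "truth.yaml", "config_resolved.yaml")
  write_manifest(od, files)
  stage_log("synth: write bundle", t0)
  invisible(list(spec = spec, crack = crack, field = field,
                 pre = ph$volume, label = ph$label, post = post$volume,
                 beads_pre = ph$beads, beads_post = post$beads,
                 template = surf, lrs = lrs, files = files))
}

# in-session mesh cache keyed by label checksum and meshing parameters
.mesh_cache <- new.env(parent = emptyenv())

#' Run the correction stage: tracking, XFEM solve, crack-aware warp
#'
#' Reads the synthetic bundle (or identically formatted real inputs) from
#' `config$out_dir`, tracks the retractor surfaces (per-face trimmed-ICP
#' augmentation of the occluded scan, then per-face nonrigid CPD), converts
#' them to boundary conditions, assembles and solves the enriched elastic
#' system and back-interpolates the model-updated volume.
#'
#' @param config a [default_config()]-style configuration.
#' @return invisibly, a list with the mesh, enrichment, solution, updated
#'   volume and model bead table.
#' @export
run_correct <- function(config = default_config()) {
  config <- validate_config(config)
  od <- config$out_dir
  t0 <- proc.time()[3]
  need <- c("pre.nii.gz", "label.nii.gz", "probe_points.csv", "lrs_cloud.ply",
            "crack.yaml")
  missing <- need[!file.exists(file.path(od, need))]
  if (length(missing))
    stop("tracking stage: missing input file(s): ", paste(missing, collapse = ", "))
  pre <- read_volume(file.path(od, "pre.nii.gz"))
  label <- read_volume(file.path(od, "label.nii.gz"))
  crack <- read_crack_yaml(file.path(od, "crack.yaml"))

  key <- paste(unname(tools::md5sum(file.path(od, "label.nii.gz"))),
               paste(config$mesh$element_size_mm, collapse = "x"),
               config$mesh$occupancy_threshold, sep = "|")
  if (!is.null(.mesh_cache[[key]])) {
    mesh <- .mesh_cache[[key]]
  } else {
    mesh <- build_hex_mesh(label, config$mesh$element_size_mm,
                           config$mesh$occupancy_threshold)
    .mesh_cache[[key]] <- mesh
  }
  enr <- classify_enrichment(mesh, crack)
  stage_log("correct: mesh+classify", t0)

  model <- cfg_retractor(config)
  probe <- as.matrix(utils::read.csv(file.path(od, "probe_points.csv")))
  template <- build_retractor_cloud(probe, model)
  lrs <- read_cloud_ply(file.path(od, "lrs_cloud.ply"))
  psi_lrs <- level_sets(lrs$points, crack)$psi
  # CPD runs against the augmentation-completed target, so no outlier mass
  w_out <- if (is.null(config$cpd$w)) 0 else config$cpd$w
  disp <- matrix(0, nrow(template$points), 3)
  for (s in c(1, -1)) {
    rows <- which(template$face == s)
    face_tmpl <- point_cloud(template$points[rows, , drop = FALSE],
                             normals = template$normals[rows, , drop = FALSE])
    part <- lrs$points[if (s > 0) psi_lrs >= 0 else psi_lrs < 0, , drop = FALSE]
    aug <- rigid_augment(face_tmpl, point_cloud(part),
                         trim = config$icp$trim,
                         residual_threshold = config$icp$residual_threshold)
    # augment: fill the occluded patch with rigidly posed template points
    nn <- nearest_neighbour(aug$cloud$points, part)
    fill <- aug$cloud$points[nn$dist > 3 * model$pitch / 2, , drop = FALSE]
    target <- point_cloud(rbind(part, fill))
    reg <- cpd_nonrigid_register(face_tmpl, target,
                                 params = list(beta = config$cpd$beta,
                                               lambda = config$cpd$lambda,
                                               w = w_out,
                                               max_iter = config$cpd$max_iter,
                                               tol = config$cpd$tol))
    disp[rows, ] <- reg$displacement
  }
  stage_log("correct: tracking", t0)

  zero_max <- config$bc$zero_max_mm
  if (is.null(zero_max)) zero_max <- min(mesh$nodes[, config$bc$zero_axis]) + 8
  zero_nodes <- select_zero_nodes(mesh, config$bc$zero_axis, zero_max)
  bcs <- extract_contact_bcs(list(cloud = template, displacement = disp),
                             model, mesh, crack, enr, zero_nodes)
  mat <- material_params(config$material$E_pa, config$material$nu)
  sys <- assemble(mesh, enr, crack, mat)
  sys <- apply_boundary_conditions(sys, bcs)
  sol <- solve_system(sys)
  stage_log("correct: assemble+solve", t0)
  message(sprintf("[retractx] solver residual %.2e, max |u| = %.2f mm",
                  sol$diagnostics$rel_residual, max(abs(sol$u))))

  cfg_w <- warp_config(background_intensity = config$warp$background_intensity,
                       interp = config$warp$interp)
  updated <- warp_back_interpolate(pre, mesh, sol, enr, crack, cfg_w)
  stage_log("correct: warp", t0)

  write_volume(updated, file.path(od, "updated.nii.gz"))
  utils::write.csv(data.frame(dof = seq_along(sol$dof), value = sol$dof),
                   file.path(od, "solution.csv"), row.names = FALSE)
  write_mesh_vtu(mesh, file.path(od, "mesh.vtu"),
                 point_data = list(displacement = sol$u),
                 cell_data = list(cut = as.numeric(enr$elem_status)))
  utils::write.csv(bcs$entries, file.path(od, "bcs.csv"), row.names = FALSE)

  beads_model <- NULL
  bp <- file.path(od, "beads_pre.csv")
  if (file.exists(bp)) {
    beads_pre <- utils::read.csv(bp)
    ctrs <- as.matrix(beads_pre[, c("x", "y", "z")])
    bdisp <- displacement_field(sol, mesh, enr, crack, ctrs,
                                side = "auto", outside = "zero")
    beads_model <- beads_pre
    beads_model[, c("x", "y", "z")] <- ctrs + bdisp
    utils::write.csv(beads_model, file.path(od, "beads_model.csv"),
                     row.names = FALSE)
  }
  invisible(list(mesh = mesh, enrichment = enr, crack = crack, bcs = bcs,
                 solution = sol, updated = updated, beads_model = beads_model))
}

#' Run the evaluation stage
#'
#' Computes per-bead forecast error and correction accuracy and the
#' slice-wise modified Hausdorff distances between Canny edges of the
#' pre-retraction, model-updated and post-retraction volumes, over
#' `config$eval$n_slices` evenly spaced axial slices through the retraction
#' corridor.
#'
#' @param config a [default_config()]-style configuration.
#' @return a `metrics_report` list (`beads`, `slices`, `summary`), also
#'   written to `report.json` / `report_beads.csv` / `report_slices.csv`.
#' @export
run_eval <- function(config = default_config()) {
  config <- validate_config(config)
  od <- config$out_dir
  t0 <- proc.time()[3]
  need <- c("beads_pre.csv", "beads_model.csv", "beads_post.csv",
            "pre.nii.gz", "updated.nii.gz", "post.nii.gz", "crack.yaml")
  missing <- need[!file.exists(file.path(od, need))]
  if (length(missing))
    stop("evaluation stage: missing input file(s): ",
         paste(missing, collapse = ", "))
  beads_pre <- utils::read.csv(file.path(od, "beads_pre.csv"))
  beads_model <- utils::read.csv(file.path(od, "beads_model.csv"))
  beads_post <- utils::read.csv(file.path(od, "beads_post.csv"))
  if (!identical(beads_pre$id, beads_post$id) ||
      !identical(beads_pre$id, beads_model$id))
    stop("bead table mismatch: ids differ between spaces")
  pre <- read_volume(file.path(od, "pre.nii.gz"))
  updated <- read_volume(file.path(od, "updated.nii.gz"))
  post <- read_volume(file.path(od, "post.nii.gz"))
  crack <- read_crack_yaml(file.path(od, "crack.yaml"))

  bead_rep <- evaluate_beads(beads_pre, beads_model, beads_post)
  mouth_z <- crack$origin[3]
  front_z <- mouth_z - crack$depth
  vs <- voxel_size(pre)
  zs <- seq(front_z + 1, mouth_z - 6, length.out = config$eval$n_slices)
  indices <- unique(pmin(pmax(floor(zs / vs[3]) + 1L, 1), dim(pre$data)[3]))
  slices <- evaluate_slices(pre, updated, post, axis = config$eval$axis,
                            indices = indices,
                            sigma = config$eval$canny_sigma,
                            low = config$eval$canny_low,
                            high = config$eval$canny_high)
  stage_log("eval: beads+slices", t0)

  report <- structure(list(
    beads = bead_rep$per_bead,
    slices = slices,
    summary = c(bead_rep$summary,
                list(mean_mhd_pre_post_mm = mean(slices$mhd_pre_post_mm),
                     mean_mhd_model_post_mm = mean(slices$mhd_model_post_mm),
                     n_slices = nrow(slices))),
    parameters = list(eval = config$eval, seed = config$seed)),
    class = "metrics_report")
  jsonlite::write_json(unclass(report), file.path(od, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(bead_rep$per_bead, file.path(od, "report_beads.csv"),
                   row.names = FALSE)
  utils::write.csv(slices, file.path(od, "report_slices.csv"),
                   row.names = FALSE)
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat("metrics_report\n")
  cat(sprintf("  beads: %d (%d excluded, zero motion)\n", s$n_beads,
              s$n_excluded_zero_motion))
  cat(sprintf("  forecast error (mm): mean %.2f, range [%.2f, %.2f]\n",
              s$mean_forecast_error_mm, s$min_forecast_error_mm,
              s$max_forecast_error_mm))
  cat(sprintf("  correction accuracy (%%): mean %.1f, range [%.1f, %.1f]\n",
              s$mean_correction_accuracy_pct, s$min_correction_accuracy_pct,
              s$max_correction_accuracy_pct))
  cat(sprintf("  modified Hausdorff over %d slices (mm): pre-vs-post %.2f -> model-vs-post %.2f\n",
              s$n_slices, s$mean_mhd_pre_post_mm, s$mean_mhd_model_post_mm))
  invisible(x)
}

#' Run the full pipeline (synth, correct, eval)
#'
#' @param config a [default_config()]-style configuration.
#' @return the final `metrics_report`.
#' @export
run_all <- function(config = default_config()) {
  run_synth(config)
  run_correct(config)
  run_eval(config)
}
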