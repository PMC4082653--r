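# shared fixtures built in code

cube_label <- function(nvox, voxel = 1) {
  image_volume(array(1, rep(nvox, 3)), voxel_size_mm = rep(voxel, 3))
}

# crack slicing a block of extent (ex, ey, ez) vertically at x = x0, inserted
# from the top, covering the full cross-section unless depth says otherwise
block_crack <- function(x0, ey, ez, depth = 2 * ez, width = 4 * ey) {
  crack_geometry(c(x0, ey / 2, ez), normal = c(1, 0, 0),
                 dir_depth = c(0, 0, -1), width_mm = width, depth_mm = depth)
}

small_phantom_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(64L, 64L, 64L),
               ellipsoid_semiaxes_mm = c(27, 23, 20),
               smooth_sigma_mm = 1.5, seed = seed)
}

small_config <- function(out_dir, seed = 1L) {
  cfg <- default_config(out_dir = out_dir, seed = seed)
  cfg$phantom$grid_shape <- c(64L, 64L, 64L)
  cfg$phantom$ellipsoid_semiaxes_mm <- c(27, 23, 20)
  cfg$phantom$smooth_sigma_mm <- 1.5
  cfg$crack$depth_mm <- 14
  cfg$crack$width_mm <- 50
  cfg$truth <- list(d_right_mm = 4, d_left_mm = 3.5, decay_radius_mm = 18,
                    front_taper_mm = 6)
  cfg$retractor$length_mm <- 14
  cfg$mesh$element_size_mm <- 4
  cfg$eval$n_slices <- 5L
  cfg
}
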