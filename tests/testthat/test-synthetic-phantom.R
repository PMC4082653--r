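test_that("phantom generation places the requested beads inside the tissue mask", {
  spec <- small_phantom_spec()
  ph <- generate_phantom_volume(spec)
  expect_equal(nrow(ph$beads), 23L)
  expect_setequal(unique(ph$beads$region), c("frontal", "parietal", "occipital"))
  expect_equal(as.integer(table(ph$beads$region)[c("frontal", "parietal", "occipital")]),
               c(4L, 12L, 7L))
  expect_equal(sum(ph$beads$deep), 2L)
  idx <- round(world_to_voxel(ph$label, as.matrix(ph$beads[, c("x", "y", "z")]))) + 1
  expect_true(all(ph$label$data[idx] > 0))
  # bead spheres rendered at the distinct bead intensity
  expect_true(any(ph$volume$data == spec$bead_intensity))
})

test_that("degenerate bead count and determinism contracts hold", {
  spec0 <- phantom_spec(grid_shape = c(40L, 40L, 40L),
                        ellipsoid_semiaxes_mm = c(16, 14, 12), n_beads = 0L)
  ph0 <- generate_phantom_volume(spec0)
  expect_equal(nrow(ph0$beads), 0L)
  expect_true(any(ph0$label$data > 0))

  spec <- small_phantom_spec(seed = 7L)
  a <- generate_phantom_volume(spec)
  b <- generate_phantom_volume(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$beads, b$beads)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(32L, 32L, 32L),
                            ellipsoid_semiaxes_mm = c(30, 30, 30)),
               "too small")
  expect_error(phantom_spec(tissue_intensity = 0, background_intensity = 0),
               "distinct")
})

test_that("analytic retraction field matches its closed form", {
  crack <- block_crack(10, 20, 20, depth = 10, width = 30)
  f <- analytic_retraction_field(crack, d_right_mm = 7.0, d_left_mm = 6.3,
                                 decay_radius_mm = 20, front_taper_mm = 5)
  centroid <- crack$origin + crack$depth / 2 * crack$e_d
  u <- evaluate_field(f, centroid, side = "+")
  expect_equal(drop(u), 7.0 * crack$e_n, tolerance = 1e-12)
  # beyond the decay radius the field vanishes
  far <- centroid + 25 * crack$e_n
  expect_equal(drop(evaluate_field(f, far)), c(0, 0, 0))
  # magnitude bound
  set.seed(1)
  pts <- cbind(runif(500, 0, 20), runif(500, 0, 20), runif(500, 0, 20))
  expect_lte(max(sqrt(rowSums(evaluate_field(f, pts)^2))), 7.0 + 1e-12)
})

test_that("field jump across the plane equals the closed form at on-plane points", {
  crack <- block_crack(10, 20, 20, depth = 10, width = 30)
  f <- analytic_retraction_field(crack, 7.0, 6.3, decay_radius_mm = 20,
                                 front_taper_mm = 5)
  set.seed(42)
  # on-plane points inside the polygon
  s <- runif(100, -14, 14)
  d <- runif(100, 0.2, 9.8)
  pts <- sweep(outer(s, crack$e_w) + outer(d, crack$e_d), 2, crack$origin, `+`)
  jump <- evaluate_field(f, pts, side = "+") - evaluate_field(f, pts, side = "-")
  phi <- level_sets(pts, crack)$phi
  expected <- (7.0 + 6.3) * pmin(pmax(-phi / 5, 0), 1)
  expect_lt(max(abs(drop(jump %*% crack$e_n) - expected)), 1e-12)
  expect_lt(max(abs(jump - outer(drop(jump %*% crack$e_n), crack$e_n))), 1e-12)
})

test_that("field construction rejects a non-unit normal", {
  crack <- block_crack(10, 20, 20)
  crack$e_n <- c(1, 1, 0)                  # corrupt
  expect_error(analytic_retraction_field(crack), "non-unit")
})

test_that("applying a field to a volume: identity, integer shift, bead motion", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L),
                       ellipsoid_semiaxes_mm = c(18, 16, 14),
                       smooth_sigma_mm = 1.5, n_beads = 10L)
  ph <- generate_phantom_volume(spec)
  crack <- default_phantom_crack(spec, depth_mm = 10, width_mm = 40)

  zero <- analytic_retraction_field(crack, 0, 0, 20, 5)
  out0 <- apply_field_to_volume(ph$volume, zero, crack, ph$beads)
  expect_identical(out0$volume$data, ph$volume$data)
  expect_equal(as.matrix(out0$beads[, c("x", "y", "z")]),
               as.matrix(ph$beads[, c("x", "y", "z")]), ignore_attr = TRUE)

  f <- analytic_retraction_field(crack, d_right_mm = 4, d_left_mm = 3.5,
                                 decay_radius_mm = 18, front_taper_mm = 5)
  out <- apply_field_to_volume(ph$volume, f, crack, ph$beads)
  disp <- sqrt(rowSums((as.matrix(out$beads[, c("x", "y", "z")]) -
                          as.matrix(ph$beads[, c("x", "y", "z")]))^2))
  expect_lte(max(disp), 4 + 1e-9)
  expect_gte(max(disp), 1.41)              # some bead in the moving zone
  # vacated voxels inside the opened crack get background
  mouth <- crack$origin
  gap_probe <- mouth + c(0, 0, -2)
  expect_equal(sample_volume(out$volume, gap_probe, "nearest"),
               spec$background_intensity)
})

test_that("a (near-)uniform integer translation shifts the array exactly", {
  set.seed(8)
  arr <- array(runif(20^3), rep(20, 3))
  vol <- image_volume(arr)
  # park the crack so the whole grid sits on the + side inside the cracked
  # zone with negligible taper: the field is a uniform 3 mm (+x) translation
  crack <- crack_geometry(c(-1, 10, 1e6), c(1, 0, 0), c(0, 0, -1),
                          width_mm = 1e7, depth_mm = 2e6)
  f <- analytic_retraction_field(crack, d_right_mm = 3, d_left_mm = 0,
                                 decay_radius_mm = 1e12, front_taper_mm = 1e-6)
  no_beads <- data.frame(id = integer(), x = numeric(), y = numeric(),
                         z = numeric(), region = character())
  out <- apply_field_to_volume(vol, f, crack, no_beads,
                               background_intensity = -1, interp = "nearest")
  expect_identical(out$volume$data[4:20, , ], arr[1:17, , ])
  expect_true(all(out$volume$data[1:3, , ] == -1))
})

test_that("simulated scanner clouds honour keep/noise/occlusion contracts", {
  crack <- block_crack(10, 20, 20, depth = 14, width = 30)
  model <- retractor_model(width_mm = 14, length_mm = 14, pitch_mm = 1)
  probe <- simulate_probe_points(crack, model)
  surf <- build_retractor_cloud(probe, model)

  # no-op settings reproduce the cloud exactly
  same <- simulate_lrs_cloud(surf, keep_fraction = 1, noise_sd_mm = 0,
                             occluded_patch_fraction = 0, seed = 3)
  expect_identical(same$points, surf$points)

  # occlusion removes the stated fraction (exact contiguous-quantile patch)
  occ <- simulate_lrs_cloud(surf, keep_fraction = 1, noise_sd_mm = 0,
                            occluded_patch_fraction = 0.3, seed = 3)
  expect_equal(nrow(occ$points), nrow(surf$points) - round(0.3 * nrow(surf$points)))

  # keep_fraction subsamples within binomial bounds
  kp <- simulate_lrs_cloud(surf, keep_fraction = 0.7, noise_sd_mm = 0,
                           occluded_patch_fraction = 0, seed = 5)
  n <- nrow(surf$points)
  expect_true(abs(nrow(kp$points) - 0.7 * n) < 4 * sqrt(n * 0.7 * 0.3))

  # noise: mean nearest-neighbour distance to the clean surface matches a
  # Monte-Carlo estimate of E||N(0, sd^2 I3)|| restricted to the surface
  nz <- simulate_lrs_cloud(surf, 1, 0.3, 0, seed = 11)
  d <- numeric(nrow(nz$points))
  for (s in seq(1, nrow(nz$points), by = 512)) {
    e <- min(s + 511, nrow(nz$points))
    D2 <- outer(rowSums(nz$points[s:e, , drop = FALSE]^2),
                rowSums(surf$points^2), `+`) -
      2 * nz$points[s:e, , drop = FALSE] %*% t(surf$points)
    d[s:e] <- sqrt(pmax(apply(D2, 1, min), 0))
  }
  # Monte-Carlo oracle with independent noise draws on the same clean grid
  set.seed(99)
  sub <- surf$points[sample(nrow(surf$points), 400), , drop = FALSE]
  noisy <- sub + matrix(rnorm(length(sub), sd = 0.3), ncol = 3)
  D2 <- outer(rowSums(noisy^2), rowSums(surf$points^2), `+`) -
    2 * noisy %*% t(surf$points)
  ref_mean <- mean(sqrt(pmax(apply(D2, 1, min), 0)))
  expect_lt(abs(mean(d) - ref_mean), 0.05)
  # and it exceeds the per-axis folded-normal mean (out-of-plane component)
  expect_gt(mean(d), 0.3 * sqrt(2 / pi) * 0.8)

  expect_error(simulate_lrs_cloud(surf, keep_fraction = 1e-9, seed = 1),
               "no points")
})

test_that("probe points encode the blade pose", {
  crack <- block_crack(10, 20, 20, depth = 14, width = 30)
  model <- retractor_model(width_mm = 14, length_mm = 14)
  probe <- simulate_probe_points(crack, model)
  expect_equal(nrow(probe), 4L)
  fit <- fit_plane(probe)
  expect_lt(min(sum((fit$normal - crack$e_n)^2),
                sum((fit$normal + crack$e_n)^2)), 1e-24)
  # equivariance: rotating the crack rotates the probe points identically
  R <- rot_z(0.4)
  cr2 <- crack_geometry(drop(R %*% crack$origin), drop(R %*% crack$e_n),
                        drop(R %*% crack$e_d), crack$width, crack$depth)
  probe2 <- simulate_probe_points(cr2, model)
  expect_equal(probe2, t(R %*% t(probe)), tolerance = 1e-12)
  # blade wider than the corridor is rejected
  expect_error(simulate_probe_points(block_crack(10, 20, 20, width = 10), model),
               "wider")
})
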