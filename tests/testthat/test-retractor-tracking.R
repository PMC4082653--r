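probe_unit <- rbind(c(-7, 0, 0), c(7, 0, 0), c(7, 60, 0), c(-7, 60, 0))

test_that("retractor template cloud has the stated grid structure and pose", {
  model <- retractor_model(width_mm = 14, length_mm = 60, pitch_mm = 1)
  cl <- build_retractor_cloud(probe_unit, model)
  expect_equal(nrow(cl$points), 2L * 15L * 61L)   # both faces
  expect_equal(sort(unique(cl$face)), c(-1, 1))
  # plane refit recovers the probe plane normal
  fit <- fit_plane(cl$points)
  expect_lt(min(sum((fit$normal - c(0, 0, 1))^2),
                sum((fit$normal + c(0, 0, 1))^2)), 1e-18)
  # rotation equivariance
  R <- rot_z(0.7)
  cl2 <- build_retractor_cloud(t(R %*% t(probe_unit)), model)
  expect_equal(cl2$points, t(R %*% t(cl$points)), tolerance = 1e-9)
  expect_equal(cl2$normals, t(R %*% t(cl$normals)), tolerance = 1e-9)
  # collinear probe points are rejected
  expect_error(build_retractor_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                     model), "collinear")
})

test_that("rigid transforms preserve lengths and validate their input", {
  cl <- build_retractor_cloud(probe_unit, retractor_model(length_mm = 60))
  expect_equal(apply_rigid(cl, diag(4))$points, cl$points)
  Tt <- rigid_T(t = c(1, -2, 3))
  expect_equal(apply_rigid(cl, Tt)$points,
               sweep(cl$points, 2, c(1, -2, 3), `+`))
  # compose with the inverse: identity to 1e-12
  Tr <- rigid_T(rot_z(0.3), c(4, 5, 6))
  back <- apply_rigid(apply_rigid(cl, Tr), solve(Tr))
  expect_lt(max(abs(back$points - cl$points)), 1e-12)
  d0 <- as.matrix(dist(cl$points[1:50, ]))
  d1 <- as.matrix(dist(apply_rigid(cl, Tr)$points[1:50, ]))
  expect_lt(max(abs(d0 - d1)), 1e-12)
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(apply_rigid(cl, bad), "orthonormal")
})

test_that("trimmed ICP recovers a known pose and is idempotent", {
  model <- retractor_model(length_mm = 25, pitch_mm = 1)
  tmpl <- build_retractor_cloud(probe_unit[, ], model)
  tmpl <- point_cloud(tmpl$points[tmpl$face == 1, ],
                      normals = tmpl$normals[tmpl$face == 1, ])
  Tr <- rigid_T(rot_z(0.12), c(3, -1, 2))
  moved <- apply_rigid(tmpl, Tr)
  fit <- rigid_augment(tmpl, moved)
  expect_lt(max(abs(fit$cloud$points - moved$points)), 1e-6)
  # self-registration: identity pose
  self <- rigid_augment(tmpl, tmpl)
  expect_lt(max(abs(self$transform - diag(4))), 1e-9)
  # idempotence on its own output
  again <- rigid_augment(fit$cloud, moved)
  expect_lt(max(abs(again$transform - diag(4))), 1e-6)
})

test_that("trimmed ICP tolerates occlusion and noise", {
  model <- retractor_model(length_mm = 25, pitch_mm = 1)
  tmpl <- build_retractor_cloud(probe_unit, model)
  tmpl <- point_cloud(tmpl$points[tmpl$face == 1, ],
                      normals = tmpl$normals[tmpl$face == 1, ])
  Tr <- rigid_T(rot_z(0.05), c(2, 1, -1))
  errs <- sapply(1:5, function(seed) {
    part <- simulate_lrs_cloud(apply_rigid(tmpl, Tr), keep_fraction = 1,
                               noise_sd_mm = 0.3, occluded_patch_fraction = 0.3,
                               seed = seed)
    fit <- rigid_augment(tmpl, part)
    sqrt(sum((fit$transform[1:3, 4] - Tr[1:3, 4])^2))
  })
  # Monte-Carlo: a seed whose occlusion wedge hides a blade edge leaves that
  # edge position unobservable, so the bound holds for the mean over seeds
  expect_lt(mean(errs), 0.5)
})

test_that("CPD registers trivial and translated clouds", {
  set.seed(10)
  Y <- cbind(runif(150, 0, 14), runif(150, 0, 25), rnorm(150, sd = 0.05))
  # identity: target is a subsample of the source; with adequate smoothness
  # the displacement vanishes everywhere (including unmatched centroids)
  sub <- Y[sample(150, 90), ]
  r0 <- suppressWarnings(cpd_nonrigid_register(point_cloud(Y), point_cloud(sub),
                                               params = list(lambda = 10)))
  expect_lt(max(abs(r0$displacement)), 0.05)
  # at the default (laxer) smoothness only isolated corner centroids drift
  r0b <- suppressWarnings(cpd_nonrigid_register(point_cloud(Y), point_cloud(sub)))
  expect_lt(sqrt(mean(rowSums(r0b$displacement^2))), 0.3)
  # pure translation recovered to well under 0.1 mm RMSE
  r1 <- cpd_nonrigid_register(point_cloud(Y),
                              point_cloud(sweep(Y, 2, c(2, 0, 0), `+`)))
  rmse <- sqrt(mean(rowSums((r1$displacement -
                               matrix(c(2, 0, 0), 150, 3, byrow = TRUE))^2)))
  expect_lt(rmse, 0.1)
  # degenerate cloud errors out
  expect_error(cpd_nonrigid_register(point_cloud(matrix(1, 40, 3)),
                                     point_cloud(matrix(1, 40, 3))),
               "degenerate")
})

test_that("CPD negative log-likelihood is monotone non-increasing", {
  set.seed(3)
  Y <- cbind(runif(120, 0, 14), runif(120, 0, 25), 0)
  u <- cbind(0, 0, 1.5 * sin(pi * Y[, 2] / 25))
  X <- Y + u + matrix(rnorm(360, sd = 0.2), ncol = 3)
  r <- suppressWarnings(cpd_nonrigid_register(point_cloud(Y), point_cloud(X)))
  expect_true(all(diff(r$nll) <= 1e-6 * pmax(1, abs(r$nll[-length(r$nll)]))))
  # smooth-deformation recovery at the noise level
  rmse <- sqrt(mean(rowSums((r$displacement - u)^2)))
  expect_lt(rmse, 0.2)
})

test_that("boundary-condition extraction applies the thickness offset and side matching", {
  # fine 1 mm mesh so snapped nodes sit close to the crack plane
  lab <- cube_label(16, voxel = 1)
  mesh <- build_hex_mesh(lab, 2)
  crack <- block_crack(8, 16, 16, depth = 30, width = 60)
  en <- classify_enrichment(mesh, crack)
  model <- retractor_model(width_mm = 8, length_mm = 8, thickness_mm = 2,
                           pitch_mm = 2)
  probe <- simulate_probe_points(crack, model)
  tmpl <- build_retractor_cloud(probe, model)
  field <- analytic_retraction_field(crack, 4, 3.5, decay_radius_mm = 40,
                                     front_taper_mm = 4)
  # tracked face displacement = tissue displacement - thickness * face normal
  disp <- matrix(0, nrow(tmpl$points), 3)
  for (s in c(1, -1)) {
    rows <- tmpl$face == s
    disp[rows, ] <- evaluate_field(field, tmpl$points[rows, , drop = FALSE],
                                   side = if (s > 0) "+" else "-") -
      model$thickness * tmpl$normals[rows, , drop = FALSE]
  }
  zero <- select_zero_nodes(mesh, 3, 2)
  bcs <- extract_contact_bcs(list(cloud = tmpl, displacement = disp),
                             model, mesh, crack, en, zero)
  expect_true(all(bcs$entries$side %in% c("+", "-")))
  # no entry sits on the wrong psi-side
  psi_n <- level_sets(mesh$nodes[bcs$entries$node, , drop = FALSE], crack)$psi
  expect_true(all((bcs$entries$side == "+") == (psi_n >= 0)))
  # BC vectors match the truth field at the snapped nodes
  for (i in seq_len(nrow(bcs$entries))) {
    nd <- bcs$entries$node[i]
    truth <- evaluate_field(field, mesh$nodes[nd, , drop = FALSE],
                            side = bcs$entries$side[i])
    got <- as.numeric(bcs$entries[i, c("ux", "uy", "uz")])
    expect_lt(sqrt(sum((got - truth)^2)), 0.2)
  }
  # zero-thickness model: BC equals the face displacement exactly
  m0 <- retractor_model(width_mm = 8, length_mm = 8, thickness_mm = 0,
                        pitch_mm = 2)
  bcs0 <- extract_contact_bcs(list(cloud = tmpl, displacement = disp),
                              m0, mesh, crack, en, zero)
  expect_true(nrow(bcs0$entries) > 0)
})

test_that("empty zero region and missing labels are rejected", {
  mesh <- build_hex_mesh(cube_label(10), 5)
  crack <- block_crack(5, 10, 10, depth = 20, width = 40)
  en <- classify_enrichment(mesh, crack)
  cl <- point_cloud(matrix(runif(30), 10, 3))
  expect_error(extract_contact_bcs(list(cloud = cl, displacement = matrix(0, 10, 3)),
                                   retractor_model(), mesh, crack, en,
                                   integer()), "empty")
  expect_error(extract_contact_bcs(list(cloud = cl, displacement = matrix(0, 10, 3)),
                                   retractor_model(), mesh, crack, en, 1L),
               "normals")
})
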