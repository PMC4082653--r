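#' Retractor blade model
#'
#' @param width_mm blade width (default 14 mm).
#' @param length_mm inserted blade length (mm).
#' @param thickness_mm blade thickness (mm); tracked inner-face displacements
#'   are offset by this distance along the face normal to reach the tissue in
#'   contact.
#' @param pitch_mm template-cloud sampling pitch (mm).
#' @return a `retractor_model`.
#' @export
retractor_model <- function(width_mm = 14, length_mm = 25, thickness_mm = 2,
                            pitch_mm = 2) {
  stopifnot(width_mm > 0, length_mm > 0, thickness_mm >= 0, pitch_mm > 0)
  structure(list(width = width_mm, length = length_mm,
                 thickness = thickness_mm, pitch = pitch_mm),
            class = "retractor_model")
}

#' Rigid transform (4 x 4 homogeneous matrix)
#'
#' @param T 4 x 4 matrix; the rotation block must be orthonormal with
#'   `det = +1` to 1e-9.
#' @return a validated `rigid_transform`.
#' @export
rigid_transform <- function(T) {
  T <- as.matrix(T)
  stopifnot(identical(dim(T), c(4L, 4L)))
  R <- T[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("rotation block is not orthonormal with det +1")
  if (max(abs(T[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row must be (0, 0, 0, 1)")
  structure(T, class = c("rigid_transform", "matrix"))
}

#' Apply a rigid transform to a point cloud
#'
#' Points and normals are transformed; lengths are preserved to 1e-12.
#'
#' @param cloud a [point_cloud()].
#' @param T a [rigid_transform()] (or 4 x 4 matrix, validated on the way in).
#' @return the transformed [point_cloud()].
#' @export
apply_rigid <- function(cloud, T) {
  if (!inherits(T, "rigid_transform")) T <- rigid_transform(T)
  R <- T[1:3, 1:3]; tt <- T[1:3, 4]
  p <- sweep(cloud$points %*% t(R), 2, tt, `+`)
  nrm <- if (!is.null(cloud$normals)) cloud$normals %*% t(R)
  point_cloud(p, normals = nrm, face = cloud$face)
}

#' Build the dense pre-retraction retractor template cloud
#'
#' Reconstructs the blade frame from probe-digitised corner coordinates
#' (mouth-left, mouth-right, tip-right and optionally tip-left) and samples both blade
#' faces on a regular grid at the model pitch, with outward unit normals and
#' face labels (+1 / -1) attached. Both faces sit on the blade mid-plane: the
#' blade's own thickness is accounted for at boundary-condition extraction,
#' where tracked face displacements are offset by the thickness along the
#' face normal.
#'
#' @param probe_points at least 3 non-collinear world points (rows), in the
#'   corner convention of [simulate_probe_points()].
#' @param model a [retractor_model()].
#' @return a [point_cloud()] with normals and `face` labels.
#' @export
build_retractor_cloud <- function(probe_points, model) {
  p <- rbind3(probe_points)
  if (nrow(p) < 3) stop("need at least 3 probe points")
  c1 <- p[1, ]; c2 <- p[2, ]
  e_w <- c2 - c1
  nw <- sqrt(sum(e_w^2))
  d_raw <- if (nrow(p) >= 4) p[4, ] - c1 else p[3, ] - c2
  cr <- c(e_w[2] * d_raw[3] - e_w[3] * d_raw[2],
          e_w[3] * d_raw[1] - e_w[1] * d_raw[3],
          e_w[1] * d_raw[2] - e_w[2] * d_raw[1])
  if (nw < 1e-9 || sqrt(sum(cr^2)) < 1e-9 * nw * max(sqrt(sum(d_raw^2)), 1e-12))
    stop("probe points are collinear: cannot reconstruct the blade plane")
  e_w <- e_w / nw
  e_d <- d_raw - sum(d_raw * e_w) * e_w
  e_d <- e_d / sqrt(sum(e_d^2))
  e_n <- c(e_d[2] * e_w[3] - e_d[3] * e_w[2],   # e_d x e_w: matches the
           e_d[3] * e_w[1] - e_d[1] * e_w[3],   # crack-frame normal (e_w =
           e_d[1] * e_w[2] - e_d[2] * e_w[1])   # e_n x e_d)
  o <- (c1 + c2) / 2
  sw <- seq(-model$width / 2, model$width / 2,
            length.out = round(model$width / model$pitch) + 1)
  sd <- seq(0, model$length, length.out = round(model$length / model$pitch) + 1)
  grid <- as.matrix(expand.grid(w = sw, d = sd))
  base <- sweep(outer(grid[, 1], e_w) + outer(grid[, 2], e_d), 2, o, `+`)
  pts <- rbind(base, base)
  nf <- nrow(base)
  face <- rep(c(1, -1), each = nf)
  normals <- rbind(matrix(e_n, nf, 3, byrow = TRUE),
                   matrix(-e_n, nf, 3, byrow = TRUE))
  point_cloud(pts, normals = normals, face = face)
}

# nearest neighbour of each row of A among rows of B (chunked, no KD-tree
# package in this stack): returns list(index, dist)
nearest_neighbour <- function(A, B, chunk = 2048L) {
  A <- rbind3(A); B <- rbind3(B)
  b2 <- rowSums(B^2)
  idx <- integer(nrow(A)); d2 <- numeric(nrow(A))
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ab <- A[s:e, , drop = FALSE]
    D2 <- outer(rowSums(Ab^2), b2, `+`) - 2 * Ab %*% t(B)
    j <- max.col(-D2, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- D2[cbind(seq_len(nrow(Ab)), j)]
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

# coarse rigid initialisation: match centroids and principal axes, trying the
# four right-handed axis-sign combinations and keeping the lowest NN cost
icp_init_candidates <- function(P, X) {
  cp <- colMeans(P); cx <- colMeans(X)
  Vp <- svd(sweep(P, 2, cp))$v
  Vx <- svd(sweep(X, 2, cx))$v
  if (det(Vp) < 0) Vp[, 3] <- -Vp[, 3]
  if (det(Vx) < 0) Vx[, 3] <- -Vx[, 3]
  cands <- list(diag(4), rigid_from(diag(3), cx - cp))
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))           # keeps det(R) = +1
    R <- Vx %*% S %*% t(Vp)
    cands[[length(cands) + 1L]] <- rigid_from(R, cx - as.numeric(R %*% cp))
  }
  cands
}

rigid_from <- function(R, t) {
  T <- diag(4); T[1:3, 1:3] <- R; T[1:3, 4] <- t
  T
}

rotation_angle <- function(T) {
  acos(pmin(pmax((sum(diag(T[1:3, 1:3])) - 1) / 2, -1), 1))
}

# project `a` onto the plane through `b` with unit normal `n`, clamping the
# in-plane excursion from `b` at `r`
proj_clamp <- function(a, b, n, r) {
  q <- a - rowSums((a - b) * n) * n
  dq <- q - b
  len <- sqrt(rowSums(dq^2))
  b + dq * pmin(1, r / pmax(len, 1e-12))
}

# Kabsch: rigid (R, t) minimising ||R p + t - q||
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Rigidly augment a partial scan with the retractor template
#'
#' Trimmed iterative-closest-point fit of the template cloud onto the partial
#' scanner cloud (keeping the best-matching fraction of pairs each iteration,
#' which resists occlusion), returning the template posed at the fit — a
#' completed post-retraction retractor surface — together with the pose and
#' the trimmed RMS residual.
#'
#' @param template dense [point_cloud()] (e.g. [build_retractor_cloud()]).
#' @param partial_scan sparse scanner [point_cloud()] (>= 50 points).
#' @param trim fraction of closest pairs kept per iteration (default 0.7).
#' @param max_iter,tol iteration controls.
#' @param residual_threshold registration fails (error) if the final trimmed
#'   RMS exceeds this (mm).
#' @return list with `cloud` (posed template), `transform`
#'   ([rigid_transform()]), `rms` (mm) and `iterations`.
#' @export
rigid_augment <- function(template, partial_scan, trim = 0.7, max_iter = 100,
                          tol = 1e-10, residual_threshold = 10) {
  stopifnot(inherits(template, "point_cloud"), inherits(partial_scan, "point_cloud"))
  if (nrow(partial_scan$points) < 50)
    stop("partial scan too sparse (< 50 points) for rigid augmentation")
  P0 <- template$points
  N0 <- template$normals
  X <- partial_scan$points
  # template sampling pitch (second-nearest self distance), for clamping
  # projective correspondences
  smp <- P0[seq(1, nrow(P0), length.out = min(100, nrow(P0))), , drop = FALSE]
  D2 <- outer(rowSums(smp^2), rowSums(P0^2), `+`) - 2 * smp %*% t(P0)
  pitch <- stats::median(apply(D2, 1, function(d) sqrt(max(sort(d)[2], 0))))
  # template boundary points (fewer neighbours than an interior grid point):
  # they keep point-to-point matching, which anchors the in-plane pose
  nbr <- integer(nrow(P0))
  for (s in seq(1, nrow(P0), by = 2048L)) {
    e <- min(s + 2047L, nrow(P0))
    DD <- outer(rowSums(P0[s:e, , drop = FALSE]^2), rowSums(P0^2), `+`) -
      2 * P0[s:e, , drop = FALSE] %*% t(P0)
    nbr[s:e] <- rowSums(DD <= (1.55 * pitch)^2)
  }
  is_boundary <- nbr <= 8L                  # interior: 8 neighbours + itself
  icp_run <- function(T0) {
    Tcur <- T0
    rms <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      R <- Tcur[1:3, 1:3]
      P <- sweep(P0 %*% t(R), 2, Tcur[1:3, 4], `+`)
      Nc <- if (!is.null(N0)) N0 %*% t(R)
      # reverse correspondences (scan -> template): every scan point has a
      # counterpart on the complete template, so occlusion cannot bias them
      nn <- nearest_neighbour(X, P)
      p_rev <- P[nn$index, , drop = FALSE]
      x_rev <- X
      if (!is.null(N0)) {
        # interior matches become projective (scan point projected onto the
        # local tangent plane, clamped to half the sampling pitch): removes
        # sampling-lattice aliasing; boundary matches stay point-to-point
        q <- proj_clamp(x_rev, p_rev, Nc[nn$index, , drop = FALSE], pitch / 2)
        inter <- !is_boundary[nn$index]
        p_rev[inter, ] <- q[inter, , drop = FALSE]
      }
      # forward correspondences (template -> scan), trimmed: penalise the
      # template protruding beyond the scan, while the trim fraction rejects
      # template points whose counterpart is occluded
      fw <- nearest_neighbour(P, X)
      fkeep <- order(fw$dist)[seq_len(max(3L, floor(trim * nrow(P))))]
      p_fwd <- P[fkeep, , drop = FALSE]
      x_fwd <- X[fw$index[fkeep], , drop = FALSE]
      if (!is.null(N0)) {
        q <- proj_clamp(p_fwd, x_fwd, Nc[fkeep, , drop = FALSE], pitch / 2)
        inter <- !is_boundary[fkeep]
        x_fwd[inter, ] <- q[inter, , drop = FALSE]
      }
      p <- rbind(p_rev, p_fwd)
      x <- rbind(x_rev, x_fwd)
      fit <- kabsch(p, x)
      Tcur <- rigid_from(fit$R, fit$t) %*% Tcur
      new_rms <- sqrt(mean(rowSums((sweep(p %*% t(fit$R), 2, fit$t, `+`) - x)^2)))
      if (it >= max_iter || abs(rms - new_rms) < tol) { rms <- new_rms; break }
      rms <- new_rms
    }
    P <- sweep(P0 %*% t(Tcur[1:3, 1:3]), 2, Tcur[1:3, 4], `+`)
    sel <- mean(nearest_neighbour(X, P)$dist)   # untrimmed point score
    list(T = Tcur, rms = rms, it = it, sel = sel)
  }
  # refine from several coarse starts (identity, centroid shift, principal
  # axes with all sign combinations); symmetric shapes make single-start ICP
  # fall into the 180-degree-flipped basin, so the best *final* residual
  # wins, with near-ties broken toward the smaller rotation
  runs <- lapply(icp_init_candidates(P0, X), icp_run)
  rmss <- vapply(runs, `[[`, numeric(1), "sel")
  angs <- vapply(runs, function(r) rotation_angle(r$T), numeric(1))
  # scores closer than a fraction of the sampling pitch are physical ties
  best <- order(round(rmss / max(1e-6 * max(rmss), 1e-4 * pitch)), angs)[1]
  Tcur <- runs[[best]]$T; rms <- runs[[best]]$rms; it <- runs[[best]]$it
  if (rms > residual_threshold)
    stop(sprintf("rigid augmentation failed: trimmed RMS %.3f mm above threshold", rms))
  posed <- apply_rigid(template, rigid_transform(Tcur))
  list(cloud = posed, transform = rigid_transform(Tcur), rms = rms,
       iterations = it)
}

#' Nonrigid coherent point drift registration
#'
#' EM registration of the dense pre-retraction cloud (Gaussian-mixture
#' centroids) toward the sparse post-retraction cloud (data points) with a
#' Gaussian coherence kernel: the centroids move as `T(Y) = Y + G W` where
#' `G_ij = exp(-||y_i - y_j||^2 / (2 beta^2))` (beta in units of the cloud
#' scale; clouds are normalised internally) and `W` solves the regularised
#' M-step system with smoothness weight `lambda`. The negative log-likelihood
#' is tracked and is non-increasing across EM iterations (up to `tol`).
#'
#' @param dense_pre [point_cloud()] of GMM centroids (moved).
#' @param sparse_post [point_cloud()] of data points (target).
#' @param params list with `beta` (kernel width, default 2), `lambda`
#'   (regularisation, default 3), `w` (outlier weight in `[0, 1)`, default
#'   0), `max_iter` (default 80), `tol` (default 1e-8).
#' @return list: `displacement` (N x 3, world mm), `transformed` (moved
#'   dense_pre points), `nll` (per-iteration negative log-likelihood),
#'   `sigma2`, `converged`, `iterations`.
#' @export
cpd_nonrigid_register <- function(dense_pre, sparse_post,
                                  params = list()) {
  stopifnot(inherits(dense_pre, "point_cloud"), inherits(sparse_post, "point_cloud"))
  p <- modifyList(list(beta = 2, lambda = 3, w = 0, max_iter = 80, tol = 1e-8),
                  params)
  stopifnot(p$beta > 0, p$lambda > 0, p$w >= 0, p$w < 1)
  Y0 <- dense_pre$points; X0 <- sparse_post$points
  N <- nrow(Y0); M <- nrow(X0)
  if (N == 0 || M == 0) stop("empty point cloud")
  # common normalisation (centroid and scale of the joined clouds) so that a
  # partial/occluded target does not get rescaled against the full template
  mu <- colMeans(rbind(X0, Y0))
  sc <- sqrt(mean(rowSums(sweep(rbind(X0, Y0), 2, mu)^2)))
  if (sc < 1e-12)
    stop("degenerate cloud (all points identical): cannot register")
  X <- sweep(X0, 2, mu) / sc
  Y <- sweep(Y0, 2, mu) / sc
  G <- exp(-as.matrix(stats::dist(Y))^2 / (2 * p$beta^2))
  W <- matrix(0, N, 3)
  TY <- Y
  sigma2 <- sum(outer(rowSums(X^2), rep(1, N)) + outer(rep(1, M), rowSums(Y^2)) -
                  2 * X %*% t(Y)) / (3 * M * N)
  nll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(p$max_iter)) {
    D2 <- outer(rowSums(X^2), rowSums(TY^2), `+`) - 2 * X %*% t(TY)
    num <- exp(-D2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^1.5 * p$w / (1 - p$w) * N / M
    den <- rowSums(num) + cst
    nll_it <- -sum(log(pmax(den, 1e-300))) + M * 1.5 * log(sigma2 * 2 * pi)
    nll <- c(nll, nll_it)
    P <- num / pmax(den, 1e-300)
    P1 <- colSums(P)                         # length N
    Np <- sum(P1)
    rhs <- crossprod(P, X) - P1 * Y
    A <- G * P1 + diag(p$lambda * sigma2, N)
    W <- solve(A, rhs)
    TY <- Y + G %*% W
    xPx <- sum(rowSums(P) * rowSums(X^2))
    trPXY <- sum((crossprod(P, X)) * TY)
    yPy <- sum(P1 * rowSums(TY^2))
    sigma2 <- max((xPx - 2 * trPXY + yPy) / (3 * Np), 1e-12)
    # stop once the residual scale is far below any data scale of interest:
    # letting sigma2 collapse de-regularises the M-step system and lets the
    # unmatched centroids drift on the ill-conditioned kernel
    if (sigma2 <= 1e-5) { converged <- TRUE; break }
    if (it > 1 && abs(nll[it - 1] - nll[it]) <
        p$tol * max(1, abs(nll[it - 1]))) { converged <- TRUE; break }
  }
  if (!converged)
    warning("CPD did not converge within max_iter; returning last iterate")
  out_pts <- sweep(as.matrix(TY) * sc, 2, mu, `+`)
  orig <- Y0
  list(displacement = out_pts - orig, transformed = out_pts,
       nll = nll, sigma2 = sigma2, converged = converged, iterations = length(nll))
}

#' Select the zero-displacement node region
#'
#' @param mesh a [build_hex_mesh()] result.
#' @param axis 1, 2 or 3.
#' @param max_mm nodes with coordinate `<= max_mm` along `axis` are fixed.
#' @return integer node indices.
#' @export
select_zero_nodes <- function(mesh, axis = 3, max_mm) {
  which(mesh$nodes[, axis] <= max_mm)
}

#' Convert tracked retractor displacements into Dirichlet boundary conditions
#'
#' Each tracked face displacement is offset by the blade thickness along that
#' face's outward normal (the tissue in contact lies one blade thickness
#' beyond the tracked inner face), then attached to the nearest
#' Heaviside-enriched mesh node on the matching side of the crack plane
#' (nearest neighbour, maximum snap distance one element size; farther points
#' are dropped with a log message). Multiple cloud points snapping to one
#' node are averaged; inconsistent prescriptions on a node raise an error.
#'
#' @param registered list with `cloud` (the dense pre-retraction template
#'   [point_cloud()] with normals and face labels) and `displacement`
#'   (N x 3 mm, e.g. from [cpd_nonrigid_register()]).
#' @param model the [retractor_model()] (for the thickness offset).
#' @param mesh,crack the discretisation.
#' @param enrichment the [classify_enrichment()] table (crack-face nodes).
#' @param zero_nodes integer node set fixed to zero (e.g.
#'   [select_zero_nodes()]); must be nonempty.
#' @param conflict_tol maximum spread (mm) tolerated among prescriptions
#'   snapped to one node before raising a conflict error.
#' @param normal_only keep only the component of the registered displacement
#'   along the face normal (default TRUE). The tangential motion of a
#'   featureless blade face is unobservable from its tracked shape (the
#'   aperture problem), so tangential components of the registration are
#'   artefacts rather than measurements.
#' @return a [displacement_bc_set()].
#' @export
extract_contact_bcs <- function(registered, model, mesh, crack, enrichment,
                                zero_nodes, conflict_tol = 3,
                                normal_only = TRUE) {
  stopifnot(is.list(registered), inherits(registered$cloud, "point_cloud"))
  cloud <- registered$cloud
  disp <- rbind3(registered$displacement)
  stopifnot(nrow(disp) == nrow(cloud$points))
  if (length(zero_nodes) == 0) stop("zero-displacement region is empty")
  if (is.null(cloud$normals) || is.null(cloud$face))
    stop("registered cloud must carry normals and face labels")
  if (normal_only)
    disp <- rowSums(disp * cloud$normals) * cloud$normals
  bc_vec <- disp + model$thickness * cloud$normals
  side_pt <- ifelse(cloud$face > 0, "+", "-")
  Jn <- enrichment$set_J
  if (length(Jn) == 0) stop("no Heaviside-enriched nodes to attach BCs to")
  Hs <- enrichment$H_node[Jn]
  max_snap <- max(mesh$h)
  entries <- list()
  dropped <- 0L
  for (s in c("+", "-")) {
    pts_i <- which(side_pt == s)
    nd_i <- Jn[if (s == "+") Hs > 0 else Hs < 0]
    if (!length(pts_i) || !length(nd_i)) next
    nn <- nearest_neighbour(cloud$points[pts_i, , drop = FALSE],
                            mesh$nodes[nd_i, , drop = FALSE])
    ok <- nn$dist <= max_snap
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    tgt <- nd_i[nn$index[ok]]
    v <- bc_vec[pts_i[ok], , drop = FALSE]
    for (nd in unique(tgt)) {
      rows <- which(tgt == nd)
      vv <- v[rows, , drop = FALSE]
      if (nrow(vv) > 1 && max(apply(vv, 2, function(z) diff(range(z)))) > conflict_tol)
        stop("conflicting prescriptions snapped to node ", nd)
      entries[[length(entries) + 1L]] <-
        data.frame(node = nd, side = s, ux = mean(vv[, 1]), uy = mean(vv[, 2]),
                   uz = mean(vv[, 3]))
    }
  }
  if (dropped > 0)
    message(dropped, " tracked point(s) beyond snap distance were dropped")
  ent <- do.call(rbind, entries)
  if (is.null(ent)) stop("no tracked point reached any crack-adjacent node")
  zero_nodes <- setdiff(as.integer(zero_nodes), ent$node)
  displacement_bc_set(ent, zero_nodes)
}
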