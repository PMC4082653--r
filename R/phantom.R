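#' Synthetic brain-phantom specification
#'
#' Parameters for the synthetic stand-in for a PVA-C brain phantom scanned by
#' CT: a smoothed-ellipsoid tissue volume with embedded high-intensity
#' fiducial beads. Defaults follow the physical rig the package emulates:
#' 1 mm isotropic voxels, 23 beads of 1.5 mm diameter split 4/12/7 between
#' frontal, parietal and occipital regions with two deep beads.
#'
#' @param grid_shape 3 positive integers, volume dimensions in voxels.
#' @param voxel_size_mm 3 positive reals (mm).
#' @param ellipsoid_semiaxes_mm 3 positive reals (mm); the tissue mask is a
#'   smoothed ellipsoid with these semiaxes, centred in the grid.
#' @param n_beads number of beads (default 23).
#' @param bead_diameter_mm bead diameter (default 1.5 mm).
#' @param background_intensity,tissue_intensity,bead_intensity image
#'   intensities; must be pairwise distinct.
#' @param smooth_sigma_mm Gaussian smoothing applied to the ellipsoid
#'   indicator before thresholding at 0.5 (surface smoothing only).
#' @param seed integer RNG seed controlling bead placement.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_size_mm = c(1, 1, 1),
                         ellipsoid_semiaxes_mm = c(55, 45, 40),
                         n_beads = 23L,
                         bead_diameter_mm = 1.5,
                         background_intensity = 0,
                         tissue_intensity = 100,
                         bead_intensity = 1000,
                         smooth_sigma_mm = 2,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(ellipsoid_semiaxes_mm) == 3L, all(ellipsoid_semiaxes_mm > 0),
            n_beads >= 0, bead_diameter_mm > 0)
  ints <- c(background_intensity, tissue_intensity, bead_intensity)
  if (anyDuplicated(ints))
    stop("background, tissue and bead intensities must be pairwise distinct")
  extent <- grid_shape * voxel_size_mm
  if (any(2 * ellipsoid_semiaxes_mm + 2 * smooth_sigma_mm >= extent))
    stop("grid too small to contain the ellipsoid (plus smoothing margin)")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 ellipsoid_semiaxes_mm = as.numeric(ellipsoid_semiaxes_mm),
                 n_beads = as.integer(n_beads),
                 bead_diameter_mm = bead_diameter_mm,
                 background_intensity = background_intensity,
                 tissue_intensity = tissue_intensity,
                 bead_intensity = bead_intensity,
                 smooth_sigma_mm = smooth_sigma_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable 3-D Gaussian smoothing by banded matrix products along each axis
smooth3d <- function(arr, sigma_mm, voxel_size_mm) {
  d <- dim(arr)
  kern1 <- function(n, sigma_vox) {
    if (sigma_vox <= 0) return(diag(n))
    half <- max(1L, ceiling(3 * sigma_vox))
    off <- -half:half
    w <- exp(-off^2 / (2 * sigma_vox^2)); w <- w / sum(w)
    S <- matrix(0, n, n)
    for (k in seq_along(off)) {
      j <- seq_len(n) + off[k]
      ok <- j >= 1 & j <= n
      S[cbind(which(ok), j[ok])] <- S[cbind(which(ok), j[ok])] + w[k]
    }
    S
  }
  S1 <- kern1(d[1], sigma_mm / voxel_size_mm[1])
  S2 <- kern1(d[2], sigma_mm / voxel_size_mm[2])
  S3 <- kern1(d[3], sigma_mm / voxel_size_mm[3])
  x <- S1 %*% matrix(arr, d[1], d[2] * d[3])
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- S2 %*% matrix(x, d[2], d[1] * d[3])
  x <- aperm(array(x, c(d[2], d[1], d[3])), c(2, 1, 3))
  x <- matrix(x, d[1] * d[2], d[3]) %*% t(S3)
  array(x, d)
}

#' Generate the synthetic phantom volume, tissue label and bead set
#'
#' Builds the smoothed-ellipsoid tissue mask, places `n_beads` bead centers
#' inside it (continuous world coordinates, never voxelised) and renders them
#' as spheres of `bead_diameter_mm`. Shallow beads sit in an upper cortical
#' band near the retraction corridor (where measurable tissue motion occurs),
#' split front-to-back into frontal / parietal / occipital groups; the last
#' two beads are deep (near the ellipsoid centre), mirroring the 4/12/7
#' regional layout with two deep fiducials of the physical phantom.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (intensities, `image_volume`), `label` (binary
#'   tissue mask, `image_volume`) and `beads` (data.frame `id, x, y, z,
#'   region` with attribute `space = "pre-retraction"`).
#' @export
generate_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  vol <- image_volume(array(0, d), voxel_size_mm = vs)
  ctr <- (d * vs) / 2                       # world centre of the grid
  ax <- spec$ellipsoid_semiaxes_mm

  xyz <- all_voxel_centers(vol)
  xn <- (xyz[, 1] - ctr[1]) / ax[1]
  yn <- (xyz[, 2] - ctr[2]) / ax[2]
  zn <- (xyz[, 3] - ctr[3]) / ax[3]
  ind <- array(as.numeric(xn^2 + yn^2 + zn^2 <= 1), d)
  sm <- smooth3d(ind, spec$smooth_sigma_mm, vs)
  mask <- sm >= 0.5
  if (!any(mask)) stop("grid too small to contain ellipsoid")

  beads <- place_beads(spec, ctr)
  img <- array(spec$background_intensity, d)
  img[mask] <- spec$tissue_intensity
  if (nrow(beads) > 0) {
    r <- spec$bead_diameter_mm / 2
    for (b in seq_len(nrow(beads))) {
      c_mm <- as.numeric(beads[b, c("x", "y", "z")])
      img <- paint_sphere(img, vol, c_mm, r, spec$bead_intensity)
    }
  }
  list(volume = image_volume(img, affine = vol$affine),
       label = image_volume(array(as.numeric(mask), d), affine = vol$affine),
       beads = beads)
}

# set voxels whose centers fall within radius r of c_mm
paint_sphere <- function(img, vol, c_mm, r, value) {
  d <- dim(img)
  i0 <- world_to_voxel(vol, c_mm)           # continuous 0-based
  vs <- voxel_size(vol)
  lo <- pmax(floor(i0 - r / vs) + 1, 1)     # 1-based bounds
  hi <- pmin(ceiling(i0 + r / vs) + 1, d)
  if (any(lo > hi)) return(img)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  w <- voxel_to_world(vol, grid - 1)
  inside <- rowSums(sweep(w, 2, c_mm)^2) <= r^2
  img[grid[inside, , drop = FALSE]] <- value
  img
}

# deterministic rejection sampling of bead centres; see generate_phantom_volume
place_beads <- function(spec, ctr) {
  n <- spec$n_beads
  empty <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), region = character())
  attr(empty, "space") <- "pre-retraction"
  if (n == 0) return(empty)
  ax <- spec$ellipsoid_semiaxes_mm
  # regional quotas in the spirit of the 4/12/7 (+2 deep) layout
  n_deep <- if (n >= 10) 2L else 0L
  n_shallow <- n - n_deep
  n_f <- round(n_shallow * 4 / 21)
  n_o <- round(n_shallow * 7 / 21)
  n_p <- n_shallow - n_f - n_o
  plan <- c(rep("frontal", n_f), rep("parietal", n_p), rep("occipital", n_o),
            rep("deep", n_deep))

  yband <- list(frontal = c(0.30, 0.75), parietal = c(-0.30, 0.30),
                occipital = c(-0.75, -0.30))
  set.seed(spec$seed)
  pts <- matrix(NA_real_, n, 3)
  min_sep <- min(5, min(ax) / 8)            # mm between bead centres
  for (b in seq_len(n)) {
    reg <- plan[b]
    for (try in 1:20000) {
      if (reg == "deep") {
        p_n <- stats::runif(3, -0.25, 0.25)
      } else {
        p_n <- c(stats::runif(1, -0.45, 0.45),
                 stats::runif(1, yband[[reg]][1], yband[[reg]][2]),
                 stats::runif(1, 0.62, 0.88))
      }
      if (sum(p_n^2) > 0.81) next           # keep >= ~4 mm inside the surface
      p <- ctr + p_n * ax
      if (b > 1 && min(rowSums(sweep(pts[seq_len(b - 1), , drop = FALSE], 2, p)^2),
                       na.rm = TRUE) < min_sep^2) next
      pts[b, ] <- p
      break
    }
    if (anyNA(pts[b, ]))
      stop("could not place bead ", b, " (constraints too tight)")
  }
  out <- data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    region = ifelse(plan == "deep", "parietal", plan),
                    stringsAsFactors = FALSE)
  out$deep <- plan == "deep"
  attr(out, "space") <- "pre-retraction"
  out
}

#' Default retraction corridor for a phantom
#'
#' Midsagittal plane (normal +x), inserted downward from the top of the
#' tissue; the rectangle spans the full fissure length so the front is the
#' single interior (bottom) edge.
#'
#' @param spec a [phantom_spec()].
#' @param depth_mm blade insertion depth (mm).
#' @param width_mm corridor width along the fissure (mm).
#' @return a [crack_geometry()].
#' @export
default_phantom_crack <- function(spec, depth_mm = 25, width_mm = 100) {
  ctr <- (spec$grid_shape * spec$voxel_size_mm) / 2
  top <- ctr[3] + spec$ellipsoid_semiaxes_mm[3]
  crack_geometry(origin_mm = c(ctr[1], ctr[2], top),
                 normal = c(1, 0, 0), dir_depth = c(0, 0, -1),
                 width_mm = width_mm, depth_mm = depth_mm)
}

#' Analytic ground-truth retraction field
#'
#' A closed-form displacement field standing in for the physical retraction:
#' `u(x) = sgn * d_side * max(0, 1 - |psi|/decay_radius) *
#' clamp(-phi/front_taper, 0, 1) * e_n`, where the side (and `d_side`) is
#' chosen by `sign(psi)` (tie toward `+`). The field is continuous everywhere
#' except across the crack plane over the cracked region, its magnitude is
#' bounded by `max(d_right, d_left)`, and it vanishes beyond `decay_radius`
#' of the plane. The jump across the plane equals
#' `(d_right + d_left) * clamp(-phi/front_taper, 0, 1)`.
#'
#' @param crack a [crack_geometry()].
#' @param d_right_mm,d_left_mm maximum retraction on the `+`/`-` side of the
#'   plane (mm); defaults 7.0 and 6.3.
#' @param decay_radius_mm support half-width normal to the plane (mm).
#' @param front_taper_mm ramp length of the opening above the front (mm).
#' @return a `ground_truth_field` object.
#' @export
analytic_retraction_field <- function(crack, d_right_mm = 7.0, d_left_mm = 6.3,
                                      decay_radius_mm = 35,
                                      front_taper_mm = 10) {
  stopifnot(inherits(crack, "crack_geometry"), decay_radius_mm > 0,
            front_taper_mm > 0, d_right_mm >= 0, d_left_mm >= 0)
  if (abs(sqrt(sum(crack$e_n^2)) - 1) > 1e-12) stop("non-unit crack normal")
  structure(list(crack = crack, d_right = d_right_mm, d_left = d_left_mm,
                 decay_radius = decay_radius_mm, front_taper = front_taper_mm),
            class = "ground_truth_field")
}

#' Evaluate a ground-truth retraction field
#'
#' @param field a [analytic_retraction_field()] result.
#' @param points n x 3 world points (mm).
#' @param side `"auto"` (side from `sign(psi)`, tie toward `+`), `"+"` or
#'   `"-"` to evaluate the one-sided continuous branch (used when inverting
#'   the map and when sampling exactly on the plane).
#' @return n x 3 matrix of displacements (mm).
#' @export
evaluate_field <- function(field, points, side = c("auto", "+", "-")) {
  side <- match.arg(side)
  p <- rbind3(points)
  ls <- level_sets(p, field$crack)
  sgn <- switch(side, auto = ifelse(ls$psi >= 0, 1, -1),
                "+" = rep(1, nrow(p)), "-" = rep(-1, nrow(p)))
  dmag <- ifelse(sgn > 0, field$d_right, field$d_left)
  taper_psi <- pmax(0, 1 - abs(ls$psi) / field$decay_radius)
  taper_f <- pmin(pmax(-ls$phi / field$front_taper, 0), 1)
  mag <- sgn * dmag * taper_psi * taper_f
  outer(mag, field$crack$e_n)
}

#' Apply a ground-truth field to a volume (synthetic post-retraction image)
#'
#' Renders the image after retraction: every material point's intensity
#' appears at its displaced location and voxels vacated inside the opened
#' crack receive `background_intensity`, so the synthetic "post" image shows
#' the visible gap. Implemented by exact per-side inversion of the analytic
#' map (side-consistent fixed point), which realises the forward push of
#' material without splat artifacts. Bead centers are displaced exactly by
#' field evaluation (never voxelised).
#'
#' @param pre pre-retraction `image_volume`.
#' @param field a `ground_truth_field`.
#' @param crack the same [crack_geometry()] the field was built on.
#' @param beads bead data.frame from [generate_phantom_volume()].
#' @param background_intensity fill for vacated (gap) voxels.
#' @param interp `"trilinear"` or `"nearest"` intensity pull.
#' @return list with `volume` (post-retraction `image_volume`) and `beads`
#'   (displaced centers, `space = "post-retraction"`).
#' @export
apply_field_to_volume <- function(pre, field, crack, beads,
                                  background_intensity = 0,
                                  interp = "trilinear") {
  stopifnot(inherits(pre, "image_volume"), inherits(field, "ground_truth_field"))
  x <- all_voxel_centers(pre)
  n <- nrow(x)
  src <- matrix(NA_real_, n, 3)
  found <- rep(FALSE, n)
  for (s in c("+", "-")) {
    Xs <- invert_field_side(field, x, s)
    ls <- level_sets(Xs, crack)
    active <- pmax(0, 1 - abs(ls$psi) / field$decay_radius) *
      pmin(pmax(-ls$phi / field$front_taper, 0), 1) > 0
    ok <- if (s == "+") (ls$psi >= 0 | !active) else (ls$psi < 0 | !active)
    take <- ok & !found
    src[take, ] <- Xs[take, , drop = FALSE]
    found <- found | ok
  }
  vals <- rep(background_intensity, n)
  vals[found] <- sample_volume(pre, src[found, , drop = FALSE], interp = interp,
                               outside = background_intensity)
  post <- image_volume(array(vals, dim(pre$data)), affine = pre$affine)

  beads_out <- beads
  if (nrow(beads) > 0) {
    ctrs <- as.matrix(beads[, c("x", "y", "z")])
    disp <- evaluate_field(field, ctrs, side = "auto")
    moved <- ctrs + disp
    idx <- world_to_voxel(pre, moved)
    d <- dim(pre$data)
    if (any(idx < -0.5) || any(sweep(idx, 2, d - 0.5) > 0))
      stop("field displaces beads outside the grid")
    beads_out$x <- moved[, 1]; beads_out$y <- moved[, 2]; beads_out$z <- moved[, 3]
  }
  attr(beads_out, "space") <- "post-retraction"
  list(volume = post, beads = beads_out)
}

# fixed-point inversion of x = X + u_side(X) for the analytic field
invert_field_side <- function(field, x, side, tol = 1e-6, maxit = 200) {
  X <- x
  for (it in seq_len(maxit)) {
    u <- evaluate_field(field, X, side = side)
    Xn <- x - u
    delta <- max(abs(Xn - X))
    X <- Xn
    if (delta < tol) break
  }
  X
}

#' Simulate probe-digitised retractor coordinates
#'
#' Returns the four blade corner coordinates (non-collinear, enough to
#' reconstruct the blade plane and pose), as a navigation probe would capture
#' before retraction. The blade is centred on the corridor mouth and inserted
#' along the corridor depth direction.
#'
#' @param crack a [crack_geometry()].
#' @param retractor a [retractor_model()].
#' @return 4 x 3 matrix of world points (mm), rows: mouth-left, mouth-right,
#'   tip-right, tip-left.
#' @export
simulate_probe_points <- function(crack, retractor) {
  stopifnot(inherits(crack, "crack_geometry"), inherits(retractor, "retractor_model"))
  if (retractor$width > crack$width)
    stop("retractor blade wider than the crack polygon")
  L <- min(retractor$length, crack$depth)
  w2 <- retractor$width / 2
  if (w2 <= 0 || L <= 0) stop("degenerate blade: corners would be collinear")
  o <- crack$origin
  rbind(o - w2 * crack$e_w,
        o + w2 * crack$e_w,
        o + w2 * crack$e_w + L * crack$e_d,
        o - w2 * crack$e_w + L * crack$e_d)
}

#' Simulate a laser-range-scanner acquisition of a surface cloud
#'
#' Random subsample with isotropic Gaussian noise, plus removal of one
#' contiguous angular patch (as seen from the cloud centroid in its principal
#' plane) to mimic partial obstruction of the laser.
#'
#' @param post_surface a [point_cloud()] of the deformed retractor surface.
#' @param keep_fraction probability of keeping each point (0 < f <= 1).
#' @param noise_sd_mm isotropic Gaussian noise sd per axis (mm).
#' @param occluded_patch_fraction fraction of remaining points removed as one
#'   contiguous angular patch (0 <= f < 1).
#' @param seed integer seed (reproducible).
#' @return a [point_cloud()].
#' @export
simulate_lrs_cloud <- function(post_surface, keep_fraction = 1,
                               noise_sd_mm = 0, occluded_patch_fraction = 0,
                               seed = 1L) {
  stopifnot(inherits(post_surface, "point_cloud"),
            keep_fraction > 0, keep_fraction <= 1,
            occluded_patch_fraction >= 0, occluded_patch_fraction < 1)
  set.seed(seed)
  p <- post_surface$points
  n <- nrow(p)
  keep <- if (keep_fraction < 1) stats::runif(n) < keep_fraction else rep(TRUE, n)
  idx <- which(keep)
  if (occluded_patch_fraction > 0 && length(idx) > 0) {
    q <- p[idx, , drop = FALSE]
    c0 <- colMeans(q)
    pc <- stats::prcomp(q, center = TRUE, rank. = 2)
    ang <- atan2(pc$x[, 2], pc$x[, 1])
    start <- stats::runif(1, -pi, pi)
    shifted <- (ang - start) %% (2 * pi)
    n_rm <- round(occluded_patch_fraction * length(idx))
    if (n_rm > 0) {
      rm_local <- order(shifted)[seq_len(n_rm)]
      idx <- idx[-rm_local]
    }
  }
  if (length(idx) == 0) stop("no points left after subsampling/occlusion")
  q <- p[idx, , drop = FALSE]
  if (noise_sd_mm > 0)
    q <- q + matrix(stats::rnorm(length(q), sd = noise_sd_mm), ncol = 3)
  point_cloud(q,
              normals = if (!is.null(post_surface$normals))
                post_surface$normals[idx, , drop = FALSE],
              face = if (!is.null(post_surface$face)) post_surface$face[idx])
}
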