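#' Build a uniform hexahedral mesh from a binary label volume
#'
#' One hexahedral element per block of `element_size_mm / voxel_size` voxels
#' whose in-mask occupancy (fraction of mask voxels in the block) reaches
#' `occupancy_threshold`. Shared nodes are deduplicated; node coordinates are
#' world mm. The element size must be an integer multiple of the voxel size
#' along each axis, which makes the mesh exactly uniform.
#'
#' @param label binary `image_volume` (tissue mask); its affine must be
#'   axis-aligned (diagonal rotation block).
#' @param element_size_mm scalar or length-3 element edge length (mm).
#' @param occupancy_threshold minimum in-mask fraction to keep an element
#'   (default 0.5).
#' @return a `hex_mesh`: `nodes` (n x 3 mm), `elems` (m x 8 node indices in
#'   VTK hexahedron order), `h` (length-3 element size), `origin` (world of
#'   lattice origin), `grid_dim` (element-grid dimensions), `elem_grid`
#'   (3-D array mapping element-grid cells to element row or 0),
#'   `node_ijk` (n x 3 0-based lattice coordinates).
#' @export
build_hex_mesh <- function(label, element_size_mm, occupancy_threshold = 0.5) {
  stopifnot(inherits(label, "image_volume"))
  mask <- label$data > 0.5
  if (!any(mask)) stop("empty mask: nothing to mesh")
  R <- label$affine[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-9)
    stop("label affine must be axis-aligned for uniform hexahedral meshing")
  vs <- diag(R)
  h <- if (length(element_size_mm) == 1) rep(element_size_mm, 3) else element_size_mm
  m <- h / vs
  if (any(abs(m - round(m)) > 1e-9) || any(round(m) < 1))
    stop("element size must be a positive integer multiple of the voxel size")
  m <- as.integer(round(m))
  d <- dim(mask)
  ng <- d %/% m                              # element-grid dims
  if (any(ng < 1)) stop("element size larger than the volume")
  crop <- mask[seq_len(ng[1] * m[1]), seq_len(ng[2] * m[2]), seq_len(ng[3] * m[3]),
               drop = FALSE]
  dim(crop) <- c(m[1], ng[1], m[2], ng[2], m[3], ng[3])
  crop <- aperm(crop, c(1, 3, 5, 2, 4, 6))
  occ <- colMeans(matrix(as.numeric(crop), prod(m), prod(ng)))
  keep <- which(occ >= occupancy_threshold)
  if (length(keep) == 0) stop("no element reaches the occupancy threshold")

  cell <- arrayInd(keep, ng) - 1L            # 0-based element cells
  # 8 corner offsets, VTK hexahedron order
  off <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  nlat <- ng + 1L
  lat_id <- function(ijk) ijk[, 1] + nlat[1] * (ijk[, 2] + nlat[2] * ijk[, 3])
  corner_ids <- matrix(0L, length(keep), 8)
  for (c8 in 1:8)
    corner_ids[, c8] <- lat_id(sweep(cell, 2, off[c8, ], `+`))
  used <- sort(unique(as.vector(corner_ids)))
  remap <- integer(max(used) + 1L)
  remap[used + 1L] <- seq_along(used)
  elems <- matrix(remap[corner_ids + 1L], ncol = 8)

  uijk <- cbind(used %% nlat[1],
                (used %/% nlat[1]) %% nlat[2],
                used %/% (nlat[1] * nlat[2]))
  origin <- drop(label$affine %*% c(0, 0, 0, 1))[1:3]  # corner of voxel (0,0,0)
  nodes <- sweep(uijk, 2, h, `*`)
  nodes <- sweep(nodes, 2, origin, `+`)

  elem_grid <- array(0L, ng)
  elem_grid[keep] <- seq_along(keep)
  structure(list(nodes = nodes, elems = elems, h = h, origin = origin,
                 grid_dim = ng, elem_grid = elem_grid,
                 node_ijk = uijk, occupancy = occ[keep]),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %d nodes, %d elements, element size %.3g x %.3g x %.3g mm\n",
              nrow(x$nodes), nrow(x$elems), x$h[1], x$h[2], x$h[3]))
  invisible(x)
}

# element-grid cell (0-based rows) containing each world point, or NA
point_to_cell <- function(mesh, points, tol = 1e-9) {
  p <- sweep(rbind3(points), 2, mesh$origin)
  t <- sweep(p, 2, mesh$h, `/`)
  ng <- mesh$grid_dim
  bad <- t[, 1] < -tol | t[, 1] > ng[1] + tol | t[, 2] < -tol |
    t[, 2] > ng[2] + tol | t[, 3] < -tol | t[, 3] > ng[3] + tol
  cell <- pmin(pmax(floor(t), 0), rep(ng - 1L, each = nrow(t)))
  cell[bad, ] <- NA_integer_
  cell
}

# element row index for world points (0 if cell empty, NA if out of grid)
point_to_element <- function(mesh, points) {
  cell <- point_to_cell(mesh, points)
  out <- rep(NA_integer_, nrow(cell))
  ok <- !is.na(cell[, 1])
  out[ok] <- mesh$elem_grid[cbind(cell[ok, 1] + 1L, cell[ok, 2] + 1L,
                                  cell[ok, 3] + 1L)]
  out
}

# convex polygon (k x 3 world points, unordered) of plane psi = 0 clipped to
# the axis-aligned box [lo, hi]; fewer than 3 points means no interior cut
clip_plane_box <- function(lo, hi, crack, tol = 1e-9) {
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  psi <- level_sets(corners, crack)$psi
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  verts <- corners[abs(psi) <= tol, , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (psi[a] * psi[b] < -tol^2) {
      t <- psi[a] / (psi[a] - psi[b])
      verts <- rbind(verts, corners[a, ] + t * (corners[b, ] - corners[a, ]))
    }
  }
  unique(round(verts, 12))
}

#' Classify mesh nodes into the XFEM enrichment sets
#'
#' An element is *completely cut* when the crack rectangle separates its 8
#' nodes into two nonempty `psi`-sign groups (the in-element plane patch lies
#' wholly inside the rectangle) and the crack front does not pass through it;
#' it is *partially cut* when the front passes through it. Nodes of
#' completely-cut elements form the Heaviside set `J`; nodes of
#' front-containing elements form the tip set `M`, which takes precedence on
#' overlap so `J` and `M` are disjoint. Nodes with `psi == 0` are assigned to
#' the `+` side.
#'
#' @param mesh a [build_hex_mesh()] result.
#' @param crack a [crack_geometry()].
#' @return an `enrichment_table`: `set_I` (all node indices), `set_J`,
#'   `set_M`, `elem_status` (0 uncut, 1 completely cut, 2 front element),
#'   `H_node` (per-node Heaviside sign), and the DOF layout (`jbase`,
#'   `mbase`, `n_dof`): 3 standard DOFs per node, +3 per `J` node, +12 per
#'   `M` node.
#' @export
classify_enrichment <- function(mesh, crack) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(crack, "crack_geometry"))
  n <- nrow(mesh$nodes)
  psi_n <- level_sets(mesh$nodes, crack)$psi
  H_node <- ifelse(psi_n >= 0, 1L, -1L)
  psi_e <- matrix(psi_n[mesh$elems], ncol = 8)
  straddle <- which(apply(psi_e < 0, 1, any) & apply(psi_e >= 0, 1, any))
  status <- integer(nrow(mesh$elems))
  w2 <- crack$width / 2
  tol <- 1e-9
  for (e in straddle) {
    nd <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    lo <- apply(nd, 2, min); hi <- apply(nd, 2, max)
    poly <- clip_plane_box(lo, hi, crack)
    if (nrow(poly) < 3) next
    ls <- level_sets(poly, crack)
    in_width <- min(ls$s) >= -w2 - tol && max(ls$s) <= w2 + tol
    if (min(ls$phi) < -tol && max(ls$phi) > tol) {
      # plane patch straddles the front; check the front segment crosses it
      s_at_front <- front_crossing_s(poly, ls)
      if (!is.null(s_at_front) &&
          max(s_at_front) >= -w2 - tol && min(s_at_front) <= w2 + tol)
        status[e] <- 2L
      else if (max(ls$phi) <= tol && in_width)
        status[e] <- 1L
    } else if (max(ls$phi) <= tol && in_width) {
      status[e] <- 1L
    }
  }
  set_J <- sort(unique(as.vector(mesh$elems[status == 1L, ])))
  set_M <- sort(unique(as.vector(mesh$elems[status == 2L, ])))
  set_J <- setdiff(set_J, set_M)            # tip enrichment takes precedence
  if (length(set_J) == 0 && length(set_M) == 0)
    warning("crack does not cut any mesh element: empty enrichment sets")

  jbase <- rep(NA_integer_, n); mbase <- rep(NA_integer_, n)
  if (length(set_J)) jbase[set_J] <- 3L * n + 3L * (seq_along(set_J) - 1L)
  if (length(set_M)) mbase[set_M] <- 3L * n + 3L * length(set_J) +
      12L * (seq_along(set_M) - 1L)
  structure(list(set_I = seq_len(n), set_J = set_J, set_M = set_M,
                 elem_status = status, H_node = H_node,
                 jbase = jbase, mbase = mbase,
                 n_dof = 3L * n + 3L * length(set_J) + 12L * length(set_M)),
            class = "enrichment_table")
}

# s-interval where the plane patch crosses phi = 0 (ordered convex polygon)
front_crossing_s <- function(poly, ls) {
  u <- cbind(ls$phi, ls$s)
  ctr <- colMeans(u)
  ord <- order(atan2(u[, 2] - ctr[2], u[, 1] - ctr[1]))
  u <- u[ord, , drop = FALSE]
  k <- nrow(u)
  out <- numeric(0)
  for (i in seq_len(k)) {
    a <- u[i, ]; b <- u[if (i == k) 1 else i + 1, ]
    if ((a[1] <= 0 && b[1] >= 0) || (a[1] >= 0 && b[1] <= 0)) {
      if (abs(b[1] - a[1]) < 1e-14) out <- c(out, a[2], b[2])
      else out <- c(out, a[2] + (0 - a[1]) / (b[1] - a[1]) * (b[2] - a[2]))
    }
  }
  if (length(out) == 0) NULL else out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d nodes, |J| = %d (Heaviside), |M| = %d (tip), %d DOFs\n",
              length(x$set_I), length(x$set_J), length(x$set_M), x$n_dof))
  invisible(x)
}
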