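#' Planar crack (retraction corridor) geometry
#'
#' The retraction-induced discontinuity is modelled as a planar rectangle.
#' `origin_mm` is the midpoint of the *mouth* edge (where the corridor meets
#' the exposed surface), `normal` the unit plane normal `e_n`, and
#' `dir_depth` the in-plane unit direction of blade insertion `e_d`. The
#' rectangle spans `width_mm` along `e_w = e_n x e_d` (centred on the mouth
#' midpoint) and `depth_mm` along `e_d`; the *front* (crack tip line) is the
#' interior edge at depth `depth_mm`.
#'
#' @param origin_mm world position of the mouth-edge midpoint (mm).
#' @param normal plane normal (normalised internally; must be non-zero and,
#'   after normalisation, unit to 1e-12).
#' @param dir_depth insertion direction; its component along `normal` is
#'   removed and the remainder normalised.
#' @param width_mm,depth_mm rectangle extent (mm), both positive.
#' @return A `crack_geometry` object with orthonormal frame `e_n`, `e_d`,
#'   `e_w`.
#' @export
crack_geometry <- function(origin_mm, normal, dir_depth, width_mm, depth_mm) {
  stopifnot(length(origin_mm) == 3L, length(normal) == 3L,
            length(dir_depth) == 3L, width_mm > 0, depth_mm > 0)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("crack normal must be non-zero")
  e_n <- normal / nn
  if (abs(sqrt(sum(e_n^2)) - 1) > 1e-12) stop("crack normal failed to normalise")
  d <- dir_depth - sum(dir_depth * e_n) * e_n
  dn <- sqrt(sum(d^2))
  if (dn < 1e-9) stop("dir_depth is parallel to the crack normal")
  e_d <- d / dn
  e_w <- c(e_n[2] * e_d[3] - e_n[3] * e_d[2],
           e_n[3] * e_d[1] - e_n[1] * e_d[3],
           e_n[1] * e_d[2] - e_n[2] * e_d[1])
  structure(list(origin = as.numeric(origin_mm), e_n = e_n, e_d = e_d,
                 e_w = e_w, width = width_mm, depth = depth_mm),
            class = "crack_geometry")
}

#' @export
print.crack_geometry <- function(x, ...) {
  cat(sprintf("crack_geometry: mouth at (%.1f, %.1f, %.1f) mm, width %.1f mm, depth %.1f mm\n",
              x$origin[1], x$origin[2], x$origin[3], x$width, x$depth))
  cat(sprintf("  e_n = (%.3f, %.3f, %.3f)\n", x$e_n[1], x$e_n[2], x$e_n[3]))
  invisible(x)
}

#' Crack level sets
#'
#' For each point returns the pair of signed distances that locate it relative
#' to the crack: `psi`, the signed distance to the crack plane (positive on
#' the `e_n` side), and `phi`, the signed in-plane distance to the crack front
#' line (negative over the cracked region between mouth and front, zero on the
#' front, positive beyond it). `s` is the in-plane width coordinate (0 on the
#' mouth midline); the point is on the crack iff `psi == 0`, `phi <= 0` and
#' `abs(s) <= width/2`.
#'
#' @param points n x 3 matrix (or length-3 vector) of world points (mm).
#' @param crack a [crack_geometry()].
#' @return list with numeric vectors `psi`, `phi`, `s`.
#' @export
level_sets <- function(points, crack) {
  p <- rbind3(points)
  dx <- sweep(p, 2, crack$origin)
  list(psi = drop(dx %*% crack$e_n),
       phi = drop(dx %*% crack$e_d) - crack$depth,
       s   = drop(dx %*% crack$e_w))
}

#' Heaviside (generalised step) enrichment function
#'
#' `+1` where `(x - x*) . e_n >= 0` with `x*` the closest point on the crack,
#' `-1` otherwise. Because `x* - proj(x)` is in-plane, the sign equals
#' `sign(psi)`; the tie at `psi == 0` is broken toward the `e_n` side (`+1`).
#'
#' @param x n x 3 matrix (or length-3 vector) of world points.
#' @param crack a [crack_geometry()].
#' @return integer vector of `+1`/`-1`.
#' @export
heaviside <- function(x, crack) {
  psi <- level_sets(x, crack)$psi
  ifelse(psi >= 0, 1L, -1L)
}

#' Corner points of the crack rectangle
#' @param crack a [crack_geometry()].
#' @return 4 x 3 matrix: mouth-left, mouth-right, front-right, front-left.
#' @keywords internal
crack_corners <- function(crack) {
  o <- crack$origin; w2 <- crack$width / 2
  rbind(o - w2 * crack$e_w,
        o + w2 * crack$e_w,
        o + w2 * crack$e_w + crack$depth * crack$e_d,
        o - w2 * crack$e_w + crack$depth * crack$e_d)
}
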