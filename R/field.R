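#' Evaluate the enriched displacement field at world points
#'
#' Computes `u(x) = sum_i N_i u_i + sum_j N_j (H(x) - H_j) a_j +
#' sum_m N_m sum_l (F_l(x) - F_l(x_m)) c_m^l` — the same shifted-enrichment
#' convention used in assembly — so the field is discontinuous across the
#' crack and continuous elsewhere, and interpolates `u_i` at the nodes.
#'
#' @param sol an [solve_system()] `xfem_solution`.
#' @param mesh,enrichment,crack the discretisation the solution was computed
#'   on.
#' @param points n x 3 world points (mm).
#' @param side `"auto"` (side decided by `sign(psi)`, tie toward `+`), or
#'   `"+"`/`"-"` to evaluate the one-sided smooth branch (needed exactly on
#'   the crack and when inverting the deformation map).
#' @param outside `"error"` or `"zero"`: behaviour for points not inside any
#'   mesh element.
#' @return n x 3 matrix of displacements (mm).
#' @export
displacement_field <- function(sol, mesh, enrichment, crack, points,
                               side = c("auto", "+", "-"),
                               outside = c("error", "zero")) {
  side <- match.arg(side)
  outside <- match.arg(outside)
  p <- rbind3(points)
  el <- point_to_element(mesh, p)
  bad <- is.na(el) | el == 0L
  if (any(bad) && outside == "error")
    stop(sum(bad), " point(s) outside the mesh")
  out <- matrix(0, nrow(p), 3)
  ok <- which(!bad)
  if (!length(ok)) return(out)
  el <- el[ok]
  q <- p[ok, , drop = FALSE]
  nodes <- mesh$elems[el, , drop = FALSE]
  p0 <- mesh$nodes[nodes[, 1], , drop = FALSE]
  loc <- 2 * (sweep(q, 2, mesh$h, `/`) - sweep(p0, 2, mesh$h, `/`)) - 1
  loc <- pmin(pmax(loc, -1), 1)
  N <- shape_N(loc)
  acc <- matrix(0, length(ok), 3)
  for (v in 1:8)
    acc <- acc + N[, v] * sol$u[nodes[, v], , drop = FALSE]

  enr <- enrichment
  has_J <- length(enr$set_J) > 0
  has_M <- length(enr$set_M) > 0
  if (has_J || has_M) {
    jset <- !is.na(enr$jbase); mset <- !is.na(enr$mbase)
    touched <- rep(FALSE, length(ok))
    for (v in 1:8) touched <- touched | jset[nodes[, v]] | mset[nodes[, v]]
    ti <- which(touched)
    if (length(ti)) {
      qt <- q[ti, , drop = FALSE]
      Hgp <- if (side == "auto") heaviside(qt, crack)
             else rep(if (side == "+") 1L else -1L, length(ti))
      Fgp <- if (has_M) tip_values_at(qt, crack, side) else NULL
      jrow <- integer(nrow(sol$u))
      if (has_J) jrow[enr$set_J] <- seq_along(enr$set_J)
      mrow <- integer(nrow(sol$u))
      if (has_M) mrow[enr$set_M] <- seq_along(enr$set_M)
      for (v in 1:8) {
        nv <- nodes[ti, v]
        jn <- which(jset[nv])
        if (length(jn) && !is.null(sol$aJ)) {
          fac <- N[ti[jn], v] * (Hgp[jn] - enr$H_node[nv[jn]])
          acc[ti[jn], ] <- acc[ti[jn], ] + fac * sol$aJ[jrow[nv[jn]], , drop = FALSE]
        }
        mn <- which(mset[nv])
        if (length(mn) && !is.null(sol$cM)) {
          Fnode <- tip_values_at(mesh$nodes[nv[mn], , drop = FALSE], crack)
          for (l in 1:4) {
            fac <- N[ti[mn], v] * (Fgp[mn, l] - Fnode[, l])
            cm <- matrix(sol$cM[mrow[nv[mn]], l, ], ncol = 3)
            acc[ti[mn], ] <- acc[ti[mn], ] + fac * cm
          }
        }
      }
    }
  }
  out[ok, ] <- acc
  out
}

#' Displacement at a single point (convenience wrapper)
#'
#' @inheritParams displacement_field
#' @param x length-3 world point (mm).
#' @param side_hint `"auto"`, `"+"` or `"-"` (needed when `psi(x) = 0`).
#' @return length-3 displacement (mm); errors if `x` is outside the mesh.
#' @export
displacement_at <- function(sol, mesh, enrichment, crack, x,
                            side_hint = "auto") {
  drop(displacement_field(sol, mesh, enrichment, crack, matrix(x, 1),
                          side = side_hint, outside = "error"))
}
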