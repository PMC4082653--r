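# Independent conforming-FEM oracle: trilinear hexahedra assembled node by
# node with an explicitly duplicated node sheet along a crack plane, solved
# densely. Written against the textbook formulas, separate from the package's
# enriched assembly, so it can serve as the reference for face-coincident
# cracks.

oracle_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(matrix(0, 3, 3)) | lower.tri(matrix(0, 3, 3))] <- lam
  D
}

# element stiffness for an axis-aligned hexahedron with edge lengths h
oracle_ke <- function(E, nu, h) {
  D <- oracle_D(E, nu)
  gp <- 1 / sqrt(3)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  # corner order must match the package's VTK convention
  signs <- signs[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  Ke <- matrix(0, 24, 24)
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    B <- matrix(0, 6, 24)
    for (v in 1:8) {
      s <- signs[v, ]
      dN <- c(s[1] * (1 + s[2] * gy) * (1 + s[3] * gz) / 8 * 2 / h[1],
              (1 + s[1] * gx) * s[2] * (1 + s[3] * gz) / 8 * 2 / h[2],
              (1 + s[1] * gx) * (1 + s[2] * gy) * s[3] / 8 * 2 / h[3])
      c0 <- 3 * (v - 1)
      B[1, c0 + 1] <- dN[1]; B[2, c0 + 2] <- dN[2]; B[3, c0 + 3] <- dN[3]
      B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
      B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
      B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
    }
    Ke <- Ke + prod(h) / 8 * t(B) %*% D %*% B
  }
  Ke
}

# Conforming FEM on a uniform bar of nel = c(nx, ny, nz) elements with edge h,
# with a duplicated node sheet at x = crack_x (element interface): elements
# left of the plane keep the original sheet nodes, elements right of it use
# the duplicates. `fixed` is a data.frame(node, ux, uy, uz) in the returned
# node numbering. Returns nodes and displacements.
oracle_fem_bar <- function(nel, h, E, nu, crack_x = NULL, fixed_fun) {
  nl <- nel + 1L
  lat <- as.matrix(expand.grid(x = 0:nel[1], y = 0:nel[2], z = 0:nel[3]))
  nodes <- lat * h
  nid <- function(i, j, k) 1L + i + nl[1] * (j + nl[2] * k)
  dup_map <- integer(nrow(nodes))          # 0 = no duplicate
  if (!is.null(crack_x)) {
    sheet <- which(abs(nodes[, 1] - crack_x) < 1e-9)
    dup_map[sheet] <- nrow(nodes) + seq_along(sheet)
    nodes <- rbind(nodes, nodes[sheet, , drop = FALSE])
  }
  elems <- list()
  for (k in 0:(nel[3] - 1)) for (j in 0:(nel[2] - 1)) for (i in 0:(nel[1] - 1)) {
    corners <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                 nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                 nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
    if (!is.null(crack_x) && (i + 0.5) * h > crack_x / 1) {
      # element right of the plane: swap sheet nodes for their duplicates
      on_sheet <- dup_map[corners] > 0
      corners[on_sheet] <- dup_map[corners[on_sheet]]
    }
    elems[[length(elems) + 1L]] <- corners
  }
  elems <- do.call(rbind, elems)
  n <- nrow(nodes)
  K <- matrix(0, 3 * n, 3 * n)
  Ke <- oracle_ke(E, nu, rep(h, 3))
  for (e in seq_len(nrow(elems))) {
    dof <- as.vector(rbind(3 * (elems[e, ] - 1) + 1, 3 * (elems[e, ] - 1) + 2,
                           3 * (elems[e, ] - 1) + 3))
    K[dof, dof] <- K[dof, dof] + Ke
  }
  fx <- fixed_fun(nodes)
  fdof <- as.vector(rbind(3 * (fx$node - 1) + 1, 3 * (fx$node - 1) + 2,
                          3 * (fx$node - 1) + 3))
  fval <- as.vector(rbind(fx$ux, fx$uy, fx$uz))
  free <- setdiff(seq_len(3 * n), fdof)
  u <- numeric(3 * n)
  u[fdof] <- fval
  u[free] <- solve(K[free, free], -K[free, fdof] %*% fval)
  list(nodes = nodes, u = matrix(u, ncol = 3, byrow = TRUE),
       dup_map = dup_map)
}

# naive double-loop directed mean-of-minima Hausdorff
brute_mhd <- function(A, B, directed = "mean") {
  h <- function(P, Q) {
    mins <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q)))
        best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
      mins[i] <- best
    }
    if (directed == "mean") mean(mins) else max(mins)
  }
  max(h(A, B), h(B, A))
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

rigid_T <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4); T[1:3, 1:3] <- R; T[1:3, 4] <- t
  T
}
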