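#' Bead forecast error
#'
#' Euclidean distance (mm) between corresponding bead positions in the
#' model-updated and post-retraction spaces.
#'
#' @param c_model,c_post n x 3 matrices (or length-3 vectors) of bead
#'   coordinates (mm), matched row-by-row; if both carry an `id` column in a
#'   data.frame they are paired by id and mismatches are an error.
#' @return numeric vector of distances (mm).
#' @export
forecast_error <- function(c_model, c_post) {
  m <- bead_coords(c_model); p <- bead_coords(c_post)
  check_pairing(c_model, c_post)
  sqrt(rowSums((m - p)^2))
}

#' Bead correction accuracy (%)
#'
#' The motion-recapture reading: `(1 - ||c_model - c_post|| /
#' ||c_post - c_pre||) * 100`, i.e. 100% when the model lands the bead on its
#' true post-retraction position and 0% when it leaves it at the
#' pre-retraction position. Beads with zero true motion are excluded
#' (returned as `NA`) and reported via a message rather than crashing.
#' `printed_form = TRUE` evaluates the variant with `||c_model - c_pre||` in
#' the numerator (the modelled fraction of motion), provided for fidelity
#' studies.
#'
#' @param c_pre,c_model,c_post bead coordinates as in [forecast_error()].
#' @param printed_form use the alternative numerator (default FALSE).
#' @return numeric vector of accuracies (%), `NA` where excluded.
#' @export
correction_accuracy <- function(c_pre, c_model, c_post, printed_form = FALSE) {
  pre <- bead_coords(c_pre); m <- bead_coords(c_model); p <- bead_coords(c_post)
  check_pairing(c_pre, c_post); check_pairing(c_model, c_post)
  den <- sqrt(rowSums((p - pre)^2))
  num <- if (printed_form) sqrt(rowSums((m - pre)^2))
         else sqrt(rowSums((m - p)^2))
  out <- ifelse(den > 0, (1 - num / den) * 100, NA_real_)
  if (any(den == 0))
    message(sum(den == 0), " bead(s) with zero true motion excluded from accuracy")
  out
}

bead_coords <- function(x) {
  if (is.data.frame(x)) as.matrix(x[, c("x", "y", "z")]) else rbind3(x)
}

check_pairing <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b) && "id" %in% names(a) &&
      "id" %in% names(b)) {
    if (!identical(a$id, b$id)) stop("bead id pairing mismatch")
  }
  n1 <- if (is.data.frame(a)) nrow(a) else nrow(rbind3(a))
  n2 <- if (is.data.frame(b)) nrow(b) else nrow(rbind3(b))
  if (n1 != n2) stop("bead sets have different sizes")
  invisible(TRUE)
}

#' Modified Hausdorff distance between two point sets
#'
#' `H(A, B) = max(h(A, B), h(B, A))` where the directed distance `h(A, B)`
#' is, in the modified (Dubuisson-Jain) form used by default, the *mean* over
#' `a` in `A` of the minimum distance to `B`; `directed = "max"` gives the
#' classical Hausdorff maximum-of-minima instead.
#'
#' @param A,B nonempty point sets (n x d matrices, any common dimension).
#' @param directed `"mean"` (modified, default) or `"max"` (classical).
#' @return distance in the units of the inputs (mm for image edges).
#' @export
modified_hausdorff <- function(A, B, directed = c("mean", "max")) {
  directed <- match.arg(directed)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty point set in Hausdorff distance")
  f <- if (directed == "mean") mean else max
  h <- function(P, Q) {
    d <- numeric(nrow(P))
    chunk <- 2048L
    q2 <- rowSums(Q^2)
    for (s in seq(1, nrow(P), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(P))
      Pb <- P[s:e, , drop = FALSE]
      D2 <- outer(rowSums(Pb^2), q2, `+`) - 2 * Pb %*% t(Q)
      d[s:e] <- sqrt(pmax(apply(D2, 1, min), 0))
    }
    f(d)
  }
  max(h(A, B), h(B, A))
}

#' Canny edge extraction from one image slice
#'
#' Standard Canny (Gaussian smoothing, Sobel gradients, non-maximum
#' suppression, hysteresis linking) on an axis-aligned slice; returns edge
#' pixel coordinates in mm in the slice plane. A blank (uniform) slice yields
#' an empty set.
#'
#' @param image an `image_volume`.
#' @param axis slice axis (1, 2 or 3).
#' @param index 1-based slice index along `axis`.
#' @param sigma Gaussian smoothing in pixels (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum gradient
#'   magnitude (defaults 0.1 and 0.2).
#' @return k x 2 matrix of edge coordinates (mm) in the two in-plane axes.
#' @export
canny_edge_points <- function(image, axis = 3, index, sigma = 1.0,
                              low = 0.1, high = 0.2) {
  stopifnot(inherits(image, "image_volume"), axis %in% 1:3)
  d <- dim(image$data)
  if (index < 1 || index > d[axis]) stop("slice index out of bounds")
  sl <- switch(axis,
               image$data[index, , ],
               image$data[, index, ],
               image$data[, , index])
  sl <- matrix(sl, nrow = dim(sl)[1])
  if (max(sl) - min(sl) <= 0) return(matrix(numeric(0), 0, 2))
  sm <- if (sigma > 0) as.matrix(EBImage::gblur(sl, sigma = sigma)) else sl
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/drow
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(sm, kx))
  gy <- as.matrix(EBImage::filter2(sm, ky))
  g <- sqrt(gx^2 + gy^2)
  gmax <- max(g)
  if (gmax <= 0) return(matrix(numeric(0), 0, 2))
  # quantise direction into 4 bins and suppress non-maxima
  ang <- atan2(gy, gx)
  bin <- (round(ang / (pi / 4)) %% 4)        # 0: row, 1: diag, 2: col, 3: anti-diag
  nr <- nrow(g); nc <- ncol(g)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  offs <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
  nms <- matrix(FALSE, nr, nc)
  for (b in 0:3) {
    o <- offs[[as.character(b)]]
    keep <- bin == b & g >= shift(g, o[1], o[2]) & g >= shift(g, -o[1], -o[2])
    nms <- nms | keep
  }
  strong <- nms & g >= high * gmax
  weak <- nms & g >= low * gmax
  if (!any(strong)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::bwlabel(weak)
  keep_ids <- setdiff(unique(lab[strong]), 0)
  edge <- weak & matrix(lab %in% keep_ids, nr, nc)
  idx <- which(edge, arr.ind = TRUE)
  vs <- voxel_size(image)
  inplane <- setdiff(1:3, axis)
  org <- drop(image$affine %*% c(0, 0, 0, 1))[1:3]
  cbind(org[inplane[1]] + (idx[, 1] - 0.5) * vs[inplane[1]],
        org[inplane[2]] + (idx[, 2] - 0.5) * vs[inplane[2]])
}

#' Localise beads in a voxelised volume
#'
#' Intensity-weighted centroids of connected high-intensity components
#' (26-connectivity), for evaluating bead positions from images rather than
#' stored truth tables.
#'
#' @param image an `image_volume`.
#' @param threshold voxels above this intensity are bead candidates.
#' @param min_voxels minimum component size (default 1).
#' @return data.frame `x, y, z` (mm), one row per detected bead.
#' @export
localize_beads <- function(image, threshold, min_voxels = 1L) {
  stopifnot(inherits(image, "image_volume"))
  idx <- which(image$data > threshold)
  if (!length(idx)) return(data.frame(x = numeric(), y = numeric(), z = numeric()))
  co <- arrayInd(idx, dim(image$data))
  # single-linkage clustering with 26-connectivity on the sparse voxel set
  n <- nrow(co)
  lab <- integer(n)
  cur <- 0L
  key <- paste(co[, 1], co[, 2], co[, 3])
  lookup <- stats::setNames(seq_len(n), key)
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- as.matrix(expand.grid(co[v, 1] + (-1:1), co[v, 2] + (-1:1),
                                  co[v, 3] + (-1:1)))
      hit <- lookup[paste(nb[, 1], nb[, 2], nb[, 3])]
      hit <- hit[!is.na(hit)]
      new <- hit[lab[hit] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  w <- image$data[idx]
  out <- do.call(rbind, lapply(seq_len(cur), function(k) {
    rows <- lab == k
    if (sum(rows) < min_voxels) return(NULL)
    ctr <- colSums(voxel_to_world(image, co[rows, , drop = FALSE] - 1) *
                     w[rows]) / sum(w[rows])
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3])
  }))
  if (is.null(out)) data.frame(x = numeric(), y = numeric(), z = numeric())
  else out
}

#' Bead-based evaluation report
#'
#' Per-bead forecast error and correction accuracy plus summary statistics.
#'
#' @param pre_beads,model_beads,post_beads bead data.frames (`id, x, y, z`),
#'   paired by id.
#' @param printed_form see [correction_accuracy()].
#' @return list with `per_bead` (data.frame) and `summary`.
#' @export
evaluate_beads <- function(pre_beads, model_beads, post_beads,
                           printed_form = FALSE) {
  fe <- forecast_error(model_beads, post_beads)
  acc <- suppressMessages(
    correction_accuracy(pre_beads, model_beads, post_beads,
                        printed_form = printed_form))
  per <- data.frame(id = pre_beads$id, region = pre_beads$region,
                    forecast_error_mm = fe, correction_accuracy_pct = acc)
  list(per_bead = per,
       summary = list(
         mean_forecast_error_mm = mean(fe),
         min_forecast_error_mm = min(fe),
         max_forecast_error_mm = max(fe),
         mean_correction_accuracy_pct = mean(acc, na.rm = TRUE),
         min_correction_accuracy_pct = suppressWarnings(min(acc, na.rm = TRUE)),
         max_correction_accuracy_pct = suppressWarnings(max(acc, na.rm = TRUE)),
         n_beads = length(fe),
         n_excluded_zero_motion = sum(is.na(acc))))
}

#' Slice-wise modified Hausdorff evaluation on Canny edges
#'
#' For each requested slice, extracts Canny edges from the pre-retraction,
#' model-updated and post-retraction volumes and reports the modified
#' Hausdorff distance of pre-vs-post and model-vs-post edge sets.
#'
#' @param pre,model,post `image_volume`s in a common space.
#' @param axis slice axis (default 3, axial).
#' @param indices 1-based slice indices.
#' @param sigma,low,high Canny parameters (see [canny_edge_points()]).
#' @return data.frame `slice, mhd_pre_post_mm, mhd_model_post_mm` (slices
#'   with an empty edge set are dropped with a warning).
#' @export
evaluate_slices <- function(pre, model, post, axis = 3, indices,
                            sigma = 1.0, low = 0.1, high = 0.2) {
  rows <- lapply(indices, function(i) {
    ep <- canny_edge_points(pre, axis, i, sigma, low, high)
    em <- canny_edge_points(model, axis, i, sigma, low, high)
    eo <- canny_edge_points(post, axis, i, sigma, low, high)
    if (nrow(ep) == 0 || nrow(em) == 0 || nrow(eo) == 0) {
      warning("slice ", i, " has an empty edge set; skipped")
      return(NULL)
    }
    data.frame(slice = i,
               mhd_pre_post_mm = modified_hausdorff(ep, eo),
               mhd_model_post_mm = modified_hausdorff(em, eo))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
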