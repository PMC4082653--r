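#' Point cloud container
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param normals optional n x 3 matrix of unit normals.
#' @param face optional per-point label (e.g. which blade face a template
#'   point samples: `+1` / `-1`).
#' @return a `point_cloud` object.
#' @export
point_cloud <- function(points, normals = NULL, face = NULL) {
  points <- rbind3(points)
  if (!is.null(normals)) {
    normals <- rbind3(normals)
    stopifnot(nrow(normals) == nrow(points))
  }
  if (!is.null(face)) stopifnot(length(face) == nrow(points))
  structure(list(points = points, normals = normals, face = face),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (!is.null(x$normals)) " (with normals)" else ""))
  invisible(x)
}

#' Read / write point clouds
#'
#' CSV columns `x,y,z[,nx,ny,nz]`; PLY is ASCII with
#' `x y z [nx ny nz]` vertex properties. All coordinates in mm.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [point_cloud()].
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- as.data.frame(cloud$points)
  names(df) <- c("x", "y", "z")
  if (!is.null(cloud$normals)) {
    nd <- as.data.frame(cloud$normals)
    names(nd) <- c("nx", "ny", "nz")
    df <- cbind(df, nd)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  normals <- if (all(c("nx", "ny", "nz") %in% names(df)))
    as.matrix(df[, c("nx", "ny", "nz")])
  point_cloud(as.matrix(df[, c("x", "y", "z")]), normals = normals)
}

#' @rdname write_cloud_csv
#' @export
write_cloud_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  has_n <- !is.null(cloud$normals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               if (has_n) c("property float nx", "property float ny",
                            "property float nz"),
               "end_header"), con)
  m <- if (has_n) cbind(cloud$points, cloud$normals) else cloud$points
  utils::write.table(format(m, scientific = FALSE, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ascii PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  props <- sub("^property float ", "", grep("^property float ", lines, value = TRUE))
  body <- lines[(end + 1):(end + nv)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nv, byrow = TRUE)
  colnames(m) <- props
  normals <- if (all(c("nx", "ny", "nz") %in% props)) m[, c("nx", "ny", "nz")]
  point_cloud(m[, c("x", "y", "z")], normals = normals)
}

#' Least-squares plane fit
#'
#' @param points n x 3 matrix, n >= 3.
#' @return list with unit `normal` (sign chosen so the first component group
#'   is positive-leaning) and `point` (centroid).
#' @export
fit_plane <- function(points) {
  p <- rbind3(points)
  if (nrow(p) < 3) stop("need at least 3 points to fit a plane")
  c0 <- colMeans(p)
  sv <- svd(sweep(p, 2, c0))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) stop("points are collinear")
  n <- sv$v[, 3]
  list(normal = n / sqrt(sum(n^2)), point = c0)
}
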