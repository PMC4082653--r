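#' Export a hexahedral mesh (with optional data) to ASCII VTU
#'
#' Minimal VTK XML unstructured-grid writer (hexahedron cells), readable by
#' ParaView/meshio.
#'
#' @param mesh a [build_hex_mesh()] result.
#' @param path output `.vtu` file.
#' @param point_data named list of per-node vectors or n x 3 matrices.
#' @param cell_data named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w('          %s', num(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w('          %s', num(t(mesh$elems) - 1L))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w('          %s', num(8L * seq_len(m)))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w('          %s', num(rep(12L, m)))
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, nc)
      w('          %s', num(if (is.matrix(v)) t(v) else v))
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      w('          %s', num(cell_data[[nm]]))
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read / write crack geometry as YAML
#' @param crack a [crack_geometry()].
#' @param path YAML file.
#' @return `write_crack_yaml` returns `path` invisibly; `read_crack_yaml` a
#'   [crack_geometry()].
#' @export
write_crack_yaml <- function(crack, path) {
  yaml::write_yaml(list(origin_mm = as.numeric(crack$origin),
                        normal = as.numeric(crack$e_n),
                        dir_depth = as.numeric(crack$e_d),
                        width_mm = crack$width, depth_mm = crack$depth), path)
  invisible(path)
}

#' @rdname write_crack_yaml
#' @export
read_crack_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  crack_geometry(y$origin_mm, y$normal, y$dir_depth, y$width_mm, y$depth_mm)
}

# manifest with checksums for a set of files in a directory
write_manifest <- function(dir, files, path = file.path(dir, "manifest.json")) {
  full <- file.path(dir, files)
  ok <- file.exists(full)
  man <- list(files = lapply(which(ok), function(i) {
    list(name = files[i], bytes = file.size(full[i]),
         md5 = unname(tools::md5sum(full[i])))
  }))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
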