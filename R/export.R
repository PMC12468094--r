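# Mesh / field / point-cloud exchange formats (text only): Gmsh 2.2 ASCII,
# VTK XML unstructured grids, whitespace point clouds.

#' Write a mesh in Gmsh 2.2 ASCII format
#'
#' Volume elements are 10-node tetrahedra (Gmsh type 11); anterior and
#' posterior surfaces are exported as 6-node triangles (type 9) with named
#' physical groups `anterior`, `posterior`; the limbal ring as 1-node
#' points is omitted (node ids are stable, see `mesh$limbus_nodes`).
#'
#' @param mesh a `corneal_mesh`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", "3",
               '2 1 "anterior"', '2 2 "posterior"', '3 3 "cornea"',
               "$EndPhysicalNames"), con)
  n <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(n)), con)
  writeLines(sprintf("%d %.9g %.9g %.9g", seq_len(n), mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  # VTK -> Gmsh tet10: swap the last two mid nodes
  tg <- mesh$tets[, c(1:8, 10, 9), drop = FALSE]
  fa <- mesh$anterior_faces
  fp <- mesh$pressure_faces
  nel <- nrow(tg) + NROW(fa) + NROW(fp)
  writeLines(c("$Elements", as.character(nel)), con)
  id <- 0L
  wr_tri <- function(f, tag) {
    if (is.null(f)) return(invisible())
    writeLines(sprintf("%d 9 2 %d %d %d %d %d %d %d %d",
                       id + seq_len(nrow(f)), tag, tag,
                       f[, 1], f[, 2], f[, 3], f[, 4], f[, 5], f[, 6]), con)
    id <<- id + nrow(f)
  }
  wr_tri(fa, 1L)
  wr_tri(fp, 2L)
  writeLines(sprintf("%d 11 2 3 3 %s", id + seq_len(nrow(tg)),
                     apply(tg, 1, paste, collapse = " ")), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write a mesh (with optional nodal fields) as a VTK XML unstructured grid
#'
#' @param mesh a `corneal_mesh`
#' @param path output file (.vtu)
#' @param point_data named list of per-node numeric vectors
#' @return invisibly, `path`
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(paste(format(point_data[[nm]], digits = 9), collapse = " "), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, function(r) paste(format(r, digits = 9),
                                                    collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 10L, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(24L, m), collapse = " "), con)  # quadratic tet
  w('        </DataArray>')
  w('      </Cells>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read/write 3-column whitespace point clouds
#'
#' @param pts n x 3 matrix
#' @param path file path
#' @return `write_points()`: invisibly `path`; `read_points()`: n x 3 matrix
#' @export
write_points <- function(pts, path) {
  write.table(format(as.matrix(pts), digits = 9), path, sep = " ",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) != 3) stop_cxl("point cloud must have 3 columns", "cxl_parse_error")
  dimnames(m) <- NULL
  m
}
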