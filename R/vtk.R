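#' Export a mesh with fields as a VTK unstructured grid
#'
#' Writes legacy ASCII VTK (`.vtk`) or ASCII XML (`.vtu`) with cell types
#' tet4 (10) or tet10 (24). Per-element scalars go to cell data, per-node
#' 3-vectors to point data.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path; format inferred from the extension unless given.
#' @param cell_data named list of per-element numeric vectors.
#' @param point_data named list of per-node vectors or `n x 3` matrices.
#' @param format `"legacy"` or `"xml"`, default from the extension.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list(),
                      format = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- format %||%
    switch(tolower(tools::file_ext(path)), vtk = "legacy", vtu = "xml",
           of_abort("cannot infer VTK format; use .vtk or .vtu"))
  for (nm in names(cell_data))
    if (length(cell_data[[nm]]) != nrow(mesh$elements))
      of_abort(sprintf("cell_data '%s' length mismatch", nm))
  if (format == "legacy") write_vtk_legacy(mesh, path, cell_data, point_data)
  else write_vtk_xml(mesh, path, cell_data, point_data)
  invisible(path)
}

vtk_cell_type <- function(mesh) if (ncol(mesh$elements) == 4L) 10L else 24L

write_vtk_legacy <- function(mesh, path, cell_data, point_data) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "osteoflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(mesh$nodes, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, m * (npe + 1L)), con)
  writeLines(apply(cbind(npe, mesh$elements - 1L), 1, paste, collapse = " "),
             con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(vtk_cell_type(mesh), m)), con)
  if (length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(v, 1, function(r) paste(sprintf("%.10g", r),
                                                 collapse = " ")), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
}

write_vtk_xml <- function(mesh, path, cell_data, point_data) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, function(r) paste(sprintf("%.17g", r),
                                                    collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elements - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * npe), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(vtk_cell_type(mesh), m)), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(cell_data) > 0) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  if (length(point_data) > 0) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, nc)
      if (is.matrix(v)) {
        writeLines(apply(v, 1, function(r) paste(sprintf("%.10g", r),
                                                 collapse = " ")), con)
      } else writeLines(sprintf("%.10g", v), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
}
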