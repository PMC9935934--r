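# File interchange: STL (ASCII and binary) for surfaces, VTU (ASCII XML)
# and Gmsh MSH v4.1 for volume meshes, CSV for element fields, YAML for the
# study configuration.

#' Write a surface mesh to STL
#'
#' @param surf A `surface_mesh`.
#' @param path Output file path.
#' @param binary Write binary STL (default ASCII).
#' @export
write_stl <- function(surf, path, binary = FALSE) {
  v <- surf$vertices
  tri <- surf$triangles
  e1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  e2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  n <- cbind(nx, ny, nz) / nn
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
    for (k in seq_len(nrow(tri))) {
      writeBin(as.numeric(c(n[k, ], t(v[tri[k, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", surf$part_label), con)
    for (k in seq_len(nrow(tri))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[tri[k, ], 1], v[tri[k, ], 2], v[tri[k, ], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", surf$part_label), con)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary) as a surface mesh
#'
#' Vertices are merged exactly by coordinate, so watertight solids written
#' by standard tools round-trip as watertight meshes.
#'
#' @param path STL file path.
#' @param part_label Label for the resulting surface.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path, part_label = "imported") {
  head5 <- readBin(path, "raw", 5)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    txt <- tryCatch(readLines(path, n = 2L, warn = FALSE), error = function(e) "")
    length(txt) >= 2 && grepl("facet|endsolid", txt[2])
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(NA_real_, 3 * ntri, 3)
    for (k in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      coords[(3 * k - 2):(3 * k), ] <- matrix(vals[4:12], 3, byrow = TRUE)
    }
  }
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- unique(key)
  idx <- match(key, uk)
  verts <- coords[match(uk, key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris, part_label = part_label)
}

#' Write a volume mesh (with optional fields) to VTU
#'
#' ASCII XML VTK unstructured grid with linear (type 10) or quadratic
#' (type 24) tetrahedra; per-element and per-node numeric fields are written
#' as cell/point data.
#'
#' @param mesh A `volume_mesh`.
#' @param path Output file path.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node numeric vectors.
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  npe <- ncol(mesh$tets)
  ctype <- if (npe == 10) 24L else 10L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * npe), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(ctype, m)), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(as.character(as.numeric(cell_data[[nm]])), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      vals <- point_data[[nm]]
      ncomp <- if (is.matrix(vals)) ncol(vals) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, ncomp)
      if (is.matrix(vals)) {
        writeLines(apply(vals, 1, paste, collapse = " "), con)
      } else writeLines(as.character(as.numeric(vals)), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a volume mesh to Gmsh MSH v4.1 (ASCII)
#'
#' @param mesh A `volume_mesh` (TET4 or TET10).
#' @param path Output file path.
#' @export
write_msh <- function(mesh, path) {
  npe <- ncol(mesh$tets)
  etype <- if (npe == 10) 11L else 4L
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$Nodes")
  w("1 %d 1 %d", n, n)
  w("3 1 0 %d", n)
  writeLines(as.character(seq_len(n)), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("$EndNodes")
  w("$Elements")
  w("1 %d 1 %d", m, m)
  w("3 1 %d %d", etype, m)
  writeLines(paste(seq_len(m), apply(mesh$tets, 1, paste, collapse = " ")), con)
  w("$EndElements")
  invisible(path)
}

#' Read / write a per-element Hounsfield-unit table
#'
#' CSV with columns `element_id`, `hu`.
#'
#' @param path CSV path.
#' @param hu Numeric HU vector (for writing).
#' @return `read_hu_csv`: numeric vector ordered by `element_id`.
#' @export
read_hu_csv <- function(path) {
  df <- utils::read.csv(path)
  check_that(all(c("element_id", "hu") %in% names(df)),
             "HU table must have columns element_id, hu")
  hu <- rep(NA_real_, max(df$element_id))
  hu[df$element_id] <- df$hu
  hu
}

#' @rdname read_hu_csv
#' @export
write_hu_csv <- function(hu, path) {
  utils::write.csv(data.frame(element_id = seq_along(hu), hu = hu), path,
                   row.names = FALSE)
  invisible(path)
}
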