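#' Triangle mesh
#'
#' Minimal indexed triangle mesh container used for the lofted lumen surface
#' and swept strut volumes. Vertices in mm; faces are 1-based vertex index
#' triples with outward-consistent winding.
#'
#' @param vertices (V x 3) numeric matrix.
#' @param faces (F x 3) integer matrix.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as_xyz_matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stopf("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stopf("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, area %.4f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_cross_products <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Total surface area of a mesh
#' @param mesh a `tri_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(row_norms(face_cross_products(mesh))) / 2
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a `tri_mesh` with outward-oriented faces.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  cr <- face_cross_products(mesh)
  sum(rowSums(a * cr)) / 6
}

#' Edge-manifold diagnostics for a triangle mesh
#'
#' @param mesh a `tri_mesh`.
#' @return list with `n_boundary_edges` (edges used by exactly one face),
#'   `n_nonmanifold_edges` (edges used by more than two faces), and
#'   `closed`/`manifold` logicals. A lofted tube is manifold with two open
#'   rings of boundary edges; a swept strut segment is closed.
#' @export
mesh_edge_info <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  list(n_boundary_edges = sum(tab == 1L),
       n_nonmanifold_edges = sum(tab > 2L),
       closed = all(tab == 2L),
       manifold = all(tab <= 2L))
}

# merge a list of tri_mesh into one (vertex blocks concatenated)
merge_meshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, function(m) nrow(m$faces) > 0L, logical(1L))]
  if (length(meshes) == 0L) return(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  off <- 0L
  vs <- vector("list", length(meshes))
  fs <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    vs[[i]] <- meshes[[i]]$vertices
    fs[[i]] <- meshes[[i]]$faces + off
    off <- off + nrow(meshes[[i]]$vertices)
  }
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Write a mesh as binary STL
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("octstent binary STL", width = 80, flag = "-"))
  writeBin(header[seq_len(80L)], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  cr <- face_cross_products(mesh)
  nrm <- cr / pmax(row_norms(cr), 1e-30)
  v <- mesh$vertices
  f <- mesh$faces
  # 12 floats per facet: normal + 3 vertices
  block <- t(cbind(nrm, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
                   v[f[, 3L], , drop = FALSE]))
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Write a mesh as binary little-endian PLY
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "little")
  f0 <- mesh$faces - 1L
  for (i in seq_len(nrow(f0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Write one or more meshes as a legacy VTK POLYDATA scene
#'
#' Meshes are appended into a single POLYDATA with a per-cell `block_id`
#' scalar identifying the source mesh (e.g. lumen = 1, stent = 2).
#' @param meshes a `tri_mesh` or list of them (optionally named).
#' @param path output file path.
#' @export
write_vtk_scene <- function(meshes, path) {
  if (inherits(meshes, "tri_mesh")) meshes <- list(meshes)
  merged <- merge_meshes(meshes)
  ids <- unlist(lapply(seq_along(meshes),
                       function(i) rep(i, nrow(meshes[[i]]$faces))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "octstent scene", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(merged$vertices))), con)
  utils::write.table(format(merged$vertices, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  nf <- nrow(merged$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  utils::write.table(cbind(3L, merged$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("CELL_DATA %d", nf), "SCALARS block_id int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(ids), con)
  invisible(path)
}
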