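# Plain-text exports: legacy-VTK mesh files for inspection and per-step CSV
# node-position dumps.

#' Export a mesh (optionally with nodal data) as legacy ASCII VTK
#'
#' Writes an unstructured grid of VTK quadratic hexahedra (cell type 25).
#'
#' @param mesh an `apdi_mesh`.
#' @param path output `.vtk` file.
#' @param u optional displacement vector (3N): written as a point-data vector
#'   field and added to the coordinates when `deformed = TRUE`.
#' @param deformed write deformed coordinates.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, u = NULL, deformed = FALSE) {
  nodes <- mesh$nodes
  if (!is.null(u)) {
    um <- matrix(u, ncol = 3, byrow = TRUE)
    if (deformed) nodes <- nodes + um
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("scleraAPDI mesh", nrow(mesh$conn), "hex20"),
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(nodes)), con)
  writeLines(apply(format(nodes, digits = 10, scientific = FALSE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  E <- nrow(mesh$conn)
  writeLines(sprintf("CELLS %d %d", E, E * 21L), con)
  writeLines(apply(cbind(20L, mesh$conn - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(rep("25", E), con)
  writeLines(sprintf("CELL_DATA %d", E), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region == "cornea")), con)
  if (!is.null(u)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    writeLines("VECTORS displacement double", con)
    writeLines(apply(format(matrix(u, ncol = 3, byrow = TRUE), digits = 10,
                            scientific = FALSE, trim = TRUE),
                     1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Export nodal positions of every load step as CSV
#'
#' One row per node and step: `node`, `step`, `x`, `y`, `z` (mm), mirroring a
#' per-step node-position dump. A header comment carries the provenance tag
#' when given.
#'
#' @param sol an `apdi_solution`.
#' @param path output CSV.
#' @param tag optional provenance string (e.g. a config hash) written as a
#'   `#` comment line.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(sol, path, tag = NULL) {
  K <- nrow(sol$steps) - 1L
  rows <- dplyr::bind_rows(lapply(0:K, function(k) {
    p <- node_positions(sol, k)
    tibble::tibble(node = seq_len(nrow(p)), step = k,
                   x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  if (!is.null(tag)) {
    writeLines(paste("#", tag), path)
    readr::write_csv(rows, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(rows, path)
  }
  invisible(path)
}
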