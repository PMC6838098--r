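# Plain-text interchange: Triangle-style .node/.ele mesh files, legacy
# ASCII VTK for visualization, CSV probe series, JSON run metadata.

#' Write a mesh as Triangle-style .node/.ele files
#'
#' `.node`: one attribute column (elevation, 0 when absent) and a boundary
#' marker. `.ele`: plain connectivity. Indices are 1-based.
#'
#' @param mesh a [tri_mesh()]
#' @param basename output path without extension
#' @return the basename, invisibly
#' @export
write_mesh_triangle <- function(mesh, basename) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  elev <- if (is.null(mesh$node_elevation)) rep(0, n) else mesh$node_elevation
  node_lines <- c(sprintf("%d 2 1 1", n),
                  sprintf("%d %.12g %.12g %.6g %d", seq_len(n),
                          mesh$nodes[, 1], mesh$nodes[, 2], elev,
                          as.integer(mesh$boundary)))
  writeLines(node_lines, paste0(basename, ".node"))
  ele_lines <- c(sprintf("%d 3 0", m),
                 sprintf("%d %d %d %d", seq_len(m), mesh$triangles[, 1],
                         mesh$triangles[, 2], mesh$triangles[, 3]))
  writeLines(ele_lines, paste0(basename, ".ele"))
  invisible(basename)
}

#' Read a mesh from Triangle-style .node/.ele files
#' @param basename path without extension
#' @return a [tri_mesh()]
#' @export
read_mesh_triangle <- function(basename) {
  nd <- utils::read.table(paste0(basename, ".node"), skip = 1)
  el <- utils::read.table(paste0(basename, ".ele"), skip = 1)
  hdr <- scan(paste0(basename, ".node"), n = 4, quiet = TRUE)
  has_attr <- hdr[3] >= 1
  mesh <- tri_mesh(as.matrix(nd[, 2:3]), as.matrix(el[, 2:4]),
                   node_elevation = if (has_attr) nd[, 4] else NULL)
  mesh
}

#' Write mesh and nodal fields as legacy ASCII VTK
#'
#' Unstructured grid of VTK cell type 5 (triangle) with optional scalar
#' point data, readable by ParaView.
#'
#' @param mesh a [tri_mesh()]
#' @param path output `.vtk` file
#' @param point_data named list of nodal vectors (`Inf` written as -1)
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "invadefem output", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      v[!is.finite(v)] <- -1
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default", sprintf("%.10g", v)), con)
    }
  }
  invisible(path)
}

#' Write probe time series as tidy CSV (time, probe, density)
#' @param result a [run_simulation()] result with probes
#' @param path output CSV
#' @export
write_probe_csv <- function(result, path) {
  if (is.null(result$probe_series)) stop("simulation has no probe series")
  df <- data.frame(
    time = rep(result$probe_times, ncol(result$probe_series)),
    probe = rep(colnames(result$probe_series),
                each = length(result$probe_times)),
    density = as.numeric(result$probe_series))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
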