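# Plain-text exporters: legacy VTK and PLY mesh snapshots, boundary
# polylines with curvature as CSV, observable traces as CSV, and a JSON
# run-metadata echo.

#' Write a mesh as a legacy-format VTK file
#'
#' ASCII legacy VTK unstructured grid with triangle cells and the material
#' tag as cell data.
#'
#' @param mesh a `trimesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk_legacy <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "morphosim mesh snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.17g %.17g 0", v[, 1], v[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                     tr[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tr)), con)
  writeLines(rep("5", nrow(tr)), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(tr)),
               "SCALARS region_tag int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$tags), con)
  invisible(path)
}

#' Write a mesh as an ASCII PLY file
#'
#' @param mesh a `trimesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g 0", v[, 1], v[, 2]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                     tr[, 3] - 1L), con)
  invisible(path)
}

#' Write boundary polylines with curvature as CSV
#'
#' One row per boundary vertex of every labeled chain: `x, y, label, part,
#' s, kappa`.
#'
#' @param mesh a `trimesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(mesh, path) {
  rows <- lapply(names(mesh$chains), function(lb) {
    cv <- boundary_curvature(mesh, lb)
    data.frame(x = cv$x, y = cv$y, label = lb, part = cv$part, s = cv$s,
               kappa = cv$kappa)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an observable trace as CSV
#'
#' @param trace the `trace` data.frame of a `sim_result` (columns `step`,
#'   `time`, `dt`, `vmax`, observables).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observables_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

# Read a closure trace CSV (columns time, value - or the first two columns).
read_closure_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(df)))
    df <- stats::setNames(df[, 1:2], c("time", "value"))
  df
}

#' Write all outputs of a preset run
#'
#' Observables CSV, boundary CSV (final state), VTK snapshots (numbered by
#' step) and a JSON metadata echo of the configuration and run summary.
#'
#' @param res a `sim_result` from [run_preset()].
#' @param out output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_run_outputs <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_observables_csv(res$trace, file.path(out, "observables.csv"))
  write_boundary_csv(res$mesh, file.path(out, "boundary_final.csv"))
  for (nm in names(res$snapshots))
    write_vtk_legacy(res$snapshots[[nm]],
                     file.path(out, sprintf("snapshot_%s.vtk", nm)))
  meta <- list(config = res$config, steps = res$steps,
               stopped_by = res$stopped_by,
               final_time = max(res$trace$time),
               n_vertices = nrow(res$mesh$vertices),
               n_triangles = nrow(res$mesh$triangles))
  jsonlite::write_json(meta, file.path(out, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}
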