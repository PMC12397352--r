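#' Write a structured-grid snapshot in legacy VTK format
#'
#' ASCII legacy VTK `STRUCTURED_POINTS` file with the cell-centred fields
#' sampled as point data (spacing equal to the grid spacing in
#' micrometres), suitable for standard viewers.
#'
#' @param fields named list of numeric arrays, all of dim
#'   `c(nx, ny, nz)`; 3-component velocity may be given as a list
#'   `list(u =, v =, w =)` under the name `velocity` (staggered components
#'   are averaged to cell centres).
#' @param grid a [grid_spec()].
#' @param path output `.vtk` path.
#' @param time time stamp (s), stored in the header comment.
#' @return the path, invisibly.
#' @export
write_snapshot_vtk <- function(fields, grid, path, time = NA_real_) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("mucosim snapshot t=%g s (lengths in um)", time),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
    sprintf("ORIGIN %g %g %g", m_to_um(grid$h) / 2, m_to_um(grid$h) / 2,
            m_to_um(grid$h) / 2),
    sprintf("SPACING %g %g %g", m_to_um(grid$h), m_to_um(grid$h),
            m_to_um(grid$h)),
    sprintf("POINT_DATA %d", nx * ny * nz)
  ), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {  # staggered velocity triple
      uc <- (f$u + shift_p(f$u, 1, -1)) / 2
      vc <- (f$v + shift_p(f$v, 2, -1)) / 2
      wc <- (f$w[, , 1:nz, drop = FALSE] +
               f$w[, , 2:(nz + 1), drop = FALSE]) / 2
      writeLines(sprintf("VECTORS %s double", nm), con)
      m <- cbind(as.vector(uc), as.vector(vc), as.vector(wc))
      writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
    } else {
      stopifnot(all(dim(f) == c(nx, ny, nz)))
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.vector(f), digits = 9, trim = TRUE,
                        scientific = TRUE), con)
    }
  }
  invisible(path)
}

#' Write a metrics time series as CSV
#'
#' @param series data.frame (e.g. `transport_result$series`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
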