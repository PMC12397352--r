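#' Uniform staggered grid specification
#'
#' A uniform Cartesian MAC grid over the reduced periodic strip
#' `[0, Lx') x [0, Ly') x [0, Lz]`: x' and y' periodic, z bounded by the
#' epithelial wall (z = 0) and the air-mucus interface (z = Lz). The spacing
#' is set by the vertical extent, `dx = Lz / nz`, and the horizontal extents
#' follow from the cell counts (`Lx' = nx * dx`), matching the convention of
#' the reference mesh family below.
#'
#' Reference meshes (total ASL depth 17 um = 7 um PCL + 10 um mucus):
#' `M1` 300x6x131, `M2` 400x8x175, `M3` 500x10x219, `M4` 600x12x262.
#'
#' @param nx,ny,nz cell counts along x', y', z.
#' @param Lz_um total ASL depth (um).
#' @param z_interface_um PCL depth (um), i.e. the PCL-mucus interface height.
#' @param preset optional name `"M1".."M4"` overriding the cell counts.
#' @return object of class `grid_spec` with spacing `h` (m), extents (m),
#'   and cell-centre / face coordinate vectors.
#' @export
grid_spec <- function(nx = 500, ny = 10, nz = 219, Lz_um = 17,
                      z_interface_um = 7, preset = NULL) {
  if (!is.null(preset)) {
    dims <- switch(preset,
      M1 = c(300, 6, 131), M2 = c(400, 8, 175),
      M3 = c(500, 10, 219), M4 = c(600, 12, 262),
      stop("unknown grid preset '", preset, "'"))
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  }
  stopifnot(nx >= 1, ny >= 1, nz >= 2, Lz_um > 0,
            z_interface_um > 0, z_interface_um < Lz_um)
  Lz <- um_to_m(Lz_um)
  h <- Lz / nz
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    h = h, Lx = nx * h, Ly = ny * h, Lz = Lz,
    z_interface = um_to_m(z_interface_um),
    xc = (seq_len(nx) - 0.5) * h,
    yc = (seq_len(ny) - 0.5) * h,
    zc = (seq_len(nz) - 0.5) * h,
    zf = (0:nz) * h
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d x %d cells, h = %.4g um, Lx' = %.3g um, Lz = %.3g um (interface %.3g um)\n",
    x$nx, x$ny, x$nz, m_to_um(x$h), m_to_um(x$Lx), m_to_um(x$Lz),
    m_to_um(x$z_interface)))
  invisible(x)
}

# mucus mask (cell centres above the PCL-mucus interface, excluding the top
# boundary cell where the elastic stress is pinned to zero)
grid_mucus_mask <- function(grid) {
  zc <- grid$zc
  in_mucus <- zc >= grid$z_interface & seq_along(zc) < grid$nz
  aperm(array(rep(in_mucus, each = grid$nx * grid$ny),
              dim = c(grid$nx, grid$ny, grid$nz)), c(1, 2, 3))
}

# periodic shift of an array along dim 1 or 2 by +1/-1 cells; z handled by
# the operators themselves through ghost rows
shift_p <- function(a, axis, by) {
  d <- dim(a)
  idx <- ((seq_len(d[axis]) - 1 + by) %% d[axis]) + 1
  if (axis == 1) a[idx, , , drop = FALSE]
  else if (axis == 2) a[, idx, , drop = FALSE]
  else a[, , idx, drop = FALSE]
}
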