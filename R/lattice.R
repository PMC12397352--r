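#' Cilia lattice on the reduced computational strip
#'
#' Arranges `n_cilia` cilia uniformly along the x' axis of the reduced
#' (counter-diagonal) computational domain. In the full square lattice the
#' one-phase shift between neighbouring rows makes every diagonal identical,
#' so a periodic strip containing each phase exactly once represents the
#' whole field; cilium `i` carries phase `(i-1)/n_cilia` and the phase
#' gradient opposes the effective-stroke direction (antiplectic metachrony).
#'
#' @param n_cilia number of cilia along x' (default 100, spanning one
#'   metachronal wavelength).
#' @param wavelength_um metachronal wavelength (um); the strip length
#'   defaults to it.
#' @param spacing_um cilium spacing (um); defaults to
#'   `wavelength_um / n_cilia`. Supplying it overrides the wavelength-derived
#'   strip length.
#' @param frequency_hz beat frequency (Hz).
#' @param length_um,diameter_um cilium length and diameter (um).
#' @param metachrony only `"antiplectic"` is implemented.
#' @param beat optional [beat_model()]; built from `length_um`/`frequency_hz`
#'   when omitted.
#' @return object of class `cilia_lattice` with per-cilium positions `x0`
#'   (m), phases in `[0, 1)`, and the geometry metadata.
#' @export
build_lattice <- function(n_cilia = 100, wavelength_um = 55,
                          spacing_um = NULL, frequency_hz = 15,
                          length_um = 5, diameter_um = 0.15,
                          metachrony = "antiplectic", beat = NULL) {
  stopifnot(n_cilia >= 1, wavelength_um > 0, length_um > 0, diameter_um > 0)
  metachrony <- match.arg(metachrony, "antiplectic")
  if (is.null(spacing_um)) spacing_um <- wavelength_um / n_cilia
  if (spacing_um <= 0) stop("cilium spacing must be positive")
  if (is.null(beat)) {
    beat <- beat_model(length_um = length_um, frequency_hz = frequency_hz)
  }
  i <- seq_len(n_cilia)
  structure(list(
    n = n_cilia,
    x0 = um_to_m((i - 0.5) * spacing_um),
    phase = (i - 1) / n_cilia,
    spacing = um_to_m(spacing_um),
    wavelength = um_to_m(wavelength_um),
    Lx = um_to_m(spacing_um * n_cilia),
    length = um_to_m(length_um),
    diameter = um_to_m(diameter_um),
    frequency = frequency_hz,
    metachrony = metachrony,
    beat = beat
  ), class = "cilia_lattice")
}

#' @export
print.cilia_lattice <- function(x, ...) {
  cat(sprintf(
    "<cilia_lattice> %d cilia, spacing %.3g um, wavelength %.3g um, %s\n",
    x$n, m_to_um(x$spacing), m_to_um(x$wavelength), x$metachrony))
  invisible(x)
}

#' Lagrangian surface markers of one cilium
#'
#' Tiles the lateral surface of the bent cylinder of given diameter around a
#' centerline with a single one-cell-thick shell of markers: `N_ax` rings
#' along the arclength times `N_ang` markers around the circumference. Each
#' marker carries the element volume `dV = patch area x grid spacing`
#' (surface shell one Eulerian cell thick), so the shell volume totals
#' `pi * diameter * L * dx`.
#'
#' Marker counts default to the grid-matched resolution
#' `N_ax = round(L/dx)`, `N_ang = max(4, round(pi * diameter / dx))`, which
#' keeps the marker spacing near the fluid grid spacing.
#'
#' @param centerline function of `s` (vector in `[0,1]`) returning an
#'   `n x 3` matrix of centerline points (m), e.g. a closure over
#'   [beat_shape()].
#' @param length cilium length (m).
#' @param diameter cilium diameter (m).
#' @param dx Eulerian grid spacing (m).
#' @param N_ax,N_ang marker counts; derived from the grid when `NULL`.
#' @param velocity optional matching closure returning centerline
#'   velocities; marker velocity is taken as the centerline velocity at its
#'   ring (the cross-section radius is far below the grid spacing, so rigid
#'   spin of the section is neglected).
#' @return list with `X` (n x 3 positions), `U` (n x 3 velocities), `dV`
#'   (element volumes, m3), `N_ax`, `N_ang`, `s` (ring arclength fractions).
#' @export
mesh_cilium_surface <- function(centerline, length, diameter, dx,
                                N_ax = NULL, N_ang = NULL, velocity = NULL) {
  stopifnot(length > 0, diameter > 0, dx > 0)
  if (is.null(N_ax)) N_ax <- max(1L, round(length / dx))
  if (is.null(N_ang)) N_ang <- max(4L, round(pi * diameter / dx))
  stopifnot(N_ax >= 1, N_ang >= 1)
  ds_len <- length / N_ax
  if (max(ds_len, pi * diameter / N_ang) > 1.5 * dx) {
    warning("marker spacing exceeds 1.5 grid cells; the delta kernel will ",
            "be under-resolved")
  }
  s <- (seq_len(N_ax) - 0.5) / N_ax
  P <- centerline(s)
  # local frame: tangent from neighbouring rings; beat is planar (x-z), the
  # binormal is y'
  Pf <- centerline(pmin(1, s + 1e-4))
  Pb <- centerline(pmax(0, s - 1e-4))
  tx <- Pf[, 1] - Pb[, 1]; tz <- Pf[, 3] - Pb[, 3]
  tn <- sqrt(tx^2 + tz^2); tx <- tx / tn; tz <- tz / tn
  # in-plane normal
  nx <- tz; nz <- -tx
  a <- diameter / 2
  th <- 2 * pi * (seq_len(N_ang) - 0.5) / N_ang
  X <- matrix(0, N_ax * N_ang, 3)
  for (j in seq_len(N_ang)) {
    rows <- (j - 1) * N_ax + seq_len(N_ax)
    X[rows, 1] <- P[, 1] + a * cos(th[j]) * nx
    X[rows, 2] <- P[, 2] + a * sin(th[j])
    X[rows, 3] <- P[, 3] + a * cos(th[j]) * nz
  }
  U <- matrix(0, N_ax * N_ang, 3)
  if (!is.null(velocity)) {
    V <- velocity(s)
    for (j in seq_len(N_ang)) {
      rows <- (j - 1) * N_ax + seq_len(N_ax)
      U[rows, ] <- V
    }
  }
  dV <- rep(ds_len * (pi * diameter / N_ang) * dx, N_ax * N_ang)
  list(X = X, U = U, dV = dV, N_ax = N_ax, N_ang = N_ang,
       s = rep(s, N_ang))
}

#' Surface markers for every cilium of a lattice at a given time
#'
#' Evaluates the beat at each cilium's phase offset, meshes its surface and
#' translates it to the cilium base. Marker z is clamped to a small positive
#' offset so that base rings sit just above the epithelial wall.
#'
#' @param lattice a [build_lattice()].
#' @param t time (s); the beat phase of cilium `i` is
#'   `t * f + phase_i` (mod 1).
#' @param dx Eulerian grid spacing (m) that sets the marker resolution.
#' @param y0 y' position of the cilia row (m).
#' @return object of class `lagrangian_markers`: `X`, `U`, `dV`, `cilium`
#'   (id per marker), `N_ax`, `N_ang`.
#' @export
cilia_markers <- function(lattice, t, dx, y0 = 0) {
  stopifnot(inherits(lattice, "cilia_lattice"))
  beat <- lattice$beat
  Xs <- vector("list", lattice$n); Us <- Xs; dVs <- Xs
  N_ax <- NA; N_ang <- NA
  for (i in seq_len(lattice$n)) {
    ph <- (t * lattice$frequency + lattice$phase[i]) %% 1
    mk <- mesh_cilium_surface(
      centerline = function(s) beat_shape(beat, ph, s),
      length = lattice$length, diameter = lattice$diameter, dx = dx,
      velocity = function(s) beat_velocity(beat, ph, s)
    )
    mk$X[, 1] <- mk$X[, 1] + lattice$x0[i]
    mk$X[, 2] <- mk$X[, 2] + y0
    mk$X[, 3] <- pmax(mk$X[, 3], 1e-3 * dx)
    Xs[[i]] <- mk$X; Us[[i]] <- mk$U; dVs[[i]] <- mk$dV
    N_ax <- mk$N_ax; N_ang <- mk$N_ang
  }
  structure(list(
    X = do.call(rbind, Xs), U = do.call(rbind, Us),
    dV = unlist(dVs),
    cilium = rep(seq_len(lattice$n), each = N_ax * N_ang),
    N_ax = N_ax, N_ang = N_ang
  ), class = "lagrangian_markers")
}

#' @export
print.lagrangian_markers <- function(x, ...) {
  cat(sprintf("<lagrangian_markers> %d markers (%d x %d per cilium)\n",
              nrow(x$X), x$N_ax, x$N_ang))
  invisible(x)
}

#' Export markers as a CSV table
#'
#' Columnar text export: cilium id, marker index, position, velocity and
#' element volume, for external visualization.
#'
#' @param markers a [cilia_markers()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  df <- data.frame(
    cilium = markers$cilium,
    l = seq_along(markers$cilium),
    x = markers$X[, 1], y = markers$X[, 2], z = markers$X[, 3],
    ux = markers$U[, 1], uy = markers$U[, 2], uz = markers$U[, 3],
    dV = markers$dV
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
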