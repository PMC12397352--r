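#' Regularized Dirac delta kernel (3-point)
#'
#' One-dimensional regularized delta weight with 1.5-cell support, used in
#' tensor-product form for all Lagrangian-Eulerian transfer. The kernel is
#' continuous, nonnegative, and satisfies the discrete partition of unity
#' `sum_i phi(r - i) = 1` for every real offset `r`.
#'
#' @param r dimensionless offset (distance / grid spacing); vectorized.
#' @return kernel weight(s) in `[0, 2/3]`.
#' @export
#' @examples
#' ibm_phi(0)      # 2/3
#' ibm_phi(1.5)    # 0
ibm_phi <- function(r) {
  a <- abs(r)
  w <- a
  w[] <- 0
  inner <- a <= 0.5
  mid <- a > 0.5 & a <= 1.5
  w[inner] <- (1 + sqrt(pmax(0, 1 - 3 * a[inner]^2))) / 3
  w[mid] <- (5 - 3 * a[mid] - sqrt(pmax(0, 1 - 3 * (1 - a[mid])^2))) / 6
  w
}

# Stencil of a marker cloud against one grid axis.
#
# x       marker coordinates (m)
# x0      coordinate of grid node index 1 (m)
# h       spacing (m)
# n       number of nodes along the axis
# periodic  wrap indices (x', y' axes); otherwise indices may fall outside
#           1..n and the caller chooses a fold policy.
# Returns list(idx = n_markers x 4 integer, w = n_markers x 4 weights).
ibm_stencil_1d <- function(x, x0, h, n, periodic = TRUE) {
  s <- (x - x0) / h + 1          # fractional node index
  i0 <- floor(s - 1.5)
  offs <- matrix(rep(1:4, each = length(s)), ncol = 4)
  idx <- i0 + offs               # 4 candidate nodes
  w <- ibm_phi(s - idx)
  if (periodic) idx <- ((idx - 1) %% n) + 1
  list(idx = idx, w = w)
}

#' Build a tensor-product delta stencil for a marker cloud
#'
#' Precomputes the 4x4x4-point interpolation/spreading stencil of each
#' marker against a node lattice. The x' and y' axes wrap periodically; the
#' z axis is bounded. Out-of-range z legs are folded back across the wall
#' with a mirror policy: `"even"` reflection (conserving; used for
#' cell-centred scalars) or `"odd"` reflection (used for velocity
#' components, consistent with a no-slip wall).
#'
#' @param X n x 3 matrix of marker positions (m).
#' @param origin coordinates (m) of node (1,1,1) of the target lattice.
#' @param h grid spacing (m).
#' @param dims integer node counts `c(nx, ny, nz)`.
#' @param zfold `"even"`, `"odd"`, or `"error"` (markers must keep 1.5 cells
#'   clearance from the walls).
#' @param zstag `"center"` when z nodes sit at `origin[3] + (k-1/2)h`
#'   relative to the wall planes (cell-centred fields), `"face"` when node 1
#'   lies exactly on the bottom wall (z-face fields); controls the mirror
#'   images used by the fold.
#' @return object of class `ibm_stencil`: linear node indices (n x 64),
#'   weights (n x 64) and the grid metadata.
#' @export
ibm_stencil <- function(X, origin, h, dims, zfold = c("even", "odd", "error"),
                        zstag = c("center", "face")) {
  zfold <- match.arg(zfold)
  zstag <- match.arg(zstag)
  stopifnot(is.matrix(X), ncol(X) == 3)
  sx <- ibm_stencil_1d(X[, 1], origin[1], h, dims[1], periodic = TRUE)
  sy <- ibm_stencil_1d(X[, 2], origin[2], h, dims[2], periodic = TRUE)
  sz <- ibm_stencil_1d(X[, 3], origin[3], h, dims[3], periodic = FALSE)
  n <- nrow(X); nz <- dims[3]
  sgn_z <- matrix(1, n, 4)
  kz <- sz$idx
  low <- kz < 1; high <- kz > nz
  if (any(low | high)) {
    if (zfold == "error") {
      stop("marker delta stencil crosses the z boundary; markers must stay ",
           "1.5 cells clear of the walls for this field")
    }
    # mirror across the wall planes; image node index depends on whether the
    # lattice is cell-centred (walls between nodes 0|1 and nz|nz+1) or
    # face-centred (walls on nodes 1 and nz)
    if (zstag == "center") {
      kz[low] <- 1 - kz[low]
      kz[high] <- 2 * nz + 1 - kz[high]
    } else {
      kz[low] <- 2 - kz[low]
      kz[high] <- 2 * nz - kz[high]
    }
    if (zfold == "odd") sgn_z[low | high] <- -1
    kz[kz < 1] <- 1; kz[kz > nz] <- nz   # pathological: clamp
  }
  # assemble 64-point tensor product
  ex <- rep(1:4, times = 16); ey <- rep(rep(1:4, each = 4), times = 4)
  ez <- rep(1:4, each = 16)
  IX <- sx$idx[, ex, drop = FALSE]; WX <- sx$w[, ex, drop = FALSE]
  IY <- sy$idx[, ey, drop = FALSE]; WY <- sy$w[, ey, drop = FALSE]
  IZ <- kz[, ez, drop = FALSE];     WZ <- sz$w[, ez, drop = FALSE]
  SZ <- sgn_z[, ez, drop = FALSE]
  lin <- IX + (IY - 1L) * dims[1] + (IZ - 1L) * dims[1] * dims[2]
  W <- WX * WY * WZ * SZ
  structure(list(lin = lin, w = W, dims = dims, h = h, n_markers = n),
            class = "ibm_stencil")
}

#' Assemble the sparse transfer operator of a stencil
#'
#' Builds the `n_cells x n_markers` sparse weight matrix `W` of a stencil
#' (summing coincident legs, e.g. mirror-folded ones), from which
#' interpolation is `t(W) %*% field` and spreading is
#' `W %*% (Q * dV / h^3)`. Also stores the collective gain
#' `G = interp(spread(1))`, the response at each marker of a uniform unit
#' source, used to normalize iterated direct-forcing corrections.
#'
#' @param stencil an [ibm_stencil()].
#' @param dV per-marker element volumes (m3) frozen into the gain.
#' @return object of class `ibm_operator`.
#' @export
ibm_operator <- function(stencil, dV) {
  n <- stencil$n_markers
  Wt <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 64L),
    j = as.vector(stencil$lin),
    x = as.vector(stencil$w),
    dims = c(n, prod(stencil$dims)))
  amp <- dV / stencil$h^3
  G <- as.vector(Wt %*% Matrix::t(Wt) %*% amp)
  # degenerate markers (odd-folded legs cancelling at a wall) get no
  # normalization rather than a divergent one
  G <- ifelse(G < 0.05, 1, G)
  structure(list(Wt = Wt, dims = stencil$dims, h = stencil$h,
                 n_markers = n, dV = dV, G = G),
            class = "ibm_operator")
}

#' Interpolate a grid field to markers
#'
#' Tensor-product regularized-delta interpolation
#' `C_l = sum_ijk c_ijk * delta_d(x_ijk - X_l) * dx dy dz`; the cell-volume
#' factor cancels the `1/dx` normalizations so the operation reduces to a
#' weighted stencil sum. A constant field interpolates to itself exactly
#' (partition of unity) and linear fields to second order.
#'
#' @param field numeric array with `prod(dims)` elements.
#' @param stencil an [ibm_stencil()] or [ibm_operator()].
#' @return numeric vector, one value per marker.
#' @export
ibm_interpolate <- function(field, stencil) {
  if (inherits(stencil, "ibm_operator")) {
    return(as.vector(stencil$Wt %*% as.vector(field)))
  }
  stopifnot(inherits(stencil, "ibm_stencil"),
            length(field) == prod(stencil$dims))
  vals <- field[stencil$lin]
  dim(vals) <- dim(stencil$lin)
  rowSums(vals * stencil$w)
}

#' Spread marker sources to the grid
#'
#' Adjoint of [ibm_interpolate()]:
#' `q_ijk = sum_l Q_l * delta_d(x_ijk - X_l) * dV_l`, i.e. each marker
#' deposits `Q_l * dV_l / h^3` distributed over its stencil weights. The
#' discrete integral `sum(q) * h^3` equals `sum(Q_l * dV_l)` to round-off
#' whenever no stencil leg is folded with odd sign.
#'
#' @param Q per-marker source strengths.
#' @param dV per-marker element volumes (m3); scalar or vector.
#' @param stencil an [ibm_stencil()] or [ibm_operator()].
#' @return numeric array of dim `dims` holding the spread field.
#' @export
ibm_spread <- function(Q, dV, stencil) {
  if (inherits(stencil, "ibm_operator")) {
    q <- as.vector(Matrix::crossprod(stencil$Wt, Q * dV / stencil$h^3))
    return(array(q, dim = stencil$dims))
  }
  stopifnot(inherits(stencil, "ibm_stencil"))
  n <- stencil$n_markers
  amp <- Q * dV / stencil$h^3          # per-marker amplitude
  contrib <- stencil$w * amp           # n x 64 (recycles amp down columns)
  v <- as.vector(contrib)
  ix <- as.vector(stencil$lin)
  acc <- rowsum(v, group = ix)
  out <- numeric(prod(stencil$dims))
  out[as.integer(rownames(acc))] <- acc[, 1]
  array(out, dim = stencil$dims)
}
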