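# shared miniature fixtures and independent oracles

# damped-Newton root-finder for the steady simple-shear balance of a single
# Giesekus mode; independent of the time-marching implementation
steady_shear_oracle <- function(gdot, lam, eta, alp) {
  Fn <- function(v) {
    txx <- v[1]; tzz <- v[2]; txz <- v[3]
    c(txx + alp * lam / eta * (txx^2 + txz^2) - lam * 2 * gdot * txz,
      tzz + alp * lam / eta * (txz^2 + tzz^2),
      txz + alp * lam / eta * (txz * (txx + tzz)) - lam * gdot * tzz -
        eta * gdot)
  }
  v <- c(0, 0, eta * gdot / 2)
  for (i in 1:200) {
    f0 <- Fn(v)
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      vp <- v; vp[j] <- vp[j] + 1e-8
      J[, j] <- (Fn(vp) - f0) / 1e-8
    }
    dv <- solve(J, -f0)
    v <- v + dv
    if (max(abs(dv)) < 1e-14) break
  }
  c(xx = v[1], zz = v[2], xz = v[3])
}

# memoized coarse 16-cilium flow cycle shared by the heavy acceptance checks
local_flow_cache <- new.env(parent = emptyenv())
reduced_flow_cycle <- function() {
  if (is.null(local_flow_cache$fc)) {
    g <- grid_spec(nx = 16, ny = 4, nz = 16)
    lat <- build_lattice(n_cilia = 16, wavelength_um = 17)
    local_flow_cache$grid <- g
    local_flow_cache$lattice <- lat
    local_flow_cache$fc <- run_flow_cycle(lat, g, n_spinup = 1,
                                          n_snapshots = 16)
  }
  list(fc = local_flow_cache$fc, grid = local_flow_cache$grid,
       lattice = local_flow_cache$lattice)
}
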