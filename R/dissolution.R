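#' Drug pharmacokinetic specification
#'
#' Builds the property set of a dissolving inhaled drug: molar mass, bulk
#' density, aqueous solubility and diffusivity in the airway surface liquid
#' (taken equal to the aqueous diffusivity of the dissolved molecule, whose
#' effective radius is well below the mucus mesh size).
#'
#' Three bundled drugs span three decades of pulmonary solubility:
#' Rifampicin (`"RIF"`, low), Tiotropium bromide (`"TIO"`, high) and
#' Salbutamol sulfate (`"SAL"`, very high).
#'
#' @param name drug identifier; one of `"RIF"`, `"TIO"`, `"SAL"`, or any
#'   string when all numeric properties are supplied explicitly.
#' @param molar_mass_g_mol molar mass (g/mol).
#' @param density_g_cm3 particle bulk density (g/cm3).
#' @param solubility_mg_ml aqueous solubility C_s (mg/ml).
#' @param diffusivity_cm2_s diffusivity D_ASL of the dissolved drug (cm2/s).
#' @return an object of class `drug_spec` with SI fields `density` (kg/m3),
#'   `Cs` (kg/m3) and `D` (m2/s) alongside the quoted units.
#' @export
#' @examples
#' drug_spec("SAL")
drug_spec <- function(name = c("RIF", "TIO", "SAL"),
                      molar_mass_g_mol = NULL,
                      density_g_cm3 = NULL,
                      solubility_mg_ml = NULL,
                      diffusivity_cm2_s = NULL) {
  defaults <- list(
    RIF = list(molar_mass = 822.9, density = 1.32, Cs = 1.71,  D = 4.1e-6),
    TIO = list(molar_mass = 472.4, density = 1.5,  Cs = 37,    D = 5.15e-6),
    SAL = list(molar_mass = 576.7, density = 1.3,  Cs = 263,   D = 4.6e-6)
  )
  if (length(name) > 1) name <- name[[1]]
  base <- defaults[[name]]
  if (is.null(base)) {
    if (is.null(density_g_cm3) || is.null(solubility_mg_ml) ||
        is.null(diffusivity_cm2_s)) {
      stop("unknown drug '", name,
           "': supply density, solubility and diffusivity explicitly")
    }
    base <- list(molar_mass = molar_mass_g_mol %||% NA_real_,
                 density = NA_real_, Cs = NA_real_, D = NA_real_)
  }
  mm  <- molar_mass_g_mol  %||% base$molar_mass
  rho <- density_g_cm3     %||% base$density
  Cs  <- solubility_mg_ml  %||% base$Cs
  D   <- diffusivity_cm2_s %||% base$D
  stopifnot(rho > 0, Cs > 0, D > 0)
  structure(list(
    name = name,
    molar_mass_g_mol = mm,
    density_g_cm3 = rho,
    solubility_mg_ml = Cs,
    diffusivity_cm2_s = D,
    density = g_cm3_to_kg_m3(rho),
    Cs = mg_ml_to_kg_m3(Cs),
    D = cm2_s_to_m2_s(D)
  ), class = "drug_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s\n", x$name))
  cat(sprintf("  molar mass : %.1f g/mol\n", x$molar_mass_g_mol))
  cat(sprintf("  density    : %.2f g/cm3\n", x$density_g_cm3))
  cat(sprintf("  solubility : %g mg/ml\n", x$solubility_mg_ml))
  cat(sprintf("  D_ASL      : %g cm2/s\n", x$diffusivity_cm2_s))
  invisible(x)
}

#' Dissolving spherical particle state
#'
#' @param drug a [drug_spec()].
#' @param diameter_um initial particle diameter (micrometres); 5 um is the
#'   bundled default, large enough to deposit in the upper airway.
#' @return object of class `particle_state` with fields `r` (m), `mass` (kg),
#'   `dissolved` (kg), `m0` (kg) and `t` (s). Surface area is `4*pi*r^2` and
#'   the diffusion-layer thickness is the dynamic radius itself (valid below
#'   a 30 um radius).
#' @export
particle_state <- function(drug, diameter_um = 5) {
  stopifnot(inherits(drug, "drug_spec"), diameter_um > 0)
  r0 <- um_to_m(diameter_um) / 2
  m0 <- drug$density * (4 / 3) * pi * r0^3
  structure(list(drug = drug, r = r0, mass = m0, dissolved = 0,
                 m0 = m0, t = 0), class = "particle_state")
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("<particle_state> %s  t=%.4g s  r=%.3g um  dissolved=%.1f%%\n",
              x$drug$name, x$t, m_to_um(x$r), 100 * x$dissolved / x$m0))
  invisible(x)
}

#' Noyes-Whitney dissolution rate
#'
#' Mass-transfer rate of a dissolving sphere,
#' `dm/dt = -A * D * (Cs - Cb) / h` with surface area `A = 4*pi*r^2` and
#' diffusion-layer thickness `h = r`, so the particle loses mass at
#' `4*pi*r*D*(Cs - Cb)`.
#'
#' @param particle a [particle_state()].
#' @param Cb bulk concentration of already-dissolved drug (kg/m3) seen by the
#'   particle; dynamically updated in coupled runs.
#' @return `dm/dt` in kg/s (negative while the particle shrinks; zero once
#'   fully dissolved). A bulk concentration above saturation flips the sign
#'   (re-precipitation) and raises an out-of-model warning.
#' @export
dissolution_rate <- function(particle, Cb = 0) {
  stopifnot(inherits(particle, "particle_state"), Cb >= 0)
  drug <- particle$drug
  if (particle$r <= 0) return(0)
  if (Cb > drug$Cs) {
    warning("bulk concentration exceeds solubility; re-precipitation is ",
            "outside the model's intended regime")
  }
  -4 * pi * particle$r * drug$D * (drug$Cs - Cb)
}

#' Advance a dissolving particle over one time step
#'
#' Integrates the equivalent-radius form `dr/dt = -D*(Cs - Cb)/(rho*r)` of
#' the Noyes-Whitney law. The square-root singularity at `r -> 0` is handled
#' exactly: for constant `Cb` the radius obeys
#' `r(t)^2 = r(t0)^2 - 2*D*(Cs - Cb)*(t - t0)/rho`, which this step uses in
#' closed form, landing exactly on `r = 0` when the step would overshoot.
#'
#' @param particle a [particle_state()].
#' @param Cb bulk concentration (kg/m3), held constant over the step.
#' @param dt step length (s), `> 0`.
#' @return the updated `particle_state`; the `dissolved` ledger grows by the
#'   mass lost so that `mass + dissolved == m0` to round-off at all times.
#' @export
advance_particle <- function(particle, Cb = 0, dt) {
  stopifnot(dt > 0)
  drug <- particle$drug
  if (particle$r <= 0) {
    particle$t <- particle$t + dt
    return(particle)
  }
  k <- 2 * drug$D * (drug$Cs - Cb) / drug$density   # d(r^2)/dt magnitude
  r2 <- particle$r^2 - k * dt
  r_new <- if (r2 <= 0) 0 else sqrt(r2)
  if (r2 <= 0 && k > 0) {
    # exact landing time on r = 0 within this step
    particle$t_dissolved <- particle$t + particle$r^2 / k
  }
  m_new <- drug$density * (4 / 3) * pi * r_new^3
  particle$dissolved <- particle$dissolved + (particle$mass - m_new)
  particle$mass <- m_new
  particle$r <- r_new
  particle$t <- particle$t + dt
  particle
}

#' Closed-form dissolution at zero bulk concentration
#'
#' With `Cb = 0` the radius ODE integrates to
#' `r(t)^2 = r0^2 - 2*D*Cs*t/rho`, full dissolution at
#' `t_d = rho*r0^2 / (2*D*Cs)` and dissolved mass fraction
#' `1 - (1 - t/t_d)^(3/2)`.
#'
#' @param drug a [drug_spec()].
#' @param diameter_um initial diameter (um).
#' @param t times (s) at which to evaluate the dissolved fraction; may be
#'   omitted.
#' @return list with `t_d` (s) and, when `t` is given, `fraction` (0..1).
#' @export
dissolution_closed_form <- function(drug, diameter_um = 5, t = NULL) {
  r0 <- um_to_m(diameter_um) / 2
  t_d <- drug$density * r0^2 / (2 * drug$D * drug$Cs)
  out <- list(t_d = t_d)
  if (!is.null(t)) {
    frac <- ifelse(t >= t_d, 1, 1 - (1 - t / t_d)^(3 / 2))
    out$fraction <- frac
  }
  out
}

#' Simulate single-particle dissolution
#'
#' Time-marches [advance_particle()] either at `Cb = 0` or coupled to a 1D
#' absorbing transport column of the ASL (see [dissolve_in_column()]), and
#' returns the radius and dissolved-fraction curves plus the complete
#' dissolution time.
#'
#' @param drug a [drug_spec()] or drug name.
#' @param diameter_um initial diameter (um).
#' @param cb_mode `"zero"` (bulk concentration held at 0) or `"coupled"`
#'   (bulk concentration from a 1D diffusion column with absorbing base).
#' @param dt time step (s); default resolves the dissolution time into
#'   ~2000 steps.
#' @param ... passed to [dissolve_in_column()] for `cb_mode = "coupled"`.
#' @return a data.frame with columns `t`, `r_um`, `fraction`, plus attributes
#'   `t_d` (s, complete dissolution time) and `drug`.
#' @export
dissolve_particle <- function(drug, diameter_um = 5,
                              cb_mode = c("zero", "coupled"),
                              dt = NULL, ...) {
  if (is.character(drug)) drug <- drug_spec(drug)
  cb_mode <- match.arg(cb_mode)
  if (cb_mode == "coupled") {
    return(dissolve_in_column(drug, diameter_um = diameter_um, dt = dt, ...))
  }
  t_d0 <- dissolution_closed_form(drug, diameter_um)$t_d
  if (is.null(dt)) dt <- t_d0 / 2000
  p <- particle_state(drug, diameter_um)
  ts <- 0; rs <- p$r; fr <- 0
  while (p$r > 0) {
    p <- advance_particle(p, Cb = 0, dt = dt)
    ts <- c(ts, p$t); rs <- c(rs, p$r); fr <- c(fr, p$dissolved / p$m0)
  }
  out <- data.frame(t = ts, r_um = m_to_um(rs), fraction = fr)
  # exact landing: last step hit r = 0 in closed form
  attr(out, "t_d") <- t_d0
  attr(out, "drug") <- drug$name
  out
}

#' Dissolution coupled to a one-dimensional ASL transport column
#'
#' The dissolved-mass flow is spread uniformly over a top area
#' `A = deposition_area` (one particle per full cilia-lattice tile, default
#' `(55 um)^2`), enters a diffusion column of depth `Lz` as a top Neumann
#' flux, is absorbed at the epithelial base (`c = 0`), and the particle sees
#' the column's volume-averaged concentration as its bulk value `Cb`, which
#' retards dissolution relative to the `Cb = 0` closed form.
#'
#' @param drug a [drug_spec()].
#' @param diameter_um initial particle diameter (um).
#' @param Lz_um column depth (um); total ASL depth by default.
#' @param nz number of cells in the column.
#' @param deposition_area_um2 top area (um2) over which the dissolved flux is
#'   spread.
#' @param dt transport time step (s); defaults to the explicit diffusion
#'   stability limit with a 0.4 safety factor.
#' @param t_max hard stop (s).
#' @return data.frame with columns `t`, `r_um`, `fraction`, `Cb`; attributes
#'   `t_d` (complete dissolution time, s) and mass-budget diagnostics.
#' @export
dissolve_in_column <- function(drug, diameter_um = 5, Lz_um = 17, nz = 48,
                               deposition_area_um2 = 55^2, dt = NULL,
                               t_max = Inf) {
  stopifnot(inherits(drug, "drug_spec"), nz >= 4)
  Lz <- um_to_m(Lz_um)
  A <- deposition_area_um2 * 1e-12
  dz <- Lz / nz
  D <- drug$D
  if (is.null(dt)) dt <- 0.4 * dz^2 / (2 * D)
  p <- particle_state(drug, diameter_um)
  cvec <- numeric(nz)                     # cell-centred concentration
  dep <- 0                                # absorbed at base (kg)
  t_d <- NA_real_
  nrec <- 400
  t_d0 <- dissolution_closed_form(drug, diameter_um)$t_d
  rec_every <- max(1L, floor((2.5 * t_d0 / dt) / nrec))
  ts <- 0; rs <- p$r; fr <- 0; cb <- 0
  step <- 0L
  repeat {
    step <- step + 1L
    Cb <- mean(cvec)
    rate_before <- p$dissolved
    p <- advance_particle(p, Cb = Cb, dt = dt)
    md <- (p$dissolved - rate_before) / dt      # kg/s into solution
    flux_top <- md / A                          # kg/m2/s
    # diffusion column update (explicit), flux top, absorbing base
    ghost_top <- cvec[nz] + dz * flux_top / D
    ghost_bot <- -cvec[1]
    cp <- c(ghost_bot, cvec, ghost_top)
    lap <- (cp[3:(nz + 2)] - 2 * cp[2:(nz + 1)] + cp[1:nz]) / dz^2
    dep_flux <- D * 2 * cvec[1] / dz            # kg/m2/s out the base
    cvec <- cvec + dt * D * lap
    dep <- dep + dep_flux * A * dt
    if (is.na(t_d) && p$r <= 0) t_d <- p$t_dissolved %||% p$t
    if (step %% rec_every == 0L || p$r <= 0) {
      ts <- c(ts, p$t); rs <- c(rs, p$r)
      fr <- c(fr, p$dissolved / p$m0); cb <- c(cb, Cb)
    }
    if (!is.na(t_d) || p$t >= t_max) break
  }
  out <- data.frame(t = ts, r_um = m_to_um(rs), fraction = fr, Cb = cb)
  attr(out, "t_d") <- t_d
  attr(out, "drug") <- drug$name
  in_domain <- sum(cvec) * dz * A
  attr(out, "mass_budget_rel_err") <-
    abs(p$dissolved - dep - in_domain) / p$m0
  out
}

#' Top-boundary mass flux from a dissolution rate
#'
#' Converts the dissolved mass flow rate of the particle into the uniform
#' Neumann flux applied at the air-mucus interface,
#' `m''_d = (dm_dissolved/dt) / A_top`.
#'
#' @param rate_dissolved dissolved-mass flow rate (kg/s, `>= 0`).
#' @param top_area top surface area of the ASL tile (m2).
#' @return flux in kg/(m2 s).
#' @export
surface_flux <- function(rate_dissolved, top_area) {
  stopifnot(top_area > 0)
  rate_dissolved / top_area
}
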