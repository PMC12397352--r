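---
title: "Modelling inhaled-drug dissolution and transport in the airway surface liquid"
author: "mucosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inhaled-drug dissolution and transport in the airway surface liquid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical picture

The airway surface liquid (ASL) is a ~17 µm film coating the conducting
airways: a low-viscosity Newtonian periciliary layer (PCL, ~7 µm) in which
cilia beat, under a viscoelastic mucus blanket (~10 µm). Coordinated ciliary
beating drives mucus toward the pharynx (mucociliary clearance). An inhaled
drug particle that lands on the film dissolves, and the dissolved drug is
carried by the cilia-driven flow, diffuses through both layers, adsorbs onto
the cilia themselves, and is absorbed by the epithelium at the film base.
`mucosim` simulates this chain end to end for a single deposited particle
and reports where the drug ends up and how fast.

## Governing model

**Flow.** Both layers share density $\rho = 1000$ kg/m³ and Newtonian
viscosity $\mu_s = 10^{-3}$ Pa s. Incompressible momentum balance with an
extra elastic stress $\boldsymbol\tau$ (mucus only) and a body force
$\mathbf f$ representing the cilia:

$$\nabla\cdot\mathbf u = 0,\qquad
\partial_t \mathbf u + \mathbf u\cdot\nabla\mathbf u =
-\tfrac1\rho\nabla p + \nu_s\nabla^2\mathbf u +
\tfrac1\rho\nabla\cdot\boldsymbol\tau + \mathbf f.$$

The mucus stress is a five-mode Giesekus law,
$\boldsymbol\tau = \sum_a \boldsymbol\tau_a$ with

$$\boldsymbol\tau_a + \lambda_a \stackrel{\nabla}{\boldsymbol\tau_a}
+ \frac{\alpha_a\lambda_a}{\eta^p_a}\,
\boldsymbol\tau_a\!\cdot\!\boldsymbol\tau_a = 2\eta^p_a \mathbf D,$$

where $\stackrel{\nabla}{(\cdot)}$ is the upper-convected derivative and
$\mathbf D$ the rate of strain. The bundled mode set (relaxation times
0.0089–49.7 s, elastic viscosities 0.03–2.2 Pa s, mobilities 0.2–0.5) is a
published five-mode fit to cultured human bronchial epithelial mucus; the
stress is identically zero in the PCL and at the flat air–mucus interface,
which behaves as a free-slip, zero-penetration boundary. The epithelium is
a no-slip wall; the horizontal directions are periodic.

**Cilia.** Each cilium follows a prescribed planar beat (below) and is
represented by a single shell of Lagrangian surface markers, one Eulerian
cell thick, with element volumes $\Delta V_l = (\text{patch area})\times
\Delta x$. Marker velocities are imposed on the fluid by direct forcing:
velocities are interpolated to the markers with the 3-point regularized
delta kernel, the defect $(\mathbf U_l - \mathbf u^*)/\Delta t$ is spread
back, and the projection step restores incompressibility. The default
lattice is 100 cilia (length 5 µm, diameter 0.15 µm, 15 Hz) with a uniform
one-phase shift per cilium — an antiplectic metachronal wave spanning one
55 µm wavelength. The simulation domain is the reduced periodic strip that
contains every beat phase exactly once (the counter-diagonal of the square
lattice); this is what makes a 100×100-cilia field tractable.

**Dissolution.** A single spherical particle (diameter 5 µm) dissolves by
Noyes–Whitney kinetics,
$\mathrm dm/\mathrm dt = -A\,D\,(C_s - C_b)/h$, with $A = 4\pi r^2$ and a
diffusion layer as thick as the dynamic radius ($h = r$, valid below 30 µm).
This gives the radius law $\mathrm dr/\mathrm dt = -D(C_s-C_b)/(\rho_d r)$,
which for constant $C_b$ has the closed form
$r^2(t) = r_0^2 - 2D(C_s-C_b)t/\rho_d$ — used both as the in-step
integrator (so the radius lands *exactly* on zero, no square-root
stiffness) and as the verification oracle. Complete dissolution at zero
bulk concentration takes $t_d = \rho_d r_0^2/(2DC_s)$. Three bundled drugs
span the solubility range: Rifampicin (1.71 mg/ml), Tiotropium bromide
(37), Salbutamol sulfate (263), with aqueous diffusivities 4.1, 5.15 and
4.6 ×10⁻⁶ cm²/s (the dissolved molecules are far smaller than the mucus
mesh, so the mucus diffusivity is taken equal to the aqueous one).

**Transport.** Dissolved drug obeys
$\partial_t c + \mathbf u\cdot\nabla c = D\nabla^2 c + q$ with a uniform
dissolution influx $m''_d$ at the top (the dissolved mass rate divided by
the deposition area), a perfect-sink epithelium ($c = 0$) at the base, and
periodic sides. The field is advanced by an explicit three-substep
Runge–Kutta scheme ($\gamma = (8/15, 5/12, 3/4)$,
$\zeta = (0, -17/60, -5/12)$) with second-order central differences in
conservative form. Ciliary attachment enters as an iterated
immersed-boundary mass source: each substep the concentration is
interpolated to the markers, the marker value is driven toward
$(1-\kappa_{\mathrm{att}})\,C_l^*$ ($\kappa_{\mathrm{att}} = 1$ is the
maximal-attachment limit $C_l = 0$), and the source is re-spread over
$N_i = 4$ corrections.

## The synthetic beat model

The classical experimentally derived beat for rabbit tracheal cilia is
published as a truncated Fourier series; that coefficient table is not
redistributable here, so `mucosim` ships a **synthetic** beat
(`inst/extdata/beat_coefficients_synthetic.csv`,
`data-raw/make_beat_coefficients.R`) built to the same functional form and
the same qualitative kinematics:

* the centerline is defined by its tangent angle
  $\psi(s,\phi) = P_0(\phi) + P_1(\phi)\,s$, each $P_m$ a truncated Fourier
  series in the beat phase — so the reconstructed shape is exactly
  1-periodic, base-anchored, and *inextensible by construction* (the
  arclength equals the cilium length for any coefficients);
* a time-warped swing makes the straight effective stroke occupy roughly
  the first third of the cycle (reference states 1–4 of 13) with about
  three times the mean tip speed of the recovery stroke;
* the bend term is gated off during the effective stroke and curls the
  cilium backward toward the epithelium mid-recovery, never crossing the
  wall.

What this does **not** emulate: the measured beat's exact envelope and
harmonic content, out-of-plane motion, and cilium-to-cilium variability.
Quantities that depend only on beat topology, periodicity and
metachronal coordination (propulsion direction, cycle periodicity, trend
behaviour) are meaningful; exact clearance velocities for a specific
species are not claimed at reduced resolution.

## Numerical choices

* **Staggered grid, projection.** MAC staggering with cell-centred
  pressure, stress and concentration; uniform spacing $\Delta = L_z/n_z$.
  The pressure Poisson equation is solved exactly (to round-off) by FFT in
  the periodic directions and a tridiagonal solve in $z$, so the
  post-projection divergence is at round-off level — monitored against
  $10^{-8}\,U_{\mathrm{ref}}/\Delta$ every step.
* **Viscous terms Crank–Nicolson.** At micrometre spacings the explicit
  viscous limit ($\Delta^2/6\nu \sim 10^{-8}$ s) is unusable; the Newtonian
  diffusion is integrated semi-implicitly by the same FFT–tridiagonal
  machinery. The verified accuracy on the oscillating-wall (Stokes-layer)
  problem is ~0.3% at 300 steps/period.
* **Elastic stress explicit.** The Giesekus modes advance explicitly; the
  time step obeys the modal shear-wave CFL
  $\Delta t \le 0.4\,\Delta/\max_a\sqrt{\eta^p_a/(\rho\lambda_a)}$ (mode 1
  is the stiffest). Stress advection is second-order central; the stress is
  hard-masked to zero below the PCL–mucus interface and in the top cell.
* **Normalized direct forcing.** For markers whose shell volume is below a
  cell volume (always the case when the 0.15 µm cilium diameter is
  under-resolved), the raw iterated forcing contracts extremely slowly. The
  correction is therefore normalized by the *collective gain*
  $G_l = \big[\mathcal I\,\mathcal S\,\mathbf 1\big]_l$ (the marker response
  to a uniform unit source through the interpolate/spread pair), which makes
  one pass exact for uniform defects and keeps the iteration contractive;
  markers whose folded stencil degenerates at the wall are left
  unnormalized. The same normalization is applied to the attachment mass
  source, whose iteration then drives the marker concentration below 5% of
  its initial value within the default four corrections.
* **Ledgers close by construction of the operators.** Injected, in-domain,
  epithelial and attached masses are accumulated from the *same* discrete
  boundary fluxes and spread sources the update uses (with the RK3 weights),
  so the global budget closes to round-off (~10⁻¹⁴ relative) and is asserted
  at $10^{-8}$ per step. Central differencing can undershoot slightly;
  `min(c)` is monitored and reported, never clipped (clipping would break
  the budget).
* **Frozen-flow replay.** The drug does not feed back on the flow, so one
  converged beat cycle of velocity snapshots (default 16) is recorded and
  replayed periodically with linear interpolation in time; marker positions
  and their transfer operators are cached at binned beat phases (default
  32–96 bins). This is what makes multi-second Rifampicin episodes
  tractable.
* **Bulk concentration for dissolution.** $C_b$ is the volume-averaged
  concentration over the whole film (a configurable alternative would be
  the top cell layer); it is updated every transport step and fed to the
  particle ODE.

## Choices where the design was open

* **Lattice spacing vs wavelength.** A 0.4 µm spacing for 100 cilia and a
  55 µm metachronal wavelength cannot both fix the strip length. The
  wavelength is taken as primary (spacing = wavelength / count = 0.55 µm by
  default); both remain independently configurable.
* **Deposition area.** The single particle's dissolved mass is spread over
  the full cilia-lattice tile, $(55\ \mu m)^2$ by default, not over the
  reduced strip: this is the physical area one deposited particle serves,
  it keeps concentrations in the 0.05–0.5 mg/ml range, and it makes the
  coupled Rifampicin dissolution time come out at 6.22 s against the
  5.88 s free-bulk bound (the domain-averaged $C_b$ retards the last stages
  of dissolution by ~6%).
* **Attachment control.** The ciliary attachment ratio (CAR = attached
  mass / cumulative interpolated marker exposure) is an *output*; the
  mechanistic knob is the per-substep absorption fraction
  $\kappa_{\mathrm{att}}$. `calibrate_car()` bisects the knob to a target
  ratio. Reported runs always state both.
* **"Maximum deposition time".** Read as the time of peak instantaneous
  epithelial deposition *rate*; the cumulative fraction is monotone, so its
  literal maximum would merely duplicate the complete-deposition time.
* **Spin-up.** The flow starts from rest; reduced-scale runs use one to
  three beat cycles of spin-up before recording the replay cycle. The
  longest mucus relaxation time (49.7 s) means the slowest stress modes
  never fully equilibrate in any affordable run — this is a known
  limitation of every explicit start-up protocol at these parameters, and
  layer-averaged velocities are reported as cycle averages of the recorded
  cycle, not as equilibrium values.
* **Snapshot time of the dissolved-fraction triplet.** The dissolved
  percentages (1.3 / 29 / 100 for RIF / TIO / SAL) are evaluated at
  t = 0.05 s, the time consistent with the closed-form radius law.

## Problem sizes used by the test-suite and acceptance runs

The packaged checks run at deliberately reduced scale: the analytic
convection–diffusion benchmark at 128–512 cells; the Stokes-layer wall
problem at 72 cells over six decay lengths; single-cilium and 4-cilium
property fixtures on 16–24-cell strips; and the coupled trend runs on a
16-cilium strip, 16×4×16 cells over the full 17 µm depth (Δ ≈ 1.06 µm),
one spin-up cycle plus one recorded cycle, with transport episodes run to
99.9% mass accounting. The reference-mesh family (300×6×131 up to
600×12×262 with 39×4 to 77×7 markers per cilium) is fully supported by the
same code paths and is the intended configuration for production runs.

## Known limitations

* **Linearity and the attachment trends.** The transport equation, its
  boundary conditions and the proportional attachment source are all linear
  in concentration. Consequently the *fraction* of injected mass that ends
  on the epithelium versus on the cilia is independent of the injection
  schedule — and therefore essentially independent of solubility at fixed
  $\kappa_{\mathrm{att}}$ (only the diffusivities differentiate the drugs,
  by ~0.1 percentage point at reduced scale). Deposited-fraction orderings
  across drugs can only arise from a nonlinear or prescribed-ratio
  attachment protocol, which this package does not invent; it exposes
  $\kappa_{\mathrm{att}}$ and the achieved CAR instead. The strong,
  robust trend — deposition strictly decreasing in attachment strength —
  is reproduced and tested.
* Under-resolved cilium diameter at coarse grids (markers below one cell):
  handled by the normalized forcing, but local flow structure at the
  cilium scale is not resolved there.
* One-way couplings only: cilia are kinematically prescribed; drug does not
  alter rheology or flow; the interfaces are flat; gravity is neglected.
* The epithelium is a perfect sink; no cellular pharmacokinetics.
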