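# Generates inst/extdata/beat_coefficients_synthetic.csv — the frozen
# coefficient table of the synthetic parametric cilium beat.
#
# The beat is defined through the centerline tangent angle psi(s, phi)
# (radians, measured from the wall normal toward the stroke direction +x'),
#   psi(s, phi) = P0(phi) + P1(phi) * s
# with s the arclength fraction in [0, 1] and phi the beat phase in cycles.
# P0 is the whole-arm swing, P1 the recovery-stroke bend. Design features:
#   * a time-warped swing makes the forward (effective) stroke fast and the
#     return (recovery) stroke slow;
#   * the bend term is gated off during the effective stroke (straight arm)
#     and peaks mid-recovery (arm curled backward near the wall);
#   * everything is 1-periodic in phi and projected onto a truncated Fourier
#     series, which is what the package ships and evaluates.
# The tangent-angle construction keeps the arclength exactly equal to the
# cilium length for any coefficient values.

w_warp <- 0.95     # phase-warp strength; effective stroke ~ 1/3 of the cycle
c_warp <- 0.15     # phase of fastest sweep (centre of the effective stroke)
psi_m <- -0.25     # mean arm tilt (rad); slight backward lean
A_sw <- 1.05       # swing half-amplitude (rad): arm sweeps -74..+46 deg
B_bend <- 1.2      # recovery bend (rad per unit arclength fraction)
N_harm <- 8        # retained Fourier harmonics

u_warp <- function(phi) phi + (w_warp / (2 * pi)) *
  (sin(2 * pi * (phi - c_warp)) + sin(2 * pi * c_warp))
P0 <- function(phi) psi_m - A_sw * cos(2 * pi * u_warp(phi))
u_peak <- 0.70     # warped phase of maximum recovery bend
gate <- function(u) ((1 + cos(2 * pi * (u - u_peak))) / 2)^2
P1 <- function(phi) -B_bend * gate(u_warp(phi))

nphi <- 4096
phi <- (seq_len(nphi) - 1) / nphi
proj <- function(f) {
  v <- f(phi)
  a <- vapply(0:N_harm, function(n) {
    s <- if (n == 0) 1 else 2
    s * mean(v * cos(2 * pi * n * phi))
  }, numeric(1))
  b <- vapply(0:N_harm, function(n) {
    if (n == 0) 0 else 2 * mean(v * sin(2 * pi * n * phi))
  }, numeric(1))
  list(a = a, b = b)
}

f0 <- proj(P0)
f1 <- proj(P1)
tab <- rbind(
  data.frame(m = 0L, n = 0:N_harm, a = f0$a, b = f0$b),
  data.frame(m = 1L, n = 0:N_harm, a = f1$a, b = f1$b)
)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(format(tab, digits = 12, trim = TRUE),
          "inst/extdata/beat_coefficients_synthetic.csv",
          row.names = FALSE, quote = FALSE)
cat("wrote", nrow(tab), "coefficient rows\n")
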