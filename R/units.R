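#' Unit conversion helpers
#'
#' The solver works in SI units (m, s, kg, Pa) internally. Published ASL and
#' pharmacokinetic parameters mix unit systems (micrometres, mg/ml, g/cm3,
#' cm2/s), so explicit converters are provided at the configuration boundary.
#'
#' @param x numeric value(s) in the source unit.
#' @return numeric value(s) in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
mg_ml_to_kg_m3 <- function(x) x            # 1 mg/ml == 1 kg/m3

#' @rdname units
#' @export
g_cm3_to_kg_m3 <- function(x) x * 1000

#' @rdname units
#' @export
cm2_s_to_m2_s <- function(x) x * 1e-4
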