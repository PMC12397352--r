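#' Deposition timing metrics
#'
#' From a deposition time series: the *complete deposition time* is the
#' first time at which deposited plus attached mass accounts for at least
#' `threshold` of the initial mass (no drug left in the domain); the
#' *maximum deposition time* is the time of peak instantaneous epithelial
#' deposition rate. (The cumulative deposition fraction is monotone, so its
#' literal maximum would coincide with complete deposition; the rate peak
#' is the quantity that identifies the optimal dosing moment.)
#'
#' @param t sample times (s).
#' @param deposited_frac cumulative epithelial deposition fraction (0..1).
#' @param attached_frac cumulative ciliary attachment fraction (0..1);
#'   zero when absent.
#' @param threshold completeness threshold on deposited+attached (0.999).
#' @return list with `max_deposition_time` and `complete_deposition_time`
#'   (s); the latter is `NA` with a warning when the series never reaches
#'   the threshold.
#' @export
deposition_times <- function(t, deposited_frac, attached_frac = 0,
                             threshold = 0.999) {
  stopifnot(length(t) == length(deposited_frac))
  if (length(attached_frac) == 1) {
    attached_frac <- rep(attached_frac, length(t))
  }
  if (any(diff(deposited_frac) < -1e-9)) {
    stop("cumulative deposition fraction must be non-decreasing")
  }
  total <- deposited_frac + attached_frac
  hit <- which(total >= threshold)
  complete <- if (length(hit)) t[hit[1]] else {
    warning("deposition series never reaches the completeness threshold")
    NA_real_
  }
  rate <- diff(deposited_frac) / diff(t)
  tmid <- (t[-1] + t[-length(t)]) / 2
  max_dep <- if (length(rate)) tmid[which.max(rate)] else NA_real_
  list(max_deposition_time = max_dep, complete_deposition_time = complete)
}

#' Percentage mass-fraction curves from ledgers
#'
#' Converts mass ledgers to percentage-of-initial-mass curves: dissolved,
#' deposited-on-epithelium, attached-to-cilia and remaining-in-domain. At
#' every sample time the four (plus the undissolved remainder) close to
#' 100%.
#'
#' @param ledgers data.frame with columns `t`, `dissolved`, `deposited`,
#'   `attached`, `in_domain` (kg, same basis).
#' @param initial_mass initial particle mass on that basis (kg, `> 0`).
#' @return data.frame of percentage curves plus `undissolved` and
#'   `closure_error` (percent).
#' @export
fractions <- function(ledgers, initial_mass) {
  if (!is.numeric(initial_mass) || initial_mass <= 0) {
    stop("initial mass must be positive")
  }
  pct <- function(x) 100 * x / initial_mass
  out <- data.frame(
    t = ledgers$t,
    dissolved = pct(ledgers$dissolved),
    deposited = pct(ledgers$deposited),
    attached = pct(ledgers$attached),
    in_domain = pct(ledgers$in_domain)
  )
  out$undissolved <- 100 - out$dissolved
  out$closure_error <- out$deposited + out$attached + out$in_domain +
    out$undissolved - 100
  out
}

#' Summary metrics of a transport episode
#'
#' @param result a [run_transport()] result.
#' @return one-row data.frame mirroring the summary-table layout: drug,
#'   attachment strength, achieved CAR, total deposition fraction (%),
#'   maximum and complete deposition times (s) and complete dissolution
#'   time (s).
#' @export
transport_metrics <- function(result) {
  stopifnot(inherits(result, "transport_result"))
  s <- result$series
  dts <- deposition_times(s$t, s$deposited_frac, s$attached_frac)
  data.frame(
    drug = result$drug,
    kappa_att = result$kappa_att,
    achieved_car = result$achieved_car,
    total_deposition_fraction = result$total_deposition_fraction,
    max_deposition_time = dts$max_deposition_time,
    complete_deposition_time = dts$complete_deposition_time,
    complete_dissolution_time = result$dissolution_time
  )
}
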