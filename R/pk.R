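## One-compartment inhibitor pharmacokinetics. Doses are in IC_50 units; in
## these units the equilibrium fraction of inhibitor-bound Mdm2 is
## F = INH_B / (1 + INH_B). Oral delivery: first-order liberation from a
## depot (gut) to blood at d_r1, first-order elimination at d_r2, so a
## single dose follows the Bateman two-exponential curve. Drip delivery:
## constant zero-order infusion at (daily dose)/24 per hour with the same
## elimination. These closed forms are the test oracle; inside the engines
## the PK states are integrated jointly with the network.

#' Pharmacokinetic parameters
#'
#' @param d_r1 liberation rate to blood, 1/h (oral only); default 1/h.
#' @param d_r2 elimination rate, 1/h; default 0.25/h.
#' @param mode `"oral"` or `"drip"`.
#' @return object of class `pk_parameters`.
#' @export
pk_parameters <- function(d_r1 = 1, d_r2 = 0.25, mode = c("oral", "drip")) {
  mode <- match.arg(mode)
  if (!is.numeric(d_r1) || !is.numeric(d_r2) || d_r2 <= 0)
    stop("rate coefficients must be positive")
  if (mode == "oral" && d_r1 <= d_r2)
    stop("oral delivery requires d_r1 > d_r2 (otherwise no blood peak exists)")
  structure(list(d_r1 = d_r1, d_r2 = d_r2, mode = mode),
            class = "pk_parameters")
}

#' Inhibitor blood level
#'
#' Closed-form blood level INH_B (IC_50 units) at time `t`. Oral delivery is
#' the superposition of per-dose Bateman responses
#' `dose * d_r1/(d_r1 - d_r2) * (exp(-d_r2 tau) - exp(-d_r1 tau))`;
#' drip delivery approaches the equilibrium `(daily_dose/24)/d_r2` with
#' relaxation time `1/d_r2`.
#'
#' @param events data.frame with columns `time_h` and `dose` (IC_50 units
#'   per administration for oral; for drip, a single row whose `dose` is the
#'   daily dose and whose `time_h` is the infusion start).
#' @param params a [pk_parameters()].
#' @param t time(s) in hours from protocol start (vectorized).
#' @return numeric vector of blood levels, same length as `t`.
#' @export
blood_level <- function(events, params, t) {
  stopifnot(inherits(params, "pk_parameters"), is.numeric(t), all(t >= -1e-9))
  if (is.null(events) || nrow(events) == 0) return(rep(0, length(t)))
  if (any(events$dose < 0)) stop("negative dose")
  if (params$mode == "oral") {
    a <- params$d_r1
    b <- params$d_r2
    sapply(t, function(tt) {
      tau <- tt - events$time_h
      on <- tau >= 0
      sum(events$dose[on] * a / (a - b) * (exp(-b * tau[on]) - exp(-a * tau[on])))
    })
  } else {
    q <- events$dose[1] / 24    # IC_50 per hour
    b <- params$d_r2
    tau <- pmax(t - events$time_h[1], 0)
    q / b * (1 - exp(-b * tau))
  }
}

#' Time of the oral blood-level peak after a single dose
#'
#' For the Bateman curve the maximum is at
#' `ln(d_r1/d_r2) / (d_r1 - d_r2)`; with the default constants (1/h and
#' 0.25/h) this is about 1.85 h, i.e. roughly 2 h after delivery.
#'
#' @param params a [pk_parameters()] in oral mode.
#' @return peak time in hours.
#' @export
peak_time <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  if (params$mode != "oral")
    stop("peak_time applies to oral delivery only (drip has no peak)")
  if (params$d_r1 == params$d_r2) stop("d_r1 must differ from d_r2")
  log(params$d_r1 / params$d_r2) / (params$d_r1 - params$d_r2)
}

#' Drip relaxation time and time to reach a fraction of equilibrium
#'
#' The drip blood level relaxes to equilibrium as `1 - exp(-d_r2 t)`; the
#' relaxation time is `1/d_r2` (4 h with the default elimination rate) and
#' the time to come within `frac` of equilibrium is `-ln(frac)/d_r2`.
#'
#' @param params a [pk_parameters()].
#' @param frac remaining fractional distance from equilibrium (e.g. 0.05
#'   for "within 5%"); if `NULL`, the relaxation time `1/d_r2` is returned.
#' @return time in hours.
#' @export
drip_relaxation_time <- function(params, frac = NULL) {
  stopifnot(inherits(params, "pk_parameters"))
  if (is.null(frac)) 1 / params$d_r2 else -log(frac) / params$d_r2
}

#' Equilibrium fraction of inhibitor-bound Mdm2
#'
#' `F = INH_B / (1 + INH_B)` with INH_B in IC_50 units, so a blood level of
#' 1 IC_50 binds half of Mdm2.
#'
#' @param inh_b blood level in IC_50 units (vectorized, non-negative).
#' @return bound fraction in `[0, 1)`.
#' @export
bound_fraction <- function(inh_b) {
  if (any(inh_b < 0)) stop("blood level must be non-negative")
  inh_b / (1 + inh_b)
}
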