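## Deterministic engine: integrate the ODE approximation of the network
## under a protocol (irradiations and oral doses are impulsive state
## updates; integration restarts at every event), detect apoptosis
## commitment on the caspase module, find critical irradiation doses by
## bisection, and characterize oscillations.

#' Integrate the deterministic model under a protocol
#'
#' Irradiation adds `dose_Gy * k_dsb` lesions to the damage species and an
#' oral administration adds its dose to the depot; both are discontinuity-
#' safe impulses handled through the integrator's event mechanism. Promoter
#' state variables relax to continuous occupancy fractions in this
#' approximation.
#'
#' @param network a `p53_network` (phenotype already applied).
#' @param protocol a [make_protocol()] with its irradiation dose set.
#' @param horizon_h simulation horizon in hours (default: protocol
#'   duration).
#' @param sample_dt_h output sampling interval, hours.
#' @param rtol,atol integrator tolerances (lsoda).
#' @param state optional initial state (default: the network's resting
#'   state).
#' @return object of class `trajectory`: list with `time_h`, `state`
#'   (time x species matrix), `events`, `apoptosis_time_h` (`NA` if never
#'   committed) and `committed` (per-sample latched flag).
#' @export
simulate_ode <- function(network, protocol, horizon_h = NULL,
                         sample_dt_h = 0.5, rtol = 1e-6, atol = 1e-2,
                         state = NULL) {
  stopifnot(inherits(network, "p53_network"), inherits(protocol, "protocol"))
  horizon_h <- horizon_h %||% protocol_duration(protocol)
  if (horizon_h < protocol_duration(protocol))
    warning("horizon is shorter than the protocol duration")

  params <- network$params
  if (protocol$mode == "drip" && protocol$inh_dose > 0) {
    network$params[["q_drip"]] <- protocol$inh_dose / 24 / 3600
  }
  ptr <- compile_for_engine(network)

  y0 <- if (is.null(state)) initial_state(network) else
    as_state_vector(network, state)
  y0 <- stats::setNames(as.numeric(y0), network$species$name)

  ev <- event_schedule(protocol)
  ev <- ev[ev$time_h <= horizon_h, , drop = FALSE]
  evd <- NULL
  imp <- ev[ev$kind != "infusion_on", , drop = FALSE]
  if (nrow(imp)) {
    evd <- data.frame(
      var = ifelse(imp$kind == "irradiate", "DNAdam", "INHd"),
      ## impulses fire a millisecond before the nominal time, so a sample
      ## taken at an event time already includes the impulse
      time = pmax(hours_to_seconds(imp$time_h) - 1e-3, 0),
      value = ifelse(imp$kind == "irradiate",
                     imp$magnitude * network$params[["k_dsb"]],
                     imp$magnitude),
      method = "add", stringsAsFactors = FALSE)
    at0 <- evd$time <= 0
    if (any(at0)) {
      for (j in which(at0)) y0[[evd$var[j]]] <- y0[[evd$var[j]]] + evd$value[j]
      evd <- evd[!at0, , drop = FALSE]
      if (nrow(evd) == 0) evd <- NULL
    }
  }

  grid <- unique(c(seq(0, hours_to_seconds(horizon_h),
                       by = hours_to_seconds(sample_dt_h)),
                   hours_to_seconds(horizon_h)))
  times <- sort(unique(c(grid, if (!is.null(evd)) evd$time)))
  rhs <- function(t, y, parms) list(net_deriv_cpp(ptr, y))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol,
                        events = if (is.null(evd)) NULL else list(data = evd),
                        maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ",
         signif(seconds_to_hours(max(sol[, 1])), 4), " h")

  keep <- sol[, 1] %in% grid          # drop the shifted event knots
  state_m <- sol[keep, -1, drop = FALSE]
  time_h <- seconds_to_hours(sol[keep, 1])
  thr <- network$params[["casp_thresh"]]
  casp <- state_m[, "Casp"]
  committed <- cummax(casp >= thr) > 0
  apop_h <- if (any(committed)) crossing_time(time_h, casp, thr) else NA_real_

  structure(list(time_h = time_h, state = state_m, events = ev,
                 apoptosis_time_h = apop_h, committed = committed,
                 phenotype = network$phenotype, protocol = protocol),
            class = "trajectory")
}

## linear interpolation of the first upward threshold crossing
crossing_time <- function(time, x, thr) {
  i <- which(x >= thr)[1]
  if (is.na(i) || i == 1) return(time[i])
  t0 <- time[i - 1]; t1 <- time[i]
  x0 <- x[i - 1]; x1 <- x[i]
  if (x1 == x0) return(t1)
  t0 + (thr - x0) / (x1 - x0) * (t1 - t0)
}

#' Apoptosis commitment time of a trajectory
#'
#' First time the active-caspase level crosses the commitment threshold;
#' the commitment flag is absorbing (the trajectory may keep evolving, but
#' the cell is counted as apoptotic from this time on).
#'
#' @param trajectory a [simulate_ode()] result.
#' @return commitment time in hours, or `NA` if the cell never commits.
#' @export
apoptosis_time <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  trajectory$apoptosis_time_h
}

#' Critical irradiation dose by bisection
#'
#' Finds the minimal irradiation dose per day at which the deterministic
#' trajectory commits to apoptosis within the horizon. The bracket is first
#' scanned at `n_scan` coarse points to detect a non-monotone apoptotic
#' predicate (warned, not hidden), then bisected to `tol`.
#'
#' @param network phenotype-specialized `p53_network`.
#' @param protocol_template protocol whose `ir_dose_per_day` is free.
#' @param horizon_h horizon for the apoptosis predicate (default protocol
#'   duration).
#' @param bracket search interval in Gy/day, default `c(0, 10)`.
#' @param tol bisection tolerance in Gy/day, default 0.01.
#' @param n_scan number of coarse pre-scan points (0 disables the scan).
#' @param ... passed to [simulate_ode()].
#' @return object of class `ir_crit_result`: list with `ir_crit` (Gy/day;
#'   `Inf` when even the upper bracket fails to induce apoptosis), achieved
#'   bracket `lo`/`hi`, `tol`, `protocol`, `phenotype`, `n_evals`.
#' @export
find_ir_crit <- function(network, protocol_template, horizon_h = NULL,
                         bracket = c(0, 10), tol = 0.01, n_scan = 8, ...) {
  stopifnot(inherits(network, "p53_network"),
            inherits(protocol_template, "protocol"),
            bracket[1] < bracket[2], tol > 0)
  n_evals <- 0L
  apoptotic <- function(dose) {
    n_evals <<- n_evals + 1L
    tr <- simulate_ode(network, with_ir_dose(protocol_template, dose),
                       horizon_h = horizon_h, ...)
    !is.na(tr$apoptosis_time_h)
  }

  lo <- bracket[1]; hi <- bracket[2]
  if (!apoptotic(hi)) {
    return(structure(list(ir_crit = Inf, lo = hi, hi = Inf, tol = tol,
                          protocol = protocol_template$name,
                          phenotype = network$phenotype, n_evals = n_evals),
                     class = "ir_crit_result"))
  }
  if (n_scan > 0) {
    grid <- seq(lo, hi, length.out = n_scan + 2)
    inner <- grid[-c(1, length(grid))]
    hits <- vapply(inner, apoptotic, logical(1))
    if (any(hits) && any(diff(hits) < 0))
      warning("non-monotone apoptotic response within the bracket; ",
              "crossings near ",
              paste(signif(inner[which(diff(hits) != 0)], 3), collapse = ", "),
              " Gy/day")
    first <- which(hits)[1]
    if (!is.na(first)) {
      hi <- inner[first]
      if (first > 1) lo <- inner[first - 1]
    } else {
      lo <- inner[length(inner)]
    }
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (apoptotic(mid)) hi <- mid else lo <- mid
  }
  structure(list(ir_crit = hi, lo = lo, hi = hi, tol = tol,
                 protocol = protocol_template$name,
                 phenotype = network$phenotype, n_evals = n_evals),
            class = "ir_crit_result")
}

#' @export
print.ir_crit_result <- function(x, ...) {
  cat("IR_crit(", x$phenotype, ", ", x$protocol, ") = ",
      ifelse(is.finite(x$ir_crit), paste(signif(x$ir_crit, 4), "Gy/day"),
             "unbounded (resistant at bracket top)"),
      "  [", signif(x$lo, 4), ", ", signif(x$hi, 4), "]\n", sep = "")
  invisible(x)
}

#' Oscillation period of a trajectory species
#'
#' Median inter-peak interval of the named species inside a time window;
#' requires at least three local maxima with non-negligible amplitude.
#'
#' @param trajectory a [simulate_ode()] result.
#' @param species species name (e.g. `"p53K"`).
#' @param window_h two-element window in hours (default: full horizon).
#' @param min_rel_amplitude peaks are counted only if the windowed series
#'   spans at least this fraction of its maximum.
#' @return period in hours, or `NA` for flat/aperiodic series.
#' @export
oscillation_period <- function(trajectory, species, window_h = NULL,
                               min_rel_amplitude = 0.05) {
  stopifnot(inherits(trajectory, "trajectory"),
            species %in% colnames(trajectory$state))
  tt <- trajectory$time_h
  xx <- trajectory$state[, species]
  if (!is.null(window_h)) {
    keep <- tt >= window_h[1] & tt <= window_h[2]
    tt <- tt[keep]; xx <- xx[keep]
  }
  if (length(xx) < 5) return(NA_real_)
  rng <- max(xx) - min(xx)
  if (max(xx) <= 0 || rng < min_rel_amplitude * max(xx)) return(NA_real_)
  level <- min(xx) + 0.2 * rng
  n <- length(xx)
  peaks <- which(xx[2:(n - 1)] > xx[1:(n - 2)] &
                 xx[2:(n - 1)] >= xx[3:n] &
                 xx[2:(n - 1)] > level) + 1
  ## merge plateau/jitter peaks closer than 2 samples
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 2)]
  if (length(peaks) < 3) return(NA_real_)
  stats::median(diff(tt[peaks]))
}

#' Export a trajectory as CSV
#'
#' Columns: `time_h`, one column per species, and the latched apoptosis
#' flag.
#'
#' @param trajectory a [simulate_ode()] (or sampled SSA) trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time_h = trajectory$time_h, trajectory$state,
                   apoptosis = as.integer(trajectory$committed),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
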