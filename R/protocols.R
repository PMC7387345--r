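## Treatment protocols: fractionated irradiation cycles (a cycle is the time
## between subsequent irradiations) plus inhibitor dosing within each cycle.
## Irradiation dose is stored per day (the reporting unit for all critical
## doses) and converted to the per-event dose dose_per_day * cycle_h/24 at
## scheduling time.

CYCLE_LENGTHS <- c(12, 18, 24, 36)

#' Construct and validate a treatment protocol
#'
#' @param cycle_h cycle length in hours: 12, 18, 24 or 36.
#' @param n_cycles number of cycles (irradiations at the start of each).
#' @param ir_dose_per_day irradiation dose in Gy per day (may be `NA` in a
#'   template whose dose is to be determined, e.g. by critical-dose search).
#' @param offsets_h inhibitor administration times in hours after each
#'   irradiation; must lie in `[0, cycle_h)`; at most one administration per
#'   12/18-h cycle and at most two per 24/36-h cycle. Ignored for drip.
#' @param inh_dose inhibitor dose in IC_50 units per administration (oral)
#'   or per day (drip); 0 or mode `"none"` for radiation monotherapy.
#' @param mode inhibitor delivery: `"oral"`, `"drip"` or `"none"`.
#' @param name optional protocol label.
#' @return object of class `protocol`.
#' @export
make_protocol <- function(cycle_h, n_cycles, ir_dose_per_day = NA,
                          offsets_h = numeric(0), inh_dose = 0,
                          mode = c("oral", "drip", "none"), name = NULL) {
  mode <- match.arg(mode)
  if (!cycle_h %in% CYCLE_LENGTHS)
    stop("cycle_h must be one of ", paste(CYCLE_LENGTHS, collapse = ", "),
         " (got ", cycle_h, ")")
  if (!is.numeric(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
    stop("n_cycles must be a positive integer")
  if (!is.na(ir_dose_per_day) && ir_dose_per_day < 0)
    stop("irradiation dose must be non-negative")
  if (inh_dose < 0) stop("inhibitor dose must be non-negative")
  if (mode == "none") {
    offsets_h <- numeric(0)
    inh_dose <- 0
  }
  if (mode == "oral" && inh_dose > 0) {
    if (any(offsets_h < 0 | offsets_h >= cycle_h))
      stop("inhibitor offsets must lie in [0, cycle_h)")
    max_adm <- if (cycle_h <= 18) 1L else 2L
    if (length(offsets_h) > max_adm)
      stop(cycle_h, "-h cycles admit at most ", max_adm,
           " inhibitor administration(s) per cycle")
  }
  structure(list(cycle_h = cycle_h,
                 n_cycles = as.integer(n_cycles),
                 ir_dose_per_day = ir_dose_per_day,
                 offsets_h = sort(offsets_h),
                 inh_dose = inh_dose,
                 mode = mode,
                 name = name %||% sprintf("%dh_custom", cycle_h)),
            class = "protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.protocol <- function(x, ...) {
  cat("protocol ", x$name, ": ", x$n_cycles, " x ", x$cycle_h, " h cycles (",
      protocol_duration(x), " h), IR ",
      ifelse(is.na(x$ir_dose_per_day), "<unset>", x$ir_dose_per_day),
      " Gy/day", sep = "")
  if (x$mode == "oral" && x$inh_dose > 0)
    cat(", inhibitor ", x$inh_dose, " IC50 at +",
        paste(x$offsets_h, collapse = ", +"), " h (oral)", sep = "")
  if (x$mode == "drip")
    cat(", inhibitor ", x$inh_dose, " IC50/day (drip)", sep = "")
  cat("\n")
  invisible(x)
}

#' Total protocol duration in hours
#' @param protocol a [make_protocol()] object.
#' @return duration in hours.
#' @export
protocol_duration <- function(protocol) protocol$cycle_h * protocol$n_cycles

#' Expand a protocol into its time-ordered event schedule
#'
#' Irradiations occur at `k * cycle_h` for `k = 0 .. n_cycles-1` with
#' per-event dose `ir_dose_per_day * cycle_h / 24` Gy; oral inhibitor doses
#' at every cycle start plus offset; drip delivery is a single `infusion_on`
#' event at time 0 carrying the daily dose.
#'
#' @param protocol a [make_protocol()] object.
#' @return data.frame with columns `time_h`, `kind`
#'   (`irradiate`/`dose_inhibitor`/`infusion_on`) and `magnitude`
#'   (Gy per event, IC_50 per administration, or IC_50 per day), sorted by
#'   time (ties: irradiation first).
#' @export
event_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "protocol"))
  if (is.na(protocol$ir_dose_per_day))
    stop("protocol has no irradiation dose set")
  starts <- (seq_len(protocol$n_cycles) - 1) * protocol$cycle_h
  ev <- data.frame(
    time_h = starts,
    kind = "irradiate",
    magnitude = protocol$ir_dose_per_day * protocol$cycle_h / 24,
    stringsAsFactors = FALSE)
  if (protocol$mode == "oral" && protocol$inh_dose > 0 &&
      length(protocol$offsets_h)) {
    dose_t <- as.vector(outer(protocol$offsets_h, starts, `+`))
    ev <- rbind(ev, data.frame(time_h = dose_t, kind = "dose_inhibitor",
                               magnitude = protocol$inh_dose,
                               stringsAsFactors = FALSE))
  }
  if (protocol$mode == "drip" && protocol$inh_dose > 0) {
    ev <- rbind(ev, data.frame(time_h = 0, kind = "infusion_on",
                               magnitude = protocol$inh_dose,
                               stringsAsFactors = FALSE))
  }
  ev[order(ev$time_h, match(ev$kind, c("irradiate", "infusion_on",
                                       "dose_inhibitor"))), , drop = FALSE]
}

#' Catalog of the studied 6-day combination protocols
#'
#' Ten oral protocols spanning 12/18/24/36-h cycles plus one drip protocol,
#' all normalized to an inhibitor dose of 20 IC_50 per day (10 IC_50 per
#' administration for 12- and 24-h cycles, 15 IC_50 for 18- and 36-h
#' cycles). Three timings are fixed as published: `24h_6_18` (6 and 18 h
#' after irradiation), `36h_6_30`, and `36h_0_24`; the remaining seven are
#' reconstructions with evenly spaced or irradiation-aligned defaults and
#' can be overridden via `offsets` (they are identified by
#' `attr(, "reconstructed")`).
#'
#' @param name optional catalog entry name; if `NULL` the full named list is
#'   returned.
#' @param n_cycles number of cycles; default 6 days' worth of each cycle
#'   length.
#' @param daily_inh_dose inhibitor dose per day, IC_50 units (default 20).
#' @param offsets optional named list overriding administration offsets of
#'   reconstructed entries, e.g. `list(`12h_mid` = 4)`.
#' @return a `protocol`, or a named list of all 11 protocols.
#' @export
protocol_catalog <- function(name = NULL, n_cycles = NULL,
                             daily_inh_dose = 20, offsets = list()) {
  specs <- list(
    `12h_0`    = list(cycle = 12, off = c(0),      fixed = FALSE),
    `12h_6`    = list(cycle = 12, off = c(6),      fixed = FALSE),
    `18h_0`    = list(cycle = 18, off = c(0),      fixed = FALSE),
    `18h_9`    = list(cycle = 18, off = c(9),      fixed = FALSE),
    `24h_0_12` = list(cycle = 24, off = c(0, 12),  fixed = FALSE),
    `24h_6_18` = list(cycle = 24, off = c(6, 18),  fixed = TRUE),
    `24h_0_6`  = list(cycle = 24, off = c(0, 6),   fixed = FALSE),
    `36h_0_18` = list(cycle = 36, off = c(0, 18),  fixed = FALSE),
    `36h_0_24` = list(cycle = 36, off = c(0, 24),  fixed = TRUE),
    `36h_6_30` = list(cycle = 36, off = c(6, 30),  fixed = TRUE),
    drip       = list(cycle = 24, off = numeric(0), fixed = TRUE)
  )
  build <- function(nm) {
    s <- specs[[nm]]
    off <- s$off
    if (nm %in% names(offsets)) {
      if (s$fixed) stop("offsets of catalog protocol '", nm, "' are fixed")
      off <- offsets[[nm]]
    }
    nc <- n_cycles %||% as.integer(144 / s$cycle)   # 6 days
    if (nm == "drip") {
      p <- make_protocol(s$cycle, nc, NA, inh_dose = daily_inh_dose,
                         mode = "drip", name = nm)
    } else {
      per_adm <- daily_inh_dose * s$cycle / 24 / length(off)
      p <- make_protocol(s$cycle, nc, NA, offsets_h = off,
                         inh_dose = per_adm, mode = "oral", name = nm)
    }
    attr(p, "reconstructed") <- !s$fixed
    p
  }
  if (is.null(name)) {
    out <- lapply(names(specs), build)
    names(out) <- names(specs)
    out
  } else {
    if (!name %in% names(specs))
      stop("unknown catalog protocol '", name, "'; available: ",
           paste(names(specs), collapse = ", "))
    build(name)
  }
}

#' Replace the irradiation dose of a protocol
#'
#' @param protocol a `protocol`.
#' @param ir_dose_per_day new dose in Gy/day.
#' @return modified copy.
#' @export
with_ir_dose <- function(protocol, ir_dose_per_day) {
  stopifnot(inherits(protocol, "protocol"), ir_dose_per_day >= 0)
  protocol$ir_dose_per_day <- ir_dose_per_day
  protocol
}

#' Replace the inhibitor dose of a protocol
#'
#' Rescales the per-administration (oral) or per-day (drip) dose.
#'
#' @param protocol a `protocol`.
#' @param inh_dose new inhibitor dose in IC_50 units.
#' @return modified copy.
#' @export
with_inh_dose <- function(protocol, inh_dose) {
  stopifnot(inherits(protocol, "protocol"), inh_dose >= 0)
  protocol$inh_dose <- inh_dose
  protocol
}
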