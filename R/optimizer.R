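## Two-step protocol selection: (1) deterministic screening by the
## normal-to-cancer ratio of critical irradiation doses as a function of
## inhibitor dose, (2) stochastic verification of apoptotic fractions
## against the plausibility thresholds (cancer >= 95% apoptotic, normal
## <= 10%), with normal cells receiving a threefold lower irradiation dose
## (intersecting beams) and a specificity-reduced inhibitor uptake.

#' Normal-to-cancer critical-dose ratio curve
#'
#' For each inhibitor dose `d` on the grid, computes the deterministic
#' critical irradiation dose for cancer cells receiving `d` and for normal
#' cells whose inhibitor-Mdm2 association constant is divided by
#' `specificity` (equivalent to an effective dose `d/specificity`), and
#' reports the ratio `R(d) = IR_crit_normal / IR_crit_cancer`. `R = 0`
#' wherever the cancer cells are resistant at the top of the search bracket
#' (radiation-resistant phenotypes at `d = 0` in particular).
#'
#' @param protocol_template combination protocol whose irradiation dose is
#'   free; its per-administration inhibitor dose is replaced by each grid
#'   value.
#' @param cancer_phenotype `"pten_cancer"` or `"wip1_cancer"` (or a
#'   [cell_phenotype()]).
#' @param specificity cancer-to-normal inhibitor uptake ratio (1, 3 or 10).
#' @param dose_grid ascending inhibitor doses in IC_50 units, starting at 0.
#' @param params model parameters ([default_parameters()]).
#' @param tol,bracket,n_scan bisection settings passed to [find_ir_crit()].
#' @param horizon_h deterministic screening horizon (default: the protocol
#'   duration).
#' @return object of class `ratio_curve`: data.frame of `dose`,
#'   `ir_crit_cancer`, `ir_crit_normal`, `ratio`, plus attributes.
#' @export
ratio_curve <- function(protocol_template, cancer_phenotype,
                        specificity = 10,
                        dose_grid = seq(0, 20, by = 0.5),
                        params = default_parameters(), tol = 0.02,
                        bracket = c(0, 10), n_scan = 8, horizon_h = NULL) {
  stopifnot(length(dose_grid) >= 1, all(diff(dose_grid) > 0),
            dose_grid[1] >= 0)
  if (is.character(cancer_phenotype))
    cancer_phenotype <- cell_phenotype(cancer_phenotype)
  base <- build_network(params)
  net_cancer <- apply_phenotype(base, cancer_phenotype)
  net_normal <- apply_phenotype(base, cell_phenotype(
    "normal", uptake_specificity = specificity))
  rest_cancer <- resting_state(net_cancer)
  rest_normal <- resting_state(net_normal)

  one <- function(net, rest, dose) {
    p <- with_inh_dose(protocol_template, dose)
    r <- tryCatch(
      find_ir_crit(net, p, horizon_h = horizon_h, bracket = bracket,
                   tol = tol, n_scan = n_scan, state = rest),
      error = function(e) {
        warning("IR_crit failed at dose ", dose, ": ",
                conditionMessage(e))
        list(ir_crit = NA_real_)
      })
    r$ir_crit
  }
  icc <- vapply(dose_grid, function(d) one(net_cancer, rest_cancer, d),
                numeric(1))
  icn <- vapply(dose_grid, function(d) one(net_normal, rest_normal, d),
                numeric(1))
  ratio <- ifelse(is.finite(icc) & icc > 0, icn / icc, 0)
  ratio[!is.finite(ratio)] <- 0
  structure(data.frame(dose = dose_grid, ir_crit_cancer = icc,
                       ir_crit_normal = icn, ratio = ratio),
            class = c("ratio_curve", "data.frame"),
            protocol = protocol_template$name,
            phenotype = cancer_phenotype$label,
            specificity = specificity)
}

#' Inhibitor dose maximizing the critical-dose ratio
#'
#' Argmax of the ratio over the curve's grid; ties are broken toward the
#' lower dose and a multimodal curve triggers a warning (both reported).
#'
#' @param curve a [ratio_curve()].
#' @return the optimal dose (IC_50 units); errors if the whole curve is
#'   zero (no dose sensitizes the cancer cells).
#' @export
optimal_inhibitor_dose <- function(curve) {
  stopifnot(inherits(curve, "ratio_curve") || is.data.frame(curve),
            nrow(curve) >= 1)
  r <- curve$ratio
  if (all(r <= 0)) stop("ratio curve is identically zero: no optimum")
  best <- which(r == max(r))[1]          # tie-break: lowest dose
  ## count interior local maxima to flag multimodality
  if (nrow(curve) >= 3) {
    n <- length(r)
    peaks <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1
    peaks <- peaks[r[peaks] > 0.05 * max(r)]
    if (length(peaks) > 1)
      warning("ratio curve is multimodal; local maxima at doses ",
              paste(curve$dose[peaks], collapse = ", "))
  }
  curve$dose[best]
}

#' Stochastic plausibility verification of a protocol
#'
#' Scans irradiation doses over `range_frac * IR_crit_cancer` (the
#' deterministic critical dose of the cancer cells at the given inhibitor
#' dose). For each dose IR the apoptotic fraction of cancer cells (full IR,
#' full inhibitor dose) and of normal cells (IR / `irradiation_ratio`,
#' uptake reduced by `specificity`) is estimated from seeded stochastic
#' ensembles over `n_cycles_verify` cycles. The protocol is plausible at
#' the first scanned dose where the cancer fraction is at least
#' `cancer_min` and the normal fraction at most `normal_max`; that dose is
#' reported as IR_opt.
#'
#' @inheritParams ratio_curve
#' @param protocol_template the combination protocol (irradiation dose
#'   free).
#' @param inh_dose inhibitor dose per administration, IC_50 units
#'   (cancer-referenced).
#' @param n_cells stochastic ensemble size per condition (1000 reproduces
#'   the reference analysis; 100 is the fast setting).
#' @param seed root seed for the per-cell random streams.
#' @param n_ir number of scanned irradiation doses.
#' @param range_frac scanned range as fractions of the cancer critical
#'   dose, default `c(0.8, 1.5)`.
#' @param irradiation_ratio cancer-to-normal irradiation dose ratio
#'   (intersecting beams), default 3.
#' @param cancer_min,normal_max plausibility thresholds (0.95 and 0.10).
#' @param n_cycles_verify verification length in cycles, default 7.
#' @param omega scaling factor for the stochastic engine.
#' @param scan_all scan the whole grid even after a plausible dose is
#'   found (default stops early at IR_opt).
#' @return object of class `plausibility_verdict`: list with `plausible`,
#'   `ir_opt`, the per-dose `scan` data.frame (fractions and CIs for both
#'   cell types, with the logged normal-cell exposures), and the settings.
#' @export
verify_protocol <- function(protocol_template, cancer_phenotype, inh_dose,
                            specificity = 10, n_cells = 100, seed = 1,
                            params = default_parameters(), n_ir = 15,
                            range_frac = c(0.8, 1.5), irradiation_ratio = 3,
                            cancer_min = 0.95, normal_max = 0.10,
                            n_cycles_verify = 7, omega = 30, tol = 0.02,
                            scan_all = FALSE) {
  if (is.character(cancer_phenotype))
    cancer_phenotype <- cell_phenotype(cancer_phenotype)
  base <- build_network(params)
  net_cancer <- apply_phenotype(base, cancer_phenotype)
  net_normal <- apply_phenotype(base, cell_phenotype(
    "normal", uptake_specificity = specificity))
  rest_cancer <- resting_state(net_cancer)
  rest_normal <- resting_state(net_normal)

  prot <- with_inh_dose(protocol_template, inh_dose)
  prot$n_cycles <- as.integer(n_cycles_verify)
  ic <- find_ir_crit(net_cancer, prot, tol = tol, state = rest_cancer)
  if (!is.finite(ic$ir_crit))
    stop("cancer cells are resistant at this inhibitor dose; ",
         "no verification range exists")
  ir_grid <- seq(range_frac[1], range_frac[2], length.out = n_ir) * ic$ir_crit

  rows <- list()
  ir_opt <- NA_real_
  for (ir in ir_grid) {
    ## normal cells first: if even the lower CI bound of their apoptotic
    ## fraction exceeds the cap, no cancer result can make this dose
    ## plausible and the cancer ensemble is skipped
    fn <- apoptotic_fraction(net_normal,
                             with_ir_dose(prot, ir / irradiation_ratio),
                             n_cells = n_cells, seed = seed + 1,
                             omega = omega, state0 = rest_normal)
    if (fn$ci[1] > normal_max) {
      fc <- NULL
    } else {
      fc <- apoptotic_fraction(net_cancer, with_ir_dose(prot, ir),
                               n_cells = n_cells, seed = seed,
                               omega = omega, state0 = rest_cancer)
    }
    ok <- !is.null(fc) && fc$fraction >= cancer_min &&
      fn$fraction <= normal_max
    rows[[length(rows) + 1]] <- data.frame(
      ir_cancer = ir, ir_normal = ir / irradiation_ratio,
      inh_dose_cancer = inh_dose,
      inh_dose_normal_effective = inh_dose / specificity,
      frac_cancer = if (is.null(fc)) NA_real_ else fc$fraction,
      cancer_lo = if (is.null(fc)) NA_real_ else fc$ci[1],
      cancer_hi = if (is.null(fc)) NA_real_ else fc$ci[2],
      frac_normal = fn$fraction, normal_lo = fn$ci[1], normal_hi = fn$ci[2],
      plausible = ok)
    if (ok && is.na(ir_opt)) {
      ir_opt <- ir
      if (!scan_all) break
    }
  }
  structure(list(
    protocol = protocol_template$name, phenotype = cancer_phenotype$label,
    inh_dose = inh_dose, specificity = specificity,
    irradiation_ratio = irradiation_ratio,
    ir_crit_cancer = ic$ir_crit, ir_opt = ir_opt,
    plausible = !is.na(ir_opt), scan = do.call(rbind, rows),
    n_cells = n_cells, seed = seed,
    thresholds = c(cancer_min = cancer_min, normal_max = normal_max)),
    class = "plausibility_verdict")
}

#' @export
print.plausibility_verdict <- function(x, ...) {
  cat(sprintf(
    "protocol %s, %s, %g IC50 (specificity %g): %s%s\n",
    x$protocol, x$phenotype, x$inh_dose, x$specificity,
    if (x$plausible) "PLAUSIBLE" else "not plausible",
    if (x$plausible) sprintf(" at IR_opt = %.2f Gy/day", x$ir_opt) else ""))
  invisible(x)
}

#' Minimize the inhibitor dose of a plausible protocol
#'
#' Starting from a dose at which the protocol is plausible (typically the
#' ratio-curve argmax), walks the dose grid downward re-running
#' [verify_protocol()] and returns the smallest dose that remains
#' plausible, with its IR_opt.
#'
#' @inheritParams verify_protocol
#' @param start_dose inhibitor dose at which the protocol must already be
#'   plausible (precondition).
#' @param dose_grid descending candidate doses are taken from this grid
#'   (values below `start_dose`).
#' @return list with `min_dose`, `ir_opt`, and the per-dose `verdicts`.
#' @export
minimize_inhibitor_dose <- function(protocol_template, cancer_phenotype,
                                    start_dose, specificity = 10,
                                    n_cells = 100, seed = 1,
                                    dose_grid = seq(0, 20, by = 0.5), ...) {
  v0 <- verify_protocol(protocol_template, cancer_phenotype, start_dose,
                        specificity = specificity, n_cells = n_cells,
                        seed = seed, ...)
  if (!v0$plausible)
    stop("protocol is not plausible at the starting dose ", start_dose,
         "; nothing to minimize")
  verdicts <- list(v0)
  best <- v0
  for (d in sort(dose_grid[dose_grid < start_dose], decreasing = TRUE)) {
    v <- tryCatch(
      verify_protocol(protocol_template, cancer_phenotype, d,
                      specificity = specificity, n_cells = n_cells,
                      seed = seed, ...),
      error = function(e) NULL)   # resistant at low dose ends the walk
    if (is.null(v) || !v$plausible) break
    verdicts[[length(verdicts) + 1]] <- v
    best <- v
  }
  list(min_dose = best$inh_dose, ir_opt = best$ir_opt,
       protocol = best$protocol, phenotype = best$phenotype,
       specificity = specificity, verdicts = verdicts)
}

#' Deterministic resting state of a network
#'
#' Relaxes the untreated deterministic system and returns its fixed point;
#' used as the pre-treatment initial condition for each phenotype.
#'
#' @param network a `p53_network`.
#' @param t_relax_h relaxation horizon in hours.
#' @return named state vector.
#' @export
resting_state <- function(network, t_relax_h = 240) {
  p <- make_protocol(24, max(1, ceiling(t_relax_h / 24)), 0, mode = "none")
  tr <- simulate_ode(network, p, sample_dt_h = 24)
  tr$state[nrow(tr$state), ]
}

#' Two-step screening of the oral protocol catalog
#'
#' Runs the full selection pipeline for one cancer phenotype and one
#' inhibitor specificity: deterministic ratio curves over the inhibitor
#' dose grid for every oral catalog protocol (normal-cell critical doses
#' are cached across protocols), selection of the ratio-argmax dose, and
#' stochastic plausibility verification at that dose. Protocols whose ratio
#' curve is identically zero (cancer cells resistant at every dose) are
#' reported as not plausible without stochastic simulation.
#'
#' @inheritParams verify_protocol
#' @param protocols named list of protocols (default: the 10 oral catalog
#'   entries).
#' @param dose_grid inhibitor doses for the deterministic screen.
#' @param verify run the stochastic verification step (deterministic-only
#'   screening if `FALSE`).
#' @return object of class `protocol_screen`: list with `results` (one
#'   entry per protocol: `curve`, `opt_dose`, `verdict`), `summary`
#'   data.frame, `n_plausible`, and the settings.
#' @export
screen_protocols <- function(cancer_phenotype, specificity = 10,
                             protocols = NULL,
                             dose_grid = seq(0, 20, by = 0.5),
                             n_cells = 100, seed = 1,
                             params = default_parameters(), n_ir = 15,
                             tol = 0.02, n_scan = 8, omega = 30,
                             verify = TRUE, ...) {
  if (is.character(cancer_phenotype))
    cancer_phenotype <- cell_phenotype(cancer_phenotype)
  if (is.null(protocols)) {
    protocols <- protocol_catalog()
    protocols <- protocols[vapply(protocols, function(p) p$mode == "oral",
                                  logical(1))]
  }
  base <- build_network(params)
  net_cancer <- apply_phenotype(base, cancer_phenotype)
  net_normal <- apply_phenotype(base, cell_phenotype(
    "normal", uptake_specificity = specificity))
  rest_cancer <- resting_state(net_cancer)
  rest_normal <- resting_state(net_normal)
  normal_cache <- new.env(parent = emptyenv())

  ircrit <- function(net, rest, protocol, dose, cache = NULL) {
    key <- paste(protocol$name, dose)
    if (!is.null(cache) && exists(key, cache)) return(get(key, cache))
    r <- find_ir_crit(net, with_inh_dose(protocol, dose), tol = tol,
                      n_scan = n_scan, state = rest)$ir_crit
    if (!is.null(cache)) assign(key, r, cache)
    r
  }

  results <- list()
  for (nm in names(protocols)) {
    prot <- protocols[[nm]]
    icc <- vapply(dose_grid, function(d)
      ircrit(net_cancer, rest_cancer, prot, d), numeric(1))
    icn <- vapply(dose_grid, function(d)
      ircrit(net_normal, rest_normal, prot, d, normal_cache), numeric(1))
    ratio <- ifelse(is.finite(icc) & icc > 0, icn / icc, 0)
    ratio[!is.finite(ratio)] <- 0
    curve <- structure(data.frame(dose = dose_grid, ir_crit_cancer = icc,
                                  ir_crit_normal = icn, ratio = ratio),
                       class = c("ratio_curve", "data.frame"),
                       protocol = nm, phenotype = cancer_phenotype$label,
                       specificity = specificity)
    entry <- list(curve = curve, opt_dose = NA_real_, verdict = NULL)
    if (any(ratio > 0)) {
      entry$opt_dose <- suppressWarnings(optimal_inhibitor_dose(curve))
      if (verify) {
        entry$verdict <- verify_protocol(
          prot, cancer_phenotype, entry$opt_dose,
          specificity = specificity, n_cells = n_cells, seed = seed,
          params = params, n_ir = n_ir, tol = tol, omega = omega, ...)
      }
    }
    results[[nm]] <- entry
  }
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    e <- results[[nm]]
    data.frame(protocol = nm,
               max_ratio = max(e$curve$ratio),
               opt_dose = e$opt_dose,
               plausible = !is.null(e$verdict) && e$verdict$plausible,
               ir_opt = if (!is.null(e$verdict)) e$verdict$ir_opt else
                 NA_real_)
  }))
  structure(list(results = results, summary = summary,
                 n_plausible = sum(summary$plausible),
                 phenotype = cancer_phenotype$label,
                 specificity = specificity, dose_grid = dose_grid,
                 n_cells = n_cells, seed = seed),
            class = "protocol_screen")
}

#' @export
print.protocol_screen <- function(x, ...) {
  cat("protocol screen:", x$phenotype, "at specificity", x$specificity,
      "-", x$n_plausible, "of", nrow(x$summary), "protocols plausible\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
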