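## Run configuration and file output. A run config is a small declarative
## YAML/JSON document naming the phenotype, the protocol (catalog name or
## inline fields), engine settings and seeds; every default is materialized
## so the emitted provenance block reloads to an identical config.

CONFIG_KEYS <- c("network_file", "phenotype", "protocol", "engine", "seed",
                 "n_cells", "omega", "horizon_h", "rtol", "tol",
                 "specificity", "irradiation_ratio", "out_dir")
PROTOCOL_KEYS <- c("name", "cycle_h", "n_cycles", "ir_dose_per_day",
                   "inhibitor")
INHIBITOR_KEYS <- c("mode", "dose", "offsets_h")

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration, rejects unknown
#' keys, validates the protocol fields and materializes every default, so
#' that re-loading the emitted provenance reproduces the identical config.
#'
#' @param path configuration file.
#' @return object of class `run_config`: validated list with `phenotype`,
#'   `protocol` (a [make_protocol()] object), `engine`, `seed`, `n_cells`,
#'   `omega`, `horizon_h`, `rtol`, `tol`, `specificity`,
#'   `irradiation_ratio`, `out_dir`, `network_file`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

validate_config <- function(raw) {
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  phenotype <- raw$phenotype %||% "normal"
  if (!phenotype %in% c("normal", "wip1_cancer", "pten_cancer"))
    stop("config key 'phenotype' must be normal, wip1_cancer or ",
         "pten_cancer (got '", phenotype, "')")

  pr <- raw$protocol
  if (is.null(pr)) stop("config key 'protocol' is required")
  protocol <- if (is.character(pr)) {
    protocol_catalog(pr)
  } else {
    unknown <- setdiff(names(pr), PROTOCOL_KEYS)
    if (length(unknown))
      stop("unknown protocol key(s): ", paste(unknown, collapse = ", "))
    inh <- pr$inhibitor %||% list(mode = "none")
    unknown <- setdiff(names(inh), INHIBITOR_KEYS)
    if (length(unknown))
      stop("unknown inhibitor key(s): ", paste(unknown, collapse = ", "))
    make_protocol(cycle_h = pr$cycle_h,
                  n_cycles = pr$n_cycles %||% round(144 / pr$cycle_h),
                  ir_dose_per_day = pr$ir_dose_per_day %||% NA,
                  offsets_h = unlist(inh$offsets_h) %||% numeric(0),
                  inh_dose = inh$dose %||% 0,
                  mode = inh$mode %||% "none",
                  name = pr$name)
  }
  cfg <- list(
    network_file = raw$network_file %||% NA_character_,
    phenotype = phenotype,
    protocol = protocol,
    engine = match.arg(raw$engine %||% "ode", c("ode", "ssa")),
    seed = as.integer(raw$seed %||% 1L),
    n_cells = as.integer(raw$n_cells %||% 100L),
    omega = raw$omega %||% 30,
    horizon_h = raw$horizon_h %||% protocol_duration(protocol),
    rtol = raw$rtol %||% 1e-6,
    tol = raw$tol %||% 0.01,
    specificity = raw$specificity %||% 10,
    irradiation_ratio = raw$irradiation_ratio %||% 3,
    out_dir = raw$out_dir %||% "."
  )
  structure(cfg, class = "run_config")
}

config_as_list <- function(cfg) {
  p <- cfg$protocol
  list(network_file = if (is.na(cfg$network_file)) NULL else cfg$network_file,
       phenotype = cfg$phenotype,
       protocol = list(
         name = p$name, cycle_h = p$cycle_h, n_cycles = p$n_cycles,
         ir_dose_per_day = if (is.na(p$ir_dose_per_day)) NULL else
           p$ir_dose_per_day,
         inhibitor = list(mode = p$mode, dose = p$inh_dose,
                          offsets_h = p$offsets_h)),
       engine = cfg$engine, seed = cfg$seed, n_cells = cfg$n_cells,
       omega = cfg$omega, horizon_h = cfg$horizon_h, rtol = cfg$rtol,
       tol = cfg$tol, specificity = cfg$specificity,
       irradiation_ratio = cfg$irradiation_ratio, out_dir = cfg$out_dir)
}

#' Write run outputs with provenance and a checksum manifest
#'
#' Writes each result to `dir` (trajectories as CSV, tables as TSV), plus a
#' `provenance.json` carrying the full config, seeds and package version,
#' and a `MANIFEST.tsv` listing every written file with its MD5 checksum.
#' Numeric output keeps full precision (15 significant digits) so files
#' reload bit-identically.
#'
#' @param results named list; each element may be a `trajectory` (CSV), a
#'   data.frame (TSV), or an `apoptotic_fraction` / `ir_crit_result`
#'   (single-row TSV).
#' @param dir output directory (created if needed).
#' @param config optional `run_config` recorded in the provenance.
#' @return data.frame manifest (file, md5), invisibly.
#' @export
write_outputs <- function(results, dir, config = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  old <- options(digits = 15); on.exit(options(old))
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "trajectory") || inherits(x, "ssa_run")) {
      f <- file.path(dir, paste0(nm, ".csv"))
      df <- data.frame(time_h = x$time_h, x$state,
                       apoptosis = as.integer(
                         x$committed %||% x$committed_flag %||% FALSE),
                       check.names = FALSE)
      utils::write.csv(format(df, digits = 15, trim = TRUE), f,
                       row.names = FALSE, quote = FALSE)
    } else if (inherits(x, "apoptotic_fraction")) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      df <- data.frame(phenotype = x$phenotype, protocol = x$protocol,
                       n_cells = x$n_cells, n_apoptotic = x$n_apoptotic,
                       fraction = x$fraction, ci_lo = x$ci[1],
                       ci_hi = x$ci[2], horizon_h = x$horizon_h,
                       seed = x$seed)
      utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (inherits(x, "ir_crit_result")) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      df <- data.frame(phenotype = x$phenotype, protocol = x$protocol,
                       ir_crit = x$ir_crit, lo = x$lo, hi = x$hi,
                       tol = x$tol)
      utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(format(x, digits = 15, trim = TRUE), f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    } else {
      stop("unsupported result type for '", nm, "': ", class(x)[1])
    }
    files <- c(files, f)
  }
  prov <- file.path(dir, "provenance.json")
  jsonlite::write_json(list(
    package = "p53combo",
    version = as.character(utils::packageVersion("p53combo")),
    config = if (is.null(config)) NULL else config_as_list(config),
    written = basename(files)),
    prov, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, prov)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
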