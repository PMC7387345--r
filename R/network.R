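## Reaction-network container: one declarative table of species and reactions
## compiled into the structures both engines (ODE fluxes, SSA propensities)
## evaluate, so the two engines can never drift apart.

SPECIES_ROLES <- c("mRNA", "protein", "protein-complex", "DNA-state",
                   "damage-lesion", "drug-pool")

#' Build a compiled reaction network
#'
#' Compiles the declarative network definition (species table + reaction
#' table + parameter set) into a network object holding the stoichiometry
#' matrix and per-reaction rate-law structures used by both the deterministic
#' and the stochastic engine.
#'
#' Every rate constant referenced by a reaction must be present in `params`;
#' a missing constant is an error naming the parameter (no silent defaults).
#'
#' @param params named numeric vector of rate constants (per-second units);
#'   defaults to [default_parameters()].
#' @param definition network definition as returned by
#'   [network_definition()] or [read_network_tsv()]: a list with elements
#'   `species` and `reactions`.
#' @return an object of class `p53_network`.
#' @seealso [apply_phenotype()], [deterministic_rates()],
#'   [stochastic_propensities()]
#' @export
build_network <- function(params = default_parameters(),
                          definition = network_definition()) {
  stopifnot(is.list(definition), !is.null(definition$species),
            !is.null(definition$reactions))
  sp <- definition$species
  rx <- definition$reactions

  if (anyDuplicated(sp$name))
    stop("duplicate species names: ",
         paste(unique(sp$name[duplicated(sp$name)]), collapse = ", "))
  if (!all(sp$role %in% SPECIES_ROLES))
    stop("unknown species role: ",
         paste(setdiff(sp$role, SPECIES_ROLES), collapse = ", "))
  if (any(sp$init < 0)) stop("negative initial amount for species: ",
                             paste(sp$name[sp$init < 0], collapse = ", "))
  if (!is.numeric(params) || is.null(names(params)))
    stop("params must be a named numeric vector")
  if (any(!is.finite(params)) || any(params < 0))
    stop("non-finite or negative parameter: ",
         paste(names(params)[!is.finite(params) | params < 0], collapse = ", "))

  idx_of <- function(name, where) {
    i <- match(name, sp$name)
    if (any(is.na(i)))
      stop("reaction '", where, "' references unknown species: ",
           paste(name[is.na(i)], collapse = ", "))
    i
  }
  par_of <- function(name, where) {
    if (!name %in% names(params))
      stop("missing parameter '", name, "' required by reaction '", where, "'")
    name
  }

  compiled <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    re <- parse_species_terms(r$reactants)
    pr <- parse_species_terms(r$products)
    ra <- parse_species_terms(r$rate)
    hl <- parse_hill_term(r$hill)
    rec <- list(
      id       = r$id,
      k_param  = par_of(r$k, r$id),
      fac      = as.numeric(r$fac),
      rate_idx = idx_of(names(ra), r$id),
      rate_pow = unname(ra),
      re_idx   = idx_of(names(re), r$id),
      re_st    = unname(re),
      pr_idx   = idx_of(names(pr), r$id),
      pr_st    = unname(pr),
      hill_idx = if (is.null(hl)) integer(0) else
                   idx_of(vapply(hl, `[[`, character(1), "species"), r$id),
      hill_K   = if (is.null(hl)) character(0) else
                   vapply(hl, function(t) par_of(t$K, r$id), character(1)),
      hill_h   = if (is.null(hl)) numeric(0) else
                   vapply(hl, `[[`, numeric(1), "h"),
      pk       = isTRUE(as.logical(r$pk))
    )
    if (any(rec$re_st <= 0) || any(rec$pr_st <= 0) ||
        any(rec$re_st != round(rec$re_st)) || any(rec$pr_st != round(rec$pr_st)))
      stop("non-positive or non-integer stoichiometry in reaction '", r$id, "'")
    compiled[[i]] <- rec
  }

  S <- matrix(0, nrow(sp), nrow(rx), dimnames = list(sp$name, rx$id))
  for (i in seq_along(compiled)) {
    rec <- compiled[[i]]
    if (length(rec$re_idx)) S[rec$re_idx, i] <- S[rec$re_idx, i] - rec$re_st
    if (length(rec$pr_idx)) S[rec$pr_idx, i] <- S[rec$pr_idx, i] + rec$pr_st
  }

  net <- structure(list(
    species    = sp,
    reactions  = rx,
    compiled   = compiled,
    params     = params,
    stoich     = S,
    phenotype  = "nominal"
  ), class = "p53_network")
  net
}

parse_species_terms <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  vals <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  stats::setNames(vals, vapply(parts, `[[`, character(1), 1))
}

parse_hill_term <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(term) {
    p <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(p) != 3) stop("malformed hill term: ", term)
    list(species = p[1], K = p[2], h = as.numeric(p[3]))
  })
}

deparse_species_terms <- function(v) {
  if (!length(v)) return("")
  paste(sprintf("%s:%g", names(v), unname(v)), collapse = ",")
}

#' @export
print.p53_network <- function(x, ...) {
  cat("p53 pathway reaction network (", x$phenotype, " phenotype)\n", sep = "")
  cat("  species:   ", nrow(x$species), "\n", sep = "")
  cat("  reactions: ", nrow(x$reactions), "\n", sep = "")
  cat("  s_1 (Wip1 transcription):", x$params[["s_1"]], "mRNA/s\n")
  cat("  s_2 (PTEN transcription):", x$params[["s_2"]], "mRNA/s\n")
  invisible(x)
}

#' Define a cell phenotype
#'
#' A phenotype rescales the Wip1 (`s_1`) and PTEN (`s_2`) transcription rate
#' coefficients of the nominal network and, for normal cells, reduces the
#' inhibitor-Mdm2 association rate constant `ka_inh` by the uptake
#' specificity divisor (cancer cells are assumed to take the inhibitor up
#' 1x, 3x or 10x faster than normal tissue; doses are always quoted with
#' respect to cancer cells).
#'
#' @param label one of `"normal"`, `"wip1_cancer"`, `"pten_cancer"`,
#'   `"custom"`. `"wip1_cancer"` means fivefold increased Wip1 transcription;
#'   `"pten_cancer"` fivefold reduced PTEN transcription.
#' @param s1_multiplier,s2_multiplier positive multipliers for the Wip1/PTEN
#'   transcription rates (defaulted from `label`).
#' @param uptake_specificity divisor applied to `ka_inh` for normal cells
#'   (1, 3 or 10); ignored for cancer phenotypes.
#' @return an object of class `cell_phenotype`.
#' @export
cell_phenotype <- function(label = c("normal", "wip1_cancer", "pten_cancer",
                                     "custom"),
                           s1_multiplier = NULL, s2_multiplier = NULL,
                           uptake_specificity = 1) {
  label <- match.arg(label)
  defaults <- switch(label,
    normal      = c(1, 1),
    wip1_cancer = c(5, 1),
    pten_cancer = c(1, 0.2),
    custom      = c(1, 1))
  if (is.null(s1_multiplier)) s1_multiplier <- defaults[1]
  if (is.null(s2_multiplier)) s2_multiplier <- defaults[2]
  if (!is.numeric(s1_multiplier) || s1_multiplier <= 0 ||
      !is.numeric(s2_multiplier) || s2_multiplier <= 0)
    stop("phenotype multipliers must be positive")
  if (label == "normal" && (s1_multiplier != 1 || s2_multiplier != 1))
    stop("the normal phenotype has unit multipliers by definition")
  if (!uptake_specificity %in% c(1, 3, 10))
    warning("uptake specificity ", uptake_specificity,
            " is outside the standard set {1, 3, 10}")
  structure(list(label = label,
                 s1_multiplier = s1_multiplier,
                 s2_multiplier = s2_multiplier,
                 uptake_specificity = uptake_specificity),
            class = "cell_phenotype")
}

#' Specialize a network for a cell phenotype
#'
#' Returns a copy of the network with `s_1 <- s_1 * s1_multiplier`,
#' `s_2 <- s_2 * s2_multiplier`, and for the normal phenotype
#' `ka_inh <- ka_inh / uptake_specificity`. The input network is untouched.
#'
#' @param network a `p53_network`.
#' @param phenotype a [cell_phenotype()].
#' @return a new `p53_network`.
#' @export
apply_phenotype <- function(network, phenotype) {
  stopifnot(inherits(network, "p53_network"),
            inherits(phenotype, "cell_phenotype"))
  if (phenotype$s1_multiplier <= 0 || phenotype$s2_multiplier <= 0)
    stop("phenotype multipliers must be positive")
  net <- network
  net$params[["s_1"]] <- net$params[["s_1"]] * phenotype$s1_multiplier
  net$params[["s_2"]] <- net$params[["s_2"]] * phenotype$s2_multiplier
  if (phenotype$label == "normal")
    net$params[["ka_inh"]] <- net$params[["ka_inh"]] / phenotype$uptake_specificity
  net$phenotype <- phenotype$label
  net
}

## Evaluate one reaction's rate-law factor (shared between flux and
## propensity up to mass-action combinatorics).
rate_constant <- function(net, rec) {
  unname(net$params[[rec$k_param]]) * rec$fac
}

hill_factor <- function(net, rec, state) {
  if (!length(rec$hill_idx)) return(1)
  f <- 1
  for (j in seq_along(rec$hill_idx)) {
    m <- state[rec$hill_idx[j]]
    if (m <= 0) return(0)
    K <- unname(net$params[[rec$hill_K[j]]])
    h <- rec$hill_h[j]
    f <- f * m^h / (K^h + m^h)
  }
  f
}

#' Deterministic reaction fluxes
#'
#' Evaluates the mass-action / Hill rate laws at a (continuous, non-negative)
#' state, returning one flux per reaction. The ODE right-hand side is the
#' stoichiometry matrix times this vector.
#'
#' @param network a `p53_network`.
#' @param state numeric vector of amounts (copies/cell), named or in species
#'   order.
#' @return numeric vector of fluxes, one per reaction, all non-negative.
#' @export
deterministic_rates <- function(network, state) {
  state <- as_state_vector(network, state)
  if (any(state < 0)) stop("negative state entry: ",
                           paste(network$species$name[state < 0], collapse = ", "))
  vapply(network$compiled, function(rec) {
    f <- rate_constant(network, rec) * hill_factor(network, rec, state)
    if (length(rec$rate_idx))
      f <- f * prod(state[rec$rate_idx]^rec$rate_pow)
    f
  }, numeric(1))
}

#' Stochastic reaction propensities
#'
#' Like [deterministic_rates()] but on integer copy numbers, with proper
#' mass-action combinatorics (a reactant entering with stoichiometry n
#' contributes the falling factorial `X(X-1)...(X-n+1)/n!`) and a hard zero
#' whenever a consumed reactant count is insufficient. Species with role
#' `drug-pool` are continuous (macroscopic blood amounts) and exempt from
#' the integrality check.
#'
#' @inheritParams deterministic_rates
#' @return numeric vector of propensities, one per reaction.
#' @export
stochastic_propensities <- function(network, state) {
  state <- as_state_vector(network, state)
  if (any(state < 0)) stop("negative copy number")
  discrete <- network$species$role != "drug-pool"
  if (any(state[discrete] != round(state[discrete])))
    stop("non-integer copy number for species: ",
         paste(network$species$name[discrete & state != round(state)],
               collapse = ", "))
  vapply(network$compiled, function(rec) {
    if (length(rec$re_idx) && any(state[rec$re_idx] < rec$re_st)) return(0)
    a <- rate_constant(network, rec) * hill_factor(network, rec, state)
    if (length(rec$rate_idx)) {
      for (j in seq_along(rec$rate_idx)) {
        si <- rec$rate_idx[j]
        n <- rec$rate_pow[j]
        x <- state[si]
        ## combinatoric form only where the species is consumed with the
        ## same multiplicity (true mass action); modifiers enter linearly
        consumed <- match(si, rec$re_idx)
        if (!is.na(consumed) && n > 1 && n == rec$re_st[consumed]) {
          a <- a * prod(x - seq_len(n) + 1)
        } else {
          a <- a * x^n
        }
      }
    }
    a
  }, numeric(1))
}

as_state_vector <- function(network, state) {
  nm <- network$species$name
  if (!is.null(names(state))) {
    missing <- setdiff(nm, names(state))
    if (length(missing)) stop("state missing species: ",
                              paste(missing, collapse = ", "))
    state <- state[nm]
  }
  if (length(state) != nrow(network$species))
    stop("state length ", length(state), " != species count ",
         nrow(network$species))
  unname(as.numeric(state))
}

#' Initial (resting) state of a network
#'
#' @param network a `p53_network`.
#' @return named numeric vector of initial amounts.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$init, network$species$name)
}

#' Write / read the declarative network definition as TSV
#'
#' The definition file has three tab-separated sections introduced by
#' `#! species`, `#! reactions` and `#! parameters` header lines; it is the
#' versioned, human-readable single source of the model.
#'
#' @param network a `p53_network` (or a definition list plus `params`).
#' @param path file path.
#' @return `write_network_tsv` returns `path` invisibly; `read_network_tsv`
#'   returns a list with `species`, `reactions` and `params` suitable for
#'   [build_network()].
#' @export
write_network_tsv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! species", con)
  utils::write.table(network$species, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("#! reactions", con)
  utils::write.table(network$reactions, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("#! parameters", con)
  pdf <- data.frame(name = names(network$params),
                    value = format(unname(network$params), digits = 17))
  utils::write.table(pdf, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  marks <- grep("^#! ", lines)
  if (length(marks) != 3) stop("expected three '#!' section headers in ", path)
  section <- function(i) {
    from <- marks[i] + 1
    to <- if (i < 3) marks[i + 1] - 1 else length(lines)
    utils::read.table(text = lines[from:to], sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = NULL,
                      colClasses = NA)
  }
  sp <- section(1)
  sp$init <- as.numeric(sp$init)
  rx <- section(2)
  for (col in c("rate", "hill", "reactants", "products"))
    rx[[col]] <- ifelse(is.na(rx[[col]]), "", as.character(rx[[col]]))
  pa <- section(3)
  list(species = sp, reactions = rx,
       params = stats::setNames(as.numeric(pa$value), pa$name))
}
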