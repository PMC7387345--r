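## Bridge between the R-level network object and the compiled evaluator.

compile_for_engine <- function(network) {
  stopifnot(inherits(network, "p53_network"))
  sp <- network$species
  p <- network$params
  getp <- function(name, default = 0) {
    if (name %in% names(p)) unname(p[[name]]) else default
  }
  rxs <- lapply(network$compiled, function(rec) {
    list(
      k        = unname(network$params[[rec$k_param]]) * rec$fac,
      rate_idx = as.integer(rec$rate_idx - 1L),
      rate_pow = as.numeric(rec$rate_pow),
      hill_idx = as.integer(rec$hill_idx - 1L),
      hill_K   = as.numeric(vapply(rec$hill_K,
                   function(k) unname(network$params[[k]]), numeric(1))),
      hill_h   = as.numeric(rec$hill_h),
      re_idx   = as.integer(rec$re_idx - 1L),
      re_st    = as.integer(rec$re_st),
      pr_idx   = as.integer(rec$pr_idx - 1L),
      pr_st    = as.integer(rec$pr_st),
      pk       = rec$pk
    )
  })
  spec <- list(
    nsp = nrow(sp),
    scaled = as.logical(sp$scalable),
    discrete = sp$role != "drug-pool",
    i_dam = as.integer(match("DNAdam", sp$name, nomatch = 0L) - 1L),
    i_depot = as.integer(match("INHd", sp$name, nomatch = 0L) - 1L),
    i_blood = as.integer(match("INHb", sp$name, nomatch = 0L) - 1L),
    i_casp = as.integer(match("Casp", sp$name, nomatch = 0L) - 1L),
    d_r1 = getp("d_r1", 1 / 3600),
    d_r2 = getp("d_r2", 0.25 / 3600),
    k_dsb = getp("k_dsb", 0),
    casp_thresh = getp("casp_thresh", Inf),
    reactions = rxs
  )
  compile_network_cpp(spec)
}

## events in engine form (seconds, integer type codes)
engine_events <- function(protocol) {
  ev <- event_schedule(protocol)
  list(time = hours_to_seconds(ev$time_h),
       type = as.integer(match(ev$kind, c("irradiate", "dose_inhibitor",
                                          "infusion_on")) - 1L),
       mag = ev$magnitude)
}
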