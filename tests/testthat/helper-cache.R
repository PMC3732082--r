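# Shared fixtures: the wild-type model and the expensive simulations are
# computed once per test session and memoized here.

rc_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = rc_cache)) assign(key, force(expr), envir = rc_cache)
  get(key, envir = rc_cache)
}

wt_model <- function() memo("wt_model", build_rod_model())

# saturating 118,000 R* flash with full species trajectories
sat_trace <- function() memo("sat_trace", {
  run_protocol(wt_model(), stimulus_protocol("flash", 118000),
               horizon = 20, dt = 2e-3, auto_extend = FALSE)
})

sat_trace_oligo_off <- function() memo("sat_trace_oligo_off", {
  net <- apply_mutant(wt_model(), mutant_spec(oligomerization_off = TRUE))
  run_protocol(net, stimulus_protocol("flash", 118000),
               horizon = 20, dt = 2e-3, auto_extend = FALSE)
})

# standardized saturation-time ladder per genotype (first four saturating
# points kept, as used by the Pepperberg procedure)
genotype_ladder <- function(name, spec) {
  memo(paste0("ladder_", name), {
    net <- if (length(spec$factors) || spec$oligomerization_off)
      apply_mutant(wt_model(), spec) else wt_model()
    tsat_ladder(net, pepperberg_strengths(), max_saturating = 4, dt = 2e-3)
  })
}

sweep_tau_d <- function(genotypes = table1_genotypes()) {
  vals <- vapply(names(genotypes), function(g) {
    lad <- genotype_ladder(g, genotypes[[g]])
    pepperberg_fit(lad$strength, lad$tsat)$tau_D
  }, numeric(1))
  tibble::tibble(genotype = names(genotypes), tau_d_s = unname(vals),
                 tau_d_norm = unname(vals) / vals[["WT"]])
}

# simple toy networks used by the model-core tests
toy_decay <- function(k = 1) {
  rod_network(
    species = tibble::tibble(name = c("A", "B"), initial = c(1, 0), unit = "count"),
    reactions = list(mass_action("decay", k, c(A = 1), c(B = 1))),
    conservation = list(total = c(A = 1, B = 1)))
}

toy_dimer <- function(kf = 2, kr = 0.5, A0 = 10) {
  rod_network(
    species = tibble::tibble(name = c("A", "A2"), initial = c(A0, 0), unit = "count"),
    reactions = list(mass_action("dim", kf, c(A = 2), c(A2 = 1)),
                     mass_action("undim", kr, c(A2 = 1), c(A = 2))),
    conservation = list(total = c(A = 1, A2 = 2)))
}
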