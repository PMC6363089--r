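# Shared fixtures, memoised so expensive objects are built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

cbb_fixture <- function() {
  memo("cbb", {
    m <- cbb_model()
    set_fluxes(m, generate_flux_vector(m))
  })
}

# a small batch of feasible metabolomes for unit tests
fmcs_fixture <- function() {
  memo("fmcs", {
    m <- cbb_fixture()
    generate_fmcs(m, default_ranges(m), max_rounds = 4e5, target = 25, seed = 42)
  })
}

# the reduced-scale reference ensemble shared by the acceptance-style tests:
# 100 fMCS x 200 parameter sets
reference_ensemble <- function() {
  memo("ensemble", {
    m <- cbb_fixture()
    fm <- memo("fmcs100",
               generate_fmcs(m, default_ranges(m), max_rounds = 2e6,
                             target = 100, seed = 20181027))
    sample_ensemble(m, fm, sets_per_fmcs = 200, seed = 1, fcc = TRUE,
                    saturation = FALSE)
  })
}

reference_fmcs100 <- function() {
  reference_ensemble()
  memo("fmcs100", stop("built by reference_ensemble"))
}

# one calibrated parameter set on the first feasible metabolome
calibrated_set <- function(seed = 7, i = 1) {
  m <- cbb_fixture()
  fm <- fmcs_fixture()
  conc <- fmcs_concentrations(m, fm, i)
  ps <- sample_parameter_set(m, conc, seed = seed, fmcs_index = i)
  list(model = m, conc = conc, params = calibrate_vmax(m, ps, conc))
}

# tiny closed-loop definition: A -> B -> A (one conserved total)
loop_definition <- function() {
  list(name = "loop",
       metabolites = list(
         list(id = "A", role = "balanced", conc_min = 0.1, conc_max = 10),
         list(id = "B", role = "balanced", conc_min = 0.1, conc_max = 10),
         list(id = "PPool", role = "phosphate-pool")),
       reactions = list(
         list(id = "f", stoichiometry = list(A = -1, B = 1),
              rate_law = "reversible-MM", dG0_prime = -5),
         list(id = "b", stoichiometry = list(B = -1, A = 1),
              rate_law = "reversible-MM", dG0_prime = -5)))
}

# open three-step chain with fully determined (full-rank) stoichiometry
open_chain_definition <- function() {
  list(name = "open_chain",
       metabolites = list(
         list(id = "S0", role = "boundary-unbalanced", conc_min = 1, conc_max = 1),
         list(id = "A", role = "balanced", conc_min = 0.1, conc_max = 10),
         list(id = "B", role = "balanced", conc_min = 0.1, conc_max = 10),
         list(id = "Out", role = "sink-pool"),
         list(id = "PPool", role = "phosphate-pool")),
       reactions = list(
         list(id = "r1", stoichiometry = list(S0 = -1, A = 1),
              rate_law = "irreversible-MM"),
         list(id = "r2", stoichiometry = list(A = -1, B = 1),
              rate_law = "reversible-MM", dG0_prime = -5),
         list(id = "r3", stoichiometry = list(B = -1, Out = 1),
              rate_law = "irreversible-MM")))
}
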