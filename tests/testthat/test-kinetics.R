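make_ab_model <- function(keq = 2) {
  def <- two_metabolite_definition()
  def$reactions[[1]]$dG0_prime <- -8.314e-3 * 298.15 * log(keq)
  build_network(def)
}

# A <-> B with explicit constants; concentrations in the same (mM) units as K
ab_params <- function(m, KA = 1, KB = 1, vmax = 1) {
  K <- numeric(m$kin$n_K)
  r <- m$kin$rxn[[1]]
  K[r$km_sub] <- KA; K[r$km_prod] <- KB
  structure(list(K = K, vmax = vmax), class = "parameter_set")
}

test_that("the reversible rate law reproduces hand-computed values", {
  m <- make_ab_model(keq = 2)
  ps <- ab_params(m)
  # note Q uses molar units; choose A, B so the mM/M factor cancels: B/A ratio
  v <- reaction_rates(m, ps, c(A = 1, B = 0.5))
  expect_equal(as.numeric(v), 1 * 1 * (1 - 0.25) / (1 + 1 + 0.5), tolerance = 1e-12)
  # equilibrium: B = A * Keq gives zero rate
  expect_equal(as.numeric(reaction_rates(m, ps, c(A = 1, B = 2))), 0,
               tolerance = 1e-14)
  # saturation limit: A >> K_A, B ~ 0
  v <- reaction_rates(m, ps, c(A = 1e8, B = 1e-8))
  expect_equal(as.numeric(v), 1, tolerance = 1e-6)
})

test_that("sign of the rate follows the thermodynamic driving force", {
  m <- make_ab_model(keq = 2)
  set.seed(99)
  for (i in 1:200) {
    ps <- ab_params(m, KA = runif_log10(1, 1e-3, 1e3),
                    KB = runif_log10(1, 1e-3, 1e3), vmax = runif_log10(1, .1, 10))
    A <- runif_log10(1, 1e-3, 1e3); B <- runif_log10(1, 1e-3, 1e3)
    v <- as.numeric(reaction_rates(m, ps, c(A = A, B = B)))
    drive <- 1 - (B / A) / 2
    if (abs(drive) > 1e-12) expect_identical(sign(v), sign(drive))
  }
})

test_that("saturation fractions map the K sampling bounds onto 1-99%", {
  expect_equal(saturation_fraction(1, 0.01), 1 / 1.01)          # 99.0%
  expect_equal(saturation_fraction(1, 100), 1 / 101)            # 0.99%
  expect_equal(saturation_fraction(1, 1), 0.5)
  expect_error(saturation_fraction(-1, 1))
})

test_that("parameter sampling spans [0.01, 100] x concentration in log space", {
  m <- cbb_fixture()
  fm <- fmcs_fixture()
  conc <- fmcs_concentrations(m, fm, 1)
  draws <- sapply(1:400, function(k)
    sample_parameter_set(m, conc, seed = k)$K)
  cmet <- conc[m$kin$constants$metabolite]
  rat <- sweep(draws, 1, cmet, "/")
  expect_gte(min(rat), 0.01)
  expect_lte(max(rat), 100)
  # log10 ratios cover the range roughly uniformly
  expect_lt(max(abs(rowMeans(log10(rat)))), 1.0)
  # determinism
  expect_identical(sample_parameter_set(m, conc, seed = 5)$K,
                   sample_parameter_set(m, conc, seed = 5)$K)
})

test_that("the shared SBP constant appears in both SBPase and FBPase slots", {
  m <- cbb_fixture()
  ct <- m$kin$constants
  sbp_idx <- ct$index[ct$reaction == "SBPase" & ct$metabolite == "SBP" &
                        ct$kind == "KM"]
  fb <- m$kin$rxn[[match("FBPase", m$reaction_ids)]]
  expect_true(sbp_idx %in% fb$comp_k)
  # and no FBPase-owned constant exists for SBP
  expect_false(any(ct$reaction == "FBPase" & ct$metabolite == "SBP"))
})

test_that("Vmax calibration reproduces the input flux exactly", {
  m <- make_ab_model(keq = 2)
  ps <- ab_params(m)
  conc <- c(A = 1, B = 0.5)
  f <- as.numeric(normalized_rates(m, ps$K, conc))
  expect_equal(f, 0.3, tolerance = 1e-12)
  cal <- calibrate_vmax(m, ps, conc, v0 = c(r1 = 0.06))
  expect_equal(cal$vmax, 0.06 / 0.3, tolerance = 1e-12)   # = 0.2
  expect_equal(as.numeric(reaction_rates(m, cal, conc)), 0.06, tolerance = 1e-12)
})

test_that("calibration on feasible CBB states hits every input flux and S v = 0", {
  m <- cbb_fixture()
  fm <- fmcs_fixture()
  for (i in seq_len(min(10, fm$n))) {
    conc <- fmcs_concentrations(m, fm, i)
    ps <- calibrate_vmax(m, sample_parameter_set(m, conc, seed = i), conc)
    v <- reaction_rates(m, ps, conc)
    expect_lt(max(abs(v - m$v0) / m$v0), 1e-10)
    expect_lt(max(abs(m$S %*% v)), 1e-9 * max(abs(m$v0)))
  }
})

test_that("competitive inhibitors slow the rate; allosteric activators speed it", {
  def <- two_metabolite_definition()
  def$metabolites <- c(def$metabolites,
                       list(list(id = "I", role = "boundary-unbalanced",
                                 conc_min = 0.01, conc_max = 10),
                            list(id = "X", role = "boundary-unbalanced",
                                 conc_min = 0.01, conc_max = 10)))
  def$reactions[[1]]$dG0_prime <- -10
  def$reactions[[1]]$regulators <- list(
    list(metabolite = "I", mode = "competitive-inhibitor"),
    list(metabolite = "X", mode = "allosteric-activator"))
  m <- build_network(def)
  K <- rep(1, m$kin$n_K)
  ps <- structure(list(K = K, vmax = 1), class = "parameter_set")
  set.seed(4)
  for (rep in 1:50) {
    base <- full_concentrations(
      m, c(A = runif_log10(1, .01, 10), B = runif_log10(1, .01, 10),
           I = 1, X = 1))
    v0 <- abs(reaction_rates(m, ps, base)[["r1"]])
    up_i <- base; up_i["I"] <- 5
    up_x <- base; up_x["X"] <- 5
    expect_lt(abs(reaction_rates(m, ps, up_i)[["r1"]]), v0)
    expect_gt(abs(reaction_rates(m, ps, up_x)[["r1"]]), v0)
  }
})

test_that("tidy export lists every constant once plus Vmax rows", {
  cs <- calibrated_set()
  tab <- as.data.frame(cs$params, cs$model)
  expect_equal(sum(tab$kind != "Vmax"), cs$model$counts$n_K)
  expect_equal(sum(tab$kind == "Vmax"), 29)
  expect_true(all(tab$value > 0))
})
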