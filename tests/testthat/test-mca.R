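test_that("zero-order supply with first-order drain gives C_X = +1 / -1", {
  # classic two-step system: v1 constant, v2 = k X
  def <- list(name = "supply_drain",
              metabolites = list(
                list(id = "S0", role = "boundary-unbalanced", conc_min = 1, conc_max = 1),
                list(id = "X", role = "balanced", conc_min = 0.1, conc_max = 10),
                list(id = "Out", role = "sink-pool"),
                list(id = "PPool", role = "phosphate-pool")),
              reactions = list(
                list(id = "supply", stoichiometry = list(S0 = -1, X = 1),
                     rate_law = "irreversible-MM"),
                list(id = "drain", stoichiometry = list(X = -1, Out = 1),
                     rate_law = "irreversible-MM")))
  m <- build_network(def)
  K <- numeric(m$kin$n_K)
  K[m$kin$rxn[[1]]$km_sub] <- 1e-9
  K[m$kin$rxn[[2]]$km_sub] <- 1e9
  m <- set_fluxes(m, c(supply = 1, drain = 1))
  conc <- full_concentrations(m, c(X = 1))
  ps <- calibrate_vmax(m, structure(list(K = K, vmax = rep(NA_real_, 2)),
                                    class = "parameter_set"), conc)
  cc <- control_coefficients(m, ps, conc)
  expect_equal(cc$C_X["X", "supply"], 1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(cc$C_X["X", "drain"], -1, tolerance = 1e-6, ignore_attr = TRUE)
  # zero-order first step holds all flux control
  expect_equal(unname(cc$C_J[, "supply"]), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(cc$C_J[, "drain"]), c(0, 0), tolerance = 1e-6)
})

test_that("toy-chain control coefficients match closed forms to 3 significant figures", {
  for (n in c(2, 4, 6)) {
    toy <- toy_linear_chain(n, "first-order",
                            rate_constants = seq(0.5, 3, length.out = n))
    ps <- structure(list(K = toy$K, vmax = toy$vmax), class = "parameter_set")
    cc <- control_coefficients(toy$model, ps, toy$X0)
    expect_equal(cc$C_J, toy$reference$fcc, tolerance = 5e-4)
    k <- seq(0.5, 3, length.out = n)
    expect_equal(unname(cc$C_J[1, ]), (1 / k) / sum(1 / k), tolerance = 5e-4)
  }
  toy <- toy_linear_chain(1, "first-order")
  ps <- structure(list(K = toy$K, vmax = toy$vmax), class = "parameter_set")
  cc <- control_coefficients(toy$model, ps, toy$X0)
  expect_equal(as.numeric(cc$C_J), 1)   # self-control of a single reaction
})

test_that("summation theorems hold for every computed CBB set", {
  m <- cbb_fixture()
  fm <- fmcs_fixture()
  done <- 0; k <- 0
  while (done < 8 && k < 60) {
    k <- k + 1
    i <- (k %% fm$n) + 1
    conc <- fmcs_concentrations(m, fm, i)
    ps <- calibrate_vmax(m, sample_parameter_set(m, conc, seed = 300 + k,
                                                 fmcs_index = i), conc)
    st <- classify_stability(m, elasticity_matrix(m, ps, conc))
    if (!st$stable) next
    cc <- control_coefficients(m, ps, conc)
    expect_lt(max(abs(rowSums(cc$C_J) - 1)), 1e-6)
    expect_lt(max(abs(rowSums(cc$C_X))), 1e-6)
    done <- done + 1
  }
  expect_gte(done, 5)
})

test_that("connectivity theorem holds on the toy chain", {
  toy <- toy_linear_chain(4, "first-order")
  ps <- structure(list(K = toy$K, vmax = toy$vmax), class = "parameter_set")
  m <- toy$model
  cc <- control_coefficients(m, ps, toy$X0)
  E <- elasticity_matrix(m, ps, toy$X0)
  bal <- m$metabolites$role == "balanced"
  # scaled elasticities: eps[j, i] = E[j, i] * X_i / v_j
  eps <- sweep(sweep(E[, bal, drop = FALSE], 2, toy$X0[bal], "*"),
               1, as.numeric(m$v0), "/")
  conn <- cc$C_J %*% eps     # targets x metabolites; each column ~ 0
  expect_lt(max(abs(conn)), 1e-5)
})

test_that("Eq-based control coefficients match the re-equilibration oracle", {
  m <- cbb_fixture()
  fm <- fmcs_fixture()
  done <- 0; k <- 0
  while (done < 5 && k < 40) {
    k <- k + 1
    i <- (k %% fm$n) + 1
    conc <- fmcs_concentrations(m, fm, i)
    ps <- calibrate_vmax(m, sample_parameter_set(m, conc, seed = 700 + k,
                                                 fmcs_index = i), conc)
    st <- classify_stability(m, elasticity_matrix(m, ps, conc))
    if (!st$stable) next
    cc <- control_coefficients(m, ps, conc)
    e <- (k %% 29) + 1
    fd <- fcc_finite_difference_oracle(m, ps, conc, e)
    if (is.null(fd)) next
    big <- abs(cc$C_J[, e]) > 1e-3
    expect_lt(max(abs(fd[big] - cc$C_J[big, e]) / abs(cc$C_J[big, e])), 0.01)
    done <- done + 1
  }
  expect_gte(done, 3)
})

test_that("the oracle is first-order consistent in delta", {
  toy <- toy_linear_chain(3, "first-order")
  ps <- structure(list(K = toy$K, vmax = toy$vmax), class = "parameter_set")
  f1 <- fcc_finite_difference_oracle(toy$model, ps, toy$X0, 2, delta = 1e-3)
  f2 <- fcc_finite_difference_oracle(toy$model, ps, toy$X0, 2, delta = 5e-4)
  expect_lt(max(abs(f1 - f2)), 1e-5)
  # single open reaction: self-control is exactly 1
  toy1 <- toy_linear_chain(1, "zero-order-supply")
  ps1 <- structure(list(K = toy1$K, vmax = toy1$vmax), class = "parameter_set")
  f <- fcc_finite_difference_oracle(toy1$model, ps1, toy1$X0, 1)
  expect_equal(as.numeric(f), 1, tolerance = 1e-9)
})

test_that("control analysis refuses unstable states and tallies singular ones", {
  m <- build_network(open_chain_definition())
  E <- matrix(0, 3, 2, dimnames = list(m$reaction_ids, c("A", "B")))
  E["r2", "A"] <- -1; E["r3", "B"] <- 2   # spectrum {1, -2}: unstable
  st <- classify_stability(m, E)
  m <- set_fluxes(m, c(r1 = 1, r2 = 1, r3 = 1))
  expect_error(concentration_control(m, st, full_concentrations(m, c(A = 1, B = 1))),
               "stable")
})
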