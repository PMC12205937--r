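test_that("driving-force expressions evaluate per the thermodynamic model", {
  model <- toy_model(toy_spec(n_chain = 1, dG0_list = -10))
  cfg <- thermo_config()
  RT <- cfg$R * cfg$T
  expr <- build_driving_forces(model, cfg)

  # equal concentrations: the concentration term cancels
  ln_eq <- c(glc = log(1e-4), c1 = log(1e-4))
  expect_equal(unname(cofactory:::eval_driving_forces(expr, ln_eq)["R1"]), 10)

  # substrate high, product low: Df = 10 + RT ln(1e4)
  ln <- c(glc = log(1e-2), c1 = log(1e-6))
  expect_equal(unname(cofactory:::eval_driving_forces(expr, ln)["R1"]),
               10 + RT * log(1e4))

  # a reaction and its reverse have opposite driving forces at any C
  m2 <- toy_model(toy_spec(include_reverse_pair = TRUE, reverse_dG0 = 7.3))
  e2 <- build_driving_forces(m2, cfg)
  for (lnc in list(c(rp1 = log(1e-3), rp2 = log(1e-5)),
                   c(rp1 = log(2e-6), rp2 = log(9e-3)))) {
    dfs <- cofactory:::eval_driving_forces(e2[c("atoDA", "atoDA_reverse")], lnc)
    expect_equal(unname(dfs[1]), -unname(dfs[2]))
  }

  model$reactions[["R1"]]$dG0_prime <- NA_real_
  expect_error(build_driving_forces(model, cfg), "missing dG0_prime")
})

test_that("growth maximization respects uptake, enzyme-pool and thermodynamic limits", {
  model <- toy_model(toy_spec(uptake_bound = 10))
  expect_equal(fba_max_growth(model)$objective_value, 10)

  # enzyme pool binds growth at pool * kcat / mw = 6
  mk <- attach_kinetics(
    model, data.frame(reaction_id = "BIOMASS", kcat_per_h_per_g = 600,
                      mw_g_per_mmol = 1), enzyme_pool = 0.01)
  sol <- fba_max_growth(mk, solve_options(use_kinetic = TRUE))
  expect_equal(sol$objective_value, 6, tolerance = 1e-9)

  # thermodynamically impossible pathway reaction with forced flux: infeasible
  m3 <- model
  m3$reactions[["R1"]]$dG0_prime <- 100
  m3$reactions[["R1"]]$lb <- 1
  expect_equal(fba_max_growth(m3, solve_options(use_thermo = TRUE))$status,
               "infeasible")

  # same but with relaxable flux: the binary turns the reaction off instead
  m4 <- model
  m4$reactions[["R1"]]$dG0_prime <- 100
  s4 <- fba_max_growth(m4, solve_options(use_thermo = TRUE))
  expect_equal(s4$objective_value, 0)
  expect_equal(unname(s4$z["R1"]), 0L)
  expect_lt(abs(s4$fluxes[["R1"]]), 1e-9)
})

test_that("production maximization trades off against the growth bound", {
  model <- toy_model(toy_spec(uptake_bound = 10))
  expect_equal(max_production(model, 7.5)$fluxes[["PROD"]], 2.5)
  expect_equal(max_production(model, 10)$fluxes[["PROD"]], 0)
  expect_equal(max_production(model, 0)$fluxes[["PROD"]], 10)
  expect_equal(max_production(model, 11)$status, "infeasible")

  # raising the growth bound never increases production
  prods <- vapply(seq(0, 10, by = 2.5), function(g)
    max_production(model, g)$fluxes[["PROD"]], numeric(1))
  expect_true(all(diff(prods) <= 1e-9))
})

test_that("thermodynamic constraints only shrink the feasible set", {
  model <- toy_model(toy_spec(dG0_list = c(-10, -10)))
  plain <- fba_max_growth(model)$objective_value
  thermo <- fba_max_growth(model, solve_options(use_thermo = TRUE))$objective_value
  expect_lte(thermo, plain + 1e-9)

  # non-binding enzyme pool reproduces the unconstrained optimum
  base <- fba_max_growth(model)
  mk <- attach_kinetics(
    model, data.frame(reaction_id = "BIOMASS", kcat_per_h_per_g = 100,
                      mw_g_per_mmol = 1),
    enzyme_pool = base$fluxes[["BIOMASS"]] * 1 / 100)
  sol <- fba_max_growth(mk, solve_options(use_kinetic = TRUE))
  expect_equal(sol$objective_value, base$objective_value, tolerance = 1e-7)
})

test_that("the MDF program matches hand-derived optima and is big-K insensitive", {
  cfg <- thermo_config()
  RT <- cfg$R * cfg$T
  span <- log(1e-2) - log(1e-6)

  m1 <- toy_model(toy_spec(n_chain = 1, dG0_list = -10))
  expect_equal(solve_mdf(m1, "R1")$B, 10 + RT * span, tolerance = 1e-9)

  # two equal steps share the concentration span: B = 10 + RT * span / 2
  m2 <- toy_model(toy_spec(n_chain = 2, dG0_list = c(-10, -10)))
  expect_equal(solve_mdf(m2, c("R1", "R2"))$B, 10 + RT * span / 2,
               tolerance = 1e-9)

  # widening a concentration interval never decreases B
  m2w <- m2
  m2w$metabolites[["c1"]]$ln_conc_ub <- log(1e-1)
  expect_gte(solve_mdf(m2w, c("R1", "R2"))$B, solve_mdf(m2, c("R1", "R2"))$B - 1e-9)

  # reported B is invariant to the big-K constant
  m4 <- toy_model(toy_spec())
  s_a <- fba_max_growth(m4, solve_options(use_thermo = TRUE),
                        thermo_config(big_K = 1000))
  s_b <- fba_max_growth(m4, solve_options(use_thermo = TRUE),
                        thermo_config(big_K = 10000))
  expect_equal(s_a$fluxes, s_b$fluxes, tolerance = 1e-6)
  expect_equal(s_a$B, s_b$B, tolerance = 1e-6)
})

test_that("lexicographic stage reports concentrations within bounds and Df >= B", {
  model <- toy_model(toy_spec(dG0_list = c(-10, -12)))
  sol <- fba_max_growth(model, solve_options(use_thermo = TRUE))
  expect_equal(sol$status, "optimal")
  for (m in names(sol$ln_conc)) {
    expect_gte(sol$ln_conc[[m]], model$metabolites[[m]]$ln_conc_lb - 1e-9)
    expect_lte(sol$ln_conc[[m]], model$metabolites[[m]]$ln_conc_ub + 1e-9)
  }
  active <- names(sol$z)[sol$z == 1]
  expect_true(all(sol$driving_forces[active] >= sol$B - 1e-6))
})
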