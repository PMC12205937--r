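test_that("model construction enforces invariants", {
  expect_error(metabolite("a", ln_conc_lb = 0, ln_conc_ub = -1), "ln_conc_lb")
  expect_error(reaction("r", c(a = 1), lb = 5, ub = 1), "flux_lb")
  expect_error(reaction("r", numeric(0)), "stoich")
  expect_error(
    metabolic_model(list(metabolite("a")),
                    list(reaction("r", c(a = 1, ghost = -1)))),
    "undefined metabolite")
  expect_error(
    metabolic_model(list(metabolite("a")),
                    list(reaction("b1", c(a = -1), role = "biomass"),
                         reaction("b2", c(a = -1), role = "biomass"))),
    "more than one biomass")
})

test_that("JSON round-trip is the identity on the internal representation", {
  model <- toy_model(toy_spec(n_chain = 3, include_reverse_pair = TRUE))
  model <- attach_kinetics(
    model, data.frame(reaction_id = c("PROD", "BIOMASS"),
                      kcat_per_h_per_g = c(6503.76, 557.18),
                      mw_g_per_mmol = c(1, 2)))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  expect_equal(load_model(path), model)
})

test_that("SBML reader recovers species, bounds and the objective reaction", {
  sbml <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="mini">
  <listOfParameters>
   <parameter id="lb0" value="0"/><parameter id="ub10" value="10"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="A" compartment="c"/><species id="B" compartment="c"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_A" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R_bio">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
   </reaction>
   <reaction id="EX_B">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="R_bio" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  model <- load_model(path)
  expect_setequal(names(model$reactions), c("EX_A", "R_bio", "EX_B"))
  expect_equal(model$reactions[["EX_A"]]$ub, 10)
  expect_equal(reactions_by_role(model, "biomass"), "R_bio")
  expect_equal(fba_max_growth(model)$objective_value, 10)

  bad <- sub('species="A" stoichiometry="1"', 'species="ghost"', sbml)
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(bad, path2)
  expect_error(load_model(path2), "undefined species")
})

test_that("thermodynamic annotation marks pathway reactions and checks reverse pairs", {
  model <- toy_model(toy_spec(include_reverse_pair = TRUE))
  tab <- data.frame(reaction_id = "EX_prod", dG0_prime_kJ_mol = -10)
  model2 <- attach_thermo(model, tab)
  expect_equal(model2$reactions[["EX_prod"]]$dG0_prime, -10)
  expect_true(model2$reactions[["EX_prod"]]$in_pathway)

  expect_error(
    attach_thermo(model, data.frame(reaction_id = "nope",
                                    dG0_prime_kJ_mol = 1)),
    "unknown reaction")
  ok <- data.frame(reaction_id = c("atoDA", "atoDA_reverse"),
                   dG0_prime_kJ_mol = c(3.2, -3.2))
  expect_silent(attach_thermo(model, ok))
  bad <- data.frame(reaction_id = c("atoDA", "atoDA_reverse"),
                    dG0_prime_kJ_mol = c(3.2, 3.2))
  expect_error(attach_thermo(model, bad), "negated")
})

test_that("kinetic annotation validates positivity and records the pool", {
  model <- toy_model(toy_spec())
  tab <- data.frame(reaction_id = "PROD", kcat_per_h_per_g = 6503.76,
                    mw_g_per_mmol = 1)
  model2 <- attach_kinetics(model, tab, enzyme_pool = 0.3)
  expect_equal(model2$reactions[["PROD"]]$kcat, 6503.76)
  expect_equal(model2$enzyme_pool, 0.3)
  tab$kcat_per_h_per_g <- 0
  expect_error(attach_kinetics(model, tab), "strictly positive")
})

test_that("untracked metabolites are excluded from driving forces", {
  mets <- list(metabolite("a"), metabolite("h", thermo_tracked = FALSE),
               metabolite("b"))
  rxns <- list(reaction("R", c(a = -1, h = -2, b = 1), dG0_prime = -10,
                        in_pathway = TRUE),
               reaction("BIO", c(b = -1), role = "biomass"))
  model <- metabolic_model(mets, rxns)
  expr <- build_driving_forces(model)
  expect_named(expr$R$coef, c("a", "b"))
})
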