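test_that("pathway MDF equalizes chain driving forces and names bottlenecks", {
  model <- toy_model(toy_spec(dG0_list = c(-10, -10)))
  rep <- pathway_mdf(model, c("R1", "R2"))
  expect_setequal(rep$bottlenecks, c("R1", "R2"))
  expect_equal(unname(rep$driving_forces[["R1"]]),
               unname(rep$driving_forces[["R2"]]))
  expect_equal(rep$B, min(rep$driving_forces))

  # order of the pathway listing does not matter
  rep_rev <- pathway_mdf(model, c("R2", "R1"))
  expect_equal(rep_rev$B, rep$B)
})

test_that("a reversible pair pins the MDF at zero with both members bottlenecked", {
  model <- toy_model(toy_spec(include_reverse_pair = TRUE))
  rep <- pathway_mdf(model, c("atoDA", "atoDA_reverse"))
  expect_equal(rep$B, 0)
  expect_setequal(rep$bottlenecks, c("atoDA", "atoDA_reverse"))
})

test_that("shadow prices are substrate-positive, product-negative, and dual = finite difference", {
  cfg <- thermo_config()
  for (dG0 in list(c(-10, -10), c(-5, -15), c(-8, -3, -12))) {
    model <- toy_model(toy_spec(n_chain = length(dG0), dG0_list = dG0))
    pathway <- paste0("R", seq_along(dG0))
    sp_dual <- cofactory:::dual_shadow_prices(
      cofactory:::mark_pathway(model, pathway), pathway, cfg)
    sp <- shadow_prices(model, pathway, cfg)
    expect_equal(as.numeric(sp), as.numeric(sp_dual[names(sp)]),
                 tolerance = 1e-4)
    expect_false(any(attr(sp, "degenerate")))
    # pathway substrate promotes, end product inhibits
    expect_gt(sp[["glc"]], 0)
    expect_lt(sp[[paste0("c", length(dG0))]], 0)
  }
})

test_that("metabolites outside the pathway have zero shadow price", {
  model <- toy_model(toy_spec(n_chain = 2, include_reverse_pair = TRUE))
  sp <- shadow_prices(model, c("R1", "R2"))
  expect_false(any(c("rp1", "rp2") %in% names(sp)))
  full <- pathway_mdf(model, c("R1", "R2"))
  expect_false("rp1" %in% names(full$shadow_prices))
})

test_that("reversible-pair pathways have all-zero shadow prices", {
  model <- toy_model(toy_spec(include_reverse_pair = TRUE))
  sp <- shadow_prices(model, c("atoDA", "atoDA_reverse"))
  expect_equal(unname(sp[c("rp1", "rp2")]), c(0, 0), tolerance = 1e-9)
})

test_that("MDF reports serialize to TSV and JSON", {
  model <- toy_model(toy_spec())
  rep <- pathway_mdf(model, c("R1", "R2"))
  rxn_tsv <- withr::local_tempfile(fileext = ".tsv")
  met_tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_mdf_report(rep, rxn_tsv, met_tsv, js)
  tab <- read.delim(rxn_tsv)
  expect_setequal(tab$reaction_id, c("R1", "R2"))
  expect_true(all(tab$bottleneck))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$B, rep$B)
})
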