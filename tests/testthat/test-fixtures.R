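test_that("toy chain has its documented closed-form optima", {
  expect_equal(fba_max_growth(toy_model(toy_spec(n_chain = 2)))$objective_value, 10)
  expect_equal(fba_max_growth(toy_model(toy_spec(uptake_bound = 4)))$objective_value, 4)
  m <- toy_model(toy_spec())
  expect_equal(max_production(m, 0.75 * 10)$fluxes[["PROD"]], 2.5)
})

test_that("synthetic generators are reproducible under a fixed seed", {
  a <- synth_monoculture(toy_spec(noise_cv = 0.05, seed = 11))
  b <- synth_monoculture(toy_spec(noise_cv = 0.05, seed = 11))
  c <- synth_monoculture(toy_spec(noise_cv = 0.05, seed = 12))
  expect_identical(a$measured_production, b$measured_production)
  expect_false(identical(a$measured_production, c$measured_production))

  s1 <- synth_coculture(noise_cv = 0.05, seed = 3)
  s2 <- synth_coculture(noise_cv = 0.05, seed = 3)
  expect_identical(vapply(s1$datasets, `[[`, numeric(1), "measured_production"),
                   vapply(s2$datasets, `[[`, numeric(1), "measured_production"))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_monoculture(toy_spec(noise_cv = 0.05, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("co-culture generator emits one dataset per requested ratio", {
  sc <- synth_coculture(ratios = list(c(1, 4), c(1, 9)))
  expect_length(sc$datasets, 2)
  expect_equal(sc$datasets[[1]]$icr, c(0.2, 0.8))
  expect_equal(sc$datasets[[2]]$icr, c(0.1, 0.9))
  expect_true(all(vapply(sc$datasets, `[[`, numeric(1),
                         "measured_production") > 0))
})

test_that("fixture output files are readable by the package's own readers", {
  spec <- toy_spec(include_reverse_pair = TRUE)
  model_path <- withr::local_tempfile(fileext = ".json")
  save_model(toy_model(spec), model_path)
  model <- load_model(model_path)
  expect_equal(pathway_mdf(model, c("atoDA", "atoDA_reverse"))$B, 0)

  mono <- synth_monoculture(spec)
  data_path <- withr::local_tempfile(fileext = ".tsv")
  write_mono_culture(mono, data_path)
  deg <- calibrate_degree(model, read_mono_culture(data_path))
  expect_equal(deg$d, spec$true_d, tolerance = 1e-12)
})
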