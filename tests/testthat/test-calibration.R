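test_that("expression degree arithmetic and guards", {
  expect_equal(compute_degree(0.8, 0.6)$d, 0.25)
  expect_equal(compute_degree(0.5, 0.5)$d, 0)
  expect_equal(compute_degree(1.0, 0.0)$d, 1)
  expect_equal(compute_degree(0.8, 0.6)$v_dec, 0.2)
  expect_error(compute_degree(0.5, 0.6), "\\[0, v_nfeg\\]")
  expect_error(compute_degree(0, 0), "v_nfeg")
})

test_that("mono-culture calibration inverts the toy production law", {
  # toy law: titer(d) = d * uptake_bound * duration; measured 2.5 * 6 at
  # uptake 10 over 6 h implies d = 0.25
  spec <- toy_spec()
  model <- toy_model(spec)
  data <- mono_culture_data(times = c(0, 3, 6), substrate_conc = c(10, 5, 0),
                            measured_production = 2.5 * 6)
  deg <- calibrate_degree(model, data)
  expect_equal(deg$d, 0.25, tolerance = 1e-12)
  expect_equal(deg$v_feg, 7.5, tolerance = 1e-9)

  # zero measurement ties toward the smallest degree
  data0 <- mono_culture_data(c(0, 3, 6), c(10, 5, 0), 0)
  expect_equal(calibrate_degree(model, data0)$d, 0)
})

test_that("calibration is monotone in the measured titer", {
  model <- toy_model(toy_spec())
  ds <- vapply(c(0.5, 1.5, 3, 4.5) * 6, function(meas) {
    calibrate_degree(model, mono_culture_data(c(0, 3, 6), c(10, 5, 0),
                                              meas))$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("non-binding extra constraints leave the calibrated degree unchanged", {
  spec <- toy_spec()
  model <- attach_kinetics(
    toy_model(spec),
    data.frame(reaction_id = "PROD", kcat_per_h_per_g = 6503.76,
               mw_g_per_mmol = 1))
  data <- mono_culture_data(c(0, 3, 6), c(10, 5, 0), 1.2)
  d_fba <- calibrate_degree(model, data)$d
  d_kin <- calibrate_degree(model, data, solve_options(use_kinetic = TRUE))$d
  d_thermo <- calibrate_degree(model, data, solve_options(use_thermo = TRUE))$d
  expect_equal(d_kin, d_fba)
  expect_equal(d_thermo, d_fba)
})

test_that("noise-free synthetic mono-culture data returns the generating degree", {
  for (true_d in c(0.0011, 0.0099, 0.035)) {
    spec <- toy_spec(true_d = true_d)
    mono <- synth_monoculture(spec)
    deg <- calibrate_degree(toy_model(spec), mono)
    expect_equal(deg$d, true_d, tolerance = 1e-12)
  }
})

test_that("joint co-culture calibration needs two distinct ratios", {
  sc <- synth_coculture()
  one <- sc$datasets[1]
  expect_error(
    calibrate_from_coculture(sc$consortium$models[[1]],
                             sc$consortium$models[[2]], one,
                             exchange_map = sc$consortium$exchange_map,
                             production_rxns = sc$consortium$production_rxns),
    "at least two")
  dup <- list(sc$datasets[[1]], sc$datasets[[1]])
  expect_error(
    calibrate_from_coculture(sc$consortium$models[[1]],
                             sc$consortium$models[[2]], dup,
                             exchange_map = sc$consortium$exchange_map,
                             production_rxns = sc$consortium$production_rxns),
    "distinct")
})

test_that("mono-culture data writer and reader round-trip", {
  mono <- synth_monoculture(toy_spec(noise_cv = 0.05, seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mono_culture(mono, path)
  back <- read_mono_culture(path)
  expect_equal(back$measured_production, mono$measured_production)
  expect_equal(back$substrate_conc, mono$substrate_conc, tolerance = 1e-9)
  expect_equal(back$culture_duration, mono$culture_duration)
})
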