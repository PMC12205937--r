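test_that("the flux multiplier is the initial-to-average concentration ratio", {
  expect_equal(mapping_multiplier(10, c(0, 1, 2), c(10, 10, 10)), 1)
  expect_equal(mapping_multiplier(10, seq(0, 6, by = 0.1),
                                  seq(10, 0, length.out = 61)), 2)
  expect_equal(mapping_multiplier(10, c(0, 1, 2), c(10, 4, 1)), 10 / 4.75)
  expect_error(mapping_multiplier(10, c(0, 1), c(0, 0)), "degenerate")
})

test_that("the consortium mapping constant is the inoculum-weighted sum", {
  expect_equal(mapping_constant(c(2, 4), c(0.5, 0.5))$k, 3)
  expect_equal(mapping_constant(c(2, 4), c(1, 0))$k, 2)
  expect_equal(mapping_constant(c(2.105, 1.5), c(0.8, 0.2))$k, 1.984)
  expect_error(mapping_constant(c(2, 4), c(0.6, 0.6)), "sum to 1")
  expect_equal(mapping_constant(c(2, 4), c(0.6, 0.6), normalize = TRUE)$k, 3)
})

test_that("integration is linear in k and steps when nothing binds", {
  st <- make_consortium_state()
  spec <- coculture_spec(st$strains, icr = c(0, 1), dt = 0.1, tp = 60,
                         exchange_map = list())
  base <- simulate_production(spec, mapping_constant(c(2, 2), c(0, 1)))
  # downstream alone: total = k * d * ub * icr * dt * tp = 2*0.011*10*0.1*60
  expect_equal(base$total, 2 * 0.011 * 10 * 0.1 * 60, tolerance = 1e-9)
  twice_k <- simulate_production(spec, mapping_constant(c(4, 4), c(0, 1)))
  expect_equal(twice_k$total, 2 * base$total, tolerance = 1e-9)
  spec2 <- spec; spec2$tp <- 120L
  expect_equal(simulate_production(spec2, mapping_constant(c(2, 2), c(0, 1)))$total,
               2 * base$total, tolerance = 1e-9)
})

test_that("consumer production tracks the supplied pool when supply limits", {
  st <- make_consortium_state()
  # upstream-poor inoculum: upstream secretion (icr*d*ub = 0.1*0.035*20)
  # cannot meet downstream demand (0.9*0.011*10); production equals supply
  spec <- coculture_spec(st$strains, icr = c(0.1, 0.9), dt = 0.4, tp = 60,
                         exchange_map = st$consortium$exchange_map)
  pred <- simulate_production(spec, mapping_constant(c(1, 1), c(0.1, 0.9)))
  supply_rate <- 0.1 * 0.035 * 20
  expect_equal(pred$total, supply_rate * 0.4 * 60, tolerance = 1e-9)
  expect_true(all(pred$exchange_pools >= -1e-12))

  # with capping disabled the violation step is reported
  diag <- simulate_production(spec, mapping_constant(c(1, 1), c(0.1, 0.9)),
                              cap_uptake = FALSE)
  expect_equal(diag$first_negative_step, 1L)
})

test_that("exchange pools accumulate when supply exceeds demand", {
  st <- make_consortium_state()
  spec <- coculture_spec(st$strains, icr = c(0.2, 0.8), dt = 0.4, tp = 60,
                         exchange_map = st$consortium$exchange_map)
  pred <- simulate_production(spec, mapping_constant(c(1, 1), c(0.2, 0.8)))
  pools <- pred$exchange_pools[, 1]
  expect_true(all(diff(pools) > 0))
  expect_equal(pred$total, 0.8 * 0.011 * 10 * 0.4 * 60, tolerance = 1e-9)
})

test_that("a substrate budget truncates the integration exactly at the budget", {
  st <- make_consortium_state()
  spec <- coculture_spec(st$strains, icr = c(0, 1), dt = 0.1, tp = 60,
                         exchange_map = list(), substrate_supply = 5)
  pred <- simulate_production(spec, mapping_constant(c(2, 2), c(0, 1)))
  expect_lt(pred$steps_run, 60)
  expect_equal(pred$substrate_consumed, 5, tolerance = 1e-9)
})

test_that("moles of product never exceed substrate consumed times maximal yield", {
  st <- make_consortium_state()
  for (icr_up in c(0.1, 0.2, 0.5)) {
    spec <- coculture_spec(st$strains, icr = c(icr_up, 1 - icr_up), dt = 0.4,
                           tp = 60, exchange_map = st$consortium$exchange_map)
    km <- mapping_constant(c(2.5, 1.5), c(icr_up, 1 - icr_up))
    pred <- simulate_production(spec, km)
    expect_lte(pred$total,
               pred$substrate_consumed * st$consortium$max_yield + 1e-9)
  }
})

test_that("total production is the sum of the per-step contributions", {
  st <- make_consortium_state()
  spec <- coculture_spec(st$strains, icr = c(0.2, 0.8), dt = 0.4, tp = 30,
                         exchange_map = st$consortium$exchange_map)
  pred <- simulate_production(spec, mapping_constant(c(2, 2), c(0.2, 0.8)))
  expect_equal(pred$total, sum(pred$per_step))
  expect_length(pred$per_step, 30)
})
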