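# Toy networks and synthetic measurements. Everything the test-suite and the
# demo pipeline consume is generated here in code; the toys have documented
# closed-form optima so solver results can be checked by hand.

#' Specification of a toy chain network
#'
#' The toy is a linear conversion chain `substrate -> c1 -> ... -> c_n`
#' feeding a branch point from which biomass and product compete 1:1 for
#' carbon. Closed forms: maximal growth equals `uptake_bound`; with a growth
#' lower bound `g`, maximal production is `uptake_bound - g`; hence at
#' expression degree d the production flux is `d * uptake_bound`.
#'
#' @param n_chain number of chain reactions (carrying the thermodynamic
#'   annotations).
#' @param dG0_list standard Gibbs energies of the chain reactions, kJ/mol.
#' @param uptake_bound substrate uptake bound, mmol/gDW/h.
#' @param include_reverse_pair add a reaction and its explicit `_reverse`
#'   twin (ids `atoDA`, `atoDA_reverse`) with negated Gibbs energies, as in
#'   a pathway operating a thermodynamically reversible step in both
#'   directions.
#' @param reverse_dG0 Gibbs energy of the forward member of the pair, kJ/mol
#'   (the pathway MDF is 0 regardless of this value).
#' @param true_d expression degree used by the synthetic-data generators.
#'   Default 0.0011, the magnitude calibrated for a tyrosol-synthesis strain
#'   under the FBA constraint.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   noise on generated titers.
#' @param seed RNG seed for the generators.
#' @return a `toy_spec`.
#' @export
toy_spec <- function(n_chain = 2, dG0_list = rep(-10, n_chain),
                     uptake_bound = 10, include_reverse_pair = FALSE,
                     reverse_dG0 = 5.99, true_d = 0.0011, noise_cv = 0,
                     seed = 1L) {
  stopifnot(n_chain >= 1, length(dG0_list) == n_chain, uptake_bound > 0,
            true_d >= 0, true_d <= 1, noise_cv >= 0)
  structure(
    list(n_chain = n_chain, dG0_list = dG0_list, uptake_bound = uptake_bound,
         include_reverse_pair = isTRUE(include_reverse_pair),
         reverse_dG0 = reverse_dG0, true_d = true_d, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "toy_spec"
  )
}

#' Build the toy chain model
#'
#' @param spec a [toy_spec()].
#' @return a `metabolic_model`. Chain reactions `R1..Rn` are pathway
#'   reactions with the given Gibbs energies; `PROD` is the production
#'   reaction; `BIOMASS` the biomass sink.
#' @export
toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  chain_mets <- c("glc", paste0("c", seq_len(spec$n_chain)))
  mets <- lapply(c(chain_mets, "prod"), metabolite)
  branch <- chain_mets[length(chain_mets)]
  rxns <- list(
    reaction("EX_glc", c(glc = 1), ub = spec$uptake_bound, role = "exchange")
  )
  for (i in seq_len(spec$n_chain)) {
    st <- stats::setNames(c(-1, 1), chain_mets[c(i, i + 1)])
    rxns[[length(rxns) + 1L]] <- reaction(
      paste0("R", i), st, dG0_prime = spec$dG0_list[i], in_pathway = TRUE)
  }
  rxns <- c(rxns, list(
    reaction("BIOMASS", stats::setNames(-1, branch), role = "biomass"),
    reaction("PROD", stats::setNames(c(-1, 1), c(branch, "prod")),
             role = "production"),
    reaction("EX_prod", c(prod = -1), role = "exchange")
  ))
  if (spec$include_reverse_pair) {
    mets <- c(mets, lapply(c("rp1", "rp2"), metabolite))
    rxns <- c(rxns, list(
      reaction("atoDA", c(rp1 = -1, rp2 = 1), dG0_prime = spec$reverse_dG0,
               in_pathway = TRUE),
      reaction("atoDA_reverse", c(rp2 = -1, rp1 = 1),
               dG0_prime = -spec$reverse_dG0, in_pathway = TRUE)
    ))
  }
  metabolic_model(mets, rxns, strain_id = "toy")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Generate a synthetic mono-culture measurement
#'
#' Forward-simulates the toy at `spec$true_d` (growth program, then the
#' production program at growth bound `(1 - d) * v_nfeg`), converts the mean
#' production flux into a titer over the culture, applies multiplicative
#' lognormal noise of the requested CV, and emits an exponentially decaying
#' substrate depletion curve on the same time grid the integrator uses.
#'
#' @param spec a [toy_spec()].
#' @param duration culture length, h (default 6 h).
#' @param tp number of grid intervals (default 60).
#' @param initial_substrate initial carbon source, g/L.
#' @param options,config solver settings for the forward simulation.
#' @param biomass_density gDW/L.
#' @return a `mono_culture_data` with attributes `true_d` and `true_titer`.
#' @export
synth_monoculture <- function(spec, duration = 6, tp = 60,
                              initial_substrate = 10,
                              options = solve_options(),
                              config = thermo_config(),
                              biomass_density = 1) {
  model <- toy_model(spec)
  base <- fba_max_growth(model, options, config)
  stopifnot(base$status == "optimal")
  titer <- simulate_mono_titer(model, spec$true_d, base$objective_value,
                               duration, options, config, biomass_density)
  measured <- titer * with_seed(spec$seed, lognormal_factor(1, spec$noise_cv))
  times <- seq(0, duration, length.out = tp + 1)
  conc <- initial_substrate * exp(-3 * times / duration)
  out <- mono_culture_data(times, conc, measured, unit = "mM",
                           culture_duration = duration)
  attr(out, "true_d") <- spec$true_d
  attr(out, "true_titer") <- titer
  out
}

#' Build a toy two-strain consortium
#'
#' Upstream strain: substrate chain with a secreted intermediate (`medi`) as
#' its product (uptake bound `ub_up`). Downstream strain: its own carbon
#' source for growth plus a production reaction consuming both the
#' intermediate and internal carbon 1:1 (uptake bound `ub_down`). Closed
#' forms: upstream secretion flux `d_up * ub_up`; downstream product flux
#' `d_down * ub_down` when intermediate supply suffices, otherwise tracking
#' the supplied pool. The default bounds (20 and 10) place the intermediate
#' supply above downstream demand at an upstream-rich inoculum and below it
#' at an upstream-poor one, so observations at two ratios jointly determine
#' both expression degrees.
#'
#' @param ub_up,ub_down uptake bounds of the two strains, mmol/gDW/h.
#' @return list with `models` (upstream, downstream), `exchange_map`,
#'   `production_rxns`, `substrate_rxns`, and `max_yield` (moles of product
#'   per mole of total substrate, for conservation checks).
#' @export
toy_consortium <- function(ub_up = 20, ub_down = 10) {
  up <- metabolic_model(
    lapply(c("glc", "u1", "medi"), metabolite),
    list(
      reaction("EX_glc", c(glc = 1), ub = ub_up, role = "exchange"),
      reaction("U1", c(glc = -1, u1 = 1)),
      reaction("BIOMASS_up", c(u1 = -1), role = "biomass"),
      reaction("MEDI", c(u1 = -1, medi = 1), role = "production"),
      reaction("EX_medi", c(medi = -1), role = "exchange")
    ),
    strain_id = "upstream")
  down <- metabolic_model(
    lapply(c("xyl", "y1", "medi", "prod"), metabolite),
    list(
      reaction("EX_xyl", c(xyl = 1), ub = ub_down, role = "exchange"),
      reaction("Y1", c(xyl = -1, y1 = 1)),
      reaction("BIOMASS_down", c(y1 = -1), role = "biomass"),
      reaction("EX_medi_in", c(medi = 1), role = "exchange"),
      reaction("PRODD", c(medi = -1, y1 = -1, prod = 1), role = "production"),
      reaction("EX_prod", c(prod = -1), role = "exchange")
    ),
    strain_id = "downstream")
  list(
    models = list(up, down),
    exchange_map = list(list(producer = 1L, consumer = 2L,
                             producer_rxn = "EX_medi",
                             consumer_rxn = "EX_medi_in")),
    production_rxns = list(NULL, "EX_prod"),
    substrate_rxns = list("EX_glc", "EX_xyl"),
    max_yield = 1
  )
}

#' Generate synthetic co-culture observations at several inoculum ratios
#'
#' Runs the forward co-culture pipeline at known expression degrees and
#' returns one observed production per ratio, optionally noised. The
#' per-strain flux multipliers come from generated substrate depletion
#' curves (near-complete exponential glucose depletion upstream, 70% linear
#' xylose utilization downstream) averaged on the integrator's own grid.
#'
#' @param d_true known expression degrees `c(up, down)` (default
#'   `c(0.035, 0.011)`, the degrees calibrated for an isobutanol /
#'   isobutyl-butyrate pair from two co-culture ratios).
#' @param ratios list of upstream:downstream inoculum ratios, e.g.
#'   `list(c(1, 4), c(1, 9))`.
#' @param dt,tp time grid (defaults 0.4 h x 60 steps: a 24-h horizon).
#' @param noise_cv multiplicative lognormal noise CV on observed production.
#' @param seed RNG seed.
#' @param consortium a [toy_consortium()] (built with defaults if missing).
#' @param options,config solver settings.
#' @param biomass_density gDW/L.
#' @return list with `consortium`, `datasets` (one per ratio: `icr`,
#'   `k_per_strain`, `measured_production`, `dt`, `tp`), and `true_d`.
#' @export
synth_coculture <- function(d_true = c(0.035, 0.011),
                            ratios = list(c(1, 4), c(1, 9)),
                            dt = 0.4, tp = 60, noise_cv = 0, seed = 1L,
                            consortium = toy_consortium(),
                            options = solve_options(),
                            config = thermo_config(),
                            biomass_density = 1) {
  stopifnot(length(ratios) >= 1)
  times <- seq(0, dt * tp, length.out = tp + 1)
  k_up <- mapping_multiplier(10, times, 10 * exp(-3 * times / (dt * tp)))
  k_down <- mapping_multiplier(10, times, 10 * (1 - 0.7 * times / (dt * tp)))
  strains <- lapply(1:2, function(j) {
    coculture_strain(consortium$models[[j]], d_true[j], options, config,
                     production_rxn = consortium$production_rxns[[j]],
                     substrate_rxn = consortium$substrate_rxns[[j]])
  })
  noise <- with_seed(seed, lognormal_factor(length(ratios), noise_cv))
  datasets <- lapply(seq_along(ratios), function(i) {
    icr <- ratios[[i]] / sum(ratios[[i]])
    spec <- coculture_spec(strains, icr = icr, dt = dt, tp = tp,
                           exchange_map = consortium$exchange_map,
                           biomass_density = biomass_density,
                           options = options, config = config)
    km <- mapping_constant(c(k_up, k_down), icr)
    total <- simulate_production(spec, km)$total
    list(icr = icr, k_per_strain = c(k_up, k_down),
         measured_production = total * noise[i], dt = dt, tp = tp,
         true_production = total)
  })
  list(consortium = consortium, datasets = datasets, true_d = d_true)
}
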