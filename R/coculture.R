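# Mean-to-instantaneous flux mapping and discrete-time co-culture
# integration with cross-feeding bookkeeping.

#' Per-strain mean-to-instantaneous flux multiplier
#'
#' The multiplier k_j is the ratio of the initial carbon-source concentration
#' to its time-averaged concentration over the mono-culture, the time average
#' taken by the trapezoid rule over the recorded series. A strain that keeps
#' its substrate nearly constant has k_j ~ 1; a strain that depletes it has
#' k_j > 1 (instantaneous fluxes early in the culture exceed the mean).
#'
#' @param initial initial carbon-source concentration, g/L.
#' @param times sampling times, h (strictly increasing, starting at 0).
#' @param conc concentrations at `times`, g/L.
#' @return dimensionless multiplier.
#' @export
mapping_multiplier <- function(initial, times, conc) {
  stopifnot(initial > 0, length(times) == length(conc), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("substrate concentrations must be non-negative", call. = FALSE)
  avg <- trapezoid_mean(times, conc)
  if (avg <= 0) {
    stop("time-averaged substrate concentration is zero; the depletion record ",
         "is degenerate (consider flooring the series)", call. = FALSE)
  }
  initial / avg
}

trapezoid_mean <- function(times, conc) {
  area <- sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  area / (times[length(times)] - times[1])
}

#' Consortium-level mapping constant
#'
#' Combines the per-strain multipliers through the inoculum ratio:
#' `k = sum_j k_j * icr_j` over the two strains.
#'
#' @param k_per_strain per-strain multipliers (length 2 for a two-strain
#'   consortium; length 1 allowed for a degenerate mono-culture).
#' @param icr inoculum fractions, summing to 1.
#' @param normalize if `TRUE`, rescale `icr` to sum to 1 instead of erroring.
#' @return a `mapping_constant` with fields `k_per_strain`, `icr`, `k`.
#' @export
mapping_constant <- function(k_per_strain, icr, normalize = FALSE) {
  stopifnot(length(k_per_strain) == length(icr))
  s <- sum(icr)
  if (abs(s - 1) > 1e-9) {
    if (!normalize) {
      stop("inoculum fractions must sum to 1 (got ", format(s),
           "); pass normalize = TRUE to rescale", call. = FALSE)
    }
    icr <- icr / s
  }
  structure(
    list(k_per_strain = as.numeric(k_per_strain), icr = as.numeric(icr),
         k = sum(k_per_strain * icr)),
    class = "mapping_constant"
  )
}

#' Co-culture specification
#'
#' Bundles the two strains (model, calibrated expression degree, and the mean
#' flux solution from the forced-expression production program), the
#' inoculum fractions, the time grid, and the cross-feeding topology.
#'
#' @param strains list of two strain entries, each a list with elements
#'   `model` (a `metabolic_model`), `d` (expression degree), `v_nfeg`
#'   (unconstrained max growth), `solution` (mean `flux_solution`),
#'   `production_rxn` (id of the final-product flux, or `NULL` if this strain
#'   does not make the final product), and `substrate_rxn` (id of the
#'   carbon-source uptake flux, or `NULL`).
#' @param icr inoculum fractions of the two strains (sum to 1).
#' @param dt time step, h.
#' @param tp number of time steps.
#' @param exchange_map list of cross-feeding links, each a list with
#'   `producer`, `consumer` (strain indices), `producer_rxn` (secretion flux
#'   in the producer's solution) and `consumer_rxn` (uptake flux in the
#'   consumer's solution).
#' @param substrate_supply optional total substrate budget (mmol per litre of
#'   culture); integration stops once cumulative consumption reaches it.
#' @param biomass_density biomass concentration, gDW/L, converting specific
#'   fluxes (mmol/gDW/h) into volumetric rates (mM/h). Held constant over
#'   the run.
#' @param options,config solver settings used to produce the strain
#'   solutions; retained so sensitivity analysis can re-solve.
#' @return a `coculture_spec`.
#' @export
coculture_spec <- function(strains, icr, dt, tp, exchange_map = list(),
                           substrate_supply = NULL, biomass_density = 1,
                           options = solve_options(), config = thermo_config()) {
  stopifnot(length(strains) == 2L, length(icr) == 2L, dt > 0, tp >= 1)
  if (abs(sum(icr) - 1) > 1e-9) {
    stop("inoculum fractions must sum to 1", call. = FALSE)
  }
  for (ex in exchange_map) {
    p <- strains[[ex$producer]]; q <- strains[[ex$consumer]]
    if (!ex$producer_rxn %in% names(p$solution$fluxes)) {
      stop("exchange producer reaction '", ex$producer_rxn,
           "' absent from producer solution", call. = FALSE)
    }
    if (!ex$consumer_rxn %in% names(q$solution$fluxes)) {
      stop("exchange consumer reaction '", ex$consumer_rxn,
           "' absent from consumer solution", call. = FALSE)
    }
  }
  structure(
    list(strains = strains, icr = as.numeric(icr), dt = dt, tp = as.integer(tp),
         exchange_map = exchange_map, substrate_supply = substrate_supply,
         biomass_density = biomass_density, options = options, config = config),
    class = "coculture_spec"
  )
}

#' Integrate co-culture production over the horizon
#'
#' At every step the instantaneous fluxes are the mean mono-culture fluxes
#' scaled by the mapping constant (`v_t = k * v_mean`). Each strain's step
#' contribution to product is its instantaneous production flux weighted by
#' its inoculum fraction, times the step length and the biomass density.
#' Exchanged-metabolite pools receive producer secretion and lose consumer
#' uptake each step; consumer uptake is capped at the available pool and the
#' consumer's fluxes in that step are scaled down proportionally. If a
#' substrate budget is set, integration stops once cumulative substrate
#' consumption reaches it (the final step is scaled to land exactly on the
#' budget).
#'
#' @param spec a [coculture_spec()].
#' @param k a [mapping_constant()] (or a bare number).
#' @param cap_uptake if `FALSE` (diagnostic mode), consumer uptake is not
#'   capped at the pool; pools may then go negative and the first violating
#'   step is reported in `first_negative_step`.
#' @return a `production_prediction`: `per_step` (mM formed in each step),
#'   `total` (mM), `exchange_pools` (matrix, steps x links, pool after each
#'   step), `substrate_consumed` (mmol/L), `steps_run`,
#'   `first_negative_step` (`NA` unless capping is disabled and a pool went
#'   negative).
#' @export
simulate_production <- function(spec, k, cap_uptake = TRUE) {
  kval <- if (inherits(k, "mapping_constant")) k$k else as.numeric(k)
  stopifnot(kval > 0)
  n_ex <- length(spec$exchange_map)
  dens <- spec$biomass_density
  dt <- spec$dt

  # constant per-step volumetric rates (mM per step) before exchange capping
  step_amt <- function(j, rxn) {
    if (is.null(rxn)) return(0)
    kval * spec$strains[[j]]$solution$fluxes[[rxn]] * spec$icr[j] * dens * dt
  }
  prod_amt <- vapply(1:2, function(j)
    step_amt(j, spec$strains[[j]]$production_rxn), numeric(1))
  sub_amt <- vapply(1:2, function(j)
    step_amt(j, spec$strains[[j]]$substrate_rxn), numeric(1))
  ex_supply <- vapply(spec$exchange_map, function(ex)
    step_amt(ex$producer, ex$producer_rxn), numeric(1))
  ex_demand <- vapply(spec$exchange_map, function(ex)
    step_amt(ex$consumer, ex$consumer_rxn), numeric(1))

  pools <- numeric(n_ex)
  per_step <- numeric(spec$tp)
  pool_trace <- matrix(NA_real_, spec$tp, n_ex)
  if (n_ex) colnames(pool_trace) <- vapply(spec$exchange_map, function(ex)
    ex$producer_rxn, character(1))
  substrate_consumed <- 0
  steps_run <- 0L
  first_negative <- NA_integer_

  for (t in seq_len(spec$tp)) {
    scale <- c(1, 1)
    if (n_ex) {
      pools <- pools + ex_supply
      if (cap_uptake) {
        for (e in seq_len(n_ex)) {
          cj <- spec$exchange_map[[e]]$consumer
          if (ex_demand[e] > 0) {
            scale[cj] <- min(scale[cj], pools[e] / ex_demand[e], 1)
          }
        }
      }
      for (e in seq_len(n_ex)) {
        cj <- spec$exchange_map[[e]]$consumer
        pools[e] <- pools[e] - ex_demand[e] * scale[cj]
      }
      if (!cap_uptake && is.na(first_negative) && any(pools < -1e-12)) {
        first_negative <- t
      }
    }
    step_prod <- sum(prod_amt * scale)
    step_sub <- sum(sub_amt * scale)
    frac <- 1
    if (!is.null(spec$substrate_supply) && step_sub > 0 &&
        substrate_consumed + step_sub >= spec$substrate_supply) {
      frac <- max(0, (spec$substrate_supply - substrate_consumed) / step_sub)
    }
    per_step[t] <- step_prod * frac
    substrate_consumed <- substrate_consumed + step_sub * frac
    if (n_ex) pool_trace[t, ] <- pools
    steps_run <- t
    if (frac < 1) break
  }
  per_step <- per_step[seq_len(steps_run)]
  structure(
    list(per_step = per_step, total = sum(per_step),
         exchange_pools = pool_trace[seq_len(steps_run), , drop = FALSE],
         substrate_consumed = substrate_consumed, steps_run = steps_run,
         first_negative_step = first_negative),
    class = "production_prediction"
  )
}

#' @export
print.production_prediction <- function(x, ...) {
  cat("<production_prediction> total =", format(x$total), "mM over",
      x$steps_run, "steps\n")
  invisible(x)
}

#' Assemble one strain entry for a co-culture specification
#'
#' Solves the forced-expression production program at expression degree `d`
#' and packages the strain for [coculture_spec()].
#'
#' @param model a `metabolic_model`.
#' @param d expression degree in `[0, 1]`.
#' @param options,config solver settings.
#' @param production_rxn id of the final-product flux (`NULL` if this strain
#'   does not produce the final product; defaults to the model's production
#'   reaction).
#' @param substrate_rxn id of the carbon-source uptake flux (`NULL` if
#'   untracked).
#' @return a strain entry list.
#' @export
coculture_strain <- function(model, d, options = solve_options(),
                             config = thermo_config(),
                             production_rxn = production_id(model),
                             substrate_rxn = NULL) {
  stopifnot(d >= 0, d <= 1)
  base <- fba_max_growth(model, options, config)
  if (base$status != "optimal") {
    stop("growth program ", base$status, " for strain '", model$strain_id, "'",
         call. = FALSE)
  }
  v_nfeg <- base$objective_value
  sol <- max_production(model, growth_lb = (1 - d) * v_nfeg, options, config)
  if (sol$status != "optimal") {
    stop("production program ", sol$status, " for strain '", model$strain_id,
         "' at d = ", d, call. = FALSE)
  }
  list(model = model, d = d, v_nfeg = v_nfeg, solution = sol,
       production_rxn = production_rxn, substrate_rxn = substrate_rxn)
}

#' Write a production prediction to TSV and JSON
#'
#' @param prediction a `production_prediction`.
#' @param spec the [coculture_spec()] that produced it.
#' @param path_tsv step table path; `NULL` to skip.
#' @param path_json summary path; `NULL` to skip.
#' @return the prediction, invisibly.
#' @export
write_prediction <- function(prediction, spec, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    tab <- data.frame(step = seq_len(prediction$steps_run),
                      time_h = seq_len(prediction$steps_run) * spec$dt,
                      step_production_mM = prediction$per_step)
    if (ncol(prediction$exchange_pools)) {
      tab <- cbind(tab, prediction$exchange_pools)
    }
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(total_mM = prediction$total, steps_run = prediction$steps_run,
           substrate_consumed = prediction$substrate_consumed,
           dt = spec$dt, tp = spec$tp, icr = spec$icr),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(prediction)
}
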