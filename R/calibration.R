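# Expression-degree computation and calibration against measured titers.
#
# The expression degree d quantifies the growth burden of forced pathway
# expression: d = (v_nfeg - v_feg) / v_nfeg, where v_nfeg is the growth rate
# without forced expression and v_feg the growth rate with it. Calibration
# scans d, re-solves the production program at growth lower bound
# (1 - d) * v_nfeg, and keeps the d whose simulated titer is closest to the
# measurement.

#' Expression degree from the two growth rates
#'
#' @param v_nfeg growth rate without forced pathway expression, 1/h (> 0).
#' @param v_feg growth rate with forced expression, 1/h (in `[0, v_nfeg]`).
#' @param constraint_set label of the constraint combination the rates came
#'   from (`"fba"`, `"fba+kin"`, `"fba+thermo"`, `"fba+kin+thermo"`).
#' @return an `expression_degree` with fields `d`, `v_nfeg`, `v_feg`,
#'   `v_dec`, `constraint_set`.
#' @export
compute_degree <- function(v_nfeg, v_feg, constraint_set = "fba") {
  stopifnot(v_nfeg > 0)
  if (v_feg < 0 || v_feg > v_nfeg) {
    stop("v_feg must lie in [0, v_nfeg]; growth gain under forced expression ",
         "is outside the model", call. = FALSE)
  }
  v_dec <- v_nfeg - v_feg
  structure(
    list(d = v_dec / v_nfeg, v_nfeg = v_nfeg, v_feg = v_feg, v_dec = v_dec,
         constraint_set = constraint_set),
    class = "expression_degree"
  )
}

#' @export
print.expression_degree <- function(x, ...) {
  cat("<expression_degree> d =", format(x$d), "(", x$constraint_set, ")\n")
  invisible(x)
}

#' Mono-culture measurement record
#'
#' @param times sampling times, h, strictly increasing from 0.
#' @param substrate_conc carbon-source concentrations at `times`, g/L.
#' @param measured_production measured product titer at the end of the
#'   culture.
#' @param unit unit of the titer (recorded, default `"mM"`).
#' @param culture_duration culture length, h (defaults to `max(times)`).
#' @return a `mono_culture_data`.
#' @export
mono_culture_data <- function(times, substrate_conc, measured_production,
                              unit = "mM", culture_duration = max(times)) {
  stopifnot(length(times) == length(substrate_conc), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(substrate_conc < 0)) stop("substrate_conc must be non-negative", call. = FALSE)
  if (measured_production < 0) stop("measured_production must be >= 0", call. = FALSE)
  structure(
    list(times = times, substrate_conc = substrate_conc,
         initial_substrate = substrate_conc[1],
         measured_production = measured_production, unit = unit,
         culture_duration = culture_duration),
    class = "mono_culture_data"
  )
}

#' Write / read mono-culture data as TSV plus JSON sidecar
#'
#' The depletion series goes to a two-column TSV (`time_h`,
#' `substrate_g_per_L`); the scalar titer and unit go to `<path>.json`.
#'
#' @param data a `mono_culture_data`.
#' @param path TSV path.
#' @return `path` (write) / a `mono_culture_data` (read).
#' @export
write_mono_culture <- function(data, path) {
  utils::write.table(
    data.frame(time_h = data$times, substrate_g_per_L = data$substrate_conc),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(measured_production = data$measured_production, unit = data$unit,
         culture_duration = data$culture_duration),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mono_culture
#' @export
read_mono_culture <- function(path) {
  tab <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  mono_culture_data(tab$time_h, tab$substrate_g_per_L,
                    meta$measured_production, unit = meta$unit,
                    culture_duration = meta$culture_duration)
}

# simulated titer at expression degree d: mean production flux times culture
# duration times biomass density (mmol/gDW/h * h * gDW/L = mM)
simulate_mono_titer <- function(model, d, v_nfeg, duration, options, config,
                                biomass_density = 1) {
  sol <- max_production(model, growth_lb = (1 - d) * v_nfeg, options, config)
  if (sol$status != "optimal") return(NA_real_)
  sol$fluxes[[production_id(model)]] * duration * biomass_density
}

#' Calibrate the expression degree against a mono-culture titer
#'
#' Computes the unconstrained maximum growth rate, then scans the expression
#' degree d over `[0, 1]`: each candidate sets the growth lower bound to
#' `(1 - d) * v_nfeg`, the production program is re-solved, and the simulated
#' titer (mean production flux x duration x biomass density) is compared
#' with the measurement. A coarse scan at `grid_step` is refined to
#' `refine_step` around the best coarse point. Ties break toward smaller d.
#'
#' @param model a `metabolic_model` with biomass and production reactions.
#' @param data a [mono_culture_data()].
#' @param options,config solver settings.
#' @param grid_step coarse scan step (default 0.01).
#' @param refine_step refinement step (default 1e-4, the precision at which
#'   degrees are conventionally reported).
#' @param biomass_density gDW/L converting specific flux to titer.
#' @return an `expression_degree` with attribute `"residual"` (absolute
#'   titer error at the optimum).
#' @export
calibrate_degree <- function(model, data, options = solve_options(),
                             config = thermo_config(), grid_step = 1e-2,
                             refine_step = 1e-4, biomass_density = 1) {
  stopifnot(inherits(data, "mono_culture_data"))
  base <- fba_max_growth(model, options, config)
  if (base$status != "optimal") {
    stop("growth program ", base$status, "; cannot calibrate", call. = FALSE)
  }
  v_nfeg <- base$objective_value
  duration <- data$culture_duration
  scan <- function(ds) {
    sims <- vapply(ds, function(d)
      simulate_mono_titer(model, d, v_nfeg, duration, options, config,
                          biomass_density), numeric(1))
    errs <- abs(sims - data$measured_production)
    if (all(is.na(errs))) {
      stop("production program infeasible at every scanned expression degree",
           call. = FALSE)
    }
    i <- which.min(errs)  # first minimum: ties toward smaller d
    list(d = ds[i], err = errs[i])
  }
  coarse <- scan(seq(0, 1, by = grid_step))
  window <- seq(max(0, coarse$d - grid_step), min(1, coarse$d + grid_step),
                by = refine_step)
  fine <- scan(window)
  out <- compute_degree(v_nfeg, (1 - fine$d) * v_nfeg,
                        constraint_set = constraint_set_label(options))
  attr(out, "residual") <- fine$err
  out
}

#' Calibrate both expression degrees from co-culture data alone
#'
#' For consortia without mono-culture measurements, the two expression
#' degrees are estimated jointly from at least two co-culture observations
#' at distinct inoculum ratios. A grid over (d_up, d_down) is scanned; for
#' each candidate pair the full co-culture pipeline (production programs at
#' each degree, flux mapping, discrete integration with cross-feeding) is
#' run for every dataset, and the pair minimizing the summed error between
#' simulated and measured production is kept, refined in two stages down to
#' `refine_step`. Ties break lexicographically toward smaller (d_up, d_down).
#'
#' @param model_up,model_down the two strain models (upstream feeds the
#'   exchanged intermediate to downstream).
#' @param datasets list of >= 2 observations, each a list with `icr`
#'   (fractions of upstream and downstream strain), `k_per_strain`
#'   (per-strain flux multipliers), `measured_production`, `dt`, `tp`.
#' @param exchange_map cross-feeding links passed to [coculture_spec()]
#'   (producer/consumer indices 1 = upstream, 2 = downstream).
#' @param production_rxns length-2 list: final-product flux id per strain
#'   (`NULL` where a strain does not make the final product).
#' @param substrate_rxns length-2 list of carbon-uptake flux ids (or `NULL`).
#' @param options,config solver settings.
#' @param grid_step,refine_step scan resolutions as in [calibrate_degree()].
#' @param error one of `"relative"` (default; sum of |sim - meas| / meas) or
#'   `"absolute"`.
#' @param biomass_density gDW/L.
#' @return list of two `expression_degree` objects (`up`, `down`) with
#'   attribute `"residual"`.
#' @export
calibrate_from_coculture <- function(model_up, model_down, datasets,
                                     exchange_map, production_rxns,
                                     substrate_rxns = list(NULL, NULL),
                                     options = solve_options(),
                                     config = thermo_config(),
                                     grid_step = 1e-2, refine_step = 1e-4,
                                     error = c("relative", "absolute"),
                                     biomass_density = 1) {
  error <- match.arg(error)
  if (length(datasets) < 2L) {
    stop("at least two co-culture datasets are required; the two expression ",
         "degrees are underdetermined otherwise", call. = FALSE)
  }
  ratios <- vapply(datasets, function(ds) ds$icr[1], numeric(1))
  if (anyDuplicated(signif(ratios, 10))) {
    stop("datasets must have distinct inoculum ratios", call. = FALSE)
  }

  models <- list(model_up, model_down)
  bases <- lapply(models, function(m) {
    sol <- fba_max_growth(m, options, config)
    if (sol$status != "optimal") {
      stop("growth program ", sol$status, " for strain '", m$strain_id, "'",
           call. = FALSE)
    }
    sol$objective_value
  })
  caches <- list(new.env(parent = emptyenv()), new.env(parent = emptyenv()))
  strain_at <- function(j, d) {
    key <- sprintf("%.10f", d)
    if (!is.null(caches[[j]][[key]])) return(caches[[j]][[key]])
    sol <- max_production(models[[j]], growth_lb = (1 - d) * bases[[j]],
                          options, config)
    entry <- if (sol$status != "optimal") NA else
      list(model = models[[j]], d = d, v_nfeg = bases[[j]], solution = sol,
           production_rxn = production_rxns[[j]],
           substrate_rxn = substrate_rxns[[j]])
    caches[[j]][[key]] <- entry
    entry
  }
  objective_at <- function(d_up, d_down) {
    up <- strain_at(1, d_up); down <- strain_at(2, d_down)
    if (!is.list(up) || !is.list(down)) return(NA_real_)
    total_err <- 0
    for (ds in datasets) {
      spec <- coculture_spec(list(up, down), icr = ds$icr, dt = ds$dt,
                             tp = ds$tp, exchange_map = exchange_map,
                             substrate_supply = ds$substrate_supply,
                             biomass_density = biomass_density,
                             options = options, config = config)
      km <- mapping_constant(ds$k_per_strain, ds$icr)
      sim <- simulate_production(spec, km)$total
      e <- abs(sim - ds$measured_production)
      if (error == "relative" && ds$measured_production > 0) {
        e <- e / ds$measured_production
      }
      total_err <- total_err + e
    }
    total_err
  }
  scan2 <- function(ds_up, ds_down) {
    best <- NULL
    for (du in ds_up) for (dd in ds_down) {  # lexicographic tie-break order
      e <- objective_at(du, dd)
      if (!is.na(e) && (is.null(best) || e < best$err - 1e-15)) {
        best <- list(d_up = du, d_down = dd, err = e)
      }
    }
    if (is.null(best)) {
      stop("co-culture pipeline infeasible at every scanned degree pair",
           call. = FALSE)
    }
    best
  }
  grid <- function(center, half, step) {
    seq(max(0, center - half), min(1, center + half), by = step)
  }
  mid_step <- max(refine_step, grid_step / 10)
  b <- scan2(seq(0, 1, by = grid_step), seq(0, 1, by = grid_step))
  b <- scan2(grid(b$d_up, grid_step, mid_step), grid(b$d_down, grid_step, mid_step))
  b <- scan2(grid(b$d_up, mid_step, refine_step), grid(b$d_down, mid_step, refine_step))

  label <- constraint_set_label(options)
  out <- list(
    up = compute_degree(bases[[1]], (1 - b$d_up) * bases[[1]], label),
    down = compute_degree(bases[[2]], (1 - b$d_down) * bases[[2]], label)
  )
  attr(out, "residual") <- b$err
  out
}

#' Write a calibration result as JSON
#'
#' @param degree an `expression_degree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(degree, path) {
  jsonlite::write_json(
    list(d = degree$d, v_nfeg = degree$v_nfeg, v_feg = degree$v_feg,
         v_dec = degree$v_dec, constraint_set = degree$constraint_set,
         residual = attr(degree, "residual")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
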