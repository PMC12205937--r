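#' Solver options
#'
#' @param use_kinetic apply the enzyme-pool constraint
#'   `sum_i v_i * mw_i / kcat_i <= enzyme_pool` over reactions annotated with
#'   kcat and mw.
#' @param use_thermo apply the max-min driving-force thermodynamic constraint
#'   to pathway reactions.
#' @param objective `"max_growth"`, `"max_production"`, or `"max_B"`.
#' @param growth_lb optional lower bound on the growth flux, mmol/gDW/h.
#' @param lexicographic_tol relative slack allowed on the primary objective
#'   when the driving-force margin B is subsequently maximized.
#' @return a `solve_options` object.
#' @export
solve_options <- function(use_kinetic = FALSE, use_thermo = FALSE,
                          objective = c("max_growth", "max_production", "max_B"),
                          growth_lb = NULL, lexicographic_tol = 1e-6) {
  objective <- match.arg(objective)
  stopifnot(lexicographic_tol >= 0, lexicographic_tol < 1)
  structure(
    list(use_kinetic = isTRUE(use_kinetic), use_thermo = isTRUE(use_thermo),
         objective = objective, growth_lb = growth_lb,
         lexicographic_tol = lexicographic_tol),
    class = "solve_options"
  )
}

#' Named constraint-set label for reporting
#' @param options a `solve_options`.
#' @return one of `"fba"`, `"fba+kin"`, `"fba+thermo"`, `"fba+kin+thermo"`.
#' @export
constraint_set_label <- function(options) {
  paste0("fba",
         if (options$use_kinetic) "+kin" else "",
         if (options$use_thermo) "+thermo" else "")
}

flux_solution <- function(fluxes = numeric(0), ln_conc = numeric(0),
                          driving_forces = numeric(0), B = NA_real_,
                          z = integer(0), objective_value = NA_real_,
                          status = "optimal") {
  structure(
    list(fluxes = fluxes, ln_conc = ln_conc, driving_forces = driving_forces,
         B = B, z = z, objective_value = objective_value, status = status),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value), "\n")
  if (!is.na(x$B)) cat("  B =", format(x$B), "kJ/mol\n")
  invisible(x)
}

#' Symbolic driving-force expressions of pathway reactions
#'
#' The driving force of reaction i is `Df_i = -(dG0'_i + R*T*sum_m s_mi *
#' lnC_m)`, the concentration sum running over thermodynamically tracked
#' metabolites only (water and protons are absorbed into dG0').
#'
#' @param model a `metabolic_model`; every pathway reaction must carry
#'   `dG0_prime`.
#' @param config a [thermo_config()].
#' @return named list per pathway reaction: `list(const, coef)` so that
#'   `Df_i = const + sum(coef * lnC[names(coef)])`.
#' @export
build_driving_forces <- function(model, config = thermo_config()) {
  ids <- pathway_ids(model)
  missing <- ids[vapply(ids, function(i) is.na(model$reactions[[i]]$dG0_prime),
                        logical(1))]
  if (length(missing)) {
    stop("pathway reaction(s) missing dG0_prime: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  RT <- rt(config)
  out <- lapply(ids, function(i) {
    rxn <- model$reactions[[i]]
    tracked <- vapply(names(rxn$stoich),
                      function(m) model$metabolites[[m]]$thermo_tracked,
                      logical(1))
    s <- rxn$stoich[tracked]
    list(const = -rxn$dG0_prime, coef = if (length(s)) -RT * s else numeric(0))
  })
  stats::setNames(out, ids)
}

eval_driving_forces <- function(df_expr, ln_conc) {
  vapply(df_expr, function(e) {
    e$const + sum(e$coef * ln_conc[names(e$coef)])
  }, numeric(1))
}

# metabolites whose ln-concentration enters any pathway driving force
thermo_metabolites <- function(model) {
  ids <- unique(unlist(lapply(pathway_ids(model), function(i)
    names(model$reactions[[i]]$stoich))))
  ids[vapply(ids, function(m) model$metabolites[[m]]$thermo_tracked, logical(1))]
}

# ---- problem assembly --------------------------------------------------------

# Assemble and solve one LP for a fixed thermodynamic binary assignment z
# (named 0/1 over pathway reactions). obj_rxn: reaction id to maximize, or
# "B". growth_lb / fix_rows add extra linear rows over the same variables.
solve_fixed_z <- function(model, options, config, z, obj_rxn,
                          growth_lb = NULL, fix_row = NULL) {
  rxn_ids <- names(model$reactions)
  n_r <- length(rxn_ids)
  met_thermo <- if (options$use_thermo || identical(obj_rxn, "B"))
    thermo_metabolites(model) else character(0)
  n_x <- length(met_thermo)
  with_B <- identical(obj_rxn, "B")
  n_var <- n_r + n_x + as.integer(with_B)
  iv <- stats::setNames(seq_len(n_r), rxn_ids)
  ix <- if (n_x) stats::setNames(n_r + seq_len(n_x), met_thermo) else integer(0)
  iB <- if (with_B) n_var else NA_integer_

  lb <- numeric(n_var); ub <- numeric(n_var)
  for (r in rxn_ids) {
    lb[iv[r]] <- model$reactions[[r]]$lb
    ub[iv[r]] <- model$reactions[[r]]$ub
  }
  # Eq (6): flux forced to zero when the binary is off
  for (r in names(z)) {
    if (z[[r]] == 0) {
      if (lb[iv[r]] > 1e-12) {  # positive lower bound cannot coexist with z=0
        return(flux_solution(status = "infeasible"))
      }
      lb[iv[r]] <- 0; ub[iv[r]] <- 0
    }
  }
  for (m in met_thermo) {
    lb[ix[m]] <- model$metabolites[[m]]$ln_conc_lb
    ub[ix[m]] <- model$metabolites[[m]]$ln_conc_ub
  }
  if (with_B) { lb[iB] <- -1e6; ub[iB] <- 1e6 }

  # steady state S v = 0
  S <- stoich_matrix(model)
  A_eq <- cbind(S, matrix(0, nrow(S), n_var - n_r))
  b_eq <- rep(0, nrow(S))

  A_ub <- NULL; b_ub <- numeric(0)
  add_row <- function(row, b) {
    A_ub <<- rbind(A_ub, row); b_ub <<- c(b_ub, b)
  }

  # enzyme-pool kinetic constraint
  if (options$use_kinetic) {
    has_kin <- vapply(model$reactions, function(r)
      !is.na(r$kcat) && !is.na(r$mw), logical(1))
    if (any(has_kin)) {
      row <- numeric(n_var)
      for (r in rxn_ids[has_kin]) {
        row[iv[r]] <- model$reactions[[r]]$mw / model$reactions[[r]]$kcat
      }
      add_row(row, model$enzyme_pool)
    }
  }

  # thermodynamic rows: Eq (7) Df_i + (1-z_i)K >= df_min, Eq (8) Df_i >= B
  if (options$use_thermo || with_B) {
    df_expr <- build_driving_forces(model, config)
    for (r in names(df_expr)) {
      e <- df_expr[[r]]
      base <- numeric(n_var)
      base[ix[names(e$coef)]] <- -e$coef  # -Df concentration part
      slack <- if (z[[r]] == 1) 0 else config$big_K
      # -Df_i <= -df_min + (1-z)K  <=>  Df_i >= df_min - (1-z)K
      add_row(base, e$const - config$df_min + slack)
      if (with_B && z[[r]] == 1) {
        rowB <- base; rowB[iB] <- 1  # B - Df_i <= 0
        add_row(rowB, e$const)
      }
    }
  }

  if (!is.null(growth_lb)) {
    row <- numeric(n_var); row[iv[biomass_id(model)]] <- -1
    add_row(row, -growth_lb)
  }
  if (!is.null(fix_row)) {
    row <- numeric(n_var); row[fix_row$idx] <- -fix_row$coef
    add_row(row, -fix_row$rhs)
  }

  obj <- numeric(n_var)
  if (with_B) obj[iB] <- 1 else obj[iv[obj_rxn]] <- 1

  res <- solve_lp(obj, A_ub, b_ub, A_eq, b_eq, lb, ub, maximize = TRUE)
  if (res$status != "optimal") return(flux_solution(status = res$status))

  fluxes <- stats::setNames(res$x[iv], rxn_ids)
  ln_conc <- if (n_x) stats::setNames(res$x[ix], met_thermo) else numeric(0)
  dfs <- if (options$use_thermo || with_B)
    eval_driving_forces(build_driving_forces(model, config), ln_conc)
  else numeric(0)
  flux_solution(
    fluxes = fluxes, ln_conc = ln_conc, driving_forces = dfs,
    B = if (with_B) res$objective else NA_real_,
    z = vapply(z, as.integer, integer(1)),
    objective_value = res$objective, status = "optimal"
  )
}

# Enumerate thermodynamic binaries over pathway reactions (exact MILP by
# enumeration; problems here have a handful of binaries). Reactions with a
# strictly positive flux lower bound are pinned active.
z_assignments <- function(model, options) {
  ids <- if (options$use_thermo) pathway_ids(model) else character(0)
  if (length(ids) == 0L) return(list(stats::setNames(integer(0), character(0))))
  forced <- ids[vapply(ids, function(r) model$reactions[[r]]$lb > 1e-12, logical(1))]
  free <- setdiff(ids, forced)
  if (length(free) > 12L) {
    stop("more than 12 free thermodynamic binaries; fix pathway activity ",
         "explicitly for problems of this size", call. = FALSE)
  }
  grid <- if (length(free))
    as.matrix(expand.grid(rep(list(c(1L, 0L)), length(free))))
  else matrix(integer(0), 1, 0)
  lapply(seq_len(nrow(grid)), function(i) {
    z <- stats::setNames(rep(1L, length(ids)), ids)
    if (length(free)) z[free] <- grid[i, ]
    z
  })
}

solve_primary <- function(model, options, config, obj_rxn, growth_lb = NULL) {
  best <- flux_solution(status = "infeasible")
  for (z in z_assignments(model, options)) {
    sol <- solve_fixed_z(model, options, config, z, obj_rxn, growth_lb)
    if (sol$status == "optimal" &&
        (best$status != "optimal" || sol$objective_value > best$objective_value)) {
      best <- sol
    }
  }
  best
}

# Second lexicographic stage: fix the primary objective (within relative
# tolerance) and maximize the driving-force margin B over active pathway
# reactions, keeping the binary assignment of the primary optimum.
maximize_B_at <- function(model, options, config, primary, obj_rxn, growth_lb) {
  z <- stats::setNames(as.integer(primary$z), names(primary$z))
  if (length(z) == 0L || all(z == 0L)) return(primary)
  obj_val <- primary$objective_value
  fix_rhs <- obj_val - options$lexicographic_tol * max(abs(obj_val), 1)
  idx <- match(obj_rxn, names(model$reactions))
  solB <- solve_fixed_z(model, options, config, z, "B", growth_lb,
                        fix_row = list(idx = idx, coef = 1, rhs = fix_rhs))
  if (solB$status != "optimal") return(primary)
  primary$B <- solB$B
  primary$ln_conc <- solB$ln_conc
  primary$driving_forces <- solB$driving_forces
  primary
}

#' Maximize growth under FBA, kinetic and thermodynamic constraints
#'
#' Solves `maximize v_bio` subject to steady state `S v = 0`, flux bounds,
#' the optional enzyme-pool constraint, and (optionally) the thermodynamic
#' constraint on pathway reactions: each active pathway reaction must achieve
#' a driving force of at least `df_min` at some admissible metabolite
#' concentration vector. When the thermodynamic constraint is on, a second
#' lexicographic stage maximizes the common driving-force margin B with the
#' growth optimum held fixed (to within `lexicographic_tol`), so that the
#' reported concentrations make the pathway as spontaneous as possible
#' without sacrificing growth.
#'
#' @param model a `metabolic_model` with a biomass reaction.
#' @param options a [solve_options()].
#' @param config a [thermo_config()].
#' @return a `flux_solution`.
#' @export
fba_max_growth <- function(model, options = solve_options(),
                           config = thermo_config()) {
  bio <- biomass_id(model)
  sol <- solve_primary(model, options, config, bio, growth_lb = options$growth_lb)
  if (sol$status != "optimal") return(sol)
  if (options$use_thermo) {
    sol <- maximize_B_at(model, options, config, sol, bio, options$growth_lb)
  }
  sol
}

#' Maximize production under a growth lower bound
#'
#' Forced-expression production mode: `maximize v_production` subject to
#' `v_bio >= growth_lb` plus all constraints of [fba_max_growth()]. The
#' growth bound encodes the calibrated expression degree d via
#' `growth_lb = (1 - d) * v_bio_max`.
#'
#' @param model a `metabolic_model` with biomass and production reactions.
#' @param growth_lb lower bound on growth flux, mmol/gDW/h.
#' @param options a [solve_options()].
#' @param config a [thermo_config()].
#' @return a `flux_solution`.
#' @export
max_production <- function(model, growth_lb, options = solve_options(),
                           config = thermo_config()) {
  stopifnot(growth_lb >= 0)
  prod <- production_id(model)
  sol <- solve_primary(model, options, config, prod, growth_lb = growth_lb)
  if (sol$status != "optimal") return(sol)
  if (options$use_thermo) {
    sol <- maximize_B_at(model, options, config, sol, prod, growth_lb)
  }
  sol
}

#' Maximize the pathway driving-force margin (MDF program)
#'
#' Maximizes B over metabolite log-concentrations subject to `Df_i >= B` for
#' every required-active pathway reaction, `Df_i >= df_min`, and the
#' concentration box. Pathway reactions not listed in `required_active` are
#' treated as inactive (their thermodynamic binary is zero), which is the
#' exact optimum of the mixed-integer formulation for this pure
#' concentration program since deactivating a reaction only relaxes it.
#'
#' @param model a `metabolic_model` with thermodynamic annotations.
#' @param required_active reaction ids forced active; defaults to all pathway
#'   reactions.
#' @param options a [solve_options()].
#' @param config a [thermo_config()].
#' @return a `flux_solution` with `B`, `ln_conc` and `driving_forces` set.
#' @export
solve_mdf <- function(model, required_active = pathway_ids(model),
                      options = solve_options(use_thermo = TRUE),
                      config = thermo_config()) {
  ids <- pathway_ids(model)
  bad <- setdiff(required_active, ids)
  if (length(bad)) {
    stop("required_active contains non-pathway reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df_expr <- build_driving_forces(model, config)
  mets <- thermo_metabolites(model)
  n_x <- length(mets)
  n_var <- n_x + 1L
  ix <- stats::setNames(seq_len(n_x), mets)
  iB <- n_var
  lb <- c(vapply(mets, function(m) model$metabolites[[m]]$ln_conc_lb, numeric(1)),
          -1e6)
  ub <- c(vapply(mets, function(m) model$metabolites[[m]]$ln_conc_ub, numeric(1)),
          1e6)
  A_ub <- NULL; b_ub <- numeric(0)
  for (r in required_active) {
    e <- df_expr[[r]]
    base <- numeric(n_var)
    base[ix[names(e$coef)]] <- -e$coef
    rowB <- base; rowB[iB] <- 1          # B - Df_i <= 0
    A_ub <- rbind(A_ub, rowB, base)      # and Df_i >= df_min
    b_ub <- c(b_ub, e$const, e$const - config$df_min)
  }
  obj <- numeric(n_var); obj[iB] <- 1
  res <- solve_lp(obj, A_ub, b_ub, NULL, NULL, lb, ub, maximize = TRUE)
  if (res$status != "optimal") return(flux_solution(status = res$status))
  ln_conc <- stats::setNames(res$x[seq_len(n_x)], mets)
  z <- stats::setNames(as.integer(ids %in% required_active), ids)
  flux_solution(
    ln_conc = ln_conc,
    driving_forces = eval_driving_forces(df_expr, ln_conc)[required_active],
    B = res$objective, z = z, objective_value = res$objective,
    status = "optimal"
  )
}

#' Serialize a flux solution to TSV and JSON
#'
#' @param solution a `flux_solution`.
#' @param path_tsv path for the per-reaction table (reaction_id, flux,
#'   driving_force, z); `NULL` to skip.
#' @param path_json path for the run summary (objective, B, status); `NULL`
#'   to skip.
#' @return the solution, invisibly.
#' @export
write_flux_solution <- function(solution, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    ids <- union(names(solution$fluxes), names(solution$driving_forces))
    tab <- data.frame(
      reaction_id = ids,
      flux = solution$fluxes[ids],
      driving_force = solution$driving_forces[ids],
      z = solution$z[ids],
      row.names = NULL
    )
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(objective = solution$objective_value, B = solution$B,
           status = solution$status),
      path_json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(solution)
}
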