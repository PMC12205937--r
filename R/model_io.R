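#' Construct a metabolite
#'
#' Metabolites carry log-concentration bounds used by the thermodynamic
#' (max-min driving force) program. Water and protons are conventionally not
#' tracked: their activities are absorbed into the standard transformed Gibbs
#' energies, so they must not contribute concentration terms to any driving
#' force.
#'
#' @param id unique metabolite identifier.
#' @param name human-readable name (defaults to `id`).
#' @param compartment compartment tag (e.g. `"c"`).
#' @param ln_conc_lb,ln_conc_ub bounds on the natural log of the molar
#'   concentration. Defaults correspond to 1e-6 and 1e-2 M, the usual
#'   physiological window assumed in MDF analysis.
#' @param thermo_tracked logical; `FALSE` for species (water, protons) whose
#'   concentration terms are excluded from driving forces.
#' @return a `metabolite` object (named list).
#' @export
metabolite <- function(id, name = id, compartment = "c",
                       ln_conc_lb = log(1e-6), ln_conc_ub = log(1e-2),
                       thermo_tracked = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (ln_conc_lb > ln_conc_ub) {
    stop("metabolite '", id, "': ln_conc_lb must be <= ln_conc_ub",
         call. = FALSE)
  }
  structure(
    list(id = id, name = name, compartment = compartment,
         ln_conc_lb = as.numeric(ln_conc_lb),
         ln_conc_ub = as.numeric(ln_conc_ub),
         thermo_tracked = isTRUE(thermo_tracked)),
    class = "metabolite"
  )
}

#' Construct a reaction
#'
#' @param id unique reaction identifier.
#' @param stoich named numeric vector mapping metabolite ids to signed
#'   stoichiometric coefficients (negative = consumed).
#' @param lb,ub flux bounds in mmol/gDW/h. Reversible conversions are modelled
#'   as two irreversible reactions, the reverse carrying a `_reverse` id
#'   suffix and `lb = 0`.
#' @param dG0_prime standard transformed Gibbs energy of reaction (kJ/mol),
#'   or `NA` if not annotated.
#' @param kcat turnover number in 1/(g*h) (flux capacity per gram of enzyme),
#'   or `NA`.
#' @param mw enzyme molecular weight in g/mmol, or `NA`.
#' @param in_pathway logical; `TRUE` for product-biosynthesis pathway
#'   reactions, which are the only reactions subject to the thermodynamic
#'   constraint.
#' @param role one of `"internal"`, `"exchange"`, `"biomass"`, `"production"`.
#' @return a `reaction` object (named list).
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000,
                     dG0_prime = NA_real_, kcat = NA_real_, mw = NA_real_,
                     in_pathway = FALSE,
                     role = c("internal", "exchange", "biomass", "production")) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoich must be a non-empty named numeric vector",
         call. = FALSE)
  }
  if (lb > ub) {
    stop("reaction '", id, "': flux_lb must be <= flux_ub", call. = FALSE)
  }
  structure(
    list(id = id, stoich = stoich, lb = as.numeric(lb), ub = as.numeric(ub),
         dG0_prime = as.numeric(dG0_prime), kcat = as.numeric(kcat),
         mw = as.numeric(mw), in_pathway = isTRUE(in_pathway), role = role),
    class = "reaction"
  )
}

#' Assemble a metabolic model for one strain
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param strain_id strain label.
#' @param enzyme_pool total catalytic protein budget in g/gDW used by the
#'   enzyme-pool kinetic constraint (default 0.227 g/gDW, the standard
#'   E. coli value used by enzyme-constrained FBA).
#' @return a `metabolic_model` object.
#' @export
metabolic_model <- function(metabolites, reactions, strain_id = "strain",
                            enzyme_pool = 0.227) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id: ", met_ids[duplicated(met_ids)][1], call. = FALSE)
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ", rxn_ids[duplicated(rxn_ids)][1], call. = FALSE)
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  model <- structure(
    list(strain_id = strain_id, metabolites = metabolites,
         reactions = reactions, enzyme_pool = as.numeric(enzyme_pool)),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model's internal consistency
#'
#' Checks id uniqueness, that every stoichiometry entry references a declared
#' metabolite, bound ordering, and that at most one reaction carries the
#' biomass role.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors on inconsistency.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- names(model$metabolites)
  for (rxn in model$reactions) {
    missing <- setdiff(names(rxn$stoich), met_ids)
    if (length(missing)) {
      stop("reaction '", rxn$id, "' references undefined metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  roles <- vapply(model$reactions, `[[`, character(1), "role")
  if (sum(roles == "biomass") > 1L) {
    stop("model '", model$strain_id, "' has more than one biomass reaction",
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  roles <- vapply(x$reactions, `[[`, character(1), "role")
  cat("<metabolic_model> strain:", x$strain_id, "\n",
      " ", length(x$metabolites), "metabolites,", length(x$reactions),
      "reactions (", sum(roles == "biomass"), "biomass,",
      sum(roles == "production"), "production,",
      sum(vapply(x$reactions, `[[`, logical(1), "in_pathway")),
      "in pathway )\n")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (rxn in model$reactions) {
    S[names(rxn$stoich), rxn$id] <- rxn$stoich
  }
  S
}

#' Ids of reactions holding a given role
#' @param model a `metabolic_model`.
#' @param role role to look up.
#' @return character vector of reaction ids.
#' @export
reactions_by_role <- function(model, role) {
  names(model$reactions)[
    vapply(model$reactions, `[[`, character(1), "role") == role]
}

biomass_id <- function(model) {
  ids <- reactions_by_role(model, "biomass")
  if (length(ids) == 0L) {
    stop("model '", model$strain_id,
         "' has no biomass reaction and none was designated", call. = FALSE)
  }
  ids[[1]]
}

production_id <- function(model) {
  ids <- reactions_by_role(model, "production")
  if (length(ids) == 0L) {
    stop("model '", model$strain_id, "' has no production reaction designated",
         call. = FALSE)
  }
  ids[[1]]
}

pathway_ids <- function(model) {
  names(model$reactions)[vapply(model$reactions, `[[`, logical(1), "in_pathway")]
}

#' Thermodynamic configuration
#'
#' Constants of the driving-force model. `Df_i = -(dG0'_i + R*T*sum_m
#' s_mi*lnC_m)`; the big-K constant deactivates the driving-force requirement
#' for reactions whose thermodynamic binary is zero; `df_min` is the minimum
#' driving force every active pathway reaction must achieve (>= 0).
#'
#' @param R gas constant, kJ/(mol*K).
#' @param T temperature, K (default 310.15 K, E. coli culture).
#' @param big_K large constant (kJ/mol) for binary deactivation.
#' @param df_min minimum driving force for active pathway reactions, kJ/mol.
#' @param default_ln_conc_lb,default_ln_conc_ub default log-concentration
#'   bounds applied where a metabolite does not override them.
#' @return a `thermo_config` object.
#' @export
thermo_config <- function(R = 8.314e-3, T = 310.15, big_K = 1000,
                          df_min = 0,
                          default_ln_conc_lb = log(1e-6),
                          default_ln_conc_ub = log(1e-2)) {
  stopifnot(R > 0, T > 0, big_K > 0, df_min >= 0)
  structure(
    list(R = R, T = T, big_K = big_K, df_min = df_min,
         default_ln_conc_lb = default_ln_conc_lb,
         default_ln_conc_ub = default_ln_conc_ub),
    class = "thermo_config"
  )
}

rt <- function(config) config$R * config$T

# ---- serialization -----------------------------------------------------------

#' Read a metabolic model from JSON or SBML
#'
#' JSON is the COBRA-style dialect written by [save_model()]: top-level
#' `metabolites`, `reactions` (with `metabolites` stoichiometry maps and
#' `lower_bound`/`upper_bound`) and an `annotation` block carrying the
#' thermodynamic/kinetic fields. SBML Level 3 with the `fbc` package is read
#' for species, stoichiometry, flux bounds, and the active objective (used to
#' detect the biomass reaction).
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @param biomass_id optional reaction id to designate as biomass when the
#'   file does not identify one.
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("guess", "json", "sbml"),
                       biomass_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "guess") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  model <- switch(format,
                  json = load_model_json(path),
                  sbml = load_model_sbml(path))
  if (!is.null(biomass_id)) {
    if (!biomass_id %in% names(model$reactions)) {
      stop("designated biomass reaction '", biomass_id, "' not in model",
           call. = FALSE)
    }
    model$reactions[[biomass_id]]$role <- "biomass"
  }
  validate_model(model)
  model
}

load_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("model JSON missing required element '", field, "'", call. = FALSE)
    }
  }
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry without id", call. = FALSE)
    metabolite(
      id = m$id, name = m$name %||% m$id, compartment = m$compartment %||% "c",
      ln_conc_lb = m$ln_conc_lb %||% log(1e-6),
      ln_conc_ub = m$ln_conc_ub %||% log(1e-2),
      thermo_tracked = m$thermo_tracked %||% TRUE
    )
  })
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without id", call. = FALSE)
    st <- unlist(r$metabolites)
    reaction(
      id = r$id, stoich = st,
      lb = r$lower_bound %||% 0, ub = r$upper_bound %||% 1000,
      dG0_prime = r$dG0_prime %||% NA_real_,
      kcat = r$kcat %||% NA_real_, mw = r$mw %||% NA_real_,
      in_pathway = r$in_pathway %||% FALSE,
      role = r$role %||% "internal"
    )
  })
  metabolic_model(mets, rxns,
                  strain_id = doc$id %||% "strain",
                  enzyme_pool = doc$annotation$enzyme_pool %||% 0.227)
}

#' Write a metabolic model as COBRA-style JSON
#'
#' The written file reloads to a field-by-field identical model via
#' [load_model()].
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    id = model$strain_id,
    metabolites = lapply(unname(model$metabolites), function(m) {
      list(id = m$id, name = m$name, compartment = m$compartment,
           ln_conc_lb = m$ln_conc_lb, ln_conc_ub = m$ln_conc_ub,
           thermo_tracked = m$thermo_tracked)
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, metabolites = as.list(r$stoich),
                  lower_bound = r$lb, upper_bound = r$ub,
                  in_pathway = r$in_pathway, role = r$role)
      if (!is.na(r$dG0_prime)) out$dG0_prime <- r$dG0_prime
      if (!is.na(r$kcat)) out$kcat <- r$kcat
      if (!is.na(r$mw)) out$mw <- r$mw
      out
    }),
    annotation = list(enzyme_pool = model$enzyme_pool)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  sp_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  if (length(sp_nodes) == 0L) {
    stop("SBML file has no species list: ", path, call. = FALSE)
  }
  mets <- lapply(sp_nodes, function(n) {
    a <- xml2::xml_attrs(n)
    metabolite(id = a[["id"]],
               name = if ("name" %in% names(a)) a[["name"]] else a[["id"]],
               compartment = if ("compartment" %in% names(a)) a[["compartment"]] else "c")
  })
  met_ids <- vapply(mets, `[[`, character(1), "id")

  # fbc flux-bound parameters
  par_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  par_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  # active fbc objective -> biomass reaction
  obj_rxn <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']"), "reaction")

  rxn_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  rxns <- lapply(rxn_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    refs <- function(kind, sign) {
      nodes <- xml2::xml_find_all(
        n, sprintf("./sbml:%s/sbml:speciesReference", kind), ns)
      if (length(nodes) == 0L) return(numeric(0))
      sp <- xml2::xml_attr(nodes, "species")
      bad <- setdiff(sp, met_ids)
      if (length(bad)) {
        stop("SBML reaction '", id, "' references undefined species: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, sp)
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    if (length(st) == 0L) {
      stop("SBML reaction '", id, "' has empty stoichiometry", call. = FALSE)
    }
    lb_ref <- xml2::xml_attr(n, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(n, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) par_vals[[lb_ref]] else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) par_vals[[ub_ref]] else 1000
    role <- if (!is.na(obj_rxn) && identical(id, obj_rxn)) "biomass"
            else if (grepl("biomass", id, ignore.case = TRUE)) "biomass"
            else "internal"
    reaction(id = id, stoich = st, lb = lb, ub = ub, role = role)
  })
  metabolic_model(mets, rxns, strain_id = xml2::xml_attr(
    xml2::xml_find_first(doc, ".//sbml:model", ns), "id") %||% "strain")
}

# ---- annotation tables -------------------------------------------------------

#' Attach standard Gibbs energies to reactions
#'
#' Reads a two-column table (`reaction_id`, `dG0_prime_kJ_mol`) and sets
#' `dG0_prime` on the listed reactions, marking them as pathway reactions
#' (subject to the thermodynamic constraint) unless an optional `in_pathway`
#' column says otherwise. Reaction pairs related by the reverse suffix must
#' carry exactly negated energies.
#'
#' @param model a `metabolic_model`.
#' @param table data frame with columns `reaction_id` and `dG0_prime_kJ_mol`
#'   (optional logical `in_pathway`), or a path to such a TSV.
#' @param reverse_suffix id suffix naming the explicit reverse of a reaction.
#' @return the annotated model.
#' @export
attach_thermo <- function(model, table, reverse_suffix = "_reverse") {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("reaction_id", "dG0_prime_kJ_mol") %in% names(table)))
  unknown <- setdiff(table$reaction_id, names(model$reactions))
  if (length(unknown)) {
    stop("thermo table references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(table))) {
    id <- table$reaction_id[i]
    model$reactions[[id]]$dG0_prime <- as.numeric(table$dG0_prime_kJ_mol[i])
    model$reactions[[id]]$in_pathway <-
      if ("in_pathway" %in% names(table)) isTRUE(as.logical(table$in_pathway[i])) else TRUE
  }
  # reverse pairs must be antisymmetric in dG0'
  for (id in names(model$reactions)) {
    if (!endsWith(id, reverse_suffix)) next
    fwd <- sub(paste0(reverse_suffix, "$"), "", id)
    if (!fwd %in% names(model$reactions)) next
    g_f <- model$reactions[[fwd]]$dG0_prime
    g_r <- model$reactions[[id]]$dG0_prime
    if (!is.na(g_f) && !is.na(g_r) && abs(g_f + g_r) > 1e-9) {
      stop("reverse pair '", fwd, "'/'", id,
           "' must carry negated dG0_prime (got ", g_f, " and ", g_r, ")",
           call. = FALSE)
    }
  }
  model
}

#' Attach enzyme kinetic parameters to reactions
#'
#' Reads a table (`reaction_id`, `kcat_per_h_per_g`, `mw_g_per_mmol`) and sets
#' the per-reaction turnover numbers and molecular weights consumed by the
#' enzyme-pool constraint `sum_i v_i * mw_i / kcat_i <= enzyme_pool`.
#'
#' @param model a `metabolic_model`.
#' @param table data frame with the columns above, or a path to such a TSV.
#' @param enzyme_pool optional override of the pool bound, g/gDW.
#' @return the annotated model.
#' @export
attach_kinetics <- function(model, table, enzyme_pool = NULL) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("reaction_id", "kcat_per_h_per_g", "mw_g_per_mmol") %in% names(table)))
  unknown <- setdiff(table$reaction_id, names(model$reactions))
  if (length(unknown)) {
    stop("kinetics table references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(table$kcat_per_h_per_g <= 0) || any(table$mw_g_per_mmol <= 0)) {
    stop("kcat and mw must be strictly positive", call. = FALSE)
  }
  for (i in seq_len(nrow(table))) {
    id <- table$reaction_id[i]
    model$reactions[[id]]$kcat <- as.numeric(table$kcat_per_h_per_g[i])
    model$reactions[[id]]$mw <- as.numeric(table$mw_g_per_mmol[i])
  }
  if (!is.null(enzyme_pool)) {
    stopifnot(enzyme_pool > 0)
    model$enzyme_pool <- as.numeric(enzyme_pool)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
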