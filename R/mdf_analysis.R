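# Pathway-level thermodynamic reporting: MDF value, bottleneck reactions,
# and metabolite shadow prices.

mark_pathway <- function(model, pathway) {
  bad <- setdiff(pathway, names(model$reactions))
  if (length(bad)) {
    stop("unknown pathway reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (r in names(model$reactions)) {
    model$reactions[[r]]$in_pathway <- r %in% pathway
  }
  model
}

#' Max-min driving force analysis of a pathway
#'
#' Solves the MDF program with every listed reaction forced active and
#' reports the optimal margin B, the per-reaction driving forces at the
#' optimizing concentration vector, the bottleneck reactions (those whose
#' driving force equals B), and the metabolite shadow prices.
#'
#' @param model a `metabolic_model`; listed reactions must carry `dG0_prime`.
#' @param pathway reaction ids forming the pathway.
#' @param config a [thermo_config()].
#' @param shadow compute shadow prices (default `TRUE`).
#' @param bottleneck_tol tolerance on `|Df - B|` for bottleneck calls.
#' @return an `mdf_report`: `B`, `driving_forces`, `bottlenecks`,
#'   `shadow_prices`, `ln_conc`.
#' @export
pathway_mdf <- function(model, pathway, config = thermo_config(),
                        shadow = TRUE, bottleneck_tol = 1e-6) {
  model <- mark_pathway(model, pathway)
  sol <- solve_mdf(model, required_active = pathway, config = config)
  if (sol$status != "optimal") {
    stop("MDF program ", sol$status, " for pathway {",
         paste(pathway, collapse = ", "), "}", call. = FALSE)
  }
  dfs <- sol$driving_forces
  bottlenecks <- names(dfs)[abs(dfs - sol$B) <= bottleneck_tol]
  sp <- if (shadow) shadow_prices(model, pathway, config) else NULL
  structure(
    list(B = sol$B, driving_forces = dfs, bottlenecks = bottlenecks,
         shadow_prices = sp, ln_conc = sol$ln_conc),
    class = "mdf_report"
  )
}

#' @export
print.mdf_report <- function(x, ...) {
  cat("<mdf_report> B =", format(x$B), "kJ/mol; bottleneck(s):",
      paste(x$bottlenecks, collapse = ", "), "\n")
  invisible(x)
}

#' Metabolite shadow prices of the pathway MDF
#'
#' Sensitivity of the optimal margin B to each tracked metabolite's allowed
#' log-concentration (both bounds shifted together): positive means raising
#' the metabolite's permitted concentration raises B. Computed from the dual
#' of the MDF linear program and cross-checked by central finite differences
#' on the bounds; when the two disagree (degenerate optimum with multiple
#' dual solutions, e.g. a pathway containing a reaction and its exact
#' reverse) the finite-difference value is reported and the metabolite is
#' flagged in the `"degenerate"` attribute.
#'
#' @param model a `metabolic_model`.
#' @param pathway reaction ids forming the pathway.
#' @param config a [thermo_config()].
#' @param method `"dual"` (default, with finite-difference cross-check) or
#'   `"fd"` (finite differences only).
#' @param fd_step finite-difference step on the ln-concentration bounds.
#' @param agree_tol dual-vs-difference agreement threshold, kJ/mol.
#' @return named numeric vector over tracked metabolites (metabolites not
#'   touched by the pathway get 0), with logical attribute `"degenerate"`.
#' @export
shadow_prices <- function(model, pathway, config = thermo_config(),
                          method = c("dual", "fd"), fd_step = 1e-3,
                          agree_tol = 1e-4) {
  method <- match.arg(method)
  model <- mark_pathway(model, pathway)
  mets <- thermo_metabolites(model)
  fd <- vapply(mets, function(m) fd_shadow_price(model, pathway, config, m, fd_step),
               numeric(1))
  if (method == "fd") {
    attr(fd, "degenerate") <- rep(FALSE, length(fd))
    return(fd)
  }
  du <- dual_shadow_prices(model, pathway, config)
  degenerate <- abs(du - fd) > agree_tol
  out <- ifelse(degenerate, fd, du)
  names(out) <- mets
  attr(out, "degenerate") <- stats::setNames(degenerate, mets)
  out
}

fd_shadow_price <- function(model, pathway, config, met, h) {
  shifted <- function(s) {
    m2 <- model
    m2$metabolites[[met]]$ln_conc_lb <- m2$metabolites[[met]]$ln_conc_lb + s
    m2$metabolites[[met]]$ln_conc_ub <- m2$metabolites[[met]]$ln_conc_ub + s
    sol <- solve_mdf(m2, required_active = pathway, config = config)
    if (sol$status != "optimal") {
      stop("MDF program ", sol$status, " during finite-difference perturbation of '",
           met, "'", call. = FALSE)
    }
    sol$B
  }
  (shifted(h) - shifted(-h)) / (2 * h)
}

# Dual of the MDF LP:  max B  s.t.  B - coef_i . x <= const_i, lb <= x <= ub.
# Dual variables y_i >= 0 (one per pathway reaction), mu_m, nu_m >= 0 (upper/
# lower box bounds). Shadow price of metabolite m (both bounds shifted
# together) is mu_m - nu_m = sum_i y_i * coef_i[m].
dual_shadow_prices <- function(model, pathway, config) {
  df_expr <- build_driving_forces(model, config)[pathway]
  mets <- thermo_metabolites(model)
  n_p <- length(pathway); n_x <- length(mets)
  n_var <- n_p + 2L * n_x
  iy <- seq_len(n_p)
  imu <- n_p + seq_len(n_x)
  inu <- n_p + n_x + seq_len(n_x)
  lbx <- vapply(mets, function(m) model$metabolites[[m]]$ln_conc_lb, numeric(1))
  ubx <- vapply(mets, function(m) model$metabolites[[m]]$ln_conc_ub, numeric(1))

  obj <- numeric(n_var)
  obj[iy] <- vapply(df_expr, `[[`, numeric(1), "const")
  obj[imu] <- ubx
  obj[inu] <- -lbx

  # sum_i y_i = 1 ; for each m: -sum_i y_i coef_i[m] + mu_m - nu_m = 0
  A_eq <- matrix(0, 1L + n_x, n_var)
  A_eq[1, iy] <- 1
  for (k in seq_len(n_x)) {
    m <- mets[k]
    for (i in seq_len(n_p)) {
      co <- df_expr[[i]]$coef
      if (m %in% names(co)) A_eq[1L + k, i] <- -co[[m]]
    }
    A_eq[1L + k, imu[k]] <- 1
    A_eq[1L + k, inu[k]] <- -1
  }
  b_eq <- c(1, rep(0, n_x))
  res <- solve_lp(obj, NULL, NULL, A_eq, b_eq,
                  lb = rep(0, n_var), ub = rep(Inf, n_var), maximize = FALSE)
  if (res$status != "optimal") {
    stop("dual MDF program ", res$status, call. = FALSE)
  }
  stats::setNames(res$x[imu] - res$x[inu], mets)
}

#' Write an MDF report to TSV and JSON
#'
#' @param report an `mdf_report`.
#' @param path_rxn_tsv per-reaction table (driving force, bottleneck flag);
#'   `NULL` to skip.
#' @param path_met_tsv per-metabolite table (ln-concentration, shadow price);
#'   `NULL` to skip.
#' @param path_json JSON summary; `NULL` to skip.
#' @return the report, invisibly.
#' @export
write_mdf_report <- function(report, path_rxn_tsv = NULL, path_met_tsv = NULL,
                             path_json = NULL) {
  if (!is.null(path_rxn_tsv)) {
    tab <- data.frame(
      reaction_id = names(report$driving_forces),
      driving_force_kJ_mol = as.numeric(report$driving_forces),
      bottleneck = names(report$driving_forces) %in% report$bottlenecks)
    utils::write.table(tab, path_rxn_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_met_tsv) && !is.null(report$shadow_prices)) {
    tab <- data.frame(
      metabolite_id = names(report$shadow_prices),
      ln_conc = as.numeric(report$ln_conc[names(report$shadow_prices)]),
      shadow_price_kJ_mol = as.numeric(report$shadow_prices))
    utils::write.table(tab, path_met_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(B = report$B,
           bottlenecks = as.list(report$bottlenecks),
           driving_forces = as.list(report$driving_forces),
           shadow_prices = as.list(report$shadow_prices)),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
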