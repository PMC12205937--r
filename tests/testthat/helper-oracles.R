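# Independent oracles and shared builders for the test-suite.

# Dense grid search over the log-concentration box: the brute-force oracle
# for the max-min driving force. Enumerates `points` values per tracked
# metabolite dimension, evaluates every pathway driving force at every grid
# node, and returns the best achievable minimum. Independent of the LP path.
grid_mdf <- function(model, pathway, config = thermo_config(), points = 41L) {
  model <- cofactory:::mark_pathway(model, pathway)
  df_expr <- build_driving_forces(model, config)[pathway]
  mets <- cofactory:::thermo_metabolites(model)
  axes <- lapply(mets, function(m) {
    seq(model$metabolites[[m]]$ln_conc_lb, model$metabolites[[m]]$ln_conc_ub,
        length.out = points)
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- mets
  mins <- rep(Inf, nrow(grid))
  for (e in df_expr) {
    df <- rep(e$const, nrow(grid))
    if (length(e$coef)) {
      df <- df + grid[, names(e$coef), drop = FALSE] %*% e$coef
    }
    mins <- pmin(mins, df)
  }
  list(B = max(mins),
       resolution = max(vapply(axes, function(a) diff(a[1:2]), numeric(1))))
}

# worst-case gap between the grid optimum and the continuous optimum:
# moving each coordinate by at most half a grid cell changes any driving
# force by at most RT * sum|s| * h / 2
grid_gap_bound <- function(model, pathway, config, resolution) {
  df_expr <- build_driving_forces(model, config)[pathway]
  max_row <- max(vapply(df_expr, function(e) sum(abs(e$coef)), numeric(1)))
  max_row * resolution / 2 + 1e-9
}

# standard two-strain toy with calibrated-degree strains, ready to integrate
make_consortium_state <- function(d = c(0.035, 0.011),
                                  options = solve_options(),
                                  config = thermo_config()) {
  tc <- toy_consortium()
  strains <- lapply(1:2, function(j) {
    coculture_strain(tc$models[[j]], d[j], options, config,
                     production_rxn = tc$production_rxns[[j]],
                     substrate_rxn = tc$substrate_rxns[[j]])
  })
  list(consortium = tc, strains = strains)
}
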