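# Finite-difference sensitivity of predicted production to biosynthesis
# features: expression degrees of either strain (up or down), and the
# mean-to-instantaneous flux mapping constant (a proxy for carbon-source
# utilization).

sensitivity_features <- c("d_up+", "d_up-", "d_down+", "d_down-",
                          "k+", "k_up+", "k_down+")

feature_label <- function(feature) {
  switch(feature,
         "d_up+" = "IBPE(up)", "d_down+" = "IBPE(down)",
         "d_up-" = "DBPE(up)", "d_down-" = "DBPE(down)",
         "k+" = "ICSU", "k_up+" = "ICSU(up)", "k_down+" = "ICSU(down)")
}

#' Production sensitivity to one biosynthesis feature
#'
#' Perturbs a feature by a relative step, re-runs the full prediction
#' pipeline (re-solving the production program when an expression degree
#' moves, re-integrating when the mapping constant moves), and reports the
#' per-unit production change `puf = (C* - C) / (x* - x)` and its relative
#' form `Rpuf = puf / C`.
#'
#' Features: `"d_up+"`/`"d_up-"` and `"d_down+"`/`"d_down-"` raise or lower
#' the expression degree of the upstream or downstream strain (IBPE/DBPE);
#' `"k+"` raises the consortium mapping constant (ICSU, enhanced
#' carbon-source utilization); `"k_up+"`/`"k_down+"` raise one strain's
#' multiplier only.
#'
#' @param spec a [coculture_spec()] (strain entries must carry `v_nfeg`).
#' @param k a [mapping_constant()].
#' @param feature one of the feature codes above.
#' @param delta relative perturbation (default 0.1); must be nonzero.
#' @return a `sensitivity_result`: `feature`, `label`, `x`, `x_star`, `C`,
#'   `C_star`, `puf`, `Rpuf`, `status`.
#' @export
evaluate_feature <- function(spec, k, feature, delta = 0.1) {
  feature <- match.arg(feature, sensitivity_features)
  if (delta == 0) stop("delta must be nonzero (Rpuf denominator)", call. = FALSE)
  stopifnot(inherits(k, "mapping_constant"))
  C0 <- simulate_production(spec, k)$total

  perturb_d <- function(j, sign) {
    st <- spec$strains[[j]]
    x <- st$d
    x_star <- x * (1 + sign * delta)
    if (x == 0 && sign > 0) x_star <- delta  # degree of exactly zero: step up absolutely
    if (x_star < 0 || x_star > 1) {
      stop("perturbed expression degree ", format(x_star),
           " outside [0, 1]", call. = FALSE)
    }
    sol <- max_production(st$model, growth_lb = (1 - x_star) * st$v_nfeg,
                          spec$options, spec$config)
    if (sol$status != "optimal") {
      return(list(x = x, x_star = x_star, C_star = NA_real_, status = sol$status))
    }
    spec2 <- spec
    spec2$strains[[j]]$d <- x_star
    spec2$strains[[j]]$solution <- sol
    list(x = x, x_star = x_star,
         C_star = simulate_production(spec2, k)$total, status = "optimal")
  }
  perturb_k <- function(which_j) {
    if (is.null(which_j)) {
      x <- k$k
      x_star <- x * (1 + delta)
      k2 <- k; k2$k <- x_star
    } else {
      x <- k$k_per_strain[which_j]
      kp <- k$k_per_strain
      kp[which_j] <- x * (1 + delta)
      x_star <- kp[which_j]
      k2 <- mapping_constant(kp, k$icr)
    }
    list(x = x, x_star = x_star,
         C_star = simulate_production(spec, k2)$total, status = "optimal")
  }
  res <- switch(feature,
                "d_up+" = perturb_d(1, +1), "d_up-" = perturb_d(1, -1),
                "d_down+" = perturb_d(2, +1), "d_down-" = perturb_d(2, -1),
                "k+" = perturb_k(NULL),
                "k_up+" = perturb_k(1), "k_down+" = perturb_k(2))
  puf <- if (res$status == "optimal") (res$C_star - C0) / (res$x_star - res$x)
         else NA_real_
  structure(
    list(feature = feature, label = feature_label(feature),
         x = res$x, x_star = res$x_star, C = C0, C_star = res$C_star,
         puf = puf, Rpuf = if (C0 > 0) puf / C0 else NA_real_,
         status = res$status),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>", x$label, " puf =", format(x$puf),
      " Rpuf =", format(x$Rpuf), "\n")
  invisible(x)
}

#' Rank engineering strategies by production sensitivity
#'
#' Evaluates every requested feature at the given consortium state and
#' returns them sorted by decreasing relative per-unit effect (Rpuf).
#'
#' @param spec a [coculture_spec()].
#' @param k a [mapping_constant()].
#' @param features feature codes (see [evaluate_feature()]); defaults to
#'   both strains' degree increases and the carbon-utilization lever.
#' @param delta relative perturbation.
#' @return data frame, one row per feature, sorted by descending `Rpuf`.
#' @export
rank_strategies <- function(spec, k,
                            features = c("d_up+", "d_down+", "k+"),
                            delta = 0.1) {
  stopifnot(length(features) >= 1)
  rows <- lapply(features, function(f) {
    r <- evaluate_feature(spec, k, f, delta)
    data.frame(feature = r$feature, label = r$label, x = r$x,
               x_star = r$x_star, C = r$C, C_star = r$C_star,
               puf = r$puf, Rpuf = r$Rpuf, status = r$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$Rpuf), , drop = FALSE]
}
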