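#' Fit metrics between simulated and experimental values
#'
#' Mean relative error `MRE = mean(|sim - exp| / exp)`, coefficient of
#' determination `R2 = 1 - SSres / SStot` (computed against the experimental
#' mean, so it may be negative for a poor model; `NA` when the experimental
#' values have zero variance), and a similarity P value: the two-sided
#' paired t-test of the differences against zero, where a large P means the
#' simulation is statistically indistinguishable from the measurements.
#' Identically zero differences give `p_similar = 1` by convention.
#'
#' @param simulated,experimental numeric vectors of equal length >= 2;
#'   experimental values must be strictly positive (MRE denominator).
#' @return a `fit_metrics` list: `mre`, `r2`, `p_similar`.
#' @export
fit_metrics <- function(simulated, experimental) {
  stopifnot(length(simulated) == length(experimental), length(simulated) >= 2)
  if (any(experimental <= 0)) {
    stop("experimental values must be strictly positive for MRE", call. = FALSE)
  }
  mre <- mean(abs(simulated - experimental) / experimental)
  ss_tot <- sum((experimental - mean(experimental))^2)
  r2 <- if (ss_tot > 0) 1 - sum((experimental - simulated)^2) / ss_tot
        else NA_real_
  d <- simulated - experimental
  p <- if (all(abs(d) < .Machine$double.eps * 100)) 1
       else stats::t.test(simulated, experimental, paired = TRUE)$p.value
  structure(list(mre = mre, r2 = r2, p_similar = p), class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("MRE = %.3f   R2 = %s   P = %.3f\n",
              x$mre, ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)),
              x$p_similar))
  invisible(x)
}
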