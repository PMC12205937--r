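# Internal linear-programming kernel.
#
# The optimization problems assembled in this package (flux balance, enzyme
# pool, driving forces over a log-concentration box, and their LP duals) are
# small and dense, but they are degenerate in ways that defeat the
# teaching-grade simplex shipped in recommended packages (boot::simplex
# produces NaN pivots on them). The kernel below is a standard two-phase
# dense simplex with Bland's anti-cycling rule: slower than a production
# solver, but deterministic and guaranteed to terminate, which is what the
# toy-scale problems and the test oracles need.
#
# dense_simplex: minimize/maximize a'x, x >= 0, subject to
#   A1 x <= b1,  A2 x >= b2,  A3 x == b3,  all b >= 0.
dense_simplex <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                          A3 = NULL, b3 = NULL, maxi = FALSE, tol = 1e-9) {
  n <- length(a)
  m1 <- length(b1); m2 <- length(b2); m3 <- length(b3)
  m <- m1 + m2 + m3
  if (m == 0L) stop("dense_simplex called without constraints")
  rows <- rbind(
    if (m1) cbind(matrix(A1, ncol = n), diag(m1),
                  matrix(0, m1, m2)) else NULL,
    if (m2) cbind(matrix(A2, ncol = n), matrix(0, m2, m1),
                  -diag(m2)) else NULL,
    if (m3) cbind(matrix(A3, ncol = n), matrix(0, m3, m1),
                  matrix(0, m3, m2)) else NULL
  )
  b <- c(b1, b2, b3)
  N <- n + m1 + m2
  # artificials for >= and == rows; slacks start basic for <= rows
  n_art <- m2 + m3
  art_cols <- if (n_art) N + seq_len(n_art) else integer(0)
  Tb <- cbind(rows,
              if (n_art) rbind(matrix(0, m1, n_art), diag(n_art)) else NULL,
              b)
  basis <- c(if (m1) n + seq_len(m1) else integer(0), art_cols)
  ncols <- ncol(Tb)
  rhs <- ncols

  run_phase <- function(Tb, basis, cost, blocked) {
    # maintain reduced-cost row for minimization of cost'x
    red <- cost
    for (i in seq_len(m)) {
      cb <- cost[basis[i]]
      if (cb != 0) red <- red - cb * Tb[i, seq_len(ncols - 1L)]
    }
    repeat {
      enter <- 0L
      for (j in seq_len(ncols - 1L)) {      # Bland: smallest eligible index
        if (!blocked[j] && red[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return(list(Tb = Tb, basis = basis, status = "optimal"))
      ratios <- ifelse(Tb[, enter] > tol, Tb[, rhs] / Tb[, enter], Inf)
      if (all(is.infinite(ratios))) {
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      }
      rmin <- min(ratios)
      cand <- which(ratios <= rmin + tol)
      leave <- cand[which.min(basis[cand])]  # Bland on ties
      piv <- Tb[leave, enter]
      Tb[leave, ] <- Tb[leave, ] / piv
      upd <- which(abs(Tb[, enter]) > 0 & seq_len(m) != leave)
      if (length(upd)) {
        Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, enter], Tb[leave, ])
      }
      red <- red - red[enter] * Tb[leave, seq_len(ncols - 1L)]
      basis[leave] <- enter
    }
  }

  blocked <- rep(FALSE, ncols - 1L)
  if (n_art) {
    cost1 <- numeric(ncols - 1L); cost1[art_cols] <- 1
    ph1 <- run_phase(Tb, basis, cost1, blocked)
    Tb <- ph1$Tb; basis <- ph1$basis
    infeas <- sum(Tb[basis %in% art_cols, rhs])
    if (ph1$status != "optimal" || infeas > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n),
                  value = NA_real_))
    }
    # drive any zero-level artificial out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      pc <- which(abs(Tb[i, seq_len(N)]) > tol)[1]
      if (!is.na(pc)) {
        piv <- Tb[i, pc]
        Tb[i, ] <- Tb[i, ] / piv
        upd <- which(abs(Tb[, pc]) > 0 & seq_len(m) != i)
        if (length(upd)) {
          Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, pc], Tb[i, ])
        }
        basis[i] <- pc
      }
    }
    blocked[art_cols] <- TRUE
  }
  cost2 <- numeric(ncols - 1L)
  cost2[seq_len(n)] <- if (maxi) -a else a
  ph2 <- run_phase(Tb, basis, cost2, blocked)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  }
  x_full <- numeric(ncols - 1L)
  x_full[ph2$basis] <- ph2$Tb[, rhs]
  x <- x_full[seq_len(n)]
  list(status = "optimal", x = x, value = sum(a * x))
}

# solve_lp: general-form front end.
#   maximize/minimize obj'x  s.t.  A_ub x <= b_ub, A_eq x = b_eq,
#   lb <= x <= ub  (bounds may be infinite; variables may be free).
solve_lp <- function(obj, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                     lb, ub, maximize = TRUE, eps = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  }
  if (is.null(A_ub)) { A_ub <- matrix(0, 0, n); b_ub <- numeric(0) }
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  A_ub <- matrix(A_ub, ncol = n); A_eq <- matrix(A_eq, ncol = n)

  # Variables touching no constraint row are resolved directly at the
  # favourable bound and removed from the solver's problem.
  touched <- colSums(abs(A_ub)) + colSums(abs(A_eq)) > 0
  if (any(!touched)) {
    loose <- which(!touched)
    xf <- numeric(n)
    for (j in loose) {
      want_hi <- (maximize && obj[j] > 0) || (!maximize && obj[j] < 0)
      xf[j] <- if (want_hi) ub[j] else lb[j]
      if (!is.finite(xf[j])) {
        if (obj[j] == 0) {
          xf[j] <- if (is.finite(lb[j])) lb[j] else if (is.finite(ub[j])) ub[j] else 0
        } else {
          return(list(x = rep(NA_real_, n), objective = NA_real_,
                      status = "unbounded"))
        }
      }
    }
    keep <- which(touched)
    if (length(keep) == 0L) {
      return(list(x = xf, objective = sum(obj * xf), status = "optimal"))
    }
    sub <- solve_lp(obj[keep], A_ub[, keep, drop = FALSE], b_ub,
                    A_eq[, keep, drop = FALSE], b_eq,
                    lb[keep], ub[keep], maximize, eps)
    if (sub$status != "optimal") return(sub)
    xf[keep] <- sub$x
    return(list(x = xf, objective = sum(obj * xf), status = "optimal"))
  }

  # column transforms onto x' >= 0: x = shift + sign * x' (free vars split)
  cols <- vector("list", n)
  shift <- numeric(n)
  extra_rows <- list()
  tcols <- 0L
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      tcols <- tcols + 1L
      cols[[j]] <- list(idx = tcols, sign = 1)
      shift[j] <- lb[j]
      if (is.finite(ub[j])) {
        extra_rows[[length(extra_rows) + 1L]] <- list(col = tcols,
                                                      rhs = ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      tcols <- tcols + 1L
      cols[[j]] <- list(idx = tcols, sign = -1)
      shift[j] <- ub[j]
    } else {
      cols[[j]] <- list(idx = c(tcols + 1L, tcols + 2L), sign = c(1, -1))
      tcols <- tcols + 2L
    }
  }
  to_t <- function(row) {
    out <- numeric(tcols)
    for (j in seq_len(n)) {
      cj <- cols[[j]]
      out[cj$idx] <- out[cj$idx] + row[j] * cj$sign
    }
    out
  }
  const_of <- function(row) sum(row * shift)

  a <- to_t(obj)
  obj_const <- const_of(obj)

  rows1 <- list(); rhs1 <- numeric(0)
  rows2 <- list(); rhs2 <- numeric(0)
  rows3 <- list(); rhs3 <- numeric(0)
  push_le <- function(r, b) {
    if (b >= 0) { rows1[[length(rows1) + 1L]] <<- r; rhs1 <<- c(rhs1, b) }
    else { rows2[[length(rows2) + 1L]] <<- -r; rhs2 <<- c(rhs2, -b) }
  }
  if (nrow(A_ub)) for (i in seq_len(nrow(A_ub))) {
    push_le(to_t(A_ub[i, ]), b_ub[i] - const_of(A_ub[i, ]))
  }
  for (er in extra_rows) {
    r <- numeric(tcols); r[er$col] <- 1; push_le(r, er$rhs)
  }
  if (nrow(A_eq)) for (i in seq_len(nrow(A_eq))) {
    r <- to_t(A_eq[i, ]); b <- b_eq[i] - const_of(A_eq[i, ])
    if (b < 0) { r <- -r; b <- -b }
    rows3[[length(rows3) + 1L]] <- r; rhs3 <- c(rhs3, b)
  }

  stack <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  res <- dense_simplex(
    a,
    A1 = stack(rows1), b1 = if (length(rhs1)) rhs1 else NULL,
    A2 = stack(rows2), b2 = if (length(rhs2)) rhs2 else NULL,
    A3 = stack(rows3), b3 = if (length(rhs3)) rhs3 else NULL,
    maxi = maximize, tol = eps
  )
  if (res$status != "optimal") {
    return(list(x = rep(NA_real_, n), objective = NA_real_,
                status = res$status))
  }
  xt <- res$x
  x <- vapply(seq_len(n), function(j) {
    cj <- cols[[j]]
    shift[j] + sum(cj$sign * xt[cj$idx])
  }, numeric(1))
  list(x = x, objective = sum(obj * x), status = "optimal")
}
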