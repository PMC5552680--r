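# Dense two-phase tableau simplex with Bland's anti-cycling rule.
# Solves   min c'x   s.t.  A x = b,  x >= 0   (b made non-negative by row
# flips).  Problem sizes in this package are tiny (tens of variables), so a
# plain dense tableau is both adequate and easy to audit.
#
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
.simplex_core <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  T <- cbind(A, diag(m), b)        # structural | artificial | rhs
  basis <- n + seq_len(m)
  rhs <- ncol(T)
  pivot <- function(r, j) {
    T[r, ] <<- T[r, ] / T[r, j]
    other <- setdiff(seq_len(m), r)
    T[other, ] <<- T[other, ] - outer(T[other, j], T[r, ])
    basis[r] <<- j
  }
  # minimise cost over the allowed columns; Bland's rule throughout
  run_phase <- function(cost, cols) {
    repeat {
      red <- cost[cols] - drop(crossprod(cost[basis],
                                         T[, cols, drop = FALSE]))
      red[match(basis, cols, nomatch = 0)] <- 0
      enter <- cols[red < -tol]
      if (!length(enter)) return("optimal")
      j <- min(enter)
      rows <- which(T[, j] > tol)
      if (!length(rows)) return("unbounded")
      ratio <- T[rows, rhs] / T[rows, j]
      r <- rows[ratio == min(ratio)]
      if (length(r) > 1) r <- r[which.min(basis[r])]
      pivot(r, j)
    }
  }
  st1 <- run_phase(c(rep(0, n), rep(1, m)), seq_len(n + m))
  if (sum(T[basis > n, rhs]) > 1e-7) return(list(status = "infeasible"))
  for (r in which(basis > n)) {    # drive zero-level artificials out
    cand <- which(abs(T[r, seq_len(n)]) > tol)
    if (length(cand)) pivot(r, min(cand))
  }
  # stuck artificials (redundant rows) stay basic at zero with zero cost;
  # restricting the column set keeps them from re-entering
  st2 <- run_phase(c(cvec, rep(0, m)), seq_len(n))
  if (st2 == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- pmax(0, T[inb, rhs])
  list(status = "optimal", x = x, value = sum(cvec * x))
}

# general interface: min/max obj'x  s.t.  Aeq x = beq,  lb <= x <= ub.
# Shifts variables by lb and adds slack rows for finite upper bounds, then
# calls .simplex_core.  Non-finite bounds are capped at +-.lp_cap; an
# optimum touching a cap is flagged as unbounded (model defect).
.lp_cap <- 1e6

.solve_lp <- function(obj, Aeq, beq, lb, ub, maximise = FALSE) {
  lb <- pmax(lb, -.lp_cap); ub <- pmin(ub, .lp_cap)
  w <- ub - lb
  if (any(w < 0)) return(list(status = "infeasible"))
  free <- which(w > 1e-12)
  b0 <- beq - drop(Aeq %*% lb)
  const <- sum(obj * lb)
  if (!length(free)) {
    if (length(b0) && max(abs(b0)) > 1e-9) return(list(status = "infeasible"))
    return(list(status = "optimal", x = lb, value = const))
  }
  nf <- length(free)
  # rows: equalities, then y_i + s_i = w_i for each shifted variable
  A <- rbind(cbind(Aeq[, free, drop = FALSE], matrix(0, nrow(Aeq), nf)),
             cbind(diag(nf), diag(nf)))
  b <- c(b0, w[free])
  cvec <- c(if (maximise) -obj[free] else obj[free], rep(0, nf))
  sol <- .simplex_core(cvec, A, b)
  if (sol$status != "optimal") return(list(status = sol$status))
  x <- lb
  x[free] <- lb[free] + sol$x[seq_len(nf)]
  if (any(abs(x) >= .lp_cap - 1e-3))
    return(list(status = "unbounded"))
  list(status = "optimal", x = x, value = sum(obj * x))
}
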