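#' Solve a linear program with a dense two-phase simplex
#'
#' Minimizes (or maximizes) `obj %*% v` subject to `Aeq v = beq`,
#' `Ale v <= ble` and box bounds `lb <= v <= ub`. All bounds must be finite;
#' flux balance problems satisfy this by construction since every reaction
#' carries finite bounds. The solver is a textbook two-phase primal simplex
#' on the dense tableau with Bland's anti-cycling rule, so repeated calls on
#' identical input are bit-stable.
#'
#' @param obj numeric objective coefficients, length n.
#' @param Aeq,beq equality constraints (matrix m_e x n, vector m_e), or NULL.
#' @param Ale,ble inequality constraints `Ale v <= ble`, or NULL.
#' @param lb,ub finite lower/upper variable bounds, length n.
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and the solution vector `x` (NA unless optimal).
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                     lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp() requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  cost <- if (maximize) -obj else obj

  # Shift x = v - lb so x >= 0, then append slacks for <= rows and upper bounds.
  me <- if (is.null(Aeq)) 0L else nrow(Aeq)
  mi <- if (is.null(Ale)) 0L else nrow(Ale)
  rng <- ub - lb
  bounded <- which(rng < Inf)            # all, given the finiteness check
  nb <- length(bounded)

  A <- matrix(0, me + mi + nb, n + mi + nb)
  b <- numeric(me + mi + nb)
  if (me > 0) {
    A[seq_len(me), seq_len(n)] <- Aeq
    b[seq_len(me)] <- beq - as.vector(Aeq %*% lb)
  }
  if (mi > 0) {
    r <- me + seq_len(mi)
    A[r, seq_len(n)] <- Ale
    A[cbind(r, n + seq_len(mi))] <- 1
    b[r] <- ble - as.vector(Ale %*% lb)
  }
  if (nb > 0) {
    r <- me + mi + seq_len(nb)
    A[cbind(r, bounded)] <- 1
    A[cbind(r, n + mi + seq_len(nb))] <- 1
    b[r] <- rng[bounded]
  }
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  m <- nrow(A)
  N <- ncol(A)
  # Phase I: artificial basis.
  Tab <- cbind(A, diag(m))
  basis <- N + seq_len(m)
  c1 <- c(rep(0, N), rep(1, m))
  ph1 <- .simplex_iterate(Tab, b, basis, c1, tol)
  if (ph1$status != "optimal" || ph1$objective > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  Tab <- ph1$Tab; b <- ph1$rhs; basis <- ph1$basis

  # Drive any residual artificial out of the (degenerate) basis.
  art <- which(basis > N)
  for (i in art) {
    row <- Tab[i, seq_len(N)]
    j <- which(abs(row) > tol)
    if (length(j) == 0) next      # redundant row; harmless to keep
    j <- j[1]
    piv <- Tab[i, j]
    Tab[i, ] <- Tab[i, ] / piv; b[i] <- b[i] / piv
    fac <- Tab[, j]; fac[i] <- 0
    Tab <- Tab - outer(fac, Tab[i, ]); b <- b - fac * b[i]
    basis[i] <- j
  }
  Tab[, N + seq_len(m)] <- 0   # artificials locked out of phase II

  c2 <- c(cost, rep(0, N - n), rep(0, m))
  ph2 <- .simplex_iterate(Tab, b, basis, c2, tol)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  xs <- numeric(N + m)
  xs[ph2$basis] <- ph2$rhs
  v <- lb + xs[seq_len(n)]
  list(status = "optimal", objective = sum(obj * v), x = v)
}

# One simplex phase on a tableau already in canonical form w.r.t. `basis`.
.simplex_iterate <- function(Tab, rhs, basis, cost, tol = 1e-9,
                             maxit = 50000L) {
  red <- cost - as.vector(crossprod(cost[basis], Tab))
  for (it in seq_len(maxit)) {
    enter <- which(red < -tol)
    if (length(enter) == 0) {
      return(list(status = "optimal", Tab = Tab, rhs = rhs, basis = basis,
                  objective = sum(cost[basis] * rhs)))
    }
    j <- enter[1]                               # Bland: lowest index enters
    col <- Tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0)
      return(list(status = "unbounded", basis = basis))
    ratios <- rhs[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- cand[which.min(basis[cand])]           # Bland: lowest basic leaves
    piv <- Tab[i, j]
    Tab[i, ] <- Tab[i, ] / piv
    rhs[i] <- rhs[i] / piv
    fac <- Tab[, j]; fac[i] <- 0
    nz <- which(abs(fac) > 0)
    if (length(nz) > 0) {
      Tab[nz, ] <- Tab[nz, , drop = FALSE] - outer(fac[nz], Tab[i, ])
      rhs[nz] <- rhs[nz] - fac[nz] * rhs[i]
    }
    red <- red - red[j] * Tab[i, ]
    rhs[rhs < 0 & rhs > -tol] <- 0
    basis[i] <- j
  }
  stop("simplex failed to converge within ", maxit, " iterations")
}
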