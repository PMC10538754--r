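# Internal optimization layer.
#
# Every stage of the pipeline is a linear or convex quadratic program over a
# finite box. LPs go through pracma::linprog (dense two-phase/big-M simplex);
# projections go through quadprog::solve.QP after eliminating the equality
# constraints with a null-space parameterization, which keeps the reduced
# Hessian positive definite and avoids the degeneracies that the active-set
# method hits when equalities are fed as opposing inequality pairs.

# Solve min/max obj'x  s.t.  Aeq x = beq, Aineq x <= bineq, lb <= x <= ub.
# All variables must satisfy lb >= 0 (callers work on split, irreversible
# networks; auxiliary variables are non-negative by construction).
lp_solve <- function(obj, Aeq, beq, Aineq = NULL, bineq = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n,
            all(lb >= 0), all(is.finite(ub)))
  A <- diag(n)               # x <= ub
  b <- ub
  pos <- which(lb > 0)
  if (length(pos) > 0) {     # -x <= -lb for strictly positive lower bounds
    A <- rbind(A, -diag(n)[pos, , drop = FALSE])
    b <- c(b, -lb[pos])
  }
  if (!is.null(Aineq)) {
    A <- rbind(A, Aineq)
    b <- c(b, bineq)
  }
  iter <- max(500L, 50L * (n + nrow(A) + nrow(Aeq)))
  res <- NULL
  for (bigM in c(1e4, 1e6, 1e8)) {
    res <- suppressWarnings(
      try(pracma::linprog(cc = obj, A = A, b = b, Aeq = Aeq, beq = beq,
                          maxiter = iter, bigM = bigM, maximize = maximize),
          silent = TRUE))
    if (!inherits(res, "try-error") && isTRUE(res$errno == 1)) break
  }
  if (inherits(res, "try-error") || !isTRUE(res$errno == 1)) {
    # the big-M code path hits singular bases on degenerate problems
    # (pairs of |.|-linearization rows active at zero); fall back to the
    # package's own two-phase simplex, which pivots with anti-cycling
    alt <- simplex_two_phase(obj, A, b, Aeq, beq, maximize = maximize)
    if (alt$status != "optimal") {
      return(list(status = "infeasible", message = alt$message, x = NULL,
                  value = NA_real_))
    }
    res <- list(x = alt$x, fval = alt$value, message = "two-phase fallback")
  }
  x <- res$x
  # audit the returned point; the big-M simplex can silently return junk
  tol <- 1e-7 * max(1, max(abs(b)), max(abs(beq)))
  if (max(abs(Aeq %*% x - beq)) > tol || any(x < lb - tol) || any(x > ub + tol) ||
      (!is.null(Aineq) && any(Aineq %*% x - bineq > tol))) {
    return(list(status = "infeasible",
                message = "solver returned an infeasible point", x = NULL,
                value = NA_real_))
  }
  list(status = "optimal", x = x, value = res$fval, message = res$message)
}

lp_feasible <- function(Aeq, beq, Aineq = NULL, bineq = NULL, lb, ub) {
  res <- lp_solve(rep(0, length(lb)), Aeq, beq, Aineq, bineq, lb, ub)
  res$status == "optimal"
}

# Reduce a (possibly redundant, consistent) equality system to independent
# rows; returns NULL if inconsistent.
reduce_equalities <- function(Aeq, beq, tol = 1e-9) {
  qrE <- qr(t(Aeq))
  rank <- qrE$rank
  keep <- sort(qrE$pivot[seq_len(rank)])
  Aeq_r <- Aeq[keep, , drop = FALSE]
  beq_r <- beq[keep]
  x0 <- drop(MASS::ginv(Aeq_r) %*% beq_r)
  scale <- max(1, max(abs(beq)))
  if (max(abs(Aeq %*% x0 - beq)) > tol * scale) return(NULL)
  list(Aeq = Aeq_r, beq = beq_r, x0 = x0)
}

# Euclidean projection of `target` onto
#   { x : Aeq x = beq, Aineq x <= bineq, lb <= x <= ub }.
# Fixed coordinates (lb == ub) are promoted to equality rows. `aux` appends
# extra variables (e.g. absolute-value linearizers) that enter the objective
# only through a tiny ridge; their target is 0.
qp_project <- function(target, Aeq, beq, Aineq = NULL, bineq = NULL,
                       lb, ub, n_aux = 0, ridge = 1e-8, tol = 1e-9) {
  nv <- length(target)
  n <- nv + n_aux
  fixed <- which(abs(ub - lb) < 1e-12)
  Eq <- Aeq
  be <- beq
  if (length(fixed) > 0) {
    Eq <- rbind(Eq, diag(n)[fixed, , drop = FALSE])
    be <- c(be, lb[fixed])
  }
  red <- reduce_equalities(Eq, be)
  if (is.null(red)) stop("projection equality system is inconsistent")
  N <- MASS::Null(t(red$Aeq))
  x0 <- red$x0
  if (ncol(N) == 0) {                      # unique point
    if (any(x0 < lb - 1e-7) || any(x0 > ub + 1e-7))
      stop("projection set is empty (unique equality point violates bounds)")
    return(x0[seq_len(nv)])
  }
  free <- setdiff(seq_len(n), fixed)
  G <- rbind(diag(n)[free, , drop = FALSE] %*% N,
             -diag(n)[free, , drop = FALSE] %*% N)
  h <- c(lb[free] - x0[free], -(ub[free] - x0[free]))
  if (!is.null(Aineq)) {
    G <- rbind(G, -Aineq %*% N)            # quadprog wants G x >= h
    h <- c(h, -(bineq - drop(Aineq %*% x0)))
  }
  nz <- sqrt(rowSums(G^2)) > 1e-10
  if (any(h[!nz] > 1e-7))
    stop("projection set is empty (constraint violated on null directions)")
  G <- G[nz, , drop = FALSE]
  h <- h[nz]
  w <- c(rep(1, nv), rep(ridge, n_aux))
  D <- crossprod(N * sqrt(w))
  D <- D + diag(1e-12, ncol(N))            # guard against rank loss
  full_target <- c(target, rep(0, n_aux))
  d <- drop(crossprod(N, w * (full_target - x0)))
  sol <- try(quadprog::solve.QP(D, d, t(G), h), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("quadratic projection failed: ",
         conditionMessage(attr(sol, "condition")))
  x <- drop(x0 + N %*% sol$solution)
  x[seq_len(nv)]
}
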