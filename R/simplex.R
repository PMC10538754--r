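# Dense two-phase primal simplex, written for the small, heavily degenerate
# LPs this package produces (absolute-value linearizations create many
# vertices where basic variables sit at zero). Dantzig pricing with an
# automatic switch to Bland's rule guards against cycling. Only intended for
# the problem sizes of this package (hundreds of variables at most).
#
# Interface matches lp_solve's internal form:
#   min/max obj'x  s.t.  A x <= b, Aeq x = beq, x >= 0
# (general bounds are translated by the caller into rows of A).

simplex_two_phase <- function(obj, A, b, Aeq, beq, maximize = FALSE,
                              tol = 1e-9, maxit = NULL) {
  n <- length(obj)
  cc <- if (maximize) -obj else obj
  # standard form: slacks on inequality rows, artificials everywhere needed
  m1 <- if (is.null(A)) 0L else nrow(A)
  m2 <- if (is.null(Aeq)) 0L else nrow(Aeq)
  M <- rbind(if (m1) cbind(A, diag(m1)) else NULL,
             if (m2) cbind(Aeq, matrix(0, m2, m1)) else NULL)
  rhs <- c(if (m1) b else NULL, if (m2) beq else NULL)
  m <- nrow(M)
  neg <- rhs < 0
  M[neg, ] <- -M[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  ntot <- ncol(M)
  # artificial variables; a slack can serve as the initial basic variable of
  # its own row when the row was not negated
  basis <- integer(m)
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    slack_col <- if (i <= m1 && !neg[i]) n + i else 0L
    if (slack_col > 0) {
      basis[i] <- slack_col
    } else {
      M <- cbind(M, replace(numeric(m), i, 1))
      art_cols <- c(art_cols, ncol(M))
      basis[i] <- ncol(M)
    }
  }
  nall <- ncol(M)
  if (is.null(maxit)) maxit <- 2000L + 60L * (nall + m)

  run_phase <- function(M, rhs, basis, cost, allow, maxit, tol) {
    m <- nrow(M)
    it <- 0L
    bland <- FALSE
    stall <- 0L
    last_obj <- Inf
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "iteration-limit", M = M,
                                  rhs = rhs, basis = basis))
      cb <- cost[basis]
      # reduced costs: c_j - cb' B^-1 A_j; with tableau form M already B^-1 A
      red <- cost - drop(crossprod(M, cb))
      red[basis] <- 0
      cand <- which(allow & red < -tol)
      if (length(cand) == 0)
        return(list(status = "optimal", M = M, rhs = rhs, basis = basis))
      j <- if (bland) cand[1] else cand[which.min(red[cand])]
      col <- M[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) return(list(status = "unbounded", M = M,
                                        rhs = rhs, basis = basis))
      ratios <- rhs[pos] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol]
      i <- if (bland) ties[which.min(basis[ties])] else ties[1]
      # pivot on (i, j)
      piv <- M[i, j]
      M[i, ] <- M[i, ] / piv
      rhs[i] <- rhs[i] / piv
      others <- setdiff(seq_len(m), i)
      f <- M[others, j]
      M[others, ] <- M[others, , drop = FALSE] - outer(f, M[i, ])
      rhs[others] <- rhs[others] - f * rhs[i]
      rhs[rhs < 0 & rhs > -tol] <- 0
      basis[i] <- j
      objv <- sum(cost[basis] * rhs)
      if (objv < last_obj - tol) {
        stall <- 0L
        bland <- FALSE
      } else {
        stall <- stall + 1L
        if (stall > 2L * m) bland <- TRUE   # anti-cycling
      }
      last_obj <- objv
    }
  }

  # phase 1: drive artificials to zero
  if (length(art_cols) > 0) {
    cost1 <- replace(numeric(nall), art_cols, 1)
    allow1 <- rep(TRUE, nall)
    ph1 <- run_phase(M, rhs, basis, cost1, allow1, maxit, tol)
    if (ph1$status != "optimal")
      return(list(status = "infeasible",
                  message = paste("phase 1:", ph1$status)))
    M <- ph1$M; rhs <- ph1$rhs; basis <- ph1$basis
    if (sum(rhs[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible",
                  message = "phase 1 optimum is positive"))
    # pivot remaining (degenerate) artificials out of the basis
    for (i in which(basis %in% art_cols)) {
      piv_j <- which(abs(M[i, seq_len(nall)]) > tol &
                     !(seq_len(nall) %in% c(basis, art_cols)))
      if (length(piv_j) == 0) next      # redundant row; keep, it is zero
      j <- piv_j[1]
      piv <- M[i, j]
      M[i, ] <- M[i, ] / piv
      rhs[i] <- rhs[i] / piv
      others <- setdiff(seq_len(nrow(M)), i)
      f <- M[others, j]
      M[others, ] <- M[others, , drop = FALSE] - outer(f, M[i, ])
      rhs[others] <- rhs[others] - f * rhs[i]
      basis[i] <- j
    }
  }
  # phase 2
  cost2 <- c(cc, numeric(nall - n))
  allow2 <- !(seq_len(nall) %in% art_cols)
  ph2 <- run_phase(M, rhs, basis, cost2, allow2, maxit, tol)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", message = "phase 2 unbounded"))
  if (ph2$status != "optimal")
    return(list(status = "infeasible", message = paste("phase 2:", ph2$status)))
  x <- numeric(nall)
  x[ph2$basis] <- ph2$rhs
  x <- x[seq_len(n)]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = val, message = "ok")
}
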