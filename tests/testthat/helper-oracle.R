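# Independent brute-force oracles used by the optimization tests.
#
# The minimum of a convex piecewise-linear function (sum of |A_i v| or sum v)
# over the polytope {S v = 0, lb <= v <= ub} is attained at a vertex of the
# polytope refined by the hyperplanes A_i v = 0. Those vertices are found by
# exhaustive enumeration of active sets: the rows of S are always active; the
# remaining degrees of freedom are pinned by choosing bound faces (v_j = lb_j
# or ub_j) or sign hyperplanes (A_i v = 0). Every full-rank choice gives a
# candidate point, kept when feasible. This is exponential and only intended
# for networks with <= 8 reactions.

enumerate_arrangement_vertices <- function(model, decomp = NULL, tol = 1e-9) {
  S <- unname(model$S)
  r <- ncol(S)
  lb <- unname(model$lower_bounds)
  ub <- unname(model$upper_bounds)
  rankS <- qr(S)$rank
  d <- r - rankS
  cand_rows <- list()
  cand_rhs <- numeric(0)
  for (j in seq_len(r)) {
    e <- replace(numeric(r), j, 1)
    cand_rows <- c(cand_rows, list(e, e))
    cand_rhs <- c(cand_rhs, lb[j], ub[j])
  }
  if (!is.null(decomp)) {
    for (i in seq_len(nrow(decomp$A))) {
      cand_rows <- c(cand_rows, list(unname(decomp$A[i, ])))
      cand_rhs <- c(cand_rhs, 0)
    }
  }
  nc <- length(cand_rows)
  pts <- list()
  if (d == 0) {
    v <- qr.solve(S, rep(0, nrow(S)))
    if (all(v >= lb - tol) && all(v <= ub + tol)) pts[[1]] <- v
  } else {
    combos <- utils::combn(nc, d)
    for (k in seq_len(ncol(combos))) {
      sel <- combos[, k]
      M <- rbind(S, do.call(rbind, cand_rows[sel]))
      rhs <- c(rep(0, nrow(S)), cand_rhs[sel])
      qrM <- qr(M)
      if (qrM$rank < r) next
      v <- qr.coef(qrM, rhs)
      if (anyNA(v)) next
      if (max(abs(M %*% v - rhs)) > tol) next
      if (all(v >= lb - tol) && all(v <= ub + tol)) pts[[length(pts) + 1]] <- v
    }
  }
  if (length(pts) == 0) return(matrix(numeric(0), 0, r))
  unique(round(do.call(rbind, pts), 9))
}

# Brute-force optimal budgets over the enumerated points.
oracle_budgets <- function(model, decomp) {
  pts <- enumerate_arrangement_vertices(model, decomp)
  stopifnot(nrow(pts) > 0)
  act <- abs(pts %*% t(unname(decomp$A)))
  list(cbfba = min(rowSums(act)), pfba = min(rowSums(abs(pts))))
}

# Pseudo-uniform feasible points: Dirichlet-weighted convex combinations of
# the arrangement vertices. Not uniform over the polytope, but supported on
# all of it, which suffices for one-sided balance checks.
sample_feasible_points <- function(model, decomp, n, seed = 1) {
  pts <- enumerate_arrangement_vertices(model, decomp)
  stopifnot(nrow(pts) > 0)
  set.seed(seed)
  w <- matrix(stats::rexp(n * nrow(pts)), n)
  (w / rowSums(w)) %*% pts
}

# Small bank of seeded random networks used across suites.
oracle_network_bank <- function() {
  specs <- list(
    list(m = 3, r = 4, seed = 11), list(m = 3, r = 5, seed = 12),
    list(m = 4, r = 5, seed = 13), list(m = 4, r = 6, seed = 14),
    list(m = 4, r = 7, seed = 15), list(m = 5, r = 6, seed = 16),
    list(m = 5, r = 7, seed = 17), list(m = 5, r = 8, seed = 18),
    list(m = 6, r = 7, seed = 19), list(m = 6, r = 8, seed = 20),
    list(m = 6, r = 8, seed = 21), list(m = 6, r = 8, seed = 22))
  lapply(specs, function(s) {
    mod <- random_network(m = s$m, r = s$r, seed = s$seed)
    r <- length(mod$reactions)
    # force one demand (the all-ones witness keeps it feasible), plus, when
    # still feasible, a second conflicting demand so that not every network
    # admits a uniform circulation with all complex activities zero
    j0 <- 1 + (s$seed %% r)
    con <- apply_scenario(mod, scenario_constraints(
      data.frame(reaction_id = mod$reactions[j0], lower = 1, upper = 1)))
    for (j1 in setdiff(seq_len(r), j0)) {
      trial <- apply_scenario(con, scenario_constraints(
        data.frame(reaction_id = mod$reactions[j1], lower = 2, upper = 2)))
      ok <- tryCatch({prune(trial); TRUE}, error = function(e) FALSE)
      if (ok) return(trial)
    }
    con
  })
}
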