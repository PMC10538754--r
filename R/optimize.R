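# Shared constraint assembly for the steady-state flux space
#   { v : S v = 0, lb <= v <= ub }
# optionally intersected with the optimal face of cbFBA or pFBA:
#   cbFBA: sum_i |A_i. v| <= budget (linearized with auxiliary t >= |A v|)
#   pFBA:  sum_i v_i      <= budget (v >= 0 on split networks)
# A cbFBA budget indistinguishable from zero is imposed as the equality
# A v = 0, which is numerically exact and avoids an empty-interior budget row.
space_constraints <- function(model, decomp = NULL, objective_kind = NULL,
                              budget = NULL, tau = 1e-6, zero_tol = 1e-9) {
  if (!is_irreversible(model))
    stop("model has reversible reactions; call split_reversible() first")
  nv <- length(model$reactions)
  Aeq <- model$S
  beq <- rep(0, nrow(Aeq))
  Aineq <- NULL; bineq <- NULL
  lb <- unname(model$lower_bounds); ub <- unname(model$upper_bounds)
  n_aux <- 0L
  if (!is.null(objective_kind)) {
    objective_kind <- match.arg(objective_kind, c("cbfba", "pfba"))
    if (is.null(budget)) stop("budget value required with objective_kind")
    cap <- budget * (1 + tau)
    if (objective_kind == "pfba") {
      Aineq <- matrix(1, 1, nv)
      bineq <- cap
    } else {
      if (is.null(decomp))
        stop("cbfba budget requires a complex_decomposition")
      Amat <- unclass(decomp$A)
      cc <- nrow(Amat)
      if (cap <= zero_tol) {
        Aeq <- rbind(Aeq, Amat)
        beq <- c(beq, rep(0, cc))
      } else {
        n_aux <- cc
        Aeq <- cbind(Aeq, matrix(0, nrow(Aeq), cc))
        Aineq <- rbind(cbind(Amat, -diag(cc)),    #  A v - t <= 0
                       cbind(-Amat, -diag(cc)),   # -A v - t <= 0
                       c(rep(0, nv), rep(1, cc))) #  sum t <= cap
        bineq <- c(rep(0, 2 * cc), cap)
        lb <- c(lb, rep(0, cc))
        ub <- c(ub, rep(cap, cc))
      }
    }
  }
  list(nv = nv, n_aux = n_aux, Aeq = Aeq, beq = beq,
       Aineq = Aineq, bineq = bineq, lb = lb, ub = ub)
}

new_flux_distribution <- function(v, model, objective_kind, budget) {
  structure(list(v = stats::setNames(v, model$reactions),
                 objective_kind = objective_kind, budget = budget),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> ", x$objective_kind, ", ", length(x$v),
      " reactions, budget = ", format(x$budget), "\n", sep = "")
  invisible(x)
}

#' Complex-balanced FBA
#'
#' Finds a steady-state flux distribution minimizing the total absolute
#' activity of complexes, `sum_i |A[i, ] %*% v|`, subject to `S v = 0` and the
#' flux bounds. Minimizing this L1 norm of activities approximates maximizing
#' the number of balanced complexes. Absolute values are linearized with
#' auxiliary variables `t_i >= +/- A[i, ] %*% v` and objective `sum t_i`; at
#' the optimum `t_i = |A[i, ] %*% v|`.
#'
#' @param model an irreversible `metabolic_model` (scenario applied, pruned).
#' @param decomp the matching `complex_decomposition`.
#' @return a `flux_distribution` with `objective_kind = "cbfba"` and `budget`
#'   equal to the optimal total absolute activity z.
#' @export
solve_cbfba <- function(model, decomp) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(decomp, "complex_decomposition"))
  if (!is_irreversible(model))
    stop("model has reversible reactions; call split_reversible() first")
  Amat <- unclass(decomp$A)
  cc <- nrow(Amat); nv <- ncol(Amat)
  ub_act <- pmax(drop(abs(Amat) %*% unname(model$upper_bounds)), 1)
  Aeq <- cbind(model$S, matrix(0, nrow(model$S), cc))
  Aineq <- rbind(cbind(Amat, -diag(cc)),
                 cbind(-Amat, -diag(cc)))
  res <- lp_solve(obj = c(rep(0, nv), rep(1, cc)),
                  Aeq = Aeq, beq = rep(0, nrow(Aeq)),
                  Aineq = Aineq, bineq = rep(0, 2 * cc),
                  lb = c(unname(model$lower_bounds), rep(0, cc)),
                  ub = c(unname(model$upper_bounds), ub_act))
  if (res$status != "optimal")
    stop("cbFBA infeasible: ", res$message)
  v <- res$x[seq_len(nv)]
  z <- sum(abs(Amat %*% v))
  new_flux_distribution(v, model, "cbfba", z)
}

#' Parsimonious FBA
#'
#' Finds a steady-state flux distribution minimizing the total flux through
#' the network, `sum_i |v_i|`, subject to `S v = 0` and the flux bounds. On a
#' split (irreversible) network all fluxes are non-negative, so the objective
#' is simply `sum_i v_i`.
#'
#' @param model an irreversible `metabolic_model` (scenario applied, pruned).
#' @return a `flux_distribution` with `objective_kind = "pfba"` and `budget`
#'   equal to the optimal total flux z'.
#' @export
solve_pfba <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is_irreversible(model))
    stop("model has reversible reactions; call split_reversible() first")
  nv <- length(model$reactions)
  res <- lp_solve(obj = rep(1, nv),
                  Aeq = model$S, beq = rep(0, nrow(model$S)),
                  lb = unname(model$lower_bounds),
                  ub = unname(model$upper_bounds))
  if (res$status != "optimal")
    stop("pFBA infeasible: ", res$message)
  new_flux_distribution(res$x, model, "pfba", sum(res$x))
}

#' Flux variability analysis at a fixed optimum
#'
#' Per-reaction minimum and maximum flux over the steady-state space
#' restricted to the optimal face of cbFBA or pFBA: the respective objective
#' is constrained to `budget * (1 + tau)`. Two LPs are solved per reaction.
#'
#' @param model an irreversible `metabolic_model`.
#' @param decomp the matching `complex_decomposition` (required for
#'   `objective_kind = "cbfba"`).
#' @param objective_kind `"cbfba"` or `"pfba"`.
#' @param budget the optimal objective value from [solve_cbfba()] /
#'   [solve_pfba()].
#' @param reactions optional subset of reaction ids (default: all).
#' @param tau relative budget tolerance (default 1e-6). The optimum is the
#'   minimum of the constraint set, so only the upper side needs slack.
#' @return a `flux_ranges` data frame with columns `reaction`, `min`, `max`;
#'   attributes `objective_kind`, `budget`, `tau`.
#' @export
fva <- function(model, decomp = NULL, objective_kind = c("cbfba", "pfba"),
                budget, reactions = NULL, tau = 1e-6) {
  objective_kind <- match.arg(objective_kind)
  cs <- space_constraints(model, decomp, objective_kind, budget, tau)
  if (is.null(reactions)) reactions <- model$reactions
  idx <- match(reactions, model$reactions)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- c(replace(rep(0, cs$nv), idx[k], 1), rep(0, cs$n_aux))
    rmin <- lp_solve(obj, cs$Aeq, cs$beq, cs$Aineq, cs$bineq, cs$lb, cs$ub)
    rmax <- lp_solve(obj, cs$Aeq, cs$beq, cs$Aineq, cs$bineq, cs$lb, cs$ub,
                     maximize = TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("FVA infeasible at the given budget for reaction '",
           reactions[k], "'; consider a larger tau. ", rmin$message)
    lo[k] <- rmin$value; hi[k] <- rmax$value
  }
  structure(data.frame(reaction = reactions, min = pmin(lo, hi),
                       max = pmax(lo, hi), stringsAsFactors = FALSE),
            objective_kind = objective_kind, budget = budget, tau = tau,
            class = c("flux_ranges", "data.frame"))
}

#' Sample steady-state flux distributions at a fixed optimum
#'
#' Draws `n` random flux vectors componentwise uniform within the bounds and
#' projects each onto the steady-state space restricted to the optimal face
#' (same constraint set as [fva()]) by minimizing the Euclidean distance
#' (one convex QP per sample). All random draws are generated up front from
#' `seed`, so per-sample results do not depend on projection order, and
#' identical seeds give identical sample sets.
#'
#' @inheritParams fva
#' @param n number of samples (default 1000).
#' @param seed integer RNG seed.
#' @return a `sample_set`: list with `samples` (n x reactions matrix), `seed`,
#'   `objective_kind`, `budget`, `tau`.
#' @export
sample_fluxes <- function(model, decomp = NULL,
                          objective_kind = c("cbfba", "pfba"),
                          budget, n = 1000, seed = 1, tau = 1e-6) {
  objective_kind <- match.arg(objective_kind)
  cs <- space_constraints(model, decomp, objective_kind, budget, tau)
  nv <- cs$nv
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  draws <- matrix(stats::runif(n * nv,
                               rep(unname(model$lower_bounds), each = n),
                               rep(unname(model$upper_bounds), each = n)),
                  nrow = n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  samples <- matrix(NA_real_, n, nv,
                    dimnames = list(NULL, model$reactions))
  for (k in seq_len(n)) {
    samples[k, ] <- qp_project(draws[k, ], cs$Aeq, cs$beq, cs$Aineq, cs$bineq,
                               cs$lb, cs$ub, n_aux = cs$n_aux)
  }
  structure(list(samples = samples, seed = as.integer(seed),
                 objective_kind = objective_kind, budget = budget, tau = tau),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$samples), " samples x ", ncol(x$samples),
      " reactions (", x$objective_kind, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Robust per-reaction mean flux of a sample set
#'
#' @param samples a `sample_set` (or plain samples-by-reactions matrix).
#' @param trim trimming fraction passed to [mean()] (default 0 = plain mean).
#' @return named numeric vector of per-reaction mean fluxes.
#' @export
robust_mean <- function(samples, trim = 0) {
  m <- if (inherits(samples, "sample_set")) samples$samples else as.matrix(samples)
  if (nrow(m) == 0) stop("empty sample set")
  apply(m, 2, mean, trim = trim)
}
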