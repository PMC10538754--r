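#' Decompose a stoichiometric matrix into complex composition and incidence
#'
#' Writes `S = Y %*% A`, where `Y` (metabolites x complexes) holds the
#' non-negative stoichiometry with which metabolites enter complexes, and `A`
#' (complexes x reactions) is the incidence matrix of the directed complex
#' graph: each reaction column has a single `-1` at its substrate complex and
#' a single `+1` at its product complex. The substrate complex of reaction j
#' collects `|S[i,j]|` over the negative entries of column j, the product
#' complex the positive entries; identical sides across reactions share one
#' complex node. All exchange reactions share the single empty complex (the
#' environment node, labelled `O`).
#'
#' @param model an irreversible `metabolic_model` (split reversibles first).
#' @param tol relative tolerance for identifying two complexes with floating
#'   point stoichiometries (default 1e-9).
#' @return a `complex_decomposition`: list with `Y`, `A`, `complexes` (list of
#'   named coefficient vectors), `labels`, `metabolites`, `reactions`.
#' @export
decompose <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is_irreversible(model))
    stop("model has reversible reactions; call split_reversible() first")
  S <- model$S
  m <- nrow(S); r <- ncol(S)
  cols <- list()             # complex coefficient vectors (length m)
  find_complex <- function(x) {
    for (k in seq_along(cols)) {
      if (max(abs(cols[[k]] - x)) <= tol * max(1, max(abs(x)), max(abs(cols[[k]]))))
        return(k)
    }
    0L
  }
  sub_of <- integer(r); prod_of <- integer(r)
  null_rxn <- logical(r)
  for (j in seq_len(r)) {
    s <- S[, j]
    h <- ifelse(s < 0, -s, 0)    # substrate side
    t <- ifelse(s > 0, s, 0)     # product side
    if (max(abs(h - t)) <= tol) {
      null_rxn[j] <- TRUE
      next
    }
    hi <- find_complex(h)
    if (hi == 0L) { cols[[length(cols) + 1L]] <- h; hi <- length(cols) }
    ti <- find_complex(t)
    if (ti == 0L) { cols[[length(cols) + 1L]] <- t; ti <- length(cols) }
    sub_of[j] <- hi; prod_of[j] <- ti
  }
  if (any(null_rxn))
    warning("reaction(s) with identical substrate and product complex ",
            "excluded from the complex graph: ",
            paste(model$reactions[null_rxn], collapse = ", "))
  cc <- length(cols)
  Y <- matrix(0, m, cc, dimnames = list(model$metabolites, NULL))
  for (k in seq_len(cc)) Y[, k] <- cols[[k]]
  A <- matrix(0L, cc, r, dimnames = list(NULL, model$reactions))
  for (j in seq_len(r)) {
    if (null_rxn[j]) next
    A[sub_of[j], j] <- -1L
    A[prod_of[j], j] <- 1L
  }
  labels <- vapply(cols, function(x) complex_label(x, model$metabolites),
                   character(1))
  rownames(A) <- labels
  colnames(Y) <- labels
  resid <- max(abs(Y %*% A - S))
  if (resid > tol * max(1, max(abs(S))))
    stop("internal error: Y %*% A does not reproduce S (residual ", resid, ")")
  complexes <- lapply(cols, function(x) {
    nz <- x > 0
    stats::setNames(x[nz], model$metabolites[nz])
  })
  structure(list(Y = Y, A = A, complexes = complexes, labels = labels,
                 metabolites = model$metabolites, reactions = model$reactions),
            class = "complex_decomposition")
}

complex_label <- function(coefs, metabolites) {
  nz <- which(coefs > 0)
  if (length(nz) == 0) return("O")
  parts <- ifelse(coefs[nz] == 1, metabolites[nz],
                  paste0(format(coefs[nz], trim = TRUE), " ",
                         metabolites[nz]))
  paste(parts, collapse = " + ")
}

#' @export
print.complex_decomposition <- function(x, ...) {
  cat("<complex_decomposition> ", length(x$labels), " complexes, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  ", paste(utils::head(x$labels, 10), collapse = ", "),
      if (length(x$labels) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Complex activities of a flux distribution
#'
#' The activity of complex i is the total flux of reactions producing the
#' complex minus the total flux of reactions consuming it: `A[i, ] %*% v`.
#'
#' @param decomp a `complex_decomposition`.
#' @param v flux vector over the decomposition's reactions.
#' @return named numeric vector of activities (mmol gDW^-1 h^-1).
#' @export
complex_activity <- function(decomp, v) {
  stopifnot(inherits(decomp, "complex_decomposition"))
  if (length(v) != length(decomp$reactions))
    stop("flux vector length ", length(v), " does not match ",
         length(decomp$reactions), " reactions")
  stats::setNames(drop(decomp$A %*% v), decomp$labels)
}

#' Complexes that can never be balanced in a positive flux distribution
#'
#' A complex whose incident reactions are all incoming or all outgoing has
#' strictly positive (respectively negative) activity whenever all its
#' incident fluxes are positive, so it is never balanced in a strictly
#' positive steady-state flux distribution. The classification is purely
#' topological.
#'
#' @param decomp a `complex_decomposition`.
#' @return integer indices (named by complex label) of the flagged complexes.
#' @export
structurally_never_balanced <- function(decomp) {
  stopifnot(inherits(decomp, "complex_decomposition"))
  flag <- apply(decomp$A, 1, function(row) {
    nz <- row[row != 0]
    length(nz) > 0 && (all(nz > 0) || all(nz < 0))
  })
  stats::setNames(which(flag), decomp$labels[flag])
}

#' Balanced complexes within a single flux distribution
#'
#' A complex is balanced for a given steady-state flux distribution when the
#' absolute value of its activity does not exceed `epsilon`.
#'
#' @param decomp a `complex_decomposition`.
#' @param v steady-state flux vector.
#' @param epsilon activity threshold (mmol gDW^-1 h^-1, default 1e-6).
#' @param feas_tol maximum allowed steady-state violation `max|S v|`
#'   (default 1e-6); exceeded means `v` is not a steady state.
#' @return integer indices (named by complex label) of balanced complexes.
#' @export
balanced_in_distribution <- function(decomp, v, epsilon = 1e-6,
                                     feas_tol = 1e-6) {
  act <- complex_activity(decomp, v)
  Sv <- decomp$Y %*% (decomp$A %*% v)
  if (max(abs(Sv)) > feas_tol)
    stop("v is not a steady state: max |S v| = ", format(max(abs(Sv))))
  idx <- which(abs(act) <= epsilon)
  stats::setNames(idx, decomp$labels[idx])
}

#' Balanced complexes over a flux space
#'
#' Computes, for every complex, the minimum and maximum activity over the
#' steady-state flux space `{v : S v = 0, lb <= v <= ub}` (two LPs per
#' complex), optionally restricted by an activity or total-flux budget and/or
#' by replacement flux intervals (e.g. experimental confidence intervals).
#' A complex is balanced over the space when both extremes are within
#' `epsilon` of zero.
#'
#' @param model an irreversible `metabolic_model`.
#' @param decomp the matching `complex_decomposition`.
#' @param epsilon activity threshold (default 1e-6).
#' @param objective_kind,budget optional: restrict to the optimal face of
#'   `"cbfba"` (total absolute complex activity <= `budget * (1 + tau)`) or
#'   `"pfba"` (total flux <= `budget * (1 + tau)`).
#' @param tau relative budget tolerance (default 1e-6).
#' @param flux_bounds optional data frame (`reaction_id`, `lower`, `upper`)
#'   overriding the model bounds for the listed reactions.
#' @return a `balanced_set`: data frame with columns `complex`, `min_activity`,
#'   `max_activity`, `balanced`; attribute `basis` records the queried space.
#' @export
balanced_over_space <- function(model, decomp, epsilon = 1e-6,
                                objective_kind = NULL, budget = NULL,
                                tau = 1e-6, flux_bounds = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(decomp, "complex_decomposition"))
  if (!is.null(flux_bounds)) {
    model <- apply_scenario(model, scenario_constraints(
      stats::setNames(flux_bounds, c("reaction_id", "lower", "upper"))))
  }
  cs <- space_constraints(model, decomp, objective_kind, budget, tau)
  cc <- nrow(decomp$A)
  mins <- maxs <- numeric(cc)
  for (i in seq_len(cc)) {
    obj <- c(decomp$A[i, ], rep(0, cs$n_aux))
    lo <- lp_solve(obj, cs$Aeq, cs$beq, cs$Aineq, cs$bineq, cs$lb, cs$ub,
                   maximize = FALSE)
    hi <- lp_solve(obj, cs$Aeq, cs$beq, cs$Aineq, cs$bineq, cs$lb, cs$ub,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("flux space is infeasible while bounding complex '",
           decomp$labels[i], "': ", lo$message)
    mins[i] <- lo$value
    maxs[i] <- hi$value
  }
  basis <- if (is.null(objective_kind) && is.null(flux_bounds)) "flux-space"
           else paste0("flux-space (",
                       paste(c(objective_kind,
                               if (!is.null(flux_bounds)) "interval bounds"),
                             collapse = ", "), ")")
  out <- data.frame(complex = decomp$labels,
                    min_activity = mins, max_activity = maxs,
                    balanced = mins >= -epsilon & maxs <= epsilon,
                    stringsAsFactors = FALSE)
  structure(out, basis = basis, epsilon = epsilon,
            class = c("balanced_set", "data.frame"))
}
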