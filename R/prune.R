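#' Remove dead-end metabolites and blocked reactions for a scenario
#'
#' After applying the scenario bounds, iterates to a fixed point:
#' \enumerate{
#'   \item a metabolite with no producing or no consuming reaction is a dead
#'     end; it is removed together with all its incident reactions;
#'   \item a reaction whose maximum attainable flux over the steady-state
#'     space is below `blocked_tol` is blocked and removed (one LP per
#'     reaction).
#' }
#' Reactions with a strictly positive lower bound encode measurements and are
#' never removed. The model must be irreversible (split first), so blocked
#' detection only needs flux maximization.
#'
#' @param model an irreversible `metabolic_model`.
#' @param scenario optional `scenario_constraints`, applied before pruning.
#' @param blocked_tol flux threshold below which a reaction counts as blocked
#'   (default 1e-6, the same activity threshold used across the package).
#' @return the pruned `metabolic_model`.
#' @export
prune <- function(model, scenario = NULL, blocked_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is_irreversible(model))
    stop("model has reversible reactions; call split_reversible() first")
  if (!is.null(scenario)) model <- apply_scenario(model, scenario)
  if (!lp_feasible(model$S, rep(0, nrow(model$S)),
                   lb = unname(model$lower_bounds),
                   ub = unname(model$upper_bounds))) {
    forced <- model$reactions[model$lower_bounds > 0]
    stop("scenario is infeasible: no steady state satisfies the bounds",
         if (length(forced) > 0)
           paste0(" (forced reactions: ", paste(forced, collapse = ", "), ")"))
  }
  repeat {
    changed <- FALSE
    # dead-end metabolites: need at least one producer and one consumer
    repeat {
      produced <- rowSums(model$S > 0) > 0
      consumed <- rowSums(model$S < 0) > 0
      dead <- which(!(produced & consumed))
      if (length(dead) == 0) break
      incident <- colSums(abs(model$S[dead, , drop = FALSE])) > 0
      forced <- incident & model$lower_bounds > 0
      if (any(forced))
        stop("dead-end metabolite(s) ",
             paste(model$metabolites[dead], collapse = ", "),
             " require removing reaction(s) with forced flux: ",
             paste(model$reactions[forced], collapse = ", "))
      model <- subset_model(model, !incident, -dead)
      changed <- TRUE
      if (length(model$reactions) == 0) return(model)
    }
    # blocked reactions: per-reaction flux maximization witness
    vmax <- rep(NA_real_, length(model$reactions))
    for (j in seq_along(model$reactions)) {
      if (model$lower_bounds[j] > 0) { vmax[j] <- Inf; next }
      res <- lp_solve(replace(rep(0, length(model$reactions)), j, 1),
                      model$S, rep(0, nrow(model$S)),
                      lb = unname(model$lower_bounds),
                      ub = unname(model$upper_bounds), maximize = TRUE)
      if (res$status != "optimal")
        stop("pruning LP failed for reaction ", model$reactions[j], ": ",
             res$message)
      vmax[j] <- res$value
    }
    blocked <- vmax < blocked_tol
    if (any(blocked)) {
      model <- subset_model(model, !blocked, seq_len(nrow(model$S)))
      changed <- TRUE
    }
    if (!changed) break
  }
  model
}

# keep_rxn: logical over reactions; keep_met: index vector over metabolites
subset_model <- function(model, keep_rxn, keep_met) {
  S <- model$S[keep_met, keep_rxn, drop = FALSE]
  metabolic_model(
    S,
    lower_bounds = model$lower_bounds[keep_rxn],
    upper_bounds = model$upper_bounds[keep_rxn],
    subsystem = if (is.null(model$subsystem)) NULL else
      model$subsystem[keep_rxn],
    biomass_reaction = if (!is.null(model$biomass_reaction) &&
                           model$biomass_reaction %in% colnames(S))
      model$biomass_reaction else NULL)
}
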