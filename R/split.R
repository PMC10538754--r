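#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' (bounds `(max(lb, 0), ub)`) and a reverse copy with negated stoichiometry
#' (bounds `(0, -lb)`). The net flux of the original reaction is forward
#' minus reverse. Already-irreversible models are returned unchanged with an
#' identity split map.
#'
#' @param model a `metabolic_model`.
#' @return a list with elements `model` (irreversible) and `split_map`, a
#'   data frame with columns `original`, `forward`, `reverse` (`NA` when no
#'   reverse copy was created).
#' @export
split_reversible <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  lb <- model$lower_bounds; ub <- model$upper_bounds
  rev_idx <- which(lb < 0)
  map <- data.frame(original = model$reactions,
                    forward = model$reactions,
                    reverse = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(rev_idx) == 0) {
    return(list(model = model, split_map = map))
  }
  rev_ids <- paste0(model$reactions[rev_idx], "_rev")
  if (any(rev_ids %in% model$reactions))
    stop("reverse reaction id collision: ",
         paste(intersect(rev_ids, model$reactions), collapse = ", "))
  S2 <- cbind(model$S, -model$S[, rev_idx, drop = FALSE])
  colnames(S2) <- c(model$reactions, rev_ids)
  lb2 <- c(pmax(lb, 0), rep(0, length(rev_idx)))
  ub2 <- c(ub, -lb[rev_idx])
  sub2 <- if (is.null(model$subsystem)) NULL else
    c(model$subsystem, model$subsystem[rev_idx])
  map$reverse[rev_idx] <- rev_ids
  out <- metabolic_model(S2, lb2, ub2,
                         subsystem = sub2,
                         biomass_reaction = model$biomass_reaction)
  list(model = out, split_map = map)
}

#' Merge a split-model flux vector back to original coordinates
#'
#' Net flux per original reaction is the forward flux minus the reverse flux.
#'
#' @param v_split named or positional flux vector on the split model (order:
#'   the split model's reactions).
#' @param split_map the `split_map` returned by [split_reversible()].
#' @return named numeric vector over the original reactions.
#' @export
merge_split_fluxes <- function(v_split, split_map) {
  ids <- c(split_map$forward, stats::na.omit(split_map$reverse))
  if (is.null(names(v_split))) {
    if (length(v_split) != length(ids))
      stop("flux vector length ", length(v_split),
           " does not match split model size ", length(ids))
    names(v_split) <- ids
  }
  missing <- setdiff(ids, names(v_split))
  if (length(missing) > 0)
    stop("flux vector lacks split reactions: ", paste(missing, collapse = ", "))
  fwd <- v_split[split_map$forward]
  rev <- ifelse(is.na(split_map$reverse), 0, v_split[split_map$reverse])
  stats::setNames(as.numeric(fwd) - as.numeric(rev), split_map$original)
}
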