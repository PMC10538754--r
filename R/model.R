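#' Construct a metabolic model
#'
#' A `metabolic_model` bundles the stoichiometric matrix of a reaction network
#' with per-reaction flux bounds and optional reaction annotation. Rows of `S`
#' are metabolites, columns are reactions; negative entries are substrate
#' stoichiometries, positive entries product stoichiometries. Bounds are in
#' mmol gDW^-1 h^-1.
#'
#' @param S numeric matrix (metabolites x reactions). Row and column names, if
#'   absent, are taken from `metabolites` / `reactions`.
#' @param lower_bounds,upper_bounds numeric vectors, one entry per reaction.
#'   `NA` entries are replaced by `-default_bound` / `default_bound` (a finite
#'   box is required by every downstream optimization and by the sampler).
#' @param metabolites,reactions character identifiers; default taken from
#'   `dimnames(S)`.
#' @param subsystem optional character vector of per-reaction pathway labels.
#' @param biomass_reaction optional id of the designated biomass reaction.
#' @param default_bound finite cap used for missing/infinite bounds
#'   (default 1000).
#'
#' @return an object of class `metabolic_model`: a list with elements
#'   `S`, `metabolites`, `reactions`, `lower_bounds`, `upper_bounds`,
#'   `subsystem`, `biomass_reaction`.
#' @export
metabolic_model <- function(S, lower_bounds = NULL, upper_bounds = NULL,
                            metabolites = rownames(S), reactions = colnames(S),
                            subsystem = NULL, biomass_reaction = NULL,
                            default_bound = 1000) {
  S <- as.matrix(S)
  m <- nrow(S); r <- ncol(S)
  if (is.null(metabolites))
    metabolites <- as.character(if (m > 0) paste0("M", seq_len(m)))
  if (is.null(reactions))
    reactions <- as.character(if (r > 0) paste0("R", seq_len(r)))
  stopifnot(length(metabolites) == m, length(reactions) == r,
            !anyDuplicated(metabolites), !anyDuplicated(reactions))
  dimnames(S) <- list(metabolites, reactions)
  if (is.null(lower_bounds)) lower_bounds <- rep(NA_real_, r)
  if (is.null(upper_bounds)) upper_bounds <- rep(NA_real_, r)
  lb <- as.numeric(lower_bounds); ub <- as.numeric(upper_bounds)
  lb[!is.finite(lb)] <- -abs(default_bound)
  ub[!is.finite(ub)] <- abs(default_bound)
  lb <- pmax(lb, -abs(default_bound))
  ub <- pmin(ub, abs(default_bound))
  if (any(lb > ub)) {
    bad <- reactions[lb > ub]
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(subsystem)) {
    subsystem <- as.character(subsystem)
    stopifnot(length(subsystem) == r)
  }
  if (!is.null(biomass_reaction) && !biomass_reaction %in% reactions)
    stop("biomass_reaction '", biomass_reaction, "' not among reactions")
  structure(
    list(S = S, metabolites = metabolites, reactions = reactions,
         lower_bounds = stats::setNames(lb, reactions),
         upper_bounds = stats::setNames(ub, reactions),
         subsystem = subsystem, biomass_reaction = biomass_reaction),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  rev <- sum(x$lower_bounds < 0)
  cat("<metabolic_model> ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", rev, " reversible)\n", sep = "")
  if (!is.null(x$biomass_reaction))
    cat("  biomass reaction: ", x$biomass_reaction, "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolic_model <- function(x) dim(x$S)

is_irreversible <- function(model) all(model$lower_bounds >= 0)

sniff_delimiter <- function(path) {
  lines <- readLines(path, n = 50L)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header)) stop("no header line found in ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a scenario constraint table
#'
#' Scenario tables carry per-strain measured bounds (uptake, secretion,
#' growth) as delimited text with columns `reaction_id`, `lower`, `upper`,
#' in mmol gDW^-1 h^-1 (h^-1 for the growth rate). Lines starting with `#`
#' are ignored.
#'
#' @param path file path (TSV or CSV; the delimiter is sniffed from the
#'   header line).
#' @param strain_id optional label stored on the result.
#' @return a `scenario_constraints` object: data frame with columns
#'   `reaction_id`, `lower`, `upper` and attribute `strain_id`.
#' @export
read_scenario <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  scenario_constraints(df, strain_id = strain_id)
}

#' Build scenario constraints from a data frame
#'
#' @param bounds data frame with columns `reaction_id`, `lower`, `upper`.
#' @param strain_id optional label.
#' @return a `scenario_constraints` object.
#' @export
scenario_constraints <- function(bounds, strain_id = NULL) {
  need <- c("reaction_id", "lower", "upper")
  if (!all(need %in% names(bounds)))
    stop("scenario table must have columns: ", paste(need, collapse = ", "))
  bounds <- bounds[, need]
  bounds$lower <- as.numeric(bounds$lower)
  bounds$upper <- as.numeric(bounds$upper)
  if (any(bounds$lower > bounds$upper, na.rm = TRUE))
    stop("scenario has lower > upper for reaction(s): ",
         paste(bounds$reaction_id[which(bounds$lower > bounds$upper)],
               collapse = ", "))
  structure(bounds, strain_id = strain_id, class = c("scenario_constraints",
                                                     "data.frame"))
}

#' Apply scenario constraints to a model
#'
#' Intersects the model's flux bounds with the scenario's measured bounds:
#' the tighter bound wins on each side. Applying the same scenario twice is
#' idempotent; the feasible region can only shrink.
#'
#' @param model a `metabolic_model`.
#' @param scenario a `scenario_constraints` object (or data frame with
#'   columns `reaction_id`, `lower`, `upper`).
#' @return the model with intersected bounds.
#' @export
apply_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(scenario$reaction_id, model$reactions)
  if (length(unknown) > 0)
    stop("scenario references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  lb <- model$lower_bounds; ub <- model$upper_bounds
  idx <- match(scenario$reaction_id, model$reactions)
  sc_lo <- ifelse(is.na(scenario$lower), -Inf, scenario$lower)
  sc_up <- ifelse(is.na(scenario$upper), Inf, scenario$upper)
  lb[idx] <- pmax(lb[idx], sc_lo)
  ub[idx] <- pmin(ub[idx], sc_up)
  if (any(lb > ub)) {
    bad <- model$reactions[lb > ub]
    stop("scenario intersection infeasible (lower > upper) for: ",
         paste(bad, collapse = ", "))
  }
  model$lower_bounds <- lb
  model$upper_bounds <- ub
  model
}
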