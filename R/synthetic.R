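#' The six-metabolite, nine-reaction toy network
#'
#' A small open metabolic network with metabolites A-F and nine irreversible
#' reactions: four exchanges with the environment O (`E1`: O -> A, `E2`:
#' D -> O, `E3`: O -> E, `E4`: O -> F) and five internal conversions (`R1`:
#' A -> B + C, `R2`: B -> D, `R3`: C -> D, `R4`: E -> B, `R5`: F -> C). Its
#' complex graph has eight complexes (O, A, D, E, F, B + C, B, C). Metabolites
#' A, D, E, F each occur in a single complex, so those four complexes are
#' balanced in every steady state; the complex B + C has only incoming
#' reactions, so it is never balanced in a strictly positive flux
#' distribution. Under the bundled demand scenario (see [toy_scenario()])
#' pFBA routes flux through R1 and balances only \{A, E, F, D\}, while cbFBA
#' attains total activity zero on the E/F cycle route and balances every
#' complex, including B, C, and O.
#'
#' @param verify when `TRUE`, run the full pipeline on the fixture and stop
#'   unless all documented balanced-set statements hold (slower; used by the
#'   test suite).
#' @return a `metabolic_model` with attribute `expected`, a list carrying the
#'   documented complex sets.
#' @export
toy_network <- function(verify = FALSE) {
  mets <- c("A", "B", "C", "D", "E", "F")
  rxns <- c("E1", "E2", "E3", "E4", "R1", "R2", "R3", "R4", "R5")
  S <- matrix(0, 6, 9, dimnames = list(mets, rxns))
  S["A", "E1"] <- 1                       # O -> A
  S["D", "E2"] <- -1                      # D -> O
  S["E", "E3"] <- 1                       # O -> E
  S["F", "E4"] <- 1                       # O -> F
  S[c("A", "B", "C"), "R1"] <- c(-1, 1, 1)  # A -> B + C
  S[c("B", "D"), "R2"] <- c(-1, 1)        # B -> D
  S[c("C", "D"), "R3"] <- c(-1, 1)        # C -> D
  S[c("E", "B"), "R4"] <- c(-1, 1)        # E -> B
  S[c("F", "C"), "R5"] <- c(-1, 1)        # F -> C
  model <- metabolic_model(S, rep(0, 9), rep(1000, 9))
  expected <- list(
    n_complexes = 8L,
    cone_balanced = c("A", "E", "F", "D"),
    structural_never_balanced = "B + C",
    pfba_balanced = c("A", "E", "F", "D"),
    cbfba_balanced_includes = c("A", "B", "C", "D", "E", "F", "O"))
  attr(model, "expected") <- expected
  if (verify) verify_toy(model, expected)
  model
}

#' Demand scenario for the toy network
#'
#' Fixes the secretion of D (`E2`) to 1 mmol gDW^-1 h^-1, the measured
#' phenotype that both cbFBA and pFBA must support.
#'
#' @return a `scenario_constraints` object.
#' @export
toy_scenario <- function() {
  scenario_constraints(
    data.frame(reaction_id = "E2", lower = 1, upper = 1,
               stringsAsFactors = FALSE),
    strain_id = "toy")
}

verify_toy <- function(model, expected) {
  scen <- toy_scenario()
  constrained <- apply_scenario(model, scen)
  dec <- decompose(constrained)
  fail <- function(...) stop("toy fixture contract violated: ", ...)
  if (length(dec$labels) != expected$n_complexes)
    fail("expected ", expected$n_complexes, " complexes, got ",
         length(dec$labels))
  cone <- balanced_over_space(model, decompose(model))
  if (!setequal(cone$complex[cone$balanced], expected$cone_balanced))
    fail("cone-balanced set is {",
         paste(cone$complex[cone$balanced], collapse = ", "), "}")
  nb <- names(structurally_never_balanced(dec))
  if (!all(expected$structural_never_balanced %in% nb))
    fail("structurally never-balanced set lacks ",
         expected$structural_never_balanced)
  pf <- solve_pfba(constrained)
  pf_bal <- names(balanced_in_distribution(dec, pf$v))
  if (!setequal(pf_bal, expected$pfba_balanced))
    fail("pFBA balanced set is {", paste(pf_bal, collapse = ", "), "}")
  cb <- solve_cbfba(constrained, dec)
  cb_bal <- names(balanced_in_distribution(dec, cb$v))
  if (!all(expected$cbfba_balanced_includes %in% cb_bal))
    fail("cbFBA balanced set {", paste(cb_bal, collapse = ", "),
         "} does not include all of {",
         paste(expected$cbfba_balanced_includes, collapse = ", "), "}")
  if (length(cb_bal) <= length(pf_bal))
    fail("cbFBA does not balance strictly more complexes than pFBA")
  invisible(TRUE)
}

#' Generate a random feasible metabolic network
#'
#' Builds a network that is feasible by construction: metabolites are grouped
#' into a pool of complexes (plus the empty environment complex when
#' `exchange = TRUE`), and reactions are laid down as a single closed walk of
#' length `r` through the pool that visits every complex. The all-ones flux
#' vector is then a steady-state witness (`S %*% rep(1, r) = 0` exactly),
#' every reaction can carry flux, and stoichiometric coefficients are small
#' integers so the complex decomposition is exact.
#'
#' @param m number of metabolites (>= 2).
#' @param r number of reactions (>= 3, and at least the number of complexes).
#' @param seed integer seed; the same seed reproduces the same model.
#' @param max_complex_size largest number of distinct metabolites per complex
#'   (default 2).
#' @param max_coeff largest stoichiometric coefficient (default 2).
#' @param exchange include the environment complex, yielding exchange
#'   reactions (default TRUE).
#' @param reversible_fraction fraction of reactions given a negative lower
#'   bound (default 0; use with [split_reversible()]).
#' @param flux_cap upper flux bound (default 10).
#' @return a `metabolic_model` with attribute `witness` (the all-ones flux
#'   vector).
#' @export
random_network <- function(m = 6, r = 8, seed = 1, max_complex_size = 2,
                           max_coeff = 2, exchange = TRUE,
                           reversible_fraction = 0, flux_cap = 10) {
  stopifnot(m >= 2, r >= 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  mets <- paste0("M", seq_len(m))
  # partition metabolites into complexes
  order <- sample(m)
  sizes <- integer(0)
  left <- m
  while (left > 0) {
    s <- sample(seq_len(min(max_complex_size, left)), 1)
    sizes <- c(sizes, s)
    left <- left - s
  }
  pool <- vector("list", length(sizes))
  at <- 1L
  for (k in seq_along(sizes)) {
    idx <- order[at:(at + sizes[k] - 1)]
    coef <- numeric(m)
    coef[idx] <- sample(seq_len(max_coeff), sizes[k], replace = TRUE)
    pool[[k]] <- coef
    at <- at + sizes[k]
  }
  # extra complexes reusing already-placed metabolites, so that complexes can
  # share species; without sharing, every steady state is a circulation of
  # the complex graph and the total complex activity is trivially zero
  n_extra <- min(max(1L, length(sizes) %/% 2L),
                 r - length(sizes) - as.integer(exchange))
  if (n_extra < 0) n_extra <- 0L
  for (k in seq_len(n_extra)) {
    s <- sample(seq_len(min(max_complex_size, m)), 1)
    coef <- numeric(m)
    coef[sample(m, s)] <- sample(seq_len(max_coeff), s, replace = TRUE)
    dup <- any(vapply(pool, function(p) all(p == coef), logical(1)))
    if (!dup) pool[[length(pool) + 1]] <- coef
  }
  if (exchange) pool <- c(pool, list(numeric(m)))
  k <- length(pool)
  if (k > r)
    stop("infeasible spec: ", k, " complexes need at least ", k,
         " reactions; increase r or max_complex_size")
  if (k < 3)
    stop("infeasible spec: need at least 3 complexes for a closed walk; ",
         "increase m or lower max_complex_size")
  # closed walk of length r visiting all complexes
  walk <- sample(k)
  while (length(walk) < r) {
    prev <- walk[length(walk)]
    cand <- setdiff(seq_len(k), prev)
    if (length(walk) == r - 1) cand <- setdiff(cand, walk[1])
    walk <- c(walk, if (length(cand) == 1) cand else sample(cand, 1))
  }
  edges <- cbind(walk, c(walk[-1], walk[1]))
  S <- matrix(0, m, r, dimnames = list(mets, paste0("R", seq_len(r))))
  for (j in seq_len(r)) {
    S[, j] <- pool[[edges[j, 2]]] - pool[[edges[j, 1]]]
  }
  lb <- rep(0, r); ub <- rep(flux_cap, r)
  n_rev <- round(reversible_fraction * r)
  if (n_rev > 0) lb[sample(r, n_rev)] <- -flux_cap
  model <- metabolic_model(S, lb, ub)
  attr(model, "witness") <- stats::setNames(rep(1, r), model$reactions)
  model
}

#' Generate a network with planted cone-balanced complexes
#'
#' Builds `k_chains` linear chains O -> Z1 -> ... -> ZL -> O in which every
#' intermediate metabolite occurs in exactly one (singleton) complex, so the
#' activity of that complex coincides with the metabolite's steady-state
#' constraint and the complex is balanced over the entire flux cone. One
#' additional branch O -> P, P -> Q + W, Q -> O, W -> O plants a complex
#' (Q + W) with only incoming reactions, which can never be balanced in a
#' positive flux distribution.
#'
#' @param k_chains number of chains (>= 1).
#' @param seed integer seed controlling chain lengths.
#' @param flux_cap upper flux bound (default 10).
#' @return a list with `model`, `planted` (labels of the planted cone-balanced
#'   complexes), and `never_balanced` (label of the planted structurally
#'   never-balanced complex).
#' @export
planted_balanced_network <- function(k_chains = 3, seed = 1, flux_cap = 10) {
  stopifnot(k_chains >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  lens <- sample(2:4, k_chains, replace = TRUE)
  mets <- c(unlist(lapply(seq_len(k_chains), function(i)
    paste0("Z", i, "_", seq_len(lens[i])))), "P", "Q", "W")
  cols <- list(); rxn <- character(0)
  add <- function(from, to, id) {
    coef <- numeric(length(mets)); names(coef) <- mets
    if (!is.null(from)) coef[from] <- coef[from] - 1
    if (!is.null(to)) coef[to] <- coef[to] + 1
    cols[[length(cols) + 1]] <<- coef
    rxn[length(rxn) + 1] <<- id
  }
  for (i in seq_len(k_chains)) {
    chain <- paste0("Z", i, "_", seq_len(lens[i]))
    add(NULL, chain[1], paste0("Ein", i))
    for (j in seq_len(lens[i] - 1))
      add(chain[j], chain[j + 1], paste0("R", i, "_", j))
    add(chain[lens[i]], NULL, paste0("Eout", i))
  }
  add(NULL, "P", "Ep")
  add("P", c("Q", "W"), "Rp")
  add("Q", NULL, "Eq")
  add("W", NULL, "Ew")
  S <- do.call(cbind, cols)
  colnames(S) <- rxn
  model <- metabolic_model(S, rep(0, ncol(S)), rep(flux_cap, ncol(S)))
  planted <- unlist(lapply(seq_len(k_chains), function(i)
    paste0("Z", i, "_", seq_len(lens[i]))))
  list(model = model, planted = planted, never_balanced = "Q + W")
}
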