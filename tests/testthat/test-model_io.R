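test_that("SBML reading preserves dimensions, identifiers, and stoichiometry", {
  model <- read_sbml(extdata("toy_network.xml"))
  expect_s3_class(model, "metabolic_model")
  expect_equal(dim(model$S), c(6L, 9L))
  expect_setequal(model$metabolites, c("A", "B", "C", "D", "E", "F"))
  expect_equal(model$reactions,
               c("E1", "E2", "E3", "E4", "R1", "R2", "R3", "R4", "R5"))
  expect_equal(unname(model$S[c("A", "B", "C"), "R1"]), c(-1, 1, 1))
  expect_equal(model$subsystem[1], "Exchange")
})

test_that("a single reaction A -> B reads as the column (-1, +1)", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  one <- metabolic_model(matrix(c(-1, 1), 2, 1,
                                dimnames = list(c("A", "B"), "v1")),
                         0, 10)
  write_sbml(one, tmp)
  back <- read_sbml(tmp)
  expect_equal(unname(back$S[c("A", "B"), "v1"]), c(-1, 1))
})

test_that("generator-emitted SBML round-trips to the in-memory model", {
  for (seed in c(2, 5, 9)) {
    model <- random_network(m = 5, r = 7, seed = seed,
                            reversible_fraction = 0.3)
    tmp <- withr::local_tempfile(fileext = ".xml")
    write_sbml(model, tmp)
    back <- read_sbml(tmp)
    expect_equal(back$S, model$S)
    expect_equal(back$lower_bounds, model$lower_bounds)
    expect_equal(back$upper_bounds, model$upper_bounds)
  }
})

test_that("missing SBML bounds are signalled and given the configurable cap", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="A" boundaryCondition="false"/>',
    '<species id="B" boundaryCondition="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="v1" reversible="true"><listOfReactants>',
    '<speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), tmp)
  expect_message(model <- read_sbml(tmp, default_bound = 50),
                 "applied defaults")
  expect_equal(unname(model$lower_bounds), -50)
  expect_equal(unname(model$upper_bounds), 50)
})

test_that("splitting maps bounds (-5, 10) to forward (0, 10), reverse (0, 5)", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "v1"))
  sp <- split_reversible(metabolic_model(S, -5, 10))
  expect_equal(unname(sp$model$lower_bounds), c(0, 0))
  expect_equal(unname(sp$model$upper_bounds), c(10, 5))
  expect_equal(unname(sp$model$S[, "v1_rev"]), c(1, -1))
  expect_equal(sp$split_map$reverse, "v1_rev")
})

test_that("an irreversible model is unchanged by splitting (identity map)", {
  toy <- toy_network()
  sp <- split_reversible(toy)
  expect_identical(sp$model$S, toy$S)
  expect_true(all(is.na(sp$split_map$reverse)))
  expect_equal(merge_split_fluxes(stats::setNames(1:9, toy$reactions),
                                  sp$split_map),
               stats::setNames(as.numeric(1:9), toy$reactions))
})

test_that("splitting then merging preserves S v = 0 and net fluxes", {
  for (seed in c(3, 4)) {
    model <- random_network(m = 6, r = 8, seed = seed,
                            reversible_fraction = 0.4)
    sp <- split_reversible(model)
    set.seed(seed)
    v_split <- runif(length(sp$model$reactions), sp$model$lower_bounds,
                     sp$model$upper_bounds)
    names(v_split) <- sp$model$reactions
    merged <- merge_split_fluxes(v_split, sp$split_map)
    expect_equal(drop(model$S %*% merged), drop(sp$model$S %*% v_split),
                 ignore_attr = TRUE)
    fwd <- v_split[sp$split_map$forward]
    rev <- ifelse(is.na(sp$split_map$reverse), 0,
                  v_split[sp$split_map$reverse])
    expect_equal(unname(merged), unname(fwd - rev))
  }
})

test_that("merge rejects dimension mismatches", {
  sp <- split_reversible(toy_network())
  expect_error(merge_split_fluxes(1:3, sp$split_map), "does not match")
})

test_that("scenario application intersects bounds and is idempotent", {
  toy <- toy_network()
  sc <- scenario_constraints(
    data.frame(reaction_id = c("E2", "R1"), lower = c(0.5, -5),
               upper = c(0.5, 2000)))
  once <- apply_scenario(toy, sc)
  expect_equal(unname(once$lower_bounds["E2"]), 0.5)
  expect_equal(unname(once$upper_bounds["E2"]), 0.5)
  # wider scenario bound: model bound retained
  expect_equal(unname(once$lower_bounds["R1"]), 0)
  expect_equal(unname(once$upper_bounds["R1"]), 1000)
  twice <- apply_scenario(once, sc)
  expect_identical(once, twice)
})

test_that("scenario application only shrinks the feasible region", {
  model <- random_network(m = 5, r = 7, seed = 21)
  sc <- scenario_constraints(
    data.frame(reaction_id = model$reactions[2], lower = 0.5, upper = 3))
  con <- apply_scenario(model, sc)
  expect_true(all(con$lower_bounds >= model$lower_bounds))
  expect_true(all(con$upper_bounds <= model$upper_bounds))
})

test_that("infeasible scenario intersections raise with the reaction named", {
  toy <- toy_network()
  sc <- scenario_constraints(
    data.frame(reaction_id = "E1", lower = -10, upper = -5))
  expect_error(apply_scenario(toy, sc), "E1")
  expect_error(apply_scenario(toy, scenario_constraints(
    data.frame(reaction_id = "nope", lower = 0, upper = 1))), "unknown")
})

test_that("a chain with no exit is pruned away entirely", {
  # O -> A -> B with no consumer of B: B is a dead end, both reactions go
  S <- matrix(c(1, 0, -1, 1), 2, 2,
              dimnames = list(c("A", "B"), c("up", "conv")))
  pruned <- prune(metabolic_model(S, c(0, 0), c(10, 10)))
  expect_equal(length(pruned$reactions), 0L)
})

test_that("nothing is pruned from the toy network under its scenario", {
  ts <- toy_setup()
  pruned <- prune(ts$work)
  expect_equal(pruned$reactions, ts$work$reactions)
  expect_equal(pruned$metabolites, ts$work$metabolites)
})

test_that("every reaction retained by pruning has a feasible flux witness", {
  for (seed in c(7, 13)) {
    model <- random_network(m = 6, r = 9, seed = seed)
    pruned <- prune(model)
    for (j in seq_along(pruned$reactions)) {
      res <- cbfba:::lp_solve(
        replace(rep(0, length(pruned$reactions)), j, 1),
        pruned$S, rep(0, nrow(pruned$S)),
        lb = unname(pruned$lower_bounds), ub = unname(pruned$upper_bounds),
        maximize = TRUE)
      expect_gt(res$value, 1e-6)
    }
    # the all-ones witness survives pruning
    expect_setequal(pruned$reactions, model$reactions)
  }
})

test_that("pruning rejects an infeasible scenario", {
  toy <- toy_network()
  sc <- scenario_constraints(
    data.frame(reaction_id = c("E2", "R2", "R3"),
               lower = c(2, 0, 0), upper = c(2, 0.1, 0.1)))
  expect_error(prune(toy, sc), "infeasible")
})
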