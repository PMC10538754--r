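#' Export the complex graph as an edge list
#'
#' One row per reaction: substrate complex, product complex, reaction id.
#'
#' @param decomp a `complex_decomposition`.
#' @param path output TSV path (omit to just get the data frame).
#' @return the edge-list data frame, invisibly when written.
#' @export
export_complex_graph <- function(decomp, path = NULL) {
  stopifnot(inherits(decomp, "complex_decomposition"))
  A <- decomp$A
  from <- to <- rep(NA_character_, ncol(A))
  for (j in seq_len(ncol(A))) {
    s <- which(A[, j] == -1); p <- which(A[, j] == 1)
    if (length(s) == 1) from[j] <- decomp$labels[s]
    if (length(p) == 1) to[j] <- decomp$labels[p]
  }
  edges <- data.frame(complex_from = from, complex_to = to,
                      reaction_id = decomp$reactions,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(edges))
  }
  edges
}

#' Export the Y and A matrices as MatrixMarket files
#'
#' @param decomp a `complex_decomposition`.
#' @param dir output directory; files `Y.mtx` and `A.mtx` are created.
#' @return the two file paths, invisibly.
#' @export
export_decomposition_matrices <- function(decomp, dir) {
  stopifnot(inherits(decomp, "complex_decomposition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("Y.mtx", "A.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(decomp$Y, sparse = TRUE),
                              "generalMatrix"), paths[1])
  Matrix::writeMM(methods::as(Matrix::Matrix(decomp$A + 0, sparse = TRUE),
                              "generalMatrix"), paths[2])
  invisible(paths)
}

#' Assemble and validate a pipeline configuration
#'
#' @param model_path SBML model file.
#' @param out_dir output directory (created if missing).
#' @param scenario_path optional scenario constraint table.
#' @param experimental_path optional experimental flux table.
#' @param method `"cbfba"` or `"pfba"`.
#' @param epsilon balance threshold (default 1e-6).
#' @param tau relative budget tolerance (default 1e-6).
#' @param n_samples flux samples to draw (default 1000).
#' @param seed integer RNG seed (default 1).
#' @param cap_bound finite cap for unbounded fluxes (default 1000).
#' @param prune_model prune dead ends/blocked reactions (default TRUE).
#' @param threshold active-reaction flux threshold (default 1e-6).
#' @param fdr_level FDR level for the mean-difference test (default 0.05).
#' @param trim trimming fraction for robust means (default 0.05).
#' @return a validated `run_config` list.
#' @export
run_config <- function(model_path, out_dir, scenario_path = NULL,
                       experimental_path = NULL,
                       method = c("cbfba", "pfba"), epsilon = 1e-6,
                       tau = 1e-6, n_samples = 1000, seed = 1,
                       cap_bound = 1000, prune_model = TRUE,
                       threshold = 1e-6, fdr_level = 0.05, trim = 0.05) {
  method <- match.arg(method)
  if (!file.exists(model_path)) stop("model file not found: ", model_path)
  for (p in c(scenario_path, experimental_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  stopifnot(epsilon > 0, tau >= 0, n_samples >= 1, cap_bound > 0,
            threshold > 0, fdr_level > 0, fdr_level < 1,
            trim >= 0, trim < 0.5)
  structure(list(model_path = model_path, out_dir = out_dir,
                 scenario_path = scenario_path,
                 experimental_path = experimental_path, method = method,
                 epsilon = epsilon, tau = tau,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed), cap_bound = cap_bound,
                 prune_model = isTRUE(prune_model), threshold = threshold,
                 fdr_level = fdr_level, trim = trim),
            class = "run_config")
}

#' Run the full prediction pipeline
#'
#' Reads the model, splits reversible reactions, applies the scenario, prunes
#' dead ends and blocked reactions, decomposes into complexes, solves the
#' requested objective, computes flux ranges at the fixed optimum, draws flux
#' samples, classifies balanced complexes, and (when an experimental table is
#' given) evaluates predictions against the measurements. All tabular outputs
#' are TSV with a header comment naming units, the configuration fingerprint,
#' and the seed.
#'
#' @param config a `run_config`.
#' @return list of in-memory results (`model`, `decomp`, `solution`, `ranges`,
#'   `samples`, `balanced`, `evaluation`), invisibly; files are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  # fingerprint the scientific configuration, not the output location
  fp_file <- tempfile(fileext = ".json")
  on.exit(unlink(fp_file), add = TRUE)
  jsonlite::write_json(unclass(config)[setdiff(names(config), "out_dir")],
                       fp_file, auto_unbox = TRUE, null = "null")
  fingerprint <- unname(tools::md5sum(fp_file))
  stamp <- paste0("# config_md5=", fingerprint, " seed=", config$seed,
                  " units=mmol_gDW-1_h-1")
  write_tsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  model <- read_sbml(config$model_path, default_bound = config$cap_bound)
  sp <- split_reversible(model)
  work <- sp$model
  if (!is.null(config$scenario_path))
    work <- apply_scenario(work, read_scenario(config$scenario_path))
  if (config$prune_model) work <- prune(work)
  decomp <- decompose(work)
  solution <- if (config$method == "cbfba") solve_cbfba(work, decomp)
              else solve_pfba(work)
  ranges <- fva(work, decomp, config$method, solution$budget,
                tau = config$tau)
  samples <- sample_fluxes(work, decomp, config$method, solution$budget,
                           n = config$n_samples, seed = config$seed,
                           tau = config$tau)
  bal_point <- balanced_in_distribution(decomp, solution$v,
                                        epsilon = config$epsilon)
  bal_space <- balanced_over_space(work, decomp, epsilon = config$epsilon,
                                   objective_kind = config$method,
                                   budget = solution$budget,
                                   tau = config$tau)
  write_tsv(data.frame(reaction_id = names(solution$v),
                       flux = unname(solution$v)), "fluxes.tsv")
  write_tsv(ranges, "ranges.tsv")
  write_tsv(as.data.frame(samples$samples), "samples.tsv")
  bal_space$balanced_in_solution <- bal_space$complex %in% names(bal_point)
  write_tsv(bal_space, "balanced_complexes.tsv")
  export_complex_graph(decomp, file.path(config$out_dir, "complex_edges.tsv"))
  export_decomposition_matrices(decomp, config$out_dir)
  evaluation <- NULL
  if (!is.null(config$experimental_path)) {
    experimental <- read_experimental_fluxes(config$experimental_path)
    mean_flux <- robust_mean(samples)
    active_pred <- classify_active(ranges, config$threshold)
    exp_idx <- match(experimental$reaction_id, names(mean_flux))
    shared <- !is.na(exp_idx)
    act_exp <- classify_active(experimental$mean[shared], config$threshold)
    act_prd <- unname(active_pred[exp_idx[shared]])
    conf <- confusion_metrics(act_prd, act_exp)
    ov <- range_overlap(ranges, experimental)
    joint <- act_prd & act_exp
    pred_means <- mean_flux[exp_idx[shared]]
    corr <- log_flux_correlation(pred_means, experimental$mean[shared], joint)
    mdt <- mean_difference_test(samples, experimental,
                                fdr_level = config$fdr_level)
    outliers <- if (sum(joint) > 2)
      detect_outliers(pred_means, experimental$mean[shared], joint)
      else character(0)
    evaluation <- list(
      confusion = conf, overlap_fraction = ov$fraction,
      log_flux_pearson = as.numeric(corr),
      n_jointly_active = sum(joint),
      fraction_no_difference = attr(mdt, "fraction_no_difference"),
      outliers = as.character(outliers))
    jsonlite::write_json(evaluation,
                         file.path(config$out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_tsv(mdt, "mean_difference.tsv")
  }
  invisible(list(model = work, decomp = decomp, solution = solution,
                 ranges = ranges, samples = samples,
                 balanced = bal_space, evaluation = evaluation))
}
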