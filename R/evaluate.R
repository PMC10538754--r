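#' Read experimentally estimated fluxes
#'
#' Expects delimited text with columns `reaction_id`, `mean`, `ci_lower`,
#' `ci_upper` (mmol gDW^-1 h^-1), e.g. flux estimates from 13C metabolic flux
#' analysis with confidence intervals.
#'
#' @param path file path (TSV or CSV; delimiter sniffed from the header).
#' @param strain_id optional label stored on the result.
#' @return an `experimental_fluxes` data frame.
#' @export
read_experimental_fluxes <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stop("flux table not found: ", path)
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  experimental_fluxes(df, strain_id = strain_id)
}

#' Build an experimental flux table from a data frame
#'
#' @param df data frame with columns `reaction_id`, `mean`, `ci_lower`,
#'   `ci_upper`.
#' @param strain_id optional label.
#' @return an `experimental_fluxes` data frame.
#' @export
experimental_fluxes <- function(df, strain_id = NULL) {
  need <- c("reaction_id", "mean", "ci_lower", "ci_upper")
  if (!all(need %in% names(df)))
    stop("flux table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  for (col in need[-1]) df[[col]] <- as.numeric(df[[col]])
  bad <- !is.na(df$ci_lower) & !is.na(df$ci_upper) &
    (df$ci_lower > df$mean | df$mean > df$ci_upper)
  if (any(bad))
    stop("mean outside its confidence interval for: ",
         paste(df$reaction_id[bad], collapse = ", "))
  structure(df, strain_id = strain_id,
            class = c("experimental_fluxes", "data.frame"))
}

#' Classify reactions as active or blocked
#'
#' A reaction is active when its flux magnitude reaches `threshold`; for a
#' flux range, when the largest magnitude over the range does.
#'
#' @param flux numeric vector of fluxes, or a `flux_ranges` data frame.
#' @param threshold activity threshold, mmol gDW^-1 h^-1 (default 1e-6).
#' @return logical vector (`TRUE` = active), named by reaction where known.
#' @export
classify_active <- function(flux, threshold = 1e-6) {
  stopifnot(threshold > 0)
  if (inherits(flux, "flux_ranges") ||
      (is.data.frame(flux) && all(c("min", "max") %in% names(flux)))) {
    mag <- pmax(abs(flux$min), abs(flux$max))
    return(stats::setNames(mag >= threshold, flux$reaction))
  }
  abs(flux) >= threshold
}

#' Confusion metrics for predicted active reactions
#'
#' Experimental activity is the positive class. Ratios with an empty
#' denominator are reported as `NaN`, never silently zero.
#'
#' @param predicted,experimental logical activity flags over the same
#'   reactions.
#' @return list with `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
confusion_metrics <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental))
  if (length(predicted) == 0) stop("empty comparison set")
  tp <- sum(predicted & experimental)
  fn <- sum(!predicted & experimental)
  tn <- sum(!predicted & !experimental)
  fp <- sum(predicted & !experimental)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = ratio(tp + tn, tp + fn + tn + fp))
}

#' Overlap between predicted and experimental flux ranges
#'
#' Two closed intervals overlap when `max(lowers) <= min(uppers)`; touching
#' endpoints count as overlap. Reactions lacking an interval on either side
#' are excluded and reported.
#'
#' @param predicted a `flux_ranges` data frame (columns `reaction`, `min`,
#'   `max`).
#' @param experimental an `experimental_fluxes` data frame (columns
#'   `reaction_id`, `ci_lower`, `ci_upper`).
#' @return list with `overlap` (named logical over compared reactions),
#'   `fraction`, and `excluded` (reaction ids lacking an interval).
#' @export
range_overlap <- function(predicted, experimental) {
  common <- intersect(predicted$reaction, experimental$reaction_id)
  pi <- match(common, predicted$reaction)
  ei <- match(common, experimental$reaction_id)
  lo_p <- predicted$min[pi]; hi_p <- predicted$max[pi]
  lo_e <- experimental$ci_lower[ei]; hi_e <- experimental$ci_upper[ei]
  ok <- !is.na(lo_p) & !is.na(hi_p) & !is.na(lo_e) & !is.na(hi_e)
  excluded <- c(setdiff(union(predicted$reaction, experimental$reaction_id),
                        common), common[!ok])
  common <- common[ok]
  flag <- pmax(lo_p[ok], lo_e[ok]) <= pmin(hi_p[ok], hi_e[ok])
  list(overlap = stats::setNames(flag, common),
       fraction = if (length(flag) == 0) NaN else mean(flag),
       excluded = excluded)
}

#' Categorize pFBA flux ranges against cbFBA flux ranges
#'
#' Assigns each reaction to one of the range-comparison categories:
#' `identical` (both endpoints equal), `same_min_higher_max` (equal minima,
#' larger pFBA maximum), `containment` (pFBA range strictly contains the
#' cbFBA range), `shifted_overlap` (pFBA shifted higher with overlap),
#' `shifted_disjoint` (pFBA shifted higher without overlap), or `other`.
#' Categories are checked in that order and are mutually exclusive under the
#' tie tolerance.
#'
#' @param pfba_range,cbfba_range `flux_ranges` data frames over the same
#'   reactions.
#' @param tie_tol tolerance for endpoint equality (default 1e-9).
#' @return character vector of categories, named by reaction.
#' @export
categorize_ranges <- function(pfba_range, cbfba_range, tie_tol = 1e-9) {
  common <- intersect(pfba_range$reaction, cbfba_range$reaction)
  p <- pfba_range[match(common, pfba_range$reaction), ]
  cb <- cbfba_range[match(common, cbfba_range$reaction), ]
  eq <- function(a, b) abs(a - b) <= tie_tol
  out <- character(length(common))
  for (i in seq_along(common)) {
    pl <- p$min[i]; pu <- p$max[i]; cl <- cb$min[i]; cu <- cb$max[i]
    out[i] <-
      if (eq(pl, cl) && eq(pu, cu)) "identical"
      else if (eq(pl, cl) && pu > cu + tie_tol) "same_min_higher_max"
      else if (pl < cl - tie_tol && pu > cu + tie_tol) "containment"
      else if (pl > cl + tie_tol && pu > cu + tie_tol && pl <= cu + tie_tol)
        "shifted_overlap"
      else if (pl > cu + tie_tol) "shifted_disjoint"
      else "other"
  }
  stats::setNames(out, common)
}

#' Pearson correlation of log-transformed fluxes
#'
#' Correlates `log10 |flux|` over reactions active in both vectors. Fewer
#' than 3 jointly active reactions yields `NaN` with a diagnostic attribute.
#'
#' @param mean_a,mean_b numeric flux vectors over the same reactions.
#' @param joint_active_mask logical mask of reactions active in both; by
#'   default computed with [classify_active()].
#' @param threshold activity threshold used for the default mask.
#' @return Pearson correlation (scalar); attribute `n` gives the number of
#'   jointly active reactions used.
#' @export
log_flux_correlation <- function(mean_a, mean_b, joint_active_mask = NULL,
                                 threshold = 1e-6) {
  stopifnot(length(mean_a) == length(mean_b))
  if (is.null(joint_active_mask))
    joint_active_mask <- classify_active(mean_a, threshold) &
      classify_active(mean_b, threshold)
  n <- sum(joint_active_mask)
  if (n < 3)
    return(structure(NaN, n = n,
                     diagnostic = "fewer than 3 jointly active reactions"))
  r <- stats::cor(log10(abs(mean_a[joint_active_mask])),
                  log10(abs(mean_b[joint_active_mask])),
                  method = "pearson")
  structure(r, n = n)
}

#' Test sampled fluxes against experimental means
#'
#' For each reaction, performs a one-sample location test of the sampled flux
#' distribution against the experimental mean (two-sided t-test), adjusts the
#' p-values across reactions by Benjamini-Hochberg, and flags reactions whose
#' adjusted p-value exceeds `fdr_level` as showing "no significant
#' difference". A reaction whose sampling distribution is numerically
#' degenerate (zero variance) is compared by absolute tolerance instead and
#' flagged as degenerate.
#'
#' @param samples a `sample_set` (or samples-by-reactions matrix with column
#'   names).
#' @param experimental an `experimental_fluxes` data frame.
#' @param fdr_level false-discovery-rate level (default 0.05).
#' @param degenerate_tol absolute tolerance used for zero-variance reactions
#'   (default 1e-6).
#' @return data frame with columns `reaction`, `p`, `p_adj`, `no_difference`,
#'   `degenerate`; attribute `fraction_no_difference`.
#' @export
mean_difference_test <- function(samples, experimental, fdr_level = 0.05,
                                 degenerate_tol = 1e-6) {
  m <- if (inherits(samples, "sample_set")) samples$samples else as.matrix(samples)
  common <- intersect(colnames(m), experimental$reaction_id)
  if (length(common) == 0) stop("no shared reactions to test")
  mu <- experimental$mean[match(common, experimental$reaction_id)]
  p <- rep(NA_real_, length(common))
  degenerate <- logical(length(common))
  nodiff_deg <- logical(length(common))
  for (i in seq_along(common)) {
    x <- m[, common[i]]
    if (stats::sd(x) < .Machine$double.eps^0.5) {
      degenerate[i] <- TRUE
      nodiff_deg[i] <- abs(mean(x) - mu[i]) <= degenerate_tol
    } else {
      p[i] <- stats::t.test(x, mu = mu[i])$p.value
    }
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  no_diff <- ifelse(degenerate, nodiff_deg, p_adj > fdr_level)
  out <- data.frame(reaction = common, p = p, p_adj = p_adj,
                    no_difference = no_diff, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  structure(out, fraction_no_difference = mean(no_diff),
            fdr_level = fdr_level)
}

#' Outlier reactions in a log-log flux comparison
#'
#' Fits an ordinary least-squares line to (log10 predicted, log10
#' experimental) over jointly active reactions, computes the residual scale
#' `s = sqrt(sum((yhat - y)^2) / (n - 2))`, and flags reactions whose
#' absolute residual exceeds `2 s`. A single pass; no refitting.
#'
#' @param predicted,experimental numeric mean flux vectors over the same
#'   (named) reactions.
#' @param joint_active_mask logical mask; default from [classify_active()].
#' @param threshold activity threshold used for the default mask.
#' @return character vector of outlier reaction names (positions when
#'   unnamed); attributes `s` and `residuals`.
#' @export
detect_outliers <- function(predicted, experimental,
                            joint_active_mask = NULL, threshold = 1e-6) {
  stopifnot(length(predicted) == length(experimental))
  if (is.null(joint_active_mask))
    joint_active_mask <- classify_active(predicted, threshold) &
      classify_active(experimental, threshold)
  if (sum(joint_active_mask) <= 2)
    stop("need at least 3 jointly active reactions")
  x <- log10(abs(predicted[joint_active_mask]))
  y <- log10(abs(experimental[joint_active_mask]))
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  s <- sqrt(sum(res^2) / (length(res) - 2))
  labels <- if (!is.null(names(predicted))) names(predicted)[joint_active_mask]
            else as.character(which(joint_active_mask))
  out <- labels[abs(res) > 2 * s]
  structure(out, s = s, residuals = stats::setNames(res, labels))
}

#' Euclidean metabolic-adjustment distance between sample sets
#'
#' Pairs sampled flux distributions of a mutant with sampled distributions of
#' the wild type (row i with row i after an optional seeded shuffle) and
#' returns the Euclidean distance of each pair over the shared reactions,
#' together with a robust (trimmed) mean. Mismatched reaction universes are
#' intersected with a warning.
#'
#' @param samples_mutant,samples_wildtype `sample_set` objects (or matrices
#'   with reaction column names).
#' @param pairing_seed optional integer; when given, wild-type rows are
#'   shuffled with this seed before pairing.
#' @param trim trimming fraction for the robust mean (default 0.05).
#' @return list with `distances` (length = number of pairs), `robust_mean`,
#'   `reactions` (shared reaction universe).
#' @export
metabolic_adjustment <- function(samples_mutant, samples_wildtype,
                                 pairing_seed = NULL, trim = 0.05) {
  a <- if (inherits(samples_mutant, "sample_set")) samples_mutant$samples
       else as.matrix(samples_mutant)
  b <- if (inherits(samples_wildtype, "sample_set")) samples_wildtype$samples
       else as.matrix(samples_wildtype)
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0) stop("no shared reactions between sample sets")
  if (length(shared) < max(ncol(a), ncol(b)))
    warning("reaction universes differ; using the ", length(shared),
            " shared reactions")
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  n <- min(nrow(a), nrow(b))
  a <- a[seq_len(n), , drop = FALSE]
  b <- b[seq_len(n), , drop = FALSE]
  if (!is.null(pairing_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(pairing_seed))
    b <- b[sample(n), , drop = FALSE]
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  d <- sqrt(rowSums((a - b)^2))
  list(distances = d, robust_mean = mean(d, trim = trim), reactions = shared)
}

#' Per-subsystem summary of flux ranges and categories
#'
#' Groups reactions by subsystem label and reports, per method, the mean
#' log10 range width, plus counts of range-comparison categories when
#' provided. Empty subsystems are omitted. No enrichment statistics are
#' computed.
#'
#' @param model a `metabolic_model` with subsystem annotation.
#' @param ranges named list of `flux_ranges` (e.g.
#'   `list(cbfba = ..., pfba = ...)`).
#' @param categories optional output of [categorize_ranges()].
#' @param zero_width log10 of a zero range width is `-Inf`; widths below
#'   `zero_width` are floored there to keep means finite (default 1e-12).
#' @return data frame with one row per subsystem.
#' @export
subsystem_summary <- function(model, ranges, categories = NULL,
                              zero_width = 1e-12) {
  if (is.null(model$subsystem)) stop("model has no subsystem annotation")
  subs <- stats::setNames(model$subsystem, model$reactions)
  rows <- list()
  for (sub in sort(unique(stats::na.omit(subs)))) {
    rxns <- names(subs)[!is.na(subs) & subs == sub]
    row <- data.frame(subsystem = sub, n_reactions = length(rxns),
                      stringsAsFactors = FALSE)
    for (method in names(ranges)) {
      rg <- ranges[[method]]
      idx <- match(rxns, rg$reaction)
      w <- pmax(rg$max[idx] - rg$min[idx], zero_width)
      row[[paste0("mean_log10_range_", method)]] <- mean(log10(w), na.rm = TRUE)
    }
    if (!is.null(categories)) {
      tab <- table(categories[intersect(rxns, names(categories))])
      for (cat in names(tab)) row[[paste0("n_", cat)]] <- as.integer(tab[[cat]])
    }
    rows[[sub]] <- row
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(row) {
    row[setdiff(cols, names(row))] <- 0L
    row[cols]
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
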