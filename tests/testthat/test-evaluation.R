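test_that("activity classification applies the 1e-6 flux threshold", {
  expect_false(classify_active(1e-7))
  expect_false(classify_active(0))
  expect_true(classify_active(1e-6))
  expect_true(classify_active(-2))          # magnitude counts
  rg <- structure(data.frame(reaction = c("a", "b"), min = c(0, 0),
                             max = c(2e-6, 5e-7)),
                  class = c("flux_ranges", "data.frame"))
  expect_equal(unname(classify_active(rg)), c(TRUE, FALSE))
})

test_that("confusion metrics reproduce hand-counted tables", {
  perfect <- confusion_metrics(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(perfect[c("sensitivity", "specificity", "accuracy")],
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  allact <- confusion_metrics(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(allact$sensitivity, 1)
  expect_equal(allact$specificity, 0)
  # constructed table TP=9 FN=1 TN=4 FP=6 -> 0.9 / 0.4 / 0.65
  pred <- c(rep(TRUE, 9), rep(FALSE, 1), rep(FALSE, 4), rep(TRUE, 6))
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.4)
  expect_equal(cm$accuracy, 0.65)
  # undefined ratios surface as NaN, never 0
  noneg <- confusion_metrics(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_true(is.nan(noneg$specificity))
  expect_error(confusion_metrics(logical(0), logical(0)), "empty")
})

test_that("interval overlap uses closed intervals and is symmetric", {
  rg <- function(lo, hi) structure(
    data.frame(reaction = "r", min = lo, max = hi),
    class = c("flux_ranges", "data.frame"))
  ex <- function(lo, hi) experimental_fluxes(
    data.frame(reaction_id = "r", mean = (lo + hi) / 2,
               ci_lower = lo, ci_upper = hi))
  expect_true(range_overlap(rg(0, 1), ex(0.5, 2))$overlap)
  expect_true(range_overlap(rg(0, 1), ex(1, 2))$overlap)      # touching
  expect_false(range_overlap(rg(0, 1), ex(1.1, 2))$overlap)
  # symmetry under swapping the interval roles
  expect_equal(unname(range_overlap(rg(0, 1), ex(1, 2))$overlap),
               unname(range_overlap(rg(1, 2), ex(0, 1))$overlap))
  # missing intervals are excluded and reported
  both <- experimental_fluxes(data.frame(
    reaction_id = c("r", "s"), mean = c(0.5, 1),
    ci_lower = c(0.4, NA), ci_upper = c(0.6, NA)))
  res <- range_overlap(structure(
    data.frame(reaction = c("r", "s"), min = c(0, 0), max = c(1, 1)),
    class = c("flux_ranges", "data.frame")), both)
  expect_equal(names(res$overlap), "r")
  expect_true("s" %in% res$excluded)
  expect_equal(res$fraction, 1)
})

test_that("range categories are assigned per the comparison taxonomy", {
  mk <- function(id, lo, hi) data.frame(reaction = id, min = lo, max = hi)
  p <- rbind(mk("a", 0, 5), mk("b", 1, 5), mk("c", 0, 3), mk("d", 2, 5),
             mk("e", 4, 5))
  cb <- rbind(mk("a", 0, 3), mk("b", 2, 3), mk("c", 0, 3), mk("d", 1, 3),
              mk("e", 1, 2))
  cats <- categorize_ranges(p, cb)
  expect_equal(unname(cats["a"]), "same_min_higher_max")
  expect_equal(unname(cats["b"]), "containment")
  expect_equal(unname(cats["c"]), "identical")
  expect_equal(unname(cats["d"]), "shifted_overlap")
  expect_equal(unname(cats["e"]), "shifted_disjoint")
})

test_that("log-flux correlation is exact on constructed data", {
  v <- c(0.5, 2, 7, 30)
  expect_equal(as.numeric(log_flux_correlation(v, v)), 1)
  # one vector a positive power of the other: log-linear, r = 1
  expect_equal(as.numeric(log_flux_correlation(v, v^1.7)), 1)
  # frozen 4-point value computed from the closed-form Pearson formula
  r <- log_flux_correlation(c(1, 2, 10, 50), c(1.2, 2.3, 8, 70))
  expect_equal(as.numeric(r), 0.9913342008, tolerance = 1e-9)
  expect_equal(attr(r, "n"), 4L)
  # fewer than 3 jointly active reactions -> NaN with diagnostic
  few <- log_flux_correlation(c(1, 2, 0), c(1, 2, 0))
  expect_true(is.nan(few))
  expect_match(attr(few, "diagnostic"), "fewer than 3")
})

test_that("mean-difference testing flags the obvious cases", {
  set.seed(5)
  n <- 60
  samples <- cbind(on_target = rnorm(n, 1, 0.05),
                   far_off = rnorm(n, 10, 0.05),
                   frozen = rep(2, n))
  ex <- experimental_fluxes(data.frame(
    reaction_id = c("on_target", "far_off", "frozen"),
    mean = c(1, 1, 2), ci_lower = c(0.9, 0.9, 1.9),
    ci_upper = c(1.1, 1.1, 2.1)))
  res <- mean_difference_test(samples, ex)
  expect_true(res$no_difference[res$reaction == "on_target"])
  expect_false(res$no_difference[res$reaction == "far_off"])
  expect_true(res$degenerate[res$reaction == "frozen"])
  expect_true(res$no_difference[res$reaction == "frozen"])
})

test_that("mean-difference testing is calibrated on null data", {
  # 200 replicates x 50 null reactions; under the global null the BH
  # procedure's false-discovery rate equals the probability of any
  # rejection, which should sit near the nominal 5%
  set.seed(42)
  reps <- 200
  fdp <- numeric(reps)
  for (b in seq_len(reps)) {
    samples <- matrix(rnorm(40 * 50, mean = 2, sd = 0.3), 40, 50,
                      dimnames = list(NULL, paste0("r", 1:50)))
    ex <- experimental_fluxes(data.frame(
      reaction_id = paste0("r", 1:50), mean = 2, ci_lower = 1, ci_upper = 3))
    res <- mean_difference_test(samples, ex, fdr_level = 0.05)
    rejected <- sum(!res$no_difference)
    # all nulls: the false-discovery proportion is 1 when anything is
    # rejected and 0 otherwise
    fdp[b] <- as.numeric(rejected > 0)
  }
  fdr_hat <- mean(fdp)
  mc_err <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(fdr_hat - 0.05), mc_err + 0.01)
})

test_that("outlier detection flags exactly the displaced point", {
  # ten collinear points plus one displaced far off the regression line
  x <- 10^seq(0, 2, length.out = 11)
  y <- x^1.3 * 2
  y[6] <- y[6] * 1e6          # push one point many residual scales away
  names(x) <- names(y) <- paste0("r", 1:11)
  out <- detect_outliers(x, y)
  expect_equal(as.character(out), "r6")
  # perfectly collinear points: no outliers
  none <- detect_outliers(x, x^2, joint_active_mask = rep(TRUE, 11))
  expect_length(as.character(none), 0)
  # flagged set equals a direct residual scan
  set.seed(9)
  xs <- 10^runif(30, -1, 2); ys <- xs^1.1 * 10^rnorm(30, 0, 0.3)
  names(xs) <- names(ys) <- paste0("q", 1:30)
  got <- detect_outliers(xs, ys)
  fit <- lm(log10(ys) ~ log10(xs))
  s <- sqrt(sum(residuals(fit)^2) / (30 - 2))
  expect_setequal(as.character(got),
                  names(xs)[abs(residuals(fit)) > 2 * s])
  expect_error(detect_outliers(xs[1:2], ys[1:2]), "at least 3")
})

test_that("metabolic adjustment distances obey the closed forms", {
  m <- matrix(runif(60), 10, 6, dimnames = list(NULL, paste0("r", 1:6)))
  same <- metabolic_adjustment(m, m)
  expect_equal(unname(same$distances), rep(0, 10))
  # shift by delta on k reactions -> every distance delta * sqrt(k)
  delta <- 0.37; k <- 4
  shifted <- m
  shifted[, 1:k] <- shifted[, 1:k] + delta
  adj <- metabolic_adjustment(m, shifted)
  expect_equal(unname(adj$distances), rep(delta * sqrt(k), 10),
               tolerance = 1e-12)
  expect_equal(adj$robust_mean, delta * sqrt(k), tolerance = 1e-12)
  # elementwise norm recomputation on random pairs
  a <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, paste0("x", 1:10)))
  b <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, paste0("x", 1:10)))
  got <- metabolic_adjustment(a, b)$distances
  expect_equal(got, sqrt(rowSums((a - b)^2)))
  # mismatched universes intersect with a warning
  expect_warning(metabolic_adjustment(a, b[, 1:7]), "shared")
})

test_that("subsystem summaries equal group-by recomputation", {
  toy <- toy_network()
  toy$subsystem <- c(rep("Exchange", 4), rep("Core", 5))
  rg <- data.frame(reaction = toy$reactions,
                   min = rep(0, 9), max = c(rep(1, 4), rep(10, 5)))
  out <- subsystem_summary(toy, list(m = rg))
  expect_equal(out$subsystem, c("Core", "Exchange"))
  expect_equal(out$mean_log10_range_m[out$subsystem == "Exchange"], 0)
  expect_equal(out$mean_log10_range_m[out$subsystem == "Core"], 1)
  # mixed widths average in log space: (log10 1 + log10 10) / 2 = 0.5
  rg2 <- data.frame(reaction = c("E1", "E2"), min = c(0, 0), max = c(1, 10))
  toy2 <- toy_network()
  toy2$subsystem <- c("S", "S", rep(NA, 7))
  out2 <- subsystem_summary(toy2, list(m = rg2))
  expect_equal(out2$mean_log10_range_m, 0.5)
})
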