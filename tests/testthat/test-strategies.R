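# Cross-validation strategies and derived selection statistics.

test_that("fold construction is balanced, exhaustive and deterministic", {
  sch <- make_folds(453, 5, 2, seed = 1)
  sizes <- sort(as.integer(table(sch$assignments[, 1])), decreasing = TRUE)
  expect_equal(sizes, c(91L, 91L, 91L, 90L, 90L))
  expect_equal(sum(sizes), 453L)

  sch10 <- make_folds(10, 5, 3, seed = 2)
  expect_true(all(apply(sch10$assignments, 2, function(a) all(table(a) == 2))))

  expect_identical(make_folds(100, 5, 4, seed = 7)$assignments,
                   make_folds(100, 5, 4, seed = 7)$assignments)
  expect_false(identical(make_folds(100, 5, 4, seed = 7)$assignments,
                         make_folds(100, 5, 4, seed = 8)$assignments))
  expect_error(make_folds(3, 5), "partition|folds")
})

test_that("growth-curve AUC follows the trapezoid rule with a planting baseline", {
  expect_equal(unname(auc_trait(matrix(c(100, 200, 300, 400), 1))), 800)
  expect_equal(unname(auc_trait(matrix(6, 1, 1))), 3)        # single measure: h/2
  # linearity under rescaling
  set.seed(12)
  H <- matrix(rexp(40, 1 / 100), 10, 4)
  expect_equal(auc_trait(3.5 * H), 3.5 * auc_trait(H), tolerance = 1e-12)
  # missing measurement propagates NA with a warning
  H[2, 3] <- NA
  expect_warning(a <- auc_trait(H), "missing")
  expect_true(is.na(a[2]) && !anyNA(a[-2]))
})

test_that("indirect index standardizes and weights secondary GEBVs", {
  set.seed(13)
  g1 <- rnorm(50); g2 <- rnorm(50)
  idx <- indirect_index(cbind(g1, g2), c(0.84, -0.45))
  # direct evaluation of the weighted standardized sum
  manual <- 0.84 * (g1 - mean(g1)) / sd(g1) - 0.45 * (g2 - mean(g2)) / sd(g2)
  expect_equal(unname(idx), unname(manual), tolerance = 1e-12)

  # two identical vectors: the index is perfectly correlated with either
  idx2 <- indirect_index(cbind(g1, g1), c(0.5, 0.5))
  expect_equal(abs(cor(idx2, g1)), 1, tolerance = 1e-12)

  # single secondary trait: correlation with any target is unchanged
  target <- rnorm(50)
  idx1 <- indirect_index(cbind(g1), 0.7)
  expect_equal(cor(idx1, target), cor(g1, target), tolerance = 1e-12)

  expect_error(indirect_index(cbind(rep(1, 10)), 0.5), "zero-variance")
})

test_that("coincidence index reproduces the chance-corrected overlap arithmetic", {
  ids <- sprintf("G%03d", 1:453)
  x <- setNames(rnorm(453), ids)
  ci <- coincidence_index(x, setNames(rnorm(453), ids), intensity = 0.20)
  expect_equal(ci$T, 91L)
  expect_equal(ci$R, 18L)

  # identical rankings give CI = 1
  ci1 <- coincidence_index(x, x, intensity = 0.20)
  expect_equal(ci1$ci, 1)
  expect_equal(ci1$B, 91L)

  # independent rankings: CI centred at ~0 (Monte Carlo)
  set.seed(14)
  cis <- replicate(2000, {
    coincidence_index(setNames(rnorm(453), ids), setNames(rnorm(453), ids))$ci
  })
  expect_lt(abs(mean(cis)), 0.02)

  # bottom selection selects the worst
  y <- setNames(seq_len(10), letters[1:10])
  cib <- coincidence_index(y, -y, intensity = 0.2, direction = "bottom")
  expect_equal(cib$B, 0L)
  expect_error(coincidence_index(y[1:4], y[1:4], intensity = 0.9), "undefined")
})

test_that("expected selection accuracies follow the phenotypic-selection formulas", {
  r <- expected_selection_accuracy(0.5, 0.9, 0.8, 0.6)
  expect_equal(r$ps, 0.5)
  expect_equal(r$ips, 0.72)
  expect_equal(r$ratio_ps, 1.2)
  expect_equal(r$ratio_ips, 0.6 / 0.72)
  expect_equal(expected_selection_accuracy(1, 1, 1, 1)$ips, 1)
  expect_equal(expected_selection_accuracy(0.3, 1, 1, 0.3)$ratio_ps, 1)
  expect_true(is.na(expected_selection_accuracy(0, 0.5, 0, 0.4)$ratio_ips))
  expect_error(expected_selection_accuracy(1.2, 0.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("accuracy is one pooled correlation per repeat, not a fold average", {
  # crafted example where the two protocols disagree by construction:
  # within every fold the prediction ranks the two genotypes backwards
  # (per-fold correlation -1), yet the fold levels track the data so the
  # pooled correlation is near +1
  x <- c(1, 2, 11, 12, 21, 22)
  pred <- c(1.6, 1.4, 11.6, 11.4, 21.6, 21.4)
  folds <- c(1, 1, 2, 2, 3, 3)
  per_fold <- sapply(1:3, function(f) cor(pred[folds == f], x[folds == f]))
  pooled <- cor(pred, x)
  expect_equal(mean(per_fold), -1)
  expect_gt(pooled, 0.99)

  # run_strategy stores per-repeat pooled predictions over all genotypes
  st <- small_study(n = 60, p = 400, seed = 61)
  sch <- make_folds(60, 5, 2, seed = 3)
  res <- run_strategy(st$phenotypes, st$A, "standard", "yield", NULL, sch)
  for (r in 1:2) {
    pooled_r <- cor(res$predictions[, r], st$phenotypes[, "yield"])
    expect_equal(res$r[r], pooled_r, tolerance = 1e-12)
    expect_false(anyNA(res$predictions[, r]))
  }
})

test_that("every strategy consumes identical fold assignments", {
  st <- small_study(n = 60, p = 400, seed = 62)
  sch <- make_folds(60, 5, 2, seed = 11)
  r1 <- run_strategy(st$phenotypes, st$A, "standard", "yield", NULL, sch)
  r2 <- run_strategy(st$phenotypes, st$A, "trait_assisted", "yield", "height", sch)
  expect_identical(r1$fold_assignments, r2$fold_assignments)
  expect_identical(r1$fold_assignments, sch$assignments)
})

test_that("an uninformative secondary trait leaves trait-assisted at the standard level", {
  cfg <- sim_config(150, 800, heritabilities = c(0.4, 0.6),
                    genetic_correlation = 0, residual_correlation = 0,
                    seed = 63)
  st <- sim_phenotypes(sim_genotypes(cfg), cfg)
  colnames(st$phenotypes) <- c("yield", "height")
  A <- vanraden_grm(st$genotypes)
  sch <- make_folds(150, 5, 3, seed = 4)
  std <- run_strategy(st$phenotypes, A, "standard", "yield", NULL, sch)
  ta <- run_strategy(st$phenotypes, A, "trait_assisted", "yield", "height", sch)
  expect_lt(abs(ta$mean - std$mean), 0.05)
})

test_that("strategy configuration errors are caught before compute", {
  st <- small_study(n = 40, p = 200, seed = 64)
  sch <- make_folds(40, 5, 1, seed = 1)
  expect_error(run_strategy(st$phenotypes, st$A, "trait_assisted", "yield",
                            NULL, sch), "secondary")
  expect_error(run_strategy(st$phenotypes, st$A, "multi_trait_indirect", "yield",
                            "height", sch), ">= 2")
  expect_error(run_strategy(st$phenotypes, st$A, "standard", "nope", NULL, sch),
               "not found")
  expect_error(run_strategy(st$phenotypes, st$A, "sideways", "yield", NULL, sch),
               "unknown strategy")
})

test_that("training-fraction sweep matches run_strategy at the default split and warns on tiny fractions", {
  st <- small_study(n = 100, p = 600, seed = 65)
  sch <- make_folds(100, 5, 3, seed = 21)
  std <- run_strategy(st$phenotypes, st$A, "standard", "yield", NULL, sch)
  sw <- training_fraction_sweep(st$phenotypes, st$A, "standard", "yield",
                                NULL, sch, fractions = c(0.8))
  # both estimate the same quantity from different random splits
  expect_equal(sw[["f0.80"]]$mean, std$mean, tolerance = 0.2)

  expect_warning(
    empty <- training_fraction_sweep(st$phenotypes, st$A, "standard", "yield",
                                     NULL, sch, fractions = c(0.1)),
    "skipped")
  expect_length(empty, 0L)
})

test_that("standard-GS accuracy increases with heritability", {
  h2s <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- vapply(seq_along(h2s), function(i) {
    cfg <- sim_config(120, 800, heritabilities = h2s[i], seed = 700 + i)
    st <- sim_phenotypes(sim_genotypes(cfg), cfg)
    A <- vanraden_grm(st$genotypes)
    y <- st$phenotypes[, 1, drop = FALSE]
    colnames(y) <- "focal"
    sch <- make_folds(120, 5, 2, seed = 31)
    run_strategy(y, A, "standard", "focal", NULL, sch)$mean
  }, 0)
  expect_gt(cor(means, h2s, method = "spearman"), 0)
  expect_gt(means[5], means[1])
})
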