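# Univariate and bivariate GBLUP: oracle equivalence against dense
# mixed-model-equation solves, prediction routes, and degenerate cases.

test_that("univariate BLUP at fixed components equals the dense MME oracle", {
  set.seed(21)
  st <- small_study(n = 40, p = 300, seed = 31)
  A <- tagsel:::as_grm_matrix(st$A)
  y <- st$phenotypes[, 1]
  obs <- sort(sample(40, 30))
  yo <- y[obs]; names(yo) <- rownames(A)[obs]
  fit <- gblup(yo, A, fix = list(sigma2_g = 0.2, sigma2_e = 0.7))
  or <- oracle_mme_univariate(unname(yo), obs, A, 0.2, 0.7)
  expect_equal(unname(fit$gebv), or$gebv, tolerance = 1e-8)
  expect_equal(fit$mu, or$mu, tolerance = 1e-8)

  # tiny n = 6 instance
  A6 <- A[1:6, 1:6]
  y6 <- y[1:6]; names(y6) <- rownames(A6)
  f6 <- gblup(y6, A6, fix = list(sigma2_g = 0.5, sigma2_e = 0.5))
  o6 <- oracle_mme_univariate(unname(y6), 1:6, A6, 0.5, 0.5)
  expect_equal(unname(f6$gebv), o6$gebv, tolerance = 1e-8)
})

test_that("constant phenotypes give zero genetic variance and zero GEBVs", {
  st <- small_study(n = 50, p = 300, seed = 32)
  A <- st$A
  y <- rep(3.7, 50); names(y) <- rownames(A$values)
  fit <- suppressWarnings(gblup(y, A))
  expect_lt(fit$sigma2_g, 1e-8)
  expect_lt(max(abs(fit$gebv)), 1e-6)
})

test_that("held-out prediction equals the joint missing-record solve", {
  st <- small_study(n = 80, p = 500, seed = 33)
  A <- tagsel:::as_grm_matrix(st$A)
  y <- st$phenotypes[, 1]
  val <- sort(sample(80, 16))
  obs <- setdiff(1:80, val)
  yo <- y[obs]; names(yo) <- rownames(A)[obs]
  fit <- gblup(yo, A)
  # route 1: joint BLUP of the fit (query records were missing)
  joint <- fit$gebv[rownames(A)[val]]
  # route 2: conditional expectation from observed GEBVs
  pred <- predict(fit, A, ids = rownames(A)[val])
  expect_equal(pred, joint, tolerance = 1e-8)

  # a duplicated genotype predicts its twin's GEBV
  A2 <- rbind(cbind(A, A[, 1]), c(A[1, ], A[1, 1]))
  rownames(A2) <- colnames(A2) <- c(rownames(A), "twin")
  fit2 <- gblup(yo, A2)
  expect_equal(unname(fit2$gebv["twin"]),
               unname(fit2$gebv[rownames(A)[1]]), tolerance = 1e-4)

  # an unrelated genotype predicts ~0
  A3 <- rbind(cbind(A, 0), c(rep(0, 80), mean(diag(A))))
  rownames(A3) <- colnames(A3) <- c(rownames(A), "stranger")
  fit3 <- gblup(yo, A3)
  expect_lt(abs(fit3$gebv["stranger"]), 1e-8)
})

test_that("univariate h2 recovery is unbiased at moderate scale", {
  h2_hat <- vapply(1:5, function(i) {
    cfg <- sim_config(250, 2000, heritabilities = 0.26, seed = 400 + i)
    st <- sim_phenotypes(sim_genotypes(cfg), cfg)
    gblup(st$phenotypes[, 1], vanraden_grm(st$genotypes))$h2_g
  }, 0)
  expect_equal(mean(h2_hat), 0.26, tolerance = 0.08)
})

test_that("bivariate BLUP at fixed components equals the dense joint MME oracle", {
  st <- small_study(n = 30, p = 300, seed = 34)
  A <- tagsel:::as_grm_matrix(st$A)
  G <- matrix(c(0.25, 0.15, 0.15, 0.45), 2)
  R <- matrix(c(0.6, 0.1, 0.1, 0.2), 2)
  # complete records
  Yc <- st$phenotypes
  blc <- blup_given_components(Yc, A, G, R)
  orc <- oracle_mme_bivariate(Yc, A, G, R)
  expect_equal(unname(blc$gebv), orc$gebv, tolerance = 1e-8)
  expect_equal(unname(blc$mu), orc$mu, tolerance = 1e-8)

  # missing focal records for 8 genotypes (trait-assisted pattern)
  Ym <- st$phenotypes
  Ym[c(2, 5, 7, 11, 13, 17, 23, 29), 1] <- NA
  blm <- blup_given_components(Ym, A, G, R)
  orm <- oracle_mme_bivariate(Ym, A, G, R)
  expect_equal(unname(blm$gebv), orm$gebv, tolerance = 1e-8)

  # n = 5 toy with printed components
  A5 <- diag(2, 5); A5[1, 2] <- A5[2, 1] <- 1.2; A5[3, 4] <- A5[4, 3] <- 0.8
  rownames(A5) <- colnames(A5) <- paste0("t", 1:5)
  Y5 <- cbind(c(1.2, NA, 0.3, -0.5, 2.0), c(0.8, 1.1, NA, -0.2, 1.5))
  rownames(Y5) <- rownames(A5)
  G5 <- matrix(c(0.3, 0.2, 0.2, 0.4), 2)
  R5 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  expect_equal(unname(blup_given_components(Y5, A5, G5, R5)$gebv),
               oracle_mme_bivariate(Y5, A5, G5, R5)$gebv, tolerance = 1e-8)
})

test_that("bivariate REML likelihood matches the dense oracle for arbitrary missingness", {
  st <- small_study(n = 25, p = 200, seed = 35)
  A <- tagsel:::as_grm_matrix(st$A)
  Y <- st$phenotypes
  Y[c(1, 4, 9), 1] <- NA
  Y[c(2, 9, 20), 2] <- NA
  ctx <- tagsel:::mt_context(Y, A, 1e-6)
  for (theta in list(c(log(0.3), log(0.5), atanh(0.6), log(0.5), log(0.3), atanh(0.2)),
                     c(log(0.1), log(0.9), atanh(-0.4), log(0.8), log(0.2), 0))) {
    GR <- tagsel:::theta_to_GR(theta)
    expect_equal(tagsel:::mt_loglik(theta, ctx),
                 oracle_mt_loglik(Y, A, GR$G, GR$R), tolerance = 1e-8)
  }
})

test_that("diagonal G and R decouple the traits to univariate BLUP", {
  st <- small_study(n = 40, p = 300, seed = 36)
  A <- tagsel:::as_grm_matrix(st$A)
  Y <- st$phenotypes
  Y[1:8, 1] <- NA
  G <- diag(c(0.3, 0.5)); R <- diag(c(0.5, 0.2))
  bl <- blup_given_components(Y, A, G, R)
  yobs <- Y[!is.na(Y[, 1]), 1]
  uni <- gblup(yobs, A, fix = list(sigma2_g = 0.3, sigma2_e = 0.5))
  expect_equal(unname(bl$gebv[, 1]), unname(uni$gebv), tolerance = 1e-8)
})

test_that("bivariate REML recovers variance components and equals the univariate route", {
  # route equivalence: trait 2 fully missing reduces to the univariate fit
  st <- small_study(n = 60, p = 400, seed = 37)
  A <- st$A
  Y <- st$phenotypes
  Y[, 2] <- NA
  bf <- gblup_mt(Y, A)
  uni <- gblup(st$phenotypes[, 1], A)
  expect_equal(bf$reml_loglik, uni$reml_loglik, tolerance = 1e-6)
  expect_equal(bf$G[1, 1], uni$sigma2_g, tolerance = 1e-4)
  expect_equal(bf$R[1, 1], uni$sigma2_e, tolerance = 1e-4)
  expect_equal(unname(bf$gebv[, 1]), unname(uni$gebv), tolerance = 1e-5)

  # duplicated trait drives the genetic correlation to 1
  Yd <- cbind(st$phenotypes[, 1], st$phenotypes[, 1])
  rownames(Yd) <- rownames(st$phenotypes)
  bd <- gblup_mt(Yd, A)
  expect_gte(bd$cor_g, 0.98)
})

test_that("optimizer never returns a worse likelihood than its start", {
  for (i in 1:3) {
    st <- small_study(n = 40, p = 300, seed = 50 + i)
    Y <- st$phenotypes
    if (i == 2) Y[1:10, 1] <- NA
    fit <- gblup_mt(Y, st$A, polish = FALSE)
    expect_gte(fit$reml_loglik, fit$loglik_start)
  }
})

test_that("GEBVs are shrunken relative to phenotypes", {
  st <- small_study(n = 100, p = 600, seed = 38)
  fit1 <- gblup(st$phenotypes[, 1], st$A)
  expect_lte(var(fit1$gebv), var(st$phenotypes[, 1]))
  fitm <- gblup_mt(st$phenotypes, st$A, polish = FALSE)
  expect_lte(var(fitm$gebv[, 1]), var(st$phenotypes[, 1]))
  expect_lte(var(fitm$gebv[, 2]), var(st$phenotypes[, 2]))
  expect_true(fit1$h2_g >= 0 && fit1$h2_g <= 1)
})

test_that("correlation standard errors are finite, nonnegative, and small in degenerate cases", {
  st <- small_study(n = 80, p = 500, seed = 39)
  fit <- gblup_mt(st$phenotypes, st$A)
  se <- correlation_se(fit)
  expect_true(all(is.finite(se)))
  expect_true(all(se >= 0))
  expect_lt(se["cor_g"], 0.5)

  # near-duplicate trait: correlation pinned near 1, SE near 0
  Yd <- cbind(st$phenotypes[, 1],
              st$phenotypes[, 1] + rnorm(80, sd = 0.01))
  rownames(Yd) <- rownames(st$phenotypes)
  bd <- gblup_mt(Yd, st$A)
  sed <- suppressWarnings(correlation_se(bd))
  if (is.finite(sed["cor_g"])) expect_lt(sed["cor_g"], 0.05)
})

test_that("bivariate fit rejects unidentifiable designs", {
  st <- small_study(n = 20, p = 150, seed = 40)
  Y <- st$phenotypes
  Y[1:10, 1] <- NA
  Y[11:20, 2] <- NA
  expect_error(gblup_mt(Y, st$A), "unidentifiable")
})
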