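# Independent brute-force oracles used to validate the package's fast
# computation routes. These deliberately use naive dense linear algebra and
# textbook formulas, never the package's own solvers.

# VanRaden method-1 GRM by elementwise summation.
oracle_vanraden <- function(dos) {
  n <- nrow(dos); p <- ncol(dos)
  freq <- colMeans(dos) / 2
  poly <- freq > 0 & freq < 1
  denom <- 2 * sum(freq[poly] * (1 - freq[poly]))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- sum((dos[i, ] - 2 * freq) * (dos[j, ] - 2 * freq)) / denom
    }
  }
  G
}

# Univariate mixed-model equations at fixed components:
# [1'R^-1 1, 1'R^-1 Z; Z'R^-1 1, Z'R^-1 Z + A^-1 * se2/sg2] [mu; g] = rhs.
# Returns BLUPs for ALL genotypes in A (unobserved handled through A^-1).
oracle_mme_univariate <- function(y_obs, obs_idx, A, sg2, se2, ridge = 1e-6) {
  n <- nrow(A)
  m <- length(obs_idx)
  Z <- matrix(0, m, n)
  Z[cbind(seq_len(m), obs_idx)] <- 1
  Ainv <- solve(A + diag(ridge, n))
  X <- matrix(1, m, 1)
  C <- rbind(cbind(crossprod(X) / se2, t(X) %*% Z / se2),
             cbind(t(Z) %*% X / se2, crossprod(Z) / se2 + Ainv / sg2))
  rhs <- c(sum(y_obs) / se2, drop(t(Z) %*% y_obs) / se2)
  sol <- solve(C, rhs)
  list(mu = unname(sol[1]), gebv = unname(sol[-1]))
}

# Bivariate mixed-model equations at fixed G, R with per-trait incidence.
# y is an n x 2 matrix with NA for missing records.
oracle_mme_bivariate <- function(Y, A, G, R, ridge = 1e-6) {
  n <- nrow(A)
  obs <- which(!is.na(Y))          # column-major cell indices into n x 2
  m <- length(obs)
  # records stacked trait-major to match u = (g trait1, g trait2)
  cell_trait <- ((obs - 1) %/% n) + 1
  cell_geno <- ((obs - 1) %% n) + 1
  Z <- matrix(0, m, 2 * n)
  Z[cbind(seq_len(m), (cell_trait - 1) * n + cell_geno)] <- 1
  X <- cbind(as.numeric(cell_trait == 1), as.numeric(cell_trait == 2))
  X <- X[, colSums(X) > 0, drop = FALSE]
  y <- Y[obs]
  # residual covariance between records of the same genotype
  Rm <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (cell_geno[i] == cell_geno[j]) {
        Rm[i, j] <- R[cell_trait[i], cell_trait[j]]
      }
    }
  }
  Rinv <- solve(Rm)
  Ginv <- solve(G) %x% solve(A + diag(ridge, n))
  C <- rbind(cbind(t(X) %*% Rinv %*% X, t(X) %*% Rinv %*% Z),
             cbind(t(Z) %*% Rinv %*% X, t(Z) %*% Rinv %*% Z + Ginv))
  rhs <- c(t(X) %*% Rinv %*% y, t(Z) %*% Rinv %*% y)
  sol <- solve(C, rhs)
  p <- ncol(X)
  list(mu = unname(sol[seq_len(p)]),
       gebv = matrix(unname(sol[-seq_len(p)]), n, 2))
}

# Dense textbook REML log-likelihood for the stage-1 spatial model,
# evaluated from the covariance built element-by-element; matches the
# error-contrast convention (log|X'X| subtracted).
oracle_stage1_loglik <- function(plots, include_block, gamma, rho_row, rho_col) {
  y <- plots$value
  m <- length(y)
  X <- stats::model.matrix(~ factor(plots$genotype))
  V0 <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      V0[i, j] <- rho_row^abs(plots$row[i] - plots$row[j]) *
        rho_col^abs(plots$col[i] - plots$col[j])
    }
  }
  if (include_block) {
    Zb <- stats::model.matrix(~ 0 + factor(plots$block))
    V0 <- V0 + gamma * tcrossprod(Zb)
  }
  Vi <- solve(V0)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  p <- ncol(X)
  s2 <- drop(t(r) %*% Vi %*% r) / (m - p)
  -0.5 * ((m - p) * (log(2 * pi * s2) + 1) +
            as.numeric(determinant(V0, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) -
            as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus))
}

# Dense REML log-likelihood of the bivariate GBLUP on observed records.
oracle_mt_loglik <- function(Y, A, G, R, ridge = 1e-6) {
  n <- nrow(A)
  Ar <- A + diag(ridge, n)
  o1 <- which(!is.na(Y[, 1])); o2 <- which(!is.na(Y[, 2]))
  V11 <- G[1, 1] * Ar[o1, o1, drop = FALSE] + R[1, 1] * diag(length(o1))
  V22 <- G[2, 2] * Ar[o2, o2, drop = FALSE] + R[2, 2] * diag(length(o2))
  E12 <- outer(o1, o2, "==")
  V12 <- G[1, 2] * Ar[o1, o2, drop = FALSE] + R[1, 2] * E12
  V <- rbind(cbind(V11, V12), cbind(t(V12), V22))
  X <- rbind(matrix(c(1, 0), length(o1), 2, byrow = TRUE),
             matrix(c(0, 1), length(o2), 2, byrow = TRUE))
  X <- X[, colSums(X) > 0, drop = FALSE]
  y <- c(Y[o1, 1], Y[o2, 2])
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) +
            drop(t(r) %*% Vi %*% r) +
            (length(y) - ncol(X)) * log(2 * pi))
}
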