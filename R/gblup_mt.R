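# Bivariate GBLUP with unstructured genetic (G) and residual (R) 2x2
# covariance matrices, REML variance components, and missing-record BLUP:
# the engine behind multi-trait and trait-assisted genomic selection.
#
# REML maximisation is direct: the residual log-likelihood is evaluated
# exactly (dense Cholesky on the observed-record covariance, or an O(n)
# eigen-rotated form when both traits are fully recorded) and maximised by
# Nelder-Mead over (log variances, Fisher-z correlations), which keeps G and
# R positive definite throughout, followed by an optional coordinate-wise
# golden-section polish.

theta_to_GR <- function(theta) {
  G <- matrix(0, 2, 2); R <- matrix(0, 2, 2)
  G[1, 1] <- exp(theta[1]); G[2, 2] <- exp(theta[2])
  G[1, 2] <- G[2, 1] <- tanh(theta[3]) * sqrt(G[1, 1] * G[2, 2])
  R[1, 1] <- exp(theta[4]); R[2, 2] <- exp(theta[5])
  R[1, 2] <- R[2, 1] <- tanh(theta[6]) * sqrt(R[1, 1] * R[2, 2])
  list(G = G, R = R)
}

# Precomputed structures shared by every likelihood evaluation.
#
# The observed-record covariance is the submatrix, at observed (trait,
# genotype) cells, of the complete-data covariance G (x) A_r + R (x) I.
# One eigendecomposition A_r = U D U' turns the complete covariance into
# independent 2x2 blocks S_i = d_i G + R per eigen-index, and missing cells
# are handled exactly by Schur-complement downdating of the inverse:
# with Q = V_full^{-1} (block-diagonal after rotation),
#   V_obs^{-1} = [Q - Q[, mis] Q[mis, mis]^{-1} Q[mis, ]]_obs,
#   log det V_obs = log det V_full + log det Q[mis, mis].
# Every REML evaluation is then O(n * n_mis^2) instead of a dense
# Cholesky of the stacked records.
mt_context <- function(Y, A, ridge) {
  n <- nrow(A)
  obs1 <- !is.na(Y[, 1])
  obs2 <- !is.na(Y[, 2])
  Ar <- A + diag(ridge, n)
  eg <- eigen(Ar, symmetric = TRUE)
  U <- eg$vectors
  y0 <- Y
  y0[is.na(y0)] <- 0
  x1 <- cbind(as.numeric(obs1), 0)
  x2 <- cbind(0, as.numeric(obs2))
  list(n = n, m = sum(obs1) + sum(obs2),
       obs1 = obs1, obs2 = obs2,
       j1 = which(!obs1), j2 = which(!obs2),
       n_mis = sum(!obs1) + sum(!obs2),
       traits_present = which(c(any(obs1), any(obs2))),
       U = U, d = pmax(eg$values, 0), Ar = Ar,
       Um1 = U[!obs1, , drop = FALSE], Um2 = U[!obs2, , drop = FALSE],
       yt = crossprod(U, y0), x1t = crossprod(U, x1), x2t = crossprod(U, x2))
}

# 2x2 block structure of the rotated complete covariance and its inverse.
mt_blocks <- function(G, R, ctx) {
  a <- ctx$d * G[1, 1] + R[1, 1]
  b <- ctx$d * G[1, 2] + R[1, 2]
  cc <- ctx$d * G[2, 2] + R[2, 2]
  det2 <- a * cc - b^2
  if (any(det2 <= 0) || any(a <= 0) || any(cc <= 0)) return(NULL)
  list(t11 = cc / det2, t12 = -b / det2, t22 = a / det2,
       logdet_full = sum(log(det2)))
}

# apply the rotated inverse blocks to a rotated n x 2 vector
mt_apply_T <- function(bl, vt) {
  cbind(bl$t11 * vt[, 1] + bl$t12 * vt[, 2],
        bl$t12 * vt[, 1] + bl$t22 * vt[, 2])
}

# Shared core: GLS pieces of the observed-record model at (G, R).
# Returns NULL when the covariance leaves the PD cone numerically.
mt_core <- function(G, R, ctx) {
  bl <- mt_blocks(G, R, ctx)
  if (is.null(bl)) return(NULL)
  qy <- mt_apply_T(bl, ctx$yt)
  qx1 <- mt_apply_T(bl, ctx$x1t)
  qx2 <- mt_apply_T(bl, ctx$x2t)
  mis_part <- function(qv) c(ctx$Um1 %*% qv[, 1], ctx$Um2 %*% qv[, 2])
  has_mis <- ctx$n_mis > 0L
  if (has_mis) {
    Qmm <- rbind(
      cbind(ctx$Um1 %*% (bl$t11 * t(ctx$Um1)), ctx$Um1 %*% (bl$t12 * t(ctx$Um2))),
      cbind(ctx$Um2 %*% (bl$t12 * t(ctx$Um1)), ctx$Um2 %*% (bl$t22 * t(ctx$Um2))))
    Lm <- tryCatch(chol(Qmm), error = function(e) NULL)
    if (is.null(Lm)) return(NULL)
    my <- mis_part(qy); mx1 <- mis_part(qx1); mx2 <- mis_part(qx2)
    sy <- backsolve(Lm, backsolve(Lm, my, transpose = TRUE))
    sx1 <- backsolve(Lm, backsolve(Lm, mx1, transpose = TRUE))
    sx2 <- backsolve(Lm, backsolve(Lm, mx2, transpose = TRUE))
    logdet_mm <- 2 * sum(log(diag(Lm)))
  } else {
    my <- mx1 <- mx2 <- sy <- sx1 <- sx2 <- numeric(0)
    logdet_mm <- 0
    Lm <- NULL
  }
  ip <- function(vt, qw, mv, sw) sum(vt * qw) - if (has_mis) sum(mv * sw) else 0
  yy <- ip(ctx$yt, qy, my, sy)
  x1y <- ip(ctx$x1t, qy, mx1, sy)
  x2y <- ip(ctx$x2t, qy, mx2, sy)
  x11 <- ip(ctx$x1t, qx1, mx1, sx1)
  x12 <- ip(ctx$x1t, qx2, mx1, sx2)
  x22 <- ip(ctx$x2t, qx2, mx2, sx2)
  tp <- ctx$traits_present
  XtVX <- matrix(c(x11, x12, x12, x22), 2, 2)[tp, tp, drop = FALSE]
  Xty <- c(x1y, x2y)[tp]
  beta <- tryCatch(solve(XtVX, Xty), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  list(bl = bl, Lm = Lm, beta = beta, XtVX = XtVX,
       yPy = yy - sum(beta * Xty),
       logdet_obs = bl$logdet_full + logdet_mm,
       qy = qy, qx1 = qx1, qx2 = qx2, my = my, mx1 = mx1, mx2 = mx2)
}

# REML log-likelihood; a large finite penalty (not -Inf) on numerical
# failure keeps optimize()/optim() well-behaved at the PD-cone boundary.
mt_loglik <- function(theta, ctx) {
  p <- theta_to_GR(theta)
  core <- mt_core(p$G, p$R, ctx)
  if (is.null(core)) return(-1e300)
  ld_x <- determinant(core$XtVX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (core$logdet_obs + ld_x + core$yPy +
                       (ctx$m - length(ctx$traits_present)) * log(2 * pi)))
}

# GLS intercepts and BLUPs for all genotypes at fixed (G, R):
# g_hat = (G (x) A_r)[, obs] V_obs^{-1} (y - X beta).
mt_blup_at <- function(G, R, ctx) {
  core <- mt_core(G, R, ctx)
  if (is.null(core)) stopf("covariance components are not positive definite")
  mu <- c(0, 0)
  mu[ctx$traits_present] <- core$beta
  rt <- ctx$yt - mu[1] * ctx$x1t - mu[2] * ctx$x2t
  qr_ <- mt_apply_T(core$bl, rt)
  if (ctx$n_mis > 0L) {
    mr <- c(ctx$Um1 %*% qr_[, 1], ctx$Um2 %*% qr_[, 2])
    alpha <- backsolve(core$Lm, backsolve(core$Lm, mr, transpose = TRUE))
    a1 <- alpha[seq_along(ctx$j1)]
    a2 <- alpha[length(ctx$j1) + seq_along(ctx$j2)]
    # rotated representation of the missing-cell correction vector
    at <- cbind(if (length(ctx$j1)) drop(crossprod(ctx$Um1, a1)) else 0,
                if (length(ctx$j2)) drop(crossprod(ctx$Um2, a2)) else 0)
    wt <- qr_ - mt_apply_T(core$bl, at)
  } else {
    wt <- qr_
  }
  # rotated w = U' V_obs^{-1} r ; apply d_i G blockwise and rotate back
  g1t <- ctx$d * (G[1, 1] * wt[, 1] + G[1, 2] * wt[, 2])
  g2t <- ctx$d * (G[1, 2] * wt[, 1] + G[2, 2] * wt[, 2])
  gebv <- cbind(ctx$U %*% g1t, ctx$U %*% g2t)
  list(mu = mu, gebv = gebv)
}

#' Fit a bivariate GBLUP model (multi-trait REML)
#'
#' Fits the two-trait mixed model `Y_i = mu + g_i + e_i` with
#' `g ~ N(0, G (x) A)` and `e ~ N(0, I (x) R)`, `G` and `R` unstructured
#' 2x2 covariance matrices, by direct REML maximisation over
#' (log variances, Fisher-z correlations). Records may be missing by trait:
#' trait-specific incidence ties each record to its genotype, and breeding
#' values are returned for every genotype in `A` and both traits, including
#' genotypes with no records on one or both traits. This is the
#' missing-record information flow that trait-assisted prediction exploits.
#'
#' @param Y numeric matrix with one row per genotype in `A` and two columns
#'   (traits); `NA` marks a missing record. Rownames must match `A`'s ids
#'   (or be absent, in which case `A`'s order is assumed).
#' @param A relationship matrix ([vanraden_grm()] result or plain symmetric
#'   matrix).
#' @param ridge diagonal conditioning added to `A` at solve time.
#' @param start optional warm start: a list with 2x2 matrices `G` and `R`.
#' @param maxit Nelder-Mead iteration cap.
#' @param polish if `TRUE`, follow Nelder-Mead with two rounds of
#'   coordinate-wise golden-section refinement.
#' @return An object of class `gblup_mt`: `mu` (per-trait intercepts), `G`,
#'   `R`, `cor_g`, `cor_r`, `gebv` (n x 2, all genotypes), `reml_loglik`,
#'   `converged`, plus internal state used by [correlation_se()].
#' @export
gblup_mt <- function(Y, A, ridge = 1e-6, start = NULL, maxit = 2000,
                     polish = TRUE) {
  A <- as_grm_matrix(A)
  ids <- rownames(A)
  if (!is.matrix(Y) || ncol(Y) != 2L) stopf("'Y' must be an n x 2 matrix")
  if (!is.null(rownames(Y))) {
    if (!all(rownames(Y) %in% ids)) {
      stopf("unknown genotype id in Y: %s", setdiff(rownames(Y), ids)[1L])
    }
    full <- matrix(NA_real_, length(ids), 2L, dimnames = list(ids, colnames(Y)))
    full[rownames(Y), ] <- Y
    Y <- full
  } else if (nrow(Y) != length(ids)) {
    stopf("unnamed 'Y' must have one row per genotype in A")
  } else rownames(Y) <- ids
  trait_names <- colnames(Y)
  if (is.null(trait_names)) trait_names <- c("trait1", "trait2")

  n1 <- sum(!is.na(Y[, 1])); n2 <- sum(!is.na(Y[, 2]))
  if (n1 + n2 == 0L) stopf("all records missing")
  both <- sum(!is.na(Y[, 1]) & !is.na(Y[, 2]))
  if (n1 > 0L && n2 > 0L && both == 0L) {
    stopf("cor_g unidentifiable: no genotype observed for both traits")
  }

  ctx <- mt_context(Y, A, ridge)

  # free parameters: mask everything tied to a trait without records
  free <- rep(TRUE, 6L)
  if (n1 == 0L) free[c(1L, 3L, 4L, 6L)] <- FALSE
  if (n2 == 0L) free[c(2L, 3L, 5L, 6L)] <- FALSE

  v1 <- if (n1 > 1L) stats::var(Y[, 1], na.rm = TRUE) else 1
  v2 <- if (n2 > 1L) stats::var(Y[, 2], na.rm = TRUE) else 1
  cc <- if (both >= 3L) stats::cor(Y[!is.na(Y[, 1]) & !is.na(Y[, 2]), ]) [1, 2] else 0
  cc <- max(min(cc, 0.9), -0.9)
  theta0 <- c(log(v1 / 2), log(v2 / 2), atanh(cc / 2),
              log(v1 / 2), log(v2 / 2), atanh(cc / 2))
  if (!is.null(start)) {
    sg <- start$G; sr <- start$R
    theta0 <- c(log(max(sg[1, 1], 1e-8)), log(max(sg[2, 2], 1e-8)),
                atanh(max(min(sg[1, 2] / sqrt(sg[1, 1] * sg[2, 2]), 0.99), -0.99)),
                log(max(sr[1, 1], 1e-8)), log(max(sr[2, 2], 1e-8)),
                atanh(max(min(sr[1, 2] / sqrt(sr[1, 1] * sr[2, 2]), 0.99), -0.99)))
  }

  obj <- function(th_free) {
    th <- theta0
    th[free] <- th_free
    mt_loglik(th, ctx)
  }
  ll0 <- obj(theta0[free])
  opt <- stats::optim(theta0[free], obj, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = maxit,
                                     reltol = 1e-10))
  n_eval <- opt$counts[["function"]]
  # restart from the incumbent until stable: a fresh simplex escapes
  # premature collapse of Nelder-Mead in the flat cor_g direction
  for (restart in 1:4) {
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(fnscale = -1, maxit = maxit,
                                        reltol = 1e-10))
    n_eval <- n_eval + opt2$counts[["function"]]
    improved <- opt2$value - opt$value
    if (opt2$value > opt$value) opt <- opt2
    if (improved < 1e-4) break
  }
  theta <- theta0
  theta[free] <- opt$par
  ll <- opt$value
  if (polish) {
    for (round in 1:2) {
      for (j in which(free)) {
        f1 <- function(v) { th <- theta; th[j] <- v; mt_loglik(th, ctx) }
        o <- stats::optimize(f1, interval = c(theta[j] - 0.5, theta[j] + 0.5),
                             maximum = TRUE, tol = 1e-9)
        if (o$objective > ll) { theta[j] <- o$maximum; ll <- o$objective }
      }
    }
  }
  converged <- opt$convergence == 0L
  if (!converged) {
    warnf("bivariate REML reached the iteration cap (%d evaluations, loglik %.6f -> %.6f)",
          n_eval, ll0, ll)
  }

  p <- theta_to_GR(theta)
  G <- p$G; R <- p$R
  dimnames(G) <- dimnames(R) <- list(trait_names, trait_names)
  bl <- mt_blup_at(G, R, ctx)
  gebv <- bl$gebv
  dimnames(gebv) <- list(ids, trait_names)
  mu <- bl$mu
  names(mu) <- trait_names

  structure(list(mu = mu, G = G, R = R,
                 cor_g = G[1, 2] / sqrt(G[1, 1] * G[2, 2]),
                 cor_r = R[1, 2] / sqrt(R[1, 1] * R[2, 2]),
                 gebv = gebv, reml_loglik = ll,
                 loglik_start = ll0, converged = converged,
                 n_eval = n_eval, theta = theta, free = free,
                 ridge = ridge, Y = Y, A_ids = ids,
                 .ctx = ctx),
            class = "gblup_mt")
}

#' @export
print.gblup_mt <- function(x, ...) {
  cat("Bivariate GBLUP fit\n")
  cat(sprintf("  records: %d / %d (trait 1 / trait 2) on %d genotypes\n",
              sum(!is.na(x$Y[, 1])), sum(!is.na(x$Y[, 2])), nrow(x$Y)))
  cat("  genetic covariance G:\n"); print(round(x$G, 4))
  cat("  residual covariance R:\n"); print(round(x$R, 4))
  cat(sprintf("  cor_g = %.3f, cor_r = %.3f\n", x$cor_g, x$cor_r))
  cat(sprintf("  REML log-likelihood %.4f (%s)\n", x$reml_loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.gblup_mt <- function(object, se = TRUE, ...) {
  ses <- if (se) tryCatch(correlation_se(object), error = function(e) NULL) else NULL
  out <- list(fit = object, se = ses,
              h2 = diag(object$G) / (diag(object$G) + diag(object$R)))
  class(out) <- "summary.gblup_mt"
  out
}

#' @export
print.summary.gblup_mt <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  per-trait h2_g: %.3f, %.3f\n", x$h2[1], x$h2[2]))
  if (!is.null(x$se)) {
    cat(sprintf("  SE(cor_g) = %.3f, SE(cor_r) = %.3f\n",
                x$se["cor_g"], x$se["cor_r"]))
  }
  invisible(x)
}

#' @export
coef.gblup_mt <- function(object, ...) object$gebv

#' @export
fitted.gblup_mt <- function(object, ...) {
  sweep(object$gebv, 2L, object$mu, "+")
}

#' @export
residuals.gblup_mt <- function(object, ...) {
  object$Y - fitted(object)
}

#' Multi-trait BLUP at fixed covariance components
#'
#' Solves the two-trait mixed model with trait-specific incidence at given
#' `G` and `R`, returning breeding values for every genotype in `A` on both
#' traits. When focal-trait records are missing for a genotype but
#' secondary-trait records are present, the focal GEBV incorporates the
#' genotype's own secondary phenotype (information flows through the
#' off-diagonals of `G` and `R`) -- the trait-assisted solve.
#'
#' @param Y n x 2 phenotype matrix with `NA` for missing records (rownames =
#'   genotype ids, or `A`'s order assumed).
#' @param A relationship matrix.
#' @param G,R 2x2 genetic and residual covariance matrices (PSD; `R` must be
#'   invertible on every observed-trait subset).
#' @param ridge diagonal conditioning added to `A` at solve time.
#' @return List with `gebv` (n x 2 matrix) and `mu` (GLS intercepts).
#' @export
blup_given_components <- function(Y, A, G, R, ridge = 1e-6) {
  A <- as_grm_matrix(A)
  ids <- rownames(A)
  if (!is.null(rownames(Y))) {
    full <- matrix(NA_real_, length(ids), 2L, dimnames = list(ids, colnames(Y)))
    full[rownames(Y), ] <- Y
    Y <- full
  } else rownames(Y) <- ids
  for (m in list(G = G, R = R)) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stopf("components must be positive semi-definite")
  }
  if (any(diag(R) <= 0)) stopf("R is singular on an observed-trait subset")
  ctx <- mt_context(Y, A, ridge)
  bl <- mt_blup_at(G, R, ctx)
  dimnames(bl$gebv) <- list(ids, colnames(Y))
  bl
}

#' Delta-method standard errors for the genetic and residual correlations
#'
#' Approximates the sampling standard errors of `cor_g` and `cor_r` by the
#' delta method applied to a numerically differentiated observed-information
#' matrix of the REML parameters (central differences on the log-variance /
#' Fisher-z scale). The result is an approximation: it relies on the
#' asymptotic normality of the REML estimator and a finite-difference
#' Hessian.
#'
#' @param fit a converged [gblup_mt()] fit.
#' @param h finite-difference step on the transformed parameter scale.
#' @return Named vector with elements `cor_g` and `cor_r`; `NA` with a
#'   warning when the information matrix is singular.
#' @export
correlation_se <- function(fit, h = 1e-4) {
  stopifnot(inherits(fit, "gblup_mt"))
  if (!fit$converged) stopf("fit did not converge; standard errors undefined")
  free <- which(fit$free)
  k <- length(free)
  f <- function(th_free) {
    th <- fit$theta
    th[free] <- th_free
    mt_loglik(th, fit$.ctx)
  }
  th0 <- fit$theta[free]
  f0 <- f(th0)
  H <- matrix(NA_real_, k, k)
  step <- h * (1 + abs(th0))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k)
      ei[i] <- step[i]; ej[j] <- step[j]
      if (i == j) {
        H[i, i] <- (f(th0 + ei) - 2 * f0 + f(th0 - ei)) / step[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(th0 + ei + ej) - f(th0 + ei - ej) -
             f(th0 - ei + ej) + f(th0 - ei - ej)) / (4 * step[i] * step[j])
      }
    }
  }
  info <- -H
  out <- c(cor_g = NA_real_, cor_r = NA_real_)
  # eigen pseudo-inverse: a saturated Fisher-z correlation (|cor| -> 1)
  # leaves an exact null direction whose delta-method contribution vanishes
  # through the (1 - cor^2) factor
  eg <- eigen(info, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!any(pos) || any(!is.finite(eg$values))) {
    warnf("singular information matrix; correlation standard errors undefined")
    return(out)
  }
  cv <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  if (any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    warnf("singular information matrix; correlation standard errors undefined")
    return(out)
  }
  # theta indices 3 and 6 are the Fisher-z correlations;
  # d cor / d z = 1 - cor^2
  pos <- match(c(3L, 6L), free)
  if (!is.na(pos[1])) {
    out["cor_g"] <- sqrt(cv[pos[1], pos[1]]) * (1 - fit$cor_g^2)
  }
  if (!is.na(pos[2])) {
    out["cor_r"] <- sqrt(cv[pos[2], pos[2]]) * (1 - fit$cor_r^2)
  }
  out
}
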