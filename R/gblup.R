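# Univariate GBLUP: REML variance components by eigendecomposition of the
# relationship matrix, breeding values for all genotypes, genomic
# heritability.

#' Fit a univariate GBLUP model
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma2_g * A)` and iid residuals,
#' where `A` is a realized additive relationship matrix. REML estimation
#' profiles out the total variance and maximises the residual log-likelihood
#' over the variance ratio `sigma2_g / (sigma2_g + sigma2_e)` on
#' (1e-6, 1 - 1e-6), using a single eigendecomposition of the
#' observed-genotype submatrix of `A`. Breeding values (GEBVs) are returned
#' for every genotype in `A`: genotypes without records are predicted
#' through their genomic relationship to the observed ones.
#'
#' Genomic heritability is reported on the component scale,
#' `h2_g = sigma2_g / (sigma2_g + sigma2_e)`, the ratio of additive to
#' phenotypic variance relative to the relationship matrix as supplied.
#' Note that for a VanRaden matrix on inbred lines the mean diagonal is
#' about 2, so the realized additive share of phenotypic variance is larger
#' than `h2_g` (about `2 h2_g / (1 + h2_g)`); the simulator uses the same
#' component-scale convention, so estimates are directly comparable to its
#' configured heritabilities.
#'
#' @param y named numeric vector of phenotypes (typically stage-1 adjusted
#'   means); names must match `A`'s ids. `NA` entries are treated as missing
#'   records.
#' @param A relationship matrix: a [vanraden_grm()] result or a plain
#'   symmetric matrix with genotype ids as dimnames.
#' @param ridge small value added to the diagonal of the observed submatrix
#'   at solve time to guarantee invertibility (never stored in `A`).
#' @param fix optional list with elements `sigma2_g` and `sigma2_e`: skip
#'   REML and compute BLUPs at these fixed components.
#' @return An object of class `gblup`: list with `mu`, `sigma2_g`,
#'   `sigma2_e`, `h2_g`, `gebv` (named, all genotypes in `A`), `observed`
#'   (ids with records), `reml_loglik`, and bookkeeping needed by
#'   [predict.gblup()].
#' @examples
#' st <- sim_phenotypes(sim_genotypes(sim_config(100, 500, seed = 2,
#'                                               heritabilities = 0.5)),
#'                      sim_config(100, 500, seed = 2, heritabilities = 0.5))
#' A <- vanraden_grm(st$genotypes)
#' fit <- gblup(st$phenotypes[, 1], A)
#' fit$h2_g
#' @export
gblup <- function(y, A, ridge = 1e-6, fix = NULL) {
  A <- as_grm_matrix(A)
  ids <- rownames(A)
  if (is.null(names(y))) {
    if (length(y) != nrow(A)) stopf("unnamed 'y' must have one value per genotype in A")
    names(y) <- ids
  }
  if (!all(names(y) %in% ids)) {
    stopf("unknown genotype id in y: %s", setdiff(names(y), ids)[1L])
  }
  yv <- rep(NA_real_, nrow(A)); names(yv) <- ids
  yv[names(y)] <- y
  obs <- which(!is.na(yv))
  n_obs <- length(obs)
  if (n_obs == 0L) stopf("all records missing")
  yo <- yv[obs]
  Aoo <- A[obs, obs, drop = FALSE] + diag(ridge, n_obs)
  eg <- eigen(Aoo, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, yo))
  xt <- drop(crossprod(U, rep(1, n_obs)))

  # profiled REML criterion in h2 (total variance profiled out)
  prof <- function(h2) {
    w <- h2 * d + (1 - h2)
    sxx <- sum(xt^2 / w)
    mu <- sum(xt * yt / w) / sxx
    rss <- sum((yt - mu * xt)^2 / w)
    sp2 <- max(rss / (n_obs - 1), 1e-300)
    ll <- -0.5 * ((n_obs - 1) * (log(2 * pi * sp2) + 1) + sum(log(w)) + log(sxx))
    list(ll = ll, mu = mu, sp2 = sp2, w = w)
  }

  abar <- mean(diag(Aoo))
  if (!is.null(fix)) {
    sg2 <- fix$sigma2_g; se2 <- fix$sigma2_e
    h2 <- sg2 / (sg2 + se2)
    st <- prof(h2)
    # recompute mu by GLS at the fixed components (same as prof's mu)
    mu <- st$mu
    ll <- reml_loglik_fixed(yt, xt, d, sg2, se2, n_obs)
  } else {
    opt <- stats::optimize(function(h2) prof(h2)$ll,
                           interval = c(1e-6, 1 - 1e-6),
                           maximum = TRUE, tol = 1e-9)
    h2 <- opt$maximum
    st <- prof(h2)
    mu <- st$mu
    sg2 <- h2 * st$sp2
    se2 <- (1 - h2) * st$sp2
    ll <- opt$objective
  }

  # BLUP for all genotypes: g_hat = sigma2_g * A[, obs] V^{-1} (y - mu)
  # computed in the eigenbasis of (A_oo + ridge I); off-diagonal blocks of A
  # are used as stored.
  w <- h2 * d + (1 - h2)           # V = sp2 * U diag(w) U'
  r <- yo - mu
  vinv_r <- drop(U %*% (crossprod(U, r) / w))      # (Aoo*h2+(1-h2)I)^{-1} r / 1
  gebv_obs <- h2 * drop(Aoo %*% vinv_r)
  gebv <- h2 * drop(A[, obs, drop = FALSE] %*% vinv_r)
  gebv[obs] <- gebv_obs            # keep ridge-consistent values on the diagonal block
  names(gebv) <- ids

  structure(list(mu = mu, sigma2_g = sg2, sigma2_e = se2,
                 h2_g = sg2 / (sg2 + se2),
                 grm_diag_mean = abar,
                 gebv = gebv, observed = ids[obs],
                 reml_loglik = ll, ridge = ridge,
                 y = yv, A_ids = ids,
                 .eig = list(U = U, d = d, w = w, vinv_r = vinv_r, h2 = h2)),
            class = "gblup")
}

# REML log-likelihood at fixed (sigma2_g, sigma2_e) in the eigenbasis.
reml_loglik_fixed <- function(yt, xt, d, sg2, se2, n_obs) {
  v <- sg2 * d + se2
  sxx <- sum(xt^2 / v)
  mu <- sum(xt * yt / v) / sxx
  rss <- sum((yt - mu * xt)^2 / v)
  -0.5 * ((n_obs - 1) * log(2 * pi) + sum(log(v)) + log(sxx) + rss)
}

#' @export
print.gblup <- function(x, ...) {
  cat("Univariate GBLUP fit\n")
  cat(sprintf("  records: %d observed of %d genotypes\n",
              length(x$observed), length(x$gebv)))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2_g = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2_g))
  cat(sprintf("  REML log-likelihood: %.4f\n", x$reml_loglik))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(n_obs = length(object$observed),
              n_total = length(object$gebv),
              mu = object$mu,
              sigma2_g = object$sigma2_g, sigma2_e = object$sigma2_e,
              h2_g = object$h2_g, reml_loglik = object$reml_loglik,
              gebv_sd = stats::sd(object$gebv))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("Univariate GBLUP\n")
  cat(sprintf("  n = %d observed / %d total genotypes\n", x$n_obs, x$n_total))
  cat(sprintf("  mu = %.4f\n  sigma2_g = %.4f  sigma2_e = %.4f  h2_g = %.3f\n",
              x$mu, x$sigma2_g, x$sigma2_e, x$h2_g))
  cat(sprintf("  sd(GEBV) = %.4f   REML loglik = %.4f\n", x$gebv_sd, x$reml_loglik))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$gebv

#' @export
fitted.gblup <- function(object, ...) {
  object$mu + object$gebv[object$observed]
}

#' @export
residuals.gblup <- function(object, ...) {
  object$y[object$observed] - fitted(object)
}

#' Predict breeding values for held-out genotypes
#'
#' Conditional-expectation prediction
#' `A_qo (A_oo + ridge I)^{-1} g_hat_o` for query genotypes from the fitted
#' GEBVs of the observed ones; identical (to numerical precision) to the
#' joint BLUP obtained by refitting with the query records missing.
#'
#' @param object a [gblup()] fit.
#' @param ids character vector of query genotype ids (must be in the fit's
#'   relationship matrix); default: all genotypes without records.
#' @param A the relationship matrix used at fit time (needed for the
#'   cross-relationships; pass the same object).
#' @param ... unused.
#' @return Named numeric vector of predicted breeding values.
#' @export
predict.gblup <- function(object, A, ids = NULL, ...) {
  A <- as_grm_matrix(A)
  if (!identical(rownames(A), object$A_ids)) {
    stopf("relationship matrix does not match the fitted model")
  }
  if (is.null(ids)) ids <- setdiff(object$A_ids, object$observed)
  unknown <- setdiff(ids, object$A_ids)
  if (length(unknown)) stopf("unknown genotype id: %s", unknown[1L])
  obs <- match(object$observed, object$A_ids)
  Aoo <- A[obs, obs, drop = FALSE] + diag(object$ridge, length(obs))
  gq <- drop(A[ids, obs, drop = FALSE] %*% solve(Aoo, object$gebv[obs]))
  names(gq) <- ids
  gq
}

#' @export
plot.gblup <- function(x, ...) {
  yo <- x$y[x$observed]
  g <- x$gebv[x$observed]
  plot(yo, g, xlab = "phenotype", ylab = "GEBV",
       main = sprintf("GBLUP (h2_g = %.2f)", x$h2_g), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$observed)
  with_seed(seed, {
    obs <- match(object$observed, object$A_ids)
    # new phenotypes at the estimated components, marginal covariance
    # sigma2_g A_oo + sigma2_e I
    Aoo <- object$.eig$U %*% (object$.eig$d * t(object$.eig$U))
    L <- chol_psd(object$sigma2_g * Aoo + object$sigma2_e * diag(n))
    out <- replicate(nsim, object$mu + drop(crossprod(L, stats::rnorm(n))))
    rownames(out) <- object$observed
    as.data.frame(out)
  })
}
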