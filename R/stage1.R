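# Stage-1 spatial analysis of a single field trial: fixed genotype effects,
# iid random block effects, and residuals with separable AR(1) x AR(1)
# correlation over rows and columns. REML on error contrasts, AIC model
# choice, genotype adjusted means (BLUEs), and multi-year combination.

#' AR(1) correlation matrix
#'
#' Returns the `size` x `size` matrix with entry `(i, j) = rho^|i - j|`:
#' first-order autoregressive correlation along a line of equally spaced
#' positions.
#'
#' @param rho correlation parameter, |rho| < 1.
#' @param size dimension, >= 1.
#' @return A positive-definite correlation matrix.
#' @examples
#' ar1_cor(0.5, 3)
#' @export
ar1_cor <- function(rho, size) {
  if (!is_number(rho) || abs(rho) >= 1) stopf("|rho| must be < 1")
  if (!is_count(size)) stopf("'size' must be a positive count")
  idx <- seq_len(size)
  rho^abs(outer(idx, idx, "-"))
}

#' Declare a stage-1 model
#'
#' @param residual residual correlation structure: `"iid"` or `"ar1xar1"`
#'   (separable AR(1) over field rows and columns).
#' @param include_block include iid random block effects.
#' @return An object of class `stage1_model`.
#' @export
stage1_model <- function(residual = c("ar1xar1", "iid"), include_block = TRUE) {
  residual <- match.arg(residual)
  structure(list(residual = residual, include_block = isTRUE(include_block)),
            class = "stage1_model")
}

#' @export
print.stage1_model <- function(x, ...) {
  cat(sprintf("Stage-1 model: intercept + genotype (fixed)%s, residual %s\n",
              if (x$include_block) " + block (random)" else "", x$residual))
  invisible(x)
}

# number of variance parameters of a stage-1 model
stage1_n_params <- function(model) {
  1L + (model$residual == "ar1xar1") * 2L + model$include_block
}

# Precompute everything the REML objective needs for one trial.
stage1_context <- function(plots, model) {
  req <- c("genotype", "row", "col", "value")
  if (!all(req %in% names(plots))) {
    stopf("plot table must have columns %s", paste(req, collapse = ", "))
  }
  if ("year" %in% names(plots) && length(unique(plots$year)) > 1L) {
    stopf("fit_stage1 expects a single trial; got %d years",
          length(unique(plots$year)))
  }
  if ("trait" %in% names(plots) && length(unique(plots$trait)) > 1L) {
    stopf("fit_stage1 expects a single trait; got %d", length(unique(plots$trait)))
  }
  if (anyDuplicated(plots[, c("row", "col")])) {
    stopf("(row, col) positions must be unique within a trial")
  }
  if (any(!nzchar(plots$genotype))) stopf("empty genotype id in plot table")
  y <- plots$value
  geno <- factor(plots$genotype)
  X <- stats::model.matrix(~ geno)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stopf("singular fixed-effects design; aliased genotype effects: %s",
          paste(sub("^geno", "", aliased), collapse = ", "))
  }
  m <- nrow(X); p <- ncol(X)
  if (m - p < 1L) {
    stopf("no residual degrees of freedom: %d plots for %d fixed effects", m, p)
  }
  # two equivalent REML evaluations: on error contrasts, O(m^2 (m - p)) per
  # evaluation, cheap when the genotype design leaves few residual df; or
  # the direct Cholesky form with the constant log|X'X| subtracted so both
  # routes return identical values.
  route <- if (m - p <= m / 3) "contrast" else "chol"
  ctx <- list(y = y, X = X, geno = geno, m = m, p = p, route = route,
              Dr = abs(outer(plots$row, plots$row, "-")),
              Dc = abs(outer(plots$col, plots$col, "-")),
              model = model)
  if (route == "contrast") {
    K <- qr.Q(qrx, complete = TRUE)[, (p + 1L):m, drop = FALSE]
    ctx$K <- K
    ctx$Ky <- drop(crossprod(K, y))
  } else {
    ctx$logdet_XtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  }
  if (model$include_block) {
    if (!"block" %in% names(plots)) stopf("model includes block but table has no block column")
    Zb <- stats::model.matrix(~ 0 + factor(plots$block))
    ctx$Zb <- Zb
    if (route == "contrast") ctx$KZ <- crossprod(ctx$K, Zb)
  }
  ctx
}

# Correlation matrix of the residual field restricted to observed plots.
stage1_sigma <- function(ctx, rho_row, rho_col) {
  if (ctx$model$residual == "iid") return(diag(ctx$m))
  (rho_row^ctx$Dr) * (rho_col^ctx$Dc)
}

# Profiled REML log-likelihood at (gamma = sigma2_b / sigma2_e, rho_row,
# rho_col); sigma2_e is profiled out. Both routes agree exactly.
stage1_loglik <- function(ctx, gamma = 0, rho_row = 0, rho_col = 0) {
  mp <- ctx$m - ctx$p
  if (ctx$route == "contrast") {
    if (ctx$model$residual == "iid") {
      KSK <- diag(mp)
    } else {
      S <- stage1_sigma(ctx, rho_row, rho_col)
      KSK <- crossprod(ctx$K, S %*% ctx$K)
    }
    if (ctx$model$include_block && gamma > 0) {
      KSK <- KSK + gamma * tcrossprod(ctx$KZ)
    }
    L <- tryCatch(chol(KSK), error = function(e) NULL)
    if (is.null(L)) return(list(ll = -Inf))
    z <- backsolve(L, ctx$Ky, transpose = TRUE)
    s2 <- max(sum(z^2) / mp, 1e-300)
    ll <- -0.5 * (mp * (log(2 * pi * s2) + 1) + 2 * sum(log(diag(L))))
    return(list(ll = ll, sigma2_e = s2))
  }
  V0 <- stage1_sigma(ctx, rho_row, rho_col)
  if (ctx$model$include_block && gamma > 0) {
    V0 <- V0 + gamma * tcrossprod(ctx$Zb)
  }
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(list(ll = -Inf))
  Xs <- backsolve(L, ctx$X, transpose = TRUE)
  ys <- backsolve(L, ctx$y, transpose = TRUE)
  XtVX <- crossprod(Xs)
  Lx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(Lx)) return(list(ll = -Inf))
  b <- crossprod(Xs, ys)
  zb <- backsolve(Lx, b, transpose = TRUE)
  s2 <- max((sum(ys^2) - sum(zb^2)) / mp, 1e-300)
  ll <- -0.5 * (mp * (log(2 * pi * s2) + 1) +
                  2 * sum(log(diag(L))) + 2 * sum(log(diag(Lx))) -
                  ctx$logdet_XtX)
  list(ll = ll, sigma2_e = s2)
}

#' Fit the stage-1 spatial model to one trial
#'
#' Maximises the REML log-likelihood of
#' `y = mu + genotype (fixed) + block (random) + e`, with residual
#' covariance `sigma2_e * AR1(rho_row) (x) AR1(rho_col)` restricted to the
#' observed plots (or iid), over the variance parameters. The likelihood is
#' evaluated on error contrasts with the residual ratio profiled out;
#' optimisation is over `(log gamma, atanh rho)` with multi-start from
#' `rho in {0, +-0.5}` for each direction. Genotype adjusted means (BLUEs)
#' are computed by generalized least squares at the converged components.
#'
#' @param plots plot table: data.frame with columns
#'   `genotype, row, col, value`, plus `block` when the model includes
#'   blocks (and optionally single-valued `year` and `trait` columns).
#' @param model a [stage1_model()].
#' @param rho_starts starting values for each AR(1) parameter.
#' @return An object of class `stage1_fit`: variance components
#'   (`sigma2_b`, `sigma2_e`, `rho_row`, `rho_col`), `genotype_blues`
#'   (data.frame `genotype`, `blue`, `se`), `reml_loglik`, `aic`,
#'   `n_params`.
#' @export
fit_stage1 <- function(plots, model = stage1_model(),
                       rho_starts = c(0, 0.5, -0.5)) {
  ctx <- stage1_context(plots, model)
  ar1 <- model$residual == "ar1xar1"
  blk <- model$include_block

  # parameter packing: (log gamma)?, (z_row, z_col)?
  unpack <- function(par) {
    i <- 1L
    gamma <- 0
    if (blk) { gamma <- exp(par[i]); i <- i + 1L }
    rr <- rc <- 0
    if (ar1) { rr <- tanh(par[i]); rc <- tanh(par[i + 1L]) }
    list(gamma = gamma, rho_row = rr, rho_col = rc)
  }
  obj <- function(par) {
    q <- unpack(par)
    stage1_loglik(ctx, q$gamma, q$rho_row, q$rho_col)$ll
  }

  if (!blk && !ar1) {
    best <- list(par = numeric(0), value = stage1_loglik(ctx)$ll)
  } else if (blk && !ar1) {
    o <- stats::optimize(function(lg) obj(lg), interval = c(-25, 10),
                         maximum = TRUE, tol = 1e-9)
    best <- list(par = o$maximum, value = o$objective)
  } else {
    # screen the rho multi-start grid by direct likelihood evaluation,
    # then optimize from the best start
    starts <- expand.grid(rr = rho_starts, rc = rho_starts)
    vals <- vapply(seq_len(nrow(starts)), function(s) {
      obj(c(if (blk) log(0.5), atanh(starts$rr[s]), atanh(starts$rc[s])))
    }, 0)
    s0 <- which.max(vals)
    par0 <- c(if (blk) log(0.5), atanh(starts$rr[s0]), atanh(starts$rc[s0]))
    best <- stats::optim(par0, obj, method = "Nelder-Mead",
                         control = list(fnscale = -1, maxit = 800,
                                        reltol = 1e-10))
    if (best$convergence != 0L) {
      stopf("stage-1 REML did not converge (loglik trace: starts %s, final %.6f)",
            paste(sprintf("%.4f", vals), collapse = ", "), best$value)
    }
  }

  q <- unpack(best$par)
  lk <- stage1_loglik(ctx, q$gamma, q$rho_row, q$rho_col)
  sigma2_e <- lk$sigma2_e
  sigma2_b <- if (blk) q$gamma * sigma2_e else 0

  # GLS fixed effects and genotype BLUEs at the converged components
  V0 <- stage1_sigma(ctx, q$rho_row, q$rho_col)
  if (blk) V0 <- V0 + q$gamma * tcrossprod(ctx$Zb)
  L <- chol(V0)
  Xs <- backsolve(L, ctx$X, transpose = TRUE)
  ys <- backsolve(L, ctx$y, transpose = TRUE)
  XtVX <- crossprod(Xs)
  beta <- solve(XtVX, crossprod(Xs, ys))
  covb <- sigma2_e * solve(XtVX)
  lev <- levels(ctx$geno)
  # BLUE of genotype i = intercept + its treatment effect
  Cmat <- cbind(1, rbind(0, diag(length(lev) - 1L)))
  blue <- drop(Cmat %*% beta)
  se <- sqrt(pmax(rowSums((Cmat %*% covb) * Cmat), 0))
  fit <- structure(list(
    sigma2_b = sigma2_b, sigma2_e = sigma2_e,
    rho_row = q$rho_row, rho_col = q$rho_col,
    genotype_blues = data.frame(genotype = lev, blue = blue, se = se,
                                stringsAsFactors = FALSE),
    reml_loglik = lk$ll,
    n_params = stage1_n_params(model),
    model = model,
    n_plots = ctx$m), class = "stage1_fit")
  fit$aic <- -2 * fit$reml_loglik + 2 * fit$n_params
  fit
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("Stage-1 spatial fit ("); print_model <- x$model
  cat(sprintf("%s%s)\n", print_model$residual,
              if (print_model$include_block) " + block" else ""))
  cat(sprintf("  plots: %d, genotypes: %d\n", x$n_plots, nrow(x$genotype_blues)))
  cat(sprintf("  sigma2_b = %.4g, sigma2_e = %.4g, rho_row = %.3f, rho_col = %.3f\n",
              x$sigma2_b, x$sigma2_e, x$rho_row, x$rho_col))
  cat(sprintf("  REML loglik = %.4f, AIC = %.4f (%d variance params)\n",
              x$reml_loglik, x$aic, x$n_params))
  invisible(x)
}

#' @export
coef.stage1_fit <- function(object, ...) {
  stats::setNames(object$genotype_blues$blue, object$genotype_blues$genotype)
}

#' Select the stage-1 model by AIC
#'
#' Fits every candidate model (all sharing the same fixed effects, so the
#' REML criteria are comparable) and returns the fit with minimal
#' `AIC = -2 loglik + 2 * n_variance_params`; ties are broken toward fewer
#' parameters, then candidate order.
#'
#' @param plots plot table (see [fit_stage1()]).
#' @param candidates list of [stage1_model()] objects.
#' @return The winning `stage1_fit`, with the per-candidate AIC table
#'   attached as attribute `"aic_table"`.
#' @export
select_stage1 <- function(plots, candidates = list(stage1_model("iid"),
                                                   stage1_model("ar1xar1"))) {
  if (length(candidates) < 1L) stopf("need at least one candidate model")
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(fit_stage1(plots, candidates[[i]]),
                          error = function(e) {
                            warnf("candidate %d failed: %s", i, conditionMessage(e))
                            NULL
                          })
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stopf("all stage-1 candidates failed")
  aic <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, 0)
  npar <- vapply(fits, function(f) if (is.null(f)) Inf else f$n_params, 0)
  ord <- order(round(aic, 8), npar, seq_along(fits))
  win <- fits[[ord[1L]]]
  attr(win, "aic_table") <- data.frame(
    candidate = seq_along(candidates),
    residual = vapply(candidates, function(m) m$residual, ""),
    block = vapply(candidates, function(m) m$include_block, TRUE),
    aic = aic, converged = ok)
  win
}

#' Combine per-year adjusted means into multi-year values
#'
#' Transforms each year's genotype BLUEs per the scaling mode, then averages
#' each genotype over the years in which it appears: the multi-year adjusted
#' mean used as the phenotypic input of all second-stage GS models.
#'
#' @param per_year named list of [fit_stage1()] results (or data.frames with
#'   columns `genotype` and `blue`), one per year.
#' @param scaling `"standardize"` (centre and divide by that year's standard
#'   deviation of BLUEs; default), `"center"`, or `"none"`.
#' @return data.frame with columns `genotype`, `xbar`, `n_years`.
#' @export
combine_years <- function(per_year, scaling = c("standardize", "center", "none")) {
  scaling <- match.arg(scaling)
  if (length(per_year) < 1L) stopf("need at least one year of adjusted means")
  tabs <- lapply(per_year, function(f) {
    if (inherits(f, "stage1_fit")) f <- f$genotype_blues
    if (!all(c("genotype", "blue") %in% names(f))) {
      stopf("each year must provide columns 'genotype' and 'blue'")
    }
    v <- f$blue
    if (scaling != "none") {
      if (scaling == "standardize") {
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) stopf("zero within-year variance; cannot standardize")
        v <- (v - mean(v)) / s
      } else v <- v - mean(v)
    }
    data.frame(genotype = f$genotype, value = v, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tabs)
  agg <- stats::aggregate(value ~ genotype, data = all, FUN = mean)
  cnt <- stats::aggregate(value ~ genotype, data = all, FUN = length)
  out <- data.frame(genotype = agg$genotype, xbar = agg$value,
                    n_years = cnt$value, stringsAsFactors = FALSE)
  out[order(out$genotype), , drop = FALSE]
}
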