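# The five genomic-selection strategies under a shared k-fold
# cross-validation scheme, plus derived statistics: growth-curve AUC trait,
# correlation-weighted indirect index, coincidence index, expected selection
# accuracies, and the training-fraction sweep.

#' Build a reusable cross-validation scheme
#'
#' Balanced random k-fold partitions (fold sizes differ by at most one),
#' repeated `n_repeats` times, deterministic given the seed. The same scheme
#' object is passed to every strategy within a run so that all strategies
#' see byte-identical folds.
#'
#' @param n number of genotypes.
#' @param k number of folds (default 5).
#' @param n_repeats number of CV repeats (default 30).
#' @param seed integer seed.
#' @return An object of class `cv_scheme` with an `n x n_repeats` integer
#'   matrix of fold labels.
#' @examples
#' table(make_folds(453, 5, 1, seed = 1)$assignments)
#' @export
make_folds <- function(n, k = 5L, n_repeats = 30L, seed = 1L) {
  if (!is_count(n) || !is_count(k) || k < 2L) stopf("need n >= k >= 2")
  if (n < k) stopf("cannot partition %d genotypes into %d folds", n, k)
  sizes <- rep(floor(n / k), k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_seed(seed, {
    assignments <- vapply(seq_len(n_repeats),
                          function(r) sample(rep.int(seq_len(k), sizes)),
                          integer(n))
  })
  structure(list(n = as.integer(n), k = as.integer(k),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 assignments = assignments),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("CV scheme: %d genotypes, %d folds x %d repeats (seed %d)\n",
              x$n, x$k, x$n_repeats, x$seed))
  invisible(x)
}

#' Area under the growth progress curve
#'
#' Trapezoidal area over `m` equally spaced measurements (unit spacing, one
#' interval per measurement gap): `A = sum_{i=1..m} (h_{i-1} + h_i) / 2`
#' with `h_0 = baseline` (default 0, the height at planting). Treated
#' downstream as one more trait.
#'
#' @param heights numeric matrix (genotypes x ordered measurements) or a
#'   single vector of measurements.
#' @param baseline value of `h_0`.
#' @return Per-genotype AUC values; genotypes with a missing measurement get
#'   `NA` with a warning.
#' @examples
#' auc_trait(matrix(c(100, 200, 300, 400), nrow = 1))  # 800
#' @export
auc_trait <- function(heights, baseline = 0) {
  if (is.vector(heights)) heights <- matrix(heights, nrow = 1L)
  h <- cbind(baseline, heights)
  out <- rowSums((h[, -ncol(h), drop = FALSE] + h[, -1L, drop = FALSE]) / 2)
  if (anyNA(out)) warnf("missing height measurement: AUC set to NA for %d genotype(s)",
                        sum(is.na(out)))
  if (!is.null(rownames(heights))) names(out) <- rownames(heights)
  out
}

#' Correlation-weighted index over secondary-trait GEBVs
#'
#' Standardises each GEBV vector to mean 0 and variance 1, then returns the
#' sum weighted by each secondary trait's genetic correlation with the focal
#' trait -- the selection index used by multi-trait indirect GS.
#'
#' @param gebvs numeric matrix, one column per secondary trait.
#' @param cor_g_with_focal numeric vector of genetic correlations with the
#'   focal trait, one per column.
#' @return Per-genotype index values.
#' @export
indirect_index <- function(gebvs, cor_g_with_focal) {
  if (is.vector(gebvs)) gebvs <- matrix(gebvs, ncol = 1L)
  if (ncol(gebvs) != length(cor_g_with_focal)) {
    stopf("need one genetic correlation per GEBV column")
  }
  sds <- apply(gebvs, 2L, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stopf("zero-variance GEBV vector cannot be standardized")
  }
  z <- scale(gebvs)
  drop(z %*% cor_g_with_focal)
}

# Out-of-fold predictions for one strategy on one train/validation split.
# Returns list(pred = named numeric over val ids, warm = warm-start info).
strategy_predict <- function(pheno, A, strategy, focal, secondary,
                             train, val, warm = NULL, ridge = 1e-6,
                             components = NULL) {
  ids <- rownames(pheno)
  out_warm <- warm
  if (strategy == "standard") {
    y <- pheno[train, focal]
    names(y) <- ids[train]
    fit <- gblup(y, A, ridge = ridge)
    pred <- fit$gebv[ids[val]]
  } else if (strategy == "indirect") {
    y <- pheno[train, secondary[1L]]
    names(y) <- ids[train]
    fit <- gblup(y, A, ridge = ridge)
    pred <- fit$gebv[ids[val]]
  } else if (strategy == "multi_trait_indirect") {
    preds <- matrix(NA_real_, length(val), length(secondary))
    wts <- numeric(length(secondary))
    for (j in seq_along(secondary)) {
      y <- pheno[train, secondary[j]]
      names(y) <- ids[train]
      fit <- gblup(y, A, ridge = ridge)
      preds[, j] <- fit$gebv[ids[val]]
      wj <- if (!is.null(out_warm$mti) && length(out_warm$mti) >= j) {
        out_warm$mti[[j]]
      } else NULL
      bf <- gblup_mt(pheno[train, c(focal, secondary[j])], A,
                     ridge = ridge, polish = FALSE, start = wj)
      wts[j] <- bf$cor_g
      out_warm$mti[[j]] <- list(G = bf$G, R = bf$R)
    }
    pred <- stats::setNames(rep(NA_real_, length(val)), ids[val])
    attr(pred, "raw") <- preds
    attr(pred, "weights") <- wts
  } else if (strategy == "multi_trait") {
    Y <- pheno[, c(focal, secondary[1L])]
    Y[val, ] <- NA
    if (is.null(components)) {
      fit <- gblup_mt(Y, A, ridge = ridge, polish = FALSE, start = out_warm$mt)
      out_warm$mt <- list(G = fit$G, R = fit$R)
      pred <- fit$gebv[ids[val], 1L]
    } else {
      bl <- blup_given_components(Y, A, components$G, components$R, ridge = ridge)
      pred <- bl$gebv[ids[val], 1L]
    }
  } else if (strategy == "trait_assisted") {
    Y <- pheno[, c(focal, secondary[1L])]
    Y[val, 1L] <- NA             # focal records of the validation fold withheld;
                                 # secondary records kept for every genotype
    if (is.null(components)) {
      fit <- gblup_mt(Y, A, ridge = ridge, polish = FALSE, start = out_warm$ta)
      out_warm$ta <- list(G = fit$G, R = fit$R)
      pred <- fit$gebv[ids[val], 1L]
    } else {
      bl <- blup_given_components(Y, A, components$G, components$R, ridge = ridge)
      pred <- bl$gebv[ids[val], 1L]
    }
  } else stopf("unknown strategy '%s'", strategy)
  list(pred = pred, warm = out_warm)
}

check_strategy <- function(strategy, focal, secondary, traits) {
  strategies <- c("standard", "indirect", "multi_trait_indirect",
                  "multi_trait", "trait_assisted")
  if (!strategy %in% strategies) {
    stopf("unknown strategy '%s' (use one of %s)", strategy,
          paste(strategies, collapse = ", "))
  }
  need_sec <- switch(strategy, standard = 0L, multi_trait_indirect = 2L, 1L)
  if (strategy == "multi_trait_indirect") {
    if (length(secondary) < 2L) stopf("multi_trait_indirect needs >= 2 secondary traits")
  } else if (need_sec == 1L && length(secondary) < 1L) {
    stopf("strategy '%s' needs a secondary trait", strategy)
  }
  if (!focal %in% traits) stopf("focal trait '%s' not found in phenotypes", focal)
  miss <- setdiff(secondary, traits)
  if (length(miss)) stopf("secondary trait '%s' not found in phenotypes", miss[1L])
  invisible(TRUE)
}

#' Run one genomic-selection strategy under cross-validation
#'
#' Executes the strategy's training/validation protocol on every fold of
#' every repeat of the scheme, pools the k folds' out-of-fold predictions,
#' and computes ONE Pearson correlation with the focal adjusted means per
#' repeat (never an average of per-fold correlations). Strategies:
#' \describe{
#'   \item{standard}{univariate GBLUP on the focal trait's training records.}
#'   \item{indirect}{univariate GBLUP on a secondary trait; its validation
#'     GEBVs are correlated with the focal adjusted means.}
#'   \item{multi_trait_indirect}{univariate GBLUP per secondary trait; the
#'     pooled GEBV vectors are standardised and combined with weights equal
#'     to each trait's genetic correlation with the focal trait (estimated
#'     by bivariate REML on the training records).}
#'   \item{multi_trait}{bivariate GBLUP on the training records of the focal
#'     and the secondary trait; validation genotypes carry no records.}
#'   \item{trait_assisted}{bivariate GBLUP with focal training records plus
#'     ALL secondary records -- including the validation genotypes' own
#'     secondary phenotypes.}
#' }
#'
#' @param pheno numeric matrix of adjusted means, genotypes x traits
#'   (rownames = genotype ids matching `A`, colnames = trait names).
#' @param A relationship matrix.
#' @param strategy one of `"standard"`, `"indirect"`,
#'   `"multi_trait_indirect"`, `"multi_trait"`, `"trait_assisted"`.
#' @param focal focal trait name.
#' @param secondary secondary trait name(s); two or more for
#'   `multi_trait_indirect`, exactly one for the other assisted strategies.
#' @param scheme a [make_folds()] scheme (shared across strategies).
#' @param ridge diagonal conditioning for the GBLUP solves.
#' @param components `"per_fold"` (default: variance components re-estimated
#'   from each fold's training records) or `"full_data"` (components
#'   estimated once from all records, folds solved at those components).
#' @return An object of class `gs_accuracy`: per-repeat pooled correlations
#'   `r`, their `mean` and `sd`, the pooled out-of-fold `predictions`
#'   (n x n_repeats), and the fold assignments used.
#' @export
run_strategy <- function(pheno, A, strategy, focal, secondary = NULL,
                         scheme, ridge = 1e-6,
                         components = c("per_fold", "full_data")) {
  components <- match.arg(components)
  A <- as_grm_matrix(A)
  ids <- rownames(A)
  if (is.null(rownames(pheno))) {
    if (nrow(pheno) != length(ids)) stopf("phenotype/relationship dimension mismatch")
    rownames(pheno) <- ids
  }
  pheno <- pheno[ids, , drop = FALSE]
  check_strategy(strategy, focal, secondary, colnames(pheno))
  stopifnot(inherits(scheme, "cv_scheme"))
  if (scheme$n != length(ids)) {
    stopf("scheme was built for %d genotypes, data has %d", scheme$n, length(ids))
  }
  n <- length(ids)
  xbar_focal <- pheno[, focal]

  comp <- NULL
  if (components == "full_data" &&
      strategy %in% c("multi_trait", "trait_assisted")) {
    full <- gblup_mt(pheno[, c(focal, secondary[1L])], A, ridge = ridge)
    comp <- list(G = full$G, R = full$R)
  }

  r <- rep(NA_real_, scheme$n_repeats)
  predictions <- matrix(NA_real_, n, scheme$n_repeats,
                        dimnames = list(ids, NULL))
  warm <- NULL
  for (rep_i in seq_len(scheme$n_repeats)) {
    fold <- scheme$assignments[, rep_i]
    ok <- tryCatch({
      pred <- rep(NA_real_, n)
      mti_raw <- vector("list", scheme$k)
      mti_w <- NULL
      for (f in seq_len(scheme$k)) {
        val <- which(fold == f)
        train <- which(fold != f)
        sp <- strategy_predict(pheno, A, strategy, focal, secondary,
                               train, val, warm = warm, ridge = ridge,
                               components = comp)
        warm <- sp$warm
        if (strategy == "multi_trait_indirect") {
          mti_raw[[f]] <- list(val = val, raw = attr(sp$pred, "raw"))
          mti_w <- rbind(mti_w, attr(sp$pred, "weights"))
        } else {
          pred[val] <- sp$pred
        }
      }
      if (strategy == "multi_trait_indirect") {
        raw <- matrix(NA_real_, n, length(secondary))
        for (f in seq_len(scheme$k)) raw[mti_raw[[f]]$val, ] <- mti_raw[[f]]$raw
        pred <- indirect_index(raw, colMeans(mti_w))
      }
      predictions[, rep_i] <- pred
      r[rep_i] <- stats::cor(pred, xbar_focal, use = "complete.obs")
      TRUE
    }, error = function(e) {
      warnf("repeat %d failed and was excluded: %s", rep_i, conditionMessage(e))
      FALSE
    })
    if (!ok) r[rep_i] <- NA_real_
  }
  structure(list(strategy = strategy, focal = focal, secondary = secondary,
                 r = r, mean = mean(r, na.rm = TRUE),
                 sd = stats::sd(r[!is.na(r)]),
                 n_repeats = scheme$n_repeats,
                 n_failed = sum(is.na(r)),
                 training_fraction = 1 - 1 / scheme$k,
                 predictions = predictions,
                 fold_assignments = scheme$assignments,
                 seed = scheme$seed),
            class = "gs_accuracy")
}

#' @export
print.gs_accuracy <- function(x, ...) {
  sec <- if (length(x$secondary)) paste0(" + ", paste(x$secondary, collapse = "/")) else ""
  cat(sprintf("%s GS (%s%s): r = %.3f +/- %.3f over %d repeats",
              x$strategy, x$focal, sec, x$mean, x$sd, x$n_repeats))
  if (x$n_failed > 0L) cat(sprintf(" (%d failed)", x$n_failed))
  cat("\n")
  invisible(x)
}

#' Coincidence index between two rankings
#'
#' Chance-corrected overlap `CI = (B - R) / (T - R)` between the `T` best
#' (or worst) genotypes by two rankings, where `T = round(intensity * n)`,
#' `B` is the observed overlap and `R = round(T^2 / n)` is the overlap
#' expected by chance. Ties are broken by genotype-id order, so the
#' selection is deterministic.
#'
#' @param x_bar named numeric vector (e.g. focal adjusted means).
#' @param gebv named numeric vector over the same genotypes.
#' @param intensity selected fraction, in (0, 1); default 0.20.
#' @param direction `"top"` or `"bottom"`.
#' @return List of class `coincidence` with `B`, `T`, `R`, `ci`.
#' @examples
#' ci <- coincidence_index(setNames(rnorm(453), paste0("G", 1:453)),
#'                         setNames(rnorm(453), paste0("G", 1:453)))
#' c(ci$T, ci$R)  # 91, 18
#' @export
coincidence_index <- function(x_bar, gebv, intensity = 0.20,
                              direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (intensity <= 0 || intensity >= 1) stopf("intensity must be in (0, 1)")
  ids <- names(x_bar)
  if (is.null(ids)) ids <- names(gebv)
  if (is.null(ids)) {
    if (length(x_bar) != length(gebv)) stopf("rankings must cover the same genotypes")
    ids <- sprintf("G%05d", seq_along(x_bar))
  } else {
    if (!setequal(names(x_bar), names(gebv))) {
      stopf("rankings must cover the same genotype set")
    }
    gebv <- gebv[names(x_bar)]
  }
  n <- length(x_bar)
  T_sel <- round(intensity * n)
  R_exp <- round(T_sel^2 / n)
  if (T_sel <= R_exp) stopf("undefined coincidence index: T = %d <= R = %d", T_sel, R_exp)
  dec <- direction == "top"
  sel1 <- ids[order_best_first(unname(x_bar), ids, dec)][seq_len(T_sel)]
  sel2 <- ids[order_best_first(unname(gebv), ids, dec)][seq_len(T_sel)]
  B <- length(intersect(sel1, sel2))
  structure(list(B = B, T = T_sel, R = R_exp,
                 ci = (B - R_exp) / (T_sel - R_exp),
                 intensity = intensity, direction = direction),
            class = "coincidence")
}

#' @export
print.coincidence <- function(x, ...) {
  cat(sprintf("Coincidence (%s %.0f%%): B = %d, T = %d, R = %d, CI = %.3f\n",
              x$direction, 100 * x$intensity, x$B, x$T, x$R, x$ci))
  invisible(x)
}

#' Coincidence indices of a cross-validation run
#'
#' Applies [coincidence_index()] to every repeat's pooled out-of-fold
#' predictions against the focal adjusted means.
#'
#' @param result a [run_strategy()] result.
#' @param x_bar focal adjusted means (named).
#' @param intensity selected fraction.
#' @param direction `"top"` or `"bottom"`.
#' @return data.frame with one row per repeat (`repeat_`, `B`, `ci`) plus
#'   attributes `mean` and `sd`.
#' @export
cv_coincidence <- function(result, x_bar, intensity = 0.20,
                           direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  stopifnot(inherits(result, "gs_accuracy"))
  reps <- which(!is.na(result$r))
  ci <- vapply(reps, function(j) {
    coincidence_index(x_bar, result$predictions[, j], intensity, direction)$ci
  }, 0)
  out <- data.frame(repeat_ = reps, ci = ci)
  attr(out, "mean") <- mean(ci)
  attr(out, "sd") <- stats::sd(ci)
  out
}

#' Expected selection accuracies relative to phenotypic selection
#'
#' Phenotypic selection on the focal trait has expected accuracy
#' `r = h_focal` (the square root of its heritability); indirect phenotypic
#' selection on a correlated trait has `r = h_secondary * cor_g`. Returns
#' both together with the ratios of a GS strategy's realized accuracy to
#' each.
#'
#' @param h_focal,h_secondary square roots of the heritabilities, in
#'   \[0, 1\].
#' @param cor_g genetic correlation between secondary and focal trait.
#' @param r_strategy realized prediction accuracy of the GS strategy.
#' @return Named list: `ps`, `ips`, `ratio_ps`, `ratio_ips` (`NA` where a
#'   denominator is zero).
#' @export
expected_selection_accuracy <- function(h_focal, h_secondary, cor_g,
                                        r_strategy) {
  if (h_focal < 0 || h_focal > 1 || h_secondary < 0 || h_secondary > 1) {
    stopf("h values must lie in [0, 1]")
  }
  if (abs(cor_g) > 1) stopf("|cor_g| must be <= 1")
  ps <- h_focal
  ips <- h_secondary * cor_g
  list(ps = ps, ips = ips,
       ratio_ps = if (ps == 0) NA_real_ else r_strategy / ps,
       ratio_ips = if (ips == 0) NA_real_ else r_strategy / ips)
}

#' Accuracy as a function of training-population size
#'
#' For each training fraction `f`, draws a fresh random `f`-subset per
#' repeat, trains the strategy on it and validates on the complement
#' (keeping the trait-assisted convention that secondary records stay
#' complete), and records the correlation between validation predictions
#' and focal adjusted means.
#'
#' @param pheno,A,strategy,focal,secondary,ridge as in [run_strategy()].
#' @param scheme a [make_folds()] scheme; its `n_repeats` and `seed` drive
#'   the subsampling.
#' @param fractions training fractions in (0, 1).
#' @return List of `gs_accuracy`-like objects, one per usable fraction.
#' @export
training_fraction_sweep <- function(pheno, A, strategy, focal,
                                    secondary = NULL, scheme,
                                    fractions = c(0.2, 0.4, 0.6, 0.8),
                                    ridge = 1e-6) {
  A <- as_grm_matrix(A)
  ids <- rownames(A)
  pheno <- pheno[ids, , drop = FALSE]
  check_strategy(strategy, focal, secondary, colnames(pheno))
  n <- length(ids)
  out <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    if (f <= 0 || f >= 1) stopf("fractions must lie in (0, 1)")
    n_train <- floor(f * n)
    if (n_train < 30L) {
      warnf("fraction %.2f gives %d training records (< 30); skipped", f, n_train)
      next
    }
    r <- rep(NA_real_, scheme$n_repeats)
    warm <- NULL
    for (rep_i in seq_len(scheme$n_repeats)) {
      train <- with_seed(scheme$seed + 7919L * fi + rep_i,
                         sort(sample.int(n, n_train)))
      val <- setdiff(seq_len(n), train)
      ok <- tryCatch({
        sp <- strategy_predict(pheno, A, strategy, focal, secondary,
                               train, val, warm = warm, ridge = ridge)
        warm <- sp$warm
        pred <- if (strategy == "multi_trait_indirect") {
          indirect_index(attr(sp$pred, "raw"), attr(sp$pred, "weights"))
        } else sp$pred
        r[rep_i] <- stats::cor(pred, pheno[val, focal])
        TRUE
      }, error = function(e) {
        warnf("fraction %.2f repeat %d failed: %s", f, rep_i, conditionMessage(e))
        FALSE
      })
      if (!ok) r[rep_i] <- NA_real_
    }
    out[[sprintf("f%.2f", f)]] <- structure(
      list(strategy = strategy, focal = focal, secondary = secondary,
           r = r, mean = mean(r, na.rm = TRUE), sd = stats::sd(r[!is.na(r)]),
           n_repeats = scheme$n_repeats, n_failed = sum(is.na(r)),
           training_fraction = f, predictions = NULL,
           fold_assignments = NULL, seed = scheme$seed),
      class = "gs_accuracy")
  }
  out
}
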