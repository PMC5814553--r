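# Synthetic genotypes, multi-trait phenotypes and field trials with the
# statistical structure the two-stage GBLUP analysis assumes.

#' Simulation configuration for genotypes and phenotypes
#'
#' Defines a panel of (by default inbred) genotypes scored at biallelic SNPs,
#' and a set of traits with given genomic heritabilities and genetic /
#' residual correlation structure. Phenotypic variance is normalised to 1 per
#' trait, so heritability is the only scale parameter.
#'
#' @param n_genotypes number of genotypes in the panel.
#' @param n_markers number of biallelic markers.
#' @param maf_low,maf_high bounds of the uniform distribution the per-marker
#'   minor-allele frequencies are drawn from; both in (0, 0.5].
#' @param heritabilities numeric vector, one value per trait, each strictly
#'   inside (0, 1): the fraction of phenotypic variance that is additive.
#' @param genetic_correlation trait-by-trait genetic correlation matrix
#'   (unit diagonal, positive semi-definite). Scalar shorthand is accepted
#'   for two traits.
#' @param residual_correlation trait-by-trait residual correlation matrix,
#'   same constraints; defaults to the identity.
#' @param n_qtl number of markers carrying effects (default
#'   `min(500, n_markers)`); set `n_qtl = n_markers` for an infinitesimal
#'   architecture.
#' @param inbred if `TRUE` (default), dosages are in \{0, 2\} as for a panel
#'   of inbred lines; otherwise two independent allele draws give \{0, 1, 2\}.
#' @param n_subpops,fst population-structure parameters: genotypes are
#'   assigned to `n_subpops` subpopulations whose marker allele frequencies
#'   are drawn around the panel frequency with Balding-Nichols dispersion
#'   `fst`. Diversity panels used for genomic selection are strongly
#'   structured, and relatedness between training and validation genotypes
#'   is what gives GBLUP its accuracy on low-heritability traits; `fst = 0`
#'   gives a fully unrelated panel.
#' @param seed integer seed; all generators are deterministic given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genotypes, n_markers,
                       maf_low = 0.05, maf_high = 0.5,
                       heritabilities = 0.5,
                       genetic_correlation = NULL,
                       residual_correlation = NULL,
                       n_qtl = min(500L, n_markers),
                       inbred = TRUE,
                       n_subpops = max(2L, round(n_genotypes / 12)),
                       fst = 0.75,
                       seed = 1L) {
  if (!is_count(n_genotypes) || !is_count(n_markers)) {
    stopf("invalid config: n_genotypes and n_markers must be positive counts")
  }
  if (!is_number(maf_low) || !is_number(maf_high) ||
      maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high) {
    stopf("invalid config: need 0 < maf_low <= maf_high <= 0.5")
  }
  n_traits <- length(heritabilities)
  if (n_traits < 1L || any(heritabilities <= 0) || any(heritabilities >= 1)) {
    stopf("invalid config: heritabilities must lie strictly inside (0, 1)")
  }
  expand_cor <- function(m, name) {
    if (is.null(m)) m <- diag(n_traits)
    if (length(m) == 1L && n_traits == 2L && !is.matrix(m)) {
      m <- matrix(c(1, m, m, 1), 2, 2)
    }
    if (!is.matrix(m) || nrow(m) != n_traits) {
      stopf("'%s' must be a %d x %d matrix", name, n_traits, n_traits)
    }
    check_corr_matrix(m, name)
  }
  gcor <- expand_cor(genetic_correlation, "genetic_correlation")
  rcor <- expand_cor(residual_correlation, "residual_correlation")
  if (!is_count(n_qtl) || n_qtl > n_markers) {
    stopf("invalid config: n_qtl must be a count <= n_markers")
  }
  if (!is_count(n_subpops) || !is_number(fst) || fst < 0 || fst >= 1) {
    stopf("invalid config: need n_subpops >= 1 and fst in [0, 1)")
  }
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_markers = as.integer(n_markers),
    maf_low = maf_low, maf_high = maf_high,
    n_traits = n_traits,
    heritabilities = heritabilities,
    genetic_correlation = gcor,
    residual_correlation = rcor,
    n_qtl = as.integer(n_qtl),
    inbred = isTRUE(inbred),
    n_subpops = as.integer(n_subpops), fst = fst,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d genotypes x %d markers (MAF U[%.3g, %.3g], %s)\n",
              x$n_genotypes, x$n_markers, x$maf_low, x$maf_high,
              if (x$inbred) "inbred" else "outbred"))
  cat(sprintf("  %d trait(s), h2 = %s, %d QTL, seed %d\n",
              x$n_traits, paste(format(x$heritabilities), collapse = ", "),
              x$n_qtl, x$seed))
  invisible(x)
}

#' Simulate a SNP dosage matrix
#'
#' Draws per-marker panel allele frequencies uniformly from
#' `[maf_low, maf_high]`; when `fst > 0`, subpopulation frequencies are
#' drawn around the panel frequency from the Balding-Nichols Beta
#' distribution with dispersion `fst`, giving the hierarchical relatedness
#' structure of a diversity panel. Genotypes are Bernoulli allele draws at
#' their subpopulation's frequencies: in inbred mode a single draw is
#' duplicated, giving dosages in \{0, 2\}; otherwise two independent draws
#' give \{0, 1, 2\}.
#'
#' @param config a [sim_config()] object.
#' @return A `genotype_matrix` (see [genotype_matrix()]) of dimension
#'   `n_genotypes` x `n_markers`, with the subpopulation assignment as
#'   attribute `"subpop"`.
#' @examples
#' g <- sim_genotypes(sim_config(20, 100, seed = 1))
#' dim(g$dosages)
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genotypes
  p <- config$n_markers
  with_seed(config$seed, {
    freq <- stats::runif(p, config$maf_low, config$maf_high)
    subpop <- rep_len(seq_len(config$n_subpops), n)
    if (config$fst > 0 && config$n_subpops > 1L) {
      th <- (1 - config$fst) / config$fst
      # n_subpops x p matrix of subpopulation frequencies
      pf <- matrix(stats::rbeta(config$n_subpops * p,
                                rep(freq * th, each = config$n_subpops),
                                rep((1 - freq) * th, each = config$n_subpops)),
                   config$n_subpops, p)
      fmat <- pf[subpop, , drop = FALSE]
    } else {
      fmat <- matrix(freq, n, p, byrow = TRUE)
    }
    if (config$inbred) {
      dos <- 2L * matrix(stats::rbinom(n * p, 1L, fmat), n, p)
    } else {
      dos <- matrix(stats::rbinom(n * p, 1L, fmat), n, p) +
        matrix(stats::rbinom(n * p, 1L, fmat), n, p)
    }
    out <- genotype_matrix(dos,
                           genotype_ids = sprintf("G%04d", seq_len(n)),
                           marker_ids = sprintf("M%05d", seq_len(p)))
    attr(out, "subpop") <- subpop
    out
  })
}

#' Simulate multi-trait phenotypes on a genotype panel
#'
#' Samples additive effects at `n_qtl` randomly chosen markers from a
#' multivariate normal with covariance proportional to the configured genetic
#' correlation matrix, builds true breeding values as dosage x effects, and
#' rescales so that total phenotypic variance is 1 per trait and the
#' configured heritability is met on the GBLUP component scale: with `abar`
#' the mean diagonal of the panel's VanRaden relationship matrix (about 2
#' for inbred dosages), the breeding-value variance is set to
#' `v = abar * h2 / (1 + h2 * (abar - 1))` and the residual variance to
#' `1 - v`, so that a GBLUP analysis of the simulated trait returns
#' `sigma2_g / (sigma2_g + sigma2_e)` equal to `h2`. Residuals are
#' multivariate normal with the configured residual correlation.
#'
#' @param genotypes a `genotype_matrix`.
#' @param config a [sim_config()] object (its `seed` + 1 drives this step, so
#'   genotypes and phenotypes use distinct streams).
#' @return An object of class `sim_study` with elements `genotypes`,
#'   `true_breeding_values`, `phenotypes` (both n x n_traits matrices),
#'   `realized_h2`, `realized_cor_g`.
#' @export
sim_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  dos <- genotypes$dosages
  n <- nrow(dos)
  t <- config$n_traits
  poly <- apply(dos, 2L, function(x) stats::var(x) > 0)
  if (sum(poly) < 2L) stopf("genotype matrix is degenerate: <2 polymorphic markers")
  ev <- eigen(config$genetic_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stopf("genetic_correlation is not PSD (smallest eigenvalue %.3g)", min(ev))
  }
  with_seed(config$seed + 1L, {
    qtl <- sample(which(poly), min(config$n_qtl, sum(poly)))
    Lg <- chol_psd(config$genetic_correlation)
    eff <- matrix(stats::rnorm(length(qtl) * t), length(qtl), t) %*% Lg
    tbv <- dos[, qtl, drop = FALSE] %*% eff
    # component-scale heritability -> breeding-value variance share, using
    # the mean diagonal of the panel's own VanRaden matrix
    pfreq <- colMeans(dos) / 2
    pq <- pfreq * (1 - pfreq)
    abar <- mean(colSums((t(dos) - 2 * pfreq)^2)) / (2 * sum(pq[pq > 0]))
    v_share <- abar * config$heritabilities /
      (1 + config$heritabilities * (abar - 1))
    Sg <- outer(sqrt(v_share), sqrt(v_share)) * config$genetic_correlation
    # recolor the breeding values to their exact target covariance so the
    # study conditions (heritabilities, cor_g, between-family share) do not
    # drift with the QTL draw; with subpopulation structure the
    # between-family and within-family strata are recolored separately to
    # shares fst and 1 - fst
    subpop <- attr(genotypes, "subpop")
    recolor <- function(M, target) {
      cv <- stats::cov(M)
      if (t == 1L) return(M / sqrt(cv[1]) * sqrt(target[1]))
      M %*% solve(chol(cv)) %*% chol_psd(target)
    }
    if (!is.null(subpop) && config$fst > 0 && config$n_subpops > t &&
        min(table(subpop)) >= 2L) {
      fam_mean <- apply(tbv, 2L, function(v) stats::ave(v, subpop))
      fam_mean <- matrix(fam_mean, n, t)
      within <- tbv - fam_mean
      tbv <- recolor(fam_mean, config$fst * Sg) +
        recolor(within, (1 - config$fst) * Sg)
    } else {
      tbv <- recolor(tbv, Sg)
    }
    tbv <- sweep(tbv, 2L, colMeans(tbv))
    rsd <- sqrt(1 - v_share)
    Sr <- outer(rsd, rsd) * config$residual_correlation
    res <- recolor(matrix(stats::rnorm(n * t), n, t), Sr)
    phe <- tbv + res
    rownames(tbv) <- rownames(phe) <- genotypes$genotype_ids
    colnames(tbv) <- colnames(phe) <- sprintf("trait%d", seq_len(t))
    varr <- apply(res, 2L, stats::var)
    vart <- apply(tbv, 2L, stats::var)
    structure(list(
      genotypes = genotypes,
      true_breeding_values = tbv,
      phenotypes = phe,
      # realized component-scale heritability: sigma2_g = var(tbv) / abar
      realized_h2 = (vart / abar) / (vart / abar + varr),
      realized_cor_g = stats::cor(tbv),
      grm_diag_mean = abar,
      qtl = genotypes$marker_ids[qtl]
    ), class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d genotypes, %d trait(s)\n",
              nrow(x$phenotypes), ncol(x$phenotypes)))
  cat("  realized h2:", paste(format(round(x$realized_h2, 3)), collapse = ", "), "\n")
  if (ncol(x$phenotypes) > 1L) {
    cat("  realized genetic correlations:\n")
    print(round(x$realized_cor_g, 3))
  }
  invisible(x)
}

# Cholesky-like factor that tolerates PSD (rank-deficient) matrices.
chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(ev), length(ev)))
}

#' Field-trial simulation configuration
#'
#' Describes a rectangular row-by-column field layout with blocks and a
#' spatially autocorrelated residual field with separable AR(1) correlation
#' along rows and columns -- the error structure the first-stage spatial
#' model assumes.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_blocks number of blocks; blocks tile the plot sequence in
#'   column-major order.
#' @param block_sd standard deviation of iid block effects (trait units).
#' @param rho_row,rho_col AR(1) correlation parameters, each in (-1, 1).
#' @param residual_sd marginal standard deviation of the residual field.
#' @param design `"rcbd"` (every genotype once per block) or `"augmented"`
#'   (unreplicated entries plus repeated checks, one per block).
#' @param seed integer seed.
#' @return An object of class `field_config`.
#' @export
field_config <- function(n_rows, n_cols, n_blocks = 1L,
                         block_sd = 0, rho_row = 0, rho_col = 0,
                         residual_sd = 1,
                         design = c("rcbd", "augmented"),
                         seed = 1L) {
  design <- match.arg(design)
  if (!is_count(n_rows) || !is_count(n_cols) || !is_count(n_blocks)) {
    stopf("invalid field config: dimensions must be positive counts")
  }
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1) {
    stopf("invalid field config: |rho_row| and |rho_col| must be < 1")
  }
  if (residual_sd <= 0 || block_sd < 0) {
    stopf("invalid field config: residual_sd > 0 and block_sd >= 0 required")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_blocks = as.integer(n_blocks), block_sd = block_sd,
                 rho_row = rho_row, rho_col = rho_col,
                 residual_sd = residual_sd, design = design,
                 seed = as.integer(seed)),
            class = "field_config")
}

# Sample one realisation of a zero-mean Gaussian field on an
# n_rows x n_cols grid with covariance sd^2 * AR1(rho_row) (x) AR1(rho_col),
# returned as a matrix indexed [row, col]. Uses the Kronecker identity
# chol(Rr (x) Rc) = chol(Rr) (x) chol(Rc): E = t(Lr) Z Lc has
# cov(vec by row-major) = Rr (x) Rc.
sim_ar1_field <- function(n_rows, n_cols, rho_row, rho_col, sd = 1) {
  Lr <- chol(ar1_cor(rho_row, n_rows))   # upper triangular, Rr = t(Lr) Lr
  Lc <- chol(ar1_cor(rho_col, n_cols))
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  sd * (t(Lr) %*% z %*% Lc)
}

#' Simulate a spatial field trial
#'
#' Lays genotypes onto a row-by-column grid and generates plot values
#' `y = mu + g_genotype + b_block + e`, with iid block effects and a
#' residual field with separable AR(1) x AR(1) covariance. Under the
#' `rcbd` design each genotype appears once per block; under `augmented`
#' the entries are unreplicated and each of `checks` appears once in every
#' block.
#'
#' @param genotype_effects named numeric vector of per-genotype true values
#'   (names are the genotype ids).
#' @param config a [field_config()] object.
#' @param mu overall mean.
#' @param year label stored in the `year` column (default `"Y1"`).
#' @param trait trait name stored in the `trait` column.
#' @param checks character vector of genotype ids treated as checks in the
#'   augmented design (must be named in `genotype_effects`).
#' @return A `data.frame` plot table with columns
#'   `genotype, year, row, col, block, trait, value`, and the latent
#'   residual field as attribute `"residual_field"`.
#' @export
sim_field_trial <- function(genotype_effects, config, mu = 0,
                            year = "Y1", trait = "trait1", checks = NULL) {
  stopifnot(inherits(config, "field_config"))
  ids <- names(genotype_effects)
  if (is.null(ids) || any(!nzchar(ids))) {
    stopf("genotype_effects must be a named vector of per-genotype values")
  }
  n_plots <- config$n_rows * config$n_cols
  with_seed(config$seed, {
    if (config$design == "rcbd") {
      if (length(ids) * config$n_blocks > n_plots) {
        stopf("layout error: %d genotypes x %d blocks exceed %d plots",
              length(ids), config$n_blocks, n_plots)
      }
      plot_geno <- unlist(lapply(seq_len(config$n_blocks),
                                 function(b) sample(ids)))
      plot_block <- rep(seq_len(config$n_blocks), each = length(ids))
    } else {
      if (is.null(checks)) checks <- ids[1L]
      if (!all(checks %in% ids)) stopf("checks must appear in genotype_effects")
      entries <- setdiff(ids, checks)
      need <- length(entries) + length(checks) * config$n_blocks
      if (need > n_plots) {
        stopf("layout error: %d required plots exceed %d available", need, n_plots)
      }
      # split unreplicated entries across blocks as evenly as possible
      entry_block <- sort(rep_len(seq_len(config$n_blocks), length(entries)))
      entries <- sample(entries)
      plot_geno <- character(0)
      plot_block <- integer(0)
      for (b in seq_len(config$n_blocks)) {
        blk <- c(entries[entry_block == b], checks)
        blk <- sample(blk)
        plot_geno <- c(plot_geno, blk)
        plot_block <- c(plot_block, rep(b, length(blk)))
      }
    }
    m <- length(plot_geno)
    # plots fill the grid column-major: plot k -> (row, col)
    rows <- ((seq_len(m) - 1L) %% config$n_rows) + 1L
    cols <- ((seq_len(m) - 1L) %/% config$n_rows) + 1L
    blocks <- stats::rnorm(config$n_blocks, 0, config$block_sd)
    efield <- sim_ar1_field(config$n_rows, config$n_cols,
                            config$rho_row, config$rho_col,
                            config$residual_sd)
    e <- efield[cbind(rows, cols)]
    y <- mu + genotype_effects[plot_geno] + blocks[plot_block] + e
    out <- data.frame(genotype = plot_geno,
                      year = year,
                      row = rows, col = cols,
                      block = sprintf("B%02d", plot_block),
                      trait = trait,
                      value = as.numeric(y),
                      stringsAsFactors = FALSE)
    attr(out, "residual_field") <- efield
    out
  })
}
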