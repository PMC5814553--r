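# Genotype container, QC filters matching the usual GBS pipeline thresholds,
# mean imputation, and the VanRaden realized relationship matrix.

#' Construct a genotype matrix
#'
#' A light container for biallelic SNP dosages: an n x p matrix with entries
#' in \{0, 1, 2\} or `NA` for missing calls, with genotype and marker ids.
#'
#' @param dosages numeric matrix, entries 0/1/2 or `NA`.
#' @param genotype_ids,marker_ids row/column labels; defaults taken from
#'   dimnames or generated.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `genotype_ids`, `marker_ids`.
#' @export
genotype_matrix <- function(dosages, genotype_ids = rownames(dosages),
                            marker_ids = colnames(dosages)) {
  if (!is.matrix(dosages)) stopf("'dosages' must be a matrix")
  if (is.null(genotype_ids)) genotype_ids <- sprintf("G%04d", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%05d", seq_len(ncol(dosages)))
  if (length(genotype_ids) != nrow(dosages) || length(marker_ids) != ncol(dosages)) {
    stopf("id lengths do not match the dosage matrix")
  }
  if (anyDuplicated(genotype_ids)) {
    stopf("duplicate genotype id: %s",
          genotype_ids[duplicated(genotype_ids)][1L])
  }
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2) |
    (dosages >= 0 & dosages <= 2)   # imputed values are continuous in [0, 2]
  if (!all(ok)) stopf("dosage entries must be in [0, 2] or NA")
  dimnames(dosages) <- list(genotype_ids, marker_ids)
  structure(list(dosages = dosages,
                 genotype_ids = as.character(genotype_ids),
                 marker_ids = as.character(marker_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("Genotype matrix: %d genotypes x %d markers (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# minor-allele frequency per marker on non-missing calls
marker_maf <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Quality-control filter for genotype matrices
#'
#' Applies, in order: drop individuals with missingness above `max_missing`,
#' drop markers with missingness above `max_missing`, then drop markers with
#' minor-allele frequency (computed on non-missing calls) below `min_maf`.
#' These are the customary GBS panel filters (e.g. discard calls >95%
#' missing and MAF < 5%).
#'
#' @param g a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction, in \[0, 1\].
#' @param min_maf minimum minor-allele frequency, in \[0, 0.5\].
#' @return The filtered `genotype_matrix`; the counts dropped by each rule
#'   are attached as attribute `"qc_report"`.
#' @examples
#' g <- sim_genotypes(sim_config(50, 200, seed = 3))
#' qc <- qc_filter(g, max_missing = 0.95, min_maf = 0.05)
#' attr(qc, "qc_report")
#' @export
qc_filter <- function(g, max_missing = 0.95, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (max_missing < 0 || max_missing > 1) stopf("max_missing must be in [0, 1]")
  if (min_maf < 0 || min_maf > 0.5) stopf("min_maf must be in [0, 0.5]")
  dos <- g$dosages
  ind_miss <- rowMeans(is.na(dos))
  keep_ind <- ind_miss <= max_missing
  dos <- dos[keep_ind, , drop = FALSE]
  mk_miss <- colMeans(is.na(dos))
  keep_mk1 <- mk_miss <= max_missing
  dos <- dos[, keep_mk1, drop = FALSE]
  maf <- marker_maf(dos)
  keep_mk2 <- !is.na(maf) & maf >= min_maf
  dos <- dos[, keep_mk2, drop = FALSE]
  if (ncol(dos) == 0L) stopf("QC removed all markers")
  if (nrow(dos) == 0L) stopf("QC removed all individuals")
  out <- genotype_matrix(dos)
  attr(out, "qc_report") <- list(
    individuals_dropped_missing = sum(!keep_ind),
    markers_dropped_missing = sum(!keep_mk1),
    markers_dropped_maf = sum(!keep_mk2),
    n_genotypes = nrow(dos), n_markers = ncol(dos))
  out
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing call by the marker's mean observed dosage
#' (continuous values are allowed downstream, where only the centred
#' cross-product matters).
#'
#' @param g a `genotype_matrix`.
#' @return A `genotype_matrix` with no missing entries.
#' @export
mean_impute <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  n_obs <- colSums(!is.na(dos))
  if (any(n_obs == 0L)) {
    stopf("cannot impute marker with zero observed calls: %s",
          g$marker_ids[which(n_obs == 0L)[1L]])
  }
  if (anyNA(dos)) {
    mk_mean <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mk_mean[idx[, 2L]]
  }
  genotype_matrix(dos, g$genotype_ids, g$marker_ids)
}

#' VanRaden realized additive relationship matrix
#'
#' Method-1 VanRaden GRM: markers are centred by twice their (data-estimated)
#' allele frequency, and the cross-product is scaled by
#' `2 * sum(p_k * (1 - p_k))` over polymorphic markers. Monomorphic markers
#' centre to zero and are excluded from the scale term.
#'
#' @param g a `genotype_matrix` with no missing entries (see [mean_impute()]).
#' @return An object of class `grm`: list with the n x n symmetric `values`
#'   matrix and `genotype_ids`.
#' @export
vanraden_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  if (anyNA(dos)) stopf("genotype matrix has missing calls; impute first")
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stopf("degenerate scale: all markers monomorphic")
  W <- sweep(dos, 2L, 2 * p, "-")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  A <- tcrossprod(W) / denom
  A <- (A + t(A)) / 2
  dimnames(A) <- list(g$genotype_ids, g$genotype_ids)
  structure(list(values = A, genotype_ids = g$genotype_ids), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Realized relationship matrix: %d genotypes, mean diagonal %.3f\n",
              nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

# Validate a grm-like input and return the plain matrix with ids.
as_grm_matrix <- function(A) {
  if (inherits(A, "grm")) A <- A$values
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("relationship matrix must be square")
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- sprintf("G%04d", seq_len(nrow(A)))
  }
  if (max(abs(A - t(A))) > 1e-8) stopf("relationship matrix must be symmetric")
  A
}
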