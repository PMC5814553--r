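# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` after seeding the RNG with `seed`, then restores the
#' caller's RNG state, so seeded generators do not disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# symmetric PSD check with tolerance on the smallest eigenvalue
check_corr_matrix <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("'%s' must be a square matrix", name)
  }
  if (max(abs(m - t(m))) > 1e-10) stopf("'%s' must be symmetric", name)
  if (max(abs(diag(m) - 1)) > 1e-10) stopf("'%s' must have unit diagonal", name)
  if (any(abs(m) > 1 + 1e-10)) stopf("'%s' has entries outside [-1, 1]", name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stopf("'%s' is not positive semi-definite (smallest eigenvalue %.3g)",
          name, min(ev))
  }
  invisible(m)
}

# stable ranking: best-first order of `x`, ties broken by id order
order_best_first <- function(x, ids, decreasing = TRUE) {
  order(if (decreasing) -x else x, ids)
}
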