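# Eigen model of a gene module's correlation matrix.

#' Principal-component model of a gene module
#'
#' Eigendecomposes the module's gene-gene correlation matrix and retains the
#' principal components whose eigenvalues exceed `lambda_min`. Near-degenerate
#' PCs carry essentially no signal but destabilise the variance-weighted
#' statistics, hence the default retention rule `lambda_k > 0.1`.
#'
#' The eigenvector sign convention is deterministic: the largest-magnitude
#' loading of each eigenvector is made positive (ties broken by the lowest
#' gene index), so that PC scores are reproducible across platforms.
#'
#' @param sigma gene correlation matrix (see [as_correlation_matrix()]).
#' @param lambda_min eigenvalue retention threshold (default 0.1).
#' @return an object of class `pco_model` with elements `sigma`, `gene_ids`,
#'   `values` (eigenvalues, non-increasing), `vectors` (orthonormal columns),
#'   `retained` (indices with `lambda > lambda_min`) and `lambda_min`.
#' @export
#' @examples
#' m <- pco_model(make_block_sigma(c(2, 2), 0.8))
#' m$values
pco_model <- function(sigma, lambda_min = 0.1) {
  sigma <- as_correlation_matrix(sigma, rownames(sigma))
  e <- eigen(sigma, symmetric = TRUE)
  k <- nrow(sigma)
  # deterministic sign: largest-|loading| entry positive, ties -> lowest index
  for (j in seq_len(k)) {
    v <- e$vectors[, j]
    i <- which.max(abs(v) - seq_len(k) * 1e-14)
    if (v[i] < 0) e$vectors[, j] <- -v
  }
  retained <- which(e$values > lambda_min)
  # lambda_1 >= 1 for any correlation matrix, so retention cannot be empty
  stopifnot(length(retained) >= 1L)
  structure(
    list(sigma = sigma, gene_ids = rownames(sigma),
         values = e$values, vectors = e$vectors,
         retained = retained, lambda_min = lambda_min,
         cache = new.env(parent = emptyenv())),
    class = "pco_model"
  )
}

#' @export
print.pco_model <- function(x, ...) {
  cat(sprintf("PC model of a %d-gene module\n", length(x$gene_ids)))
  cat(sprintf("  retained PCs: %d of %d (lambda > %g)\n",
              length(x$retained), length(x$values), x$lambda_min))
  cat(sprintf("  leading eigenvalues: %s\n",
              paste(signif(utils::head(x$values, 5), 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.pco_model <- function(object, ...) {
  lam <- object$values
  out <- list(
    n_genes = length(object$gene_ids),
    n_retained = length(object$retained),
    lambda_min = object$lambda_min,
    eigenvalues = lam,
    variance_explained = cumsum(lam) / sum(lam)
  )
  class(out) <- "summary.pco_model"
  out
}

#' @export
print.summary.pco_model <- function(x, ...) {
  cat(sprintf("%d genes, %d retained PCs (lambda > %g)\n",
              x$n_genes, x$n_retained, x$lambda_min))
  cat(sprintf("variance explained by retained PCs: %.1f%%\n",
              100 * x$variance_explained[x$n_retained]))
  invisible(x)
}

# Subset a model to a surviving gene set (same-chromosome / cross-map
# exclusions re-derive the eigen model on the submatrix).
#' @noRd
subset_model <- function(model, keep_ids) {
  idx <- match(keep_ids, model$gene_ids)
  if (anyNA(idx)) stopf("genes not in model: %s",
                        paste(keep_ids[is.na(idx)], collapse = ", "))
  pco_model(model$sigma[idx, idx, drop = FALSE], lambda_min = model$lambda_min)
}
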