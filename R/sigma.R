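# Gene correlation matrices: validation, block fixtures, PSD repair.

#' Validate a gene correlation matrix
#'
#' Checks symmetry (within 1e-8), a unit diagonal (within 1e-8) and finiteness,
#' and attaches gene identifiers as dimnames.
#'
#' @param sigma K x K numeric matrix of pairwise gene expression correlations.
#' @param gene_ids optional character vector of gene identifiers; defaults to
#'   existing rownames or `g1..gK`.
#' @return the validated matrix with gene ids as dimnames.
#' @export
as_correlation_matrix <- function(sigma, gene_ids = NULL) {
  if (!is_square_matrix(sigma)) stopf("sigma must be a square matrix")
  if (!all(is.finite(sigma))) stopf("sigma contains non-finite entries")
  if (max(abs(sigma - t(sigma))) > 1e-8) stopf("sigma is not symmetric (tolerance 1e-8)")
  if (max(abs(diag(sigma) - 1)) > 1e-8) stopf("sigma diagonal must be 1 (tolerance 1e-8)")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(sigma)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(sigma)))
  }
  if (length(gene_ids) != nrow(sigma)) stopf("gene_ids length does not match sigma dimension")
  if (anyDuplicated(gene_ids)) stopf("gene_ids must be unique")
  sigma <- (sigma + t(sigma)) / 2
  diag(sigma) <- 1
  dimnames(sigma) <- list(gene_ids, gene_ids)
  sigma
}

#' Block-diagonal equicorrelation matrix
#'
#' Builds the synthetic module correlation structure used throughout the
#' simulation framework: genes fall into blocks with a common within-block
#' correlation and a common (usually zero) between-block correlation.
#'
#' @param block_sizes integer vector of block sizes; the module size K is
#'   their sum.
#' @param rho_within within-block correlation, in `[0, 1)`.
#' @param rho_between between-block correlation (default 0).
#' @param gene_ids optional gene identifiers.
#' @return a K x K correlation matrix.
#' @export
#' @examples
#' make_block_sigma(c(2, 2), rho_within = 0.8)
make_block_sigma <- function(block_sizes, rho_within, rho_between = 0, gene_ids = NULL) {
  if (any(block_sizes < 1)) stopf("block sizes must be >= 1")
  if (rho_within < 0 || rho_within >= 1) stopf("rho_within must be in [0, 1)")
  k <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  sigma <- matrix(rho_between, k, k)
  for (b in seq_along(block_sizes)) {
    idx <- which(block == b)
    sigma[idx, idx] <- rho_within
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stopf("rho choices yield a non-positive-semidefinite matrix")
  as_correlation_matrix(sigma, gene_ids)
}

#' Factor-model correlation matrix with a smoothly decaying spectrum
#'
#' Builds `cor(L L' + D)` for random factor loadings `L` (K x n_factors)
#' and uniquenesses `D`. Unlike equicorrelated blocks, whose repeated
#' eigenvalues leave eigenvectors unidentifiable, this resembles the
#' smoothly decaying spectra of real co-expression modules and is the
#' preferred fixture when estimation noise interacts with the
#' eigenstructure.
#'
#' @param n_genes module size K.
#' @param n_factors number of latent factors (default 4).
#' @param seed integer seed; the matrix is deterministic given it.
#' @param gene_ids optional gene identifiers.
#' @return a K x K correlation matrix.
#' @export
make_factor_sigma <- function(n_genes, n_factors = 4, seed = 1L, gene_ids = NULL) {
  S <- with_seed(seed, {
    L <- matrix(stats::rnorm(n_genes * n_factors), n_genes) %*%
      diag(seq(2, 0.7, length.out = n_factors), n_factors)
    tcrossprod(L) + diag(stats::runif(n_genes, 0.5, 2))
  })
  as_correlation_matrix(stats::cov2cor(S), gene_ids)
}

#' Repair a nearly-degenerate correlation matrix
#'
#' Clips eigenvalues at `floor`, reconstructs, and rescales to a unit
#' diagonal. Used on correlation matrices estimated from finite null-SNP
#' panels, which can be rank-deficient.
#'
#' @param sigma symmetric matrix with unit diagonal (approximately).
#' @param floor eigenvalue floor (default 1e-6).
#' @return a valid positive-definite correlation matrix.
#' @export
psd_repair <- function(sigma, floor = 1e-6) {
  if (!is_square_matrix(sigma)) stopf("sigma must be a square matrix")
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) >= floor) {
    diag(sigma) <- 1
    return(as_correlation_matrix(sigma, rownames(sigma)))
  }
  v <- pmax(e$values, floor)
  rep <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(rep))
  rep <- rep / tcrossprod(d)
  diag(rep) <- 1
  dimnames(rep) <- dimnames(sigma)
  as_correlation_matrix(rep, rownames(sigma))
}
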