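# Expression preprocessing: TPM, quantile + inverse-normal normalisation,
# covariate residualisation, gene/genotype QC filters.

.BIOTYPES <- c("protein_coding", "lincRNA", "pseudogene", "miRNA", "snoRNA",
               "antisense", "snRNA", "rRNA", "misc_RNA", "other")

#' @noRd
expr_stage <- function(x) attr(x, "stage") %||% "unknown"

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
set_stage <- function(x, stage) { attr(x, "stage") <- stage; x }

#' @noRd
check_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("expression must be a numeric matrix (samples x genes)")
  if (is.null(rownames(x)) || is.null(colnames(x))) stopf("expression needs sample rownames and gene colnames")
  invisible(x)
}

#' TPM normalisation
#'
#' Converts a count matrix to transcripts per million: per sample, each
#' gene's length-normalised read rate is scaled so rates sum to one million.
#'
#' @param counts samples x genes count matrix (sample rownames, gene
#'   colnames).
#' @param gene_lengths per-gene lengths in bp, named by or ordered as the
#'   columns of `counts`.
#' @return TPM matrix with stage attribute `"tpm"`; every row sums to 1e6.
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  check_expression(counts)
  if (!is.null(names(gene_lengths))) gene_lengths <- gene_lengths[colnames(counts)]
  if (length(gene_lengths) != ncol(counts)) stopf("gene_lengths must cover every gene")
  if (any(!is.finite(gene_lengths) | gene_lengths <= 0)) stopf("gene lengths must be positive")
  rate <- sweep(counts, 2, gene_lengths, "/")
  tot <- rowSums(rate)
  if (any(tot <= 0)) stopf("zero total expression rate in sample(s): %s",
                           paste(rownames(counts)[tot <= 0], collapse = ", "))
  set_stage(rate / tot * 1e6, "tpm")
}

#' Quantile normalisation followed by an inverse-normal transform
#'
#' Step 1 equalises every sample's empirical distribution to the mean
#' quantile profile across samples. Step 2 maps each gene column to
#' `qnorm((rank - 0.5) / N)` with average ranks for ties, so every gene is
#' exactly standard-normal in rank.
#'
#' @param x samples x genes expression matrix (typically TPM).
#' @return normalised matrix, stage `"normalized"`; genes constant after
#'   step 1 are dropped with a warning.
#' @export
quantile_then_inverse_normal <- function(x) {
  check_expression(x)
  if (nrow(x) < 2) stopf("need at least 2 samples")
  qn <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  const <- apply(qn, 2, function(v) stats::sd(v) < 1e-12)
  if (any(const)) {
    warnf("dropping %d constant gene(s) after quantile normalisation: %s",
          sum(const), paste(utils::head(colnames(qn)[const], 5), collapse = ", "))
    qn <- qn[, !const, drop = FALSE]
  }
  n <- nrow(qn)
  out <- apply(qn, 2, function(v) stats::qnorm((rank(v, ties.method = "average") - 0.5) / n))
  dimnames(out) <- dimnames(qn)
  set_stage(out, "normalized")
}

#' Regress covariates out of expression
#'
#' Removes known biological and technical covariates (genotype PCs,
#' expression PCs, cell-type proportions, batch, ...) from every gene by
#' least squares, with an implicit intercept. Module detection and testing
#' then operate on the residuals so co-expression is not driven by
#' confounders.
#'
#' @param x samples x genes normalised expression matrix.
#' @param covariates samples x C numeric matrix (sample rownames matching
#'   `x`), or NULL for intercept-only (centering).
#' @return residual matrix, stage `"residual"`.
#' @export
regress_out_covariates <- function(x, covariates = NULL) {
  check_expression(x)
  if (is.null(covariates)) {
    res <- scale(x, center = TRUE, scale = FALSE)
    attr(res, "scaled:center") <- NULL
    return(set_stage(res, "residual"))
  }
  if (!is.matrix(covariates)) covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(x)) stopf("covariates and expression have different sample counts")
  if (!is.null(rownames(covariates)) &&
      !identical(rownames(covariates), rownames(x)))
    stopf("covariate sample order does not match expression")
  if (nrow(x) <= ncol(covariates) + 1) stopf("need more samples than covariates")
  design <- cbind(`(Intercept)` = 1, covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stopf("rank-deficient covariates; collinear column(s): %s", paste(bad, collapse = ", "))
  }
  res <- stats::lm.fit(design, x)$residuals
  dimnames(res) <- dimnames(x)
  set_stage(res, "residual")
}

#' Gene-level mappability and biotype filter
#'
#' Keeps genes whose biotype is in the allowed set and whose gene-level
#' mappability score is at least `min_mappability`. Low-mappability genes
#' attract multi-mapping reads and generate spurious expression correlation
#' with their homologs, which is a major source of false-positive trans
#' associations.
#'
#' @param annotation data.frame with columns gene_id, chrom, start, end,
#'   biotype, mappability (see [read_annotation()]).
#' @param allowed_biotypes biotypes to keep (default protein_coding and
#'   lincRNA).
#' @param min_mappability minimum gene mappability in `[0, 1]` (default 1,
#'   i.e. only uniquely-mappable genes).
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(annotation,
                         allowed_biotypes = c("protein_coding", "lincRNA"),
                         min_mappability = 1.0) {
  check_annotation(annotation)
  unknown <- !(annotation$biotype %in% .BIOTYPES)
  if (any(unknown)) {
    warnf("excluding %d gene(s) with unknown biotype: %s", sum(unknown),
          paste(unique(annotation$biotype[unknown]), collapse = ", "))
  }
  keep <- !unknown &
    annotation$biotype %in% allowed_biotypes &
    annotation$mappability >= min_mappability
  annotation$gene_id[keep]
}

#' Genotype quality control
#'
#' Drops SNPs failing any of: call rate > 0.99, minor allele frequency
#' > 0.05, Hardy-Weinberg equilibrium p >= 1e-6. HWE uses the exact test on
#' rounded hard calls for up to 1000 samples and the chi-square test beyond.
#'
#' @param genotypes a genotype object (see [genotype_matrix()]) or a plain
#'   samples x SNPs dosage matrix in `[0, 2]` with NA for missing.
#' @param min_call_rate,min_maf,hwe_p QC thresholds.
#' @return the filtered genotype object, with a `qc_report` attribute
#'   counting SNPs dropped per criterion.
#' @export
genotype_qc <- function(genotypes, min_call_rate = 0.99, min_maf = 0.05,
                        hwe_p = 1e-6) {
  g <- as_genotypes(genotypes)
  D <- g$dosages
  if (any(D < -1e-9 | D > 2 + 1e-9, na.rm = TRUE)) stopf("dosages must lie in [0, 2]")
  call_rate <- colMeans(!is.na(D))
  p_alt <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hard <- round(D)
  hwe <- vapply(seq_len(ncol(D)), function(j) {
    x <- hard[!is.na(hard[, j]), j]
    hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  fail_call <- call_rate <= min_call_rate
  fail_maf <- maf <= min_maf
  fail_hwe <- hwe < hwe_p
  drop <- fail_call | fail_maf | fail_hwe
  report <- c(n_input = ncol(D), n_kept = sum(!drop),
              dropped_call_rate = sum(fail_call),
              dropped_maf = sum(fail_maf), dropped_hwe = sum(fail_hwe))
  if (all(drop)) {
    stopf("all SNPs dropped by QC (call rate: %d, MAF: %d, HWE: %d)",
          sum(fail_call), sum(fail_maf), sum(fail_hwe))
  }
  out <- genotype_matrix(D[, !drop, drop = FALSE], g$snps[!drop, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

# Exact Hardy-Weinberg test (conditional on allele counts) for modest sample
# sizes, chi-square approximation otherwise.
#' @noRd
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  if (n <= 1000) return(hwe_exact(n_aa, n_ab, n_bb))
  p <- (2 * n_aa + n_ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_aa, n_ab, n_bb)
  if (any(e == 0)) return(1)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

#' @noRd
hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab          # rarer allele re-oriented below
  if (n_a > n) {
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_a <- 2 * n_aa + n_ab
  }
  # enumerate heterozygote counts with the parity of n_a;
  # P(het | n_a) = n! / (naa! nab! nbb!) * 2^nab / C(2n, n_a)
  het <- seq(n_a %% 2, n_a, by = 2)
  naa <- (n_a - het) / 2
  nbb <- n - naa - het
  lp <- lgamma(n + 1) - lgamma(naa + 1) - lgamma(het + 1) - lgamma(nbb + 1) +
    het * log(2) - lchoose(2 * n, n_a)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, het)]
  if (is.na(obs)) return(1)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}
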