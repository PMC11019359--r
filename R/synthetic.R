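# Synthetic cohort fixtures: genotypes, expression with planted trans
# effects, annotation and cross-mappability tables. Everything is
# regenerable bit-identically from a seed, so no stored fixtures are needed.

#' Deterministic gene annotation and cross-mappability table
#'
#' Genes are laid out on the given chromosomes in order, spaced `spacing_bp`
#' apart with span `gene_length_bp`. Biotypes and mappability scores can be
#' set per gene; cross-mappability pairs get their symmetric closure.
#'
#' @param genes character vector of gene ids (unique).
#' @param chroms chromosome per gene (recycled).
#' @param crossmap_pairs optional data.frame (gene_a, gene_b).
#' @param biotype per-gene biotype (recycled; default protein_coding).
#' @param mappability per-gene score in `[0, 1]` (recycled; default 1).
#' @param spacing_bp,gene_length_bp layout parameters.
#' @return list with `annotation` (data.frame) and `crossmap` (data.frame
#'   or NULL).
#' @export
make_annotation_and_crossmap <- function(genes, chroms,
                                         crossmap_pairs = NULL,
                                         biotype = "protein_coding",
                                         mappability = 1,
                                         spacing_bp = 1e6,
                                         gene_length_bp = 2e4) {
  if (anyDuplicated(genes)) stopf("overlapping gene ids in annotation request")
  chroms <- rep_len(as.character(chroms), length(genes))
  biotype <- rep_len(biotype, length(genes))
  mappability <- rep_len(mappability, length(genes))
  ann <- do.call(rbind, lapply(split(seq_along(genes), chroms), function(idx) {
    k <- seq_along(idx)
    data.frame(gene_id = genes[idx], chrom = chroms[idx][1],
               start = 1 + (k - 1) * spacing_bp,
               end = (k - 1) * spacing_bp + gene_length_bp,
               biotype = biotype[idx], mappability = mappability[idx])
  }))
  ann <- ann[match(genes, ann$gene_id), ]
  rownames(ann) <- NULL
  cm <- NULL
  if (!is.null(crossmap_pairs)) {
    cm <- as.data.frame(crossmap_pairs)
    names(cm)[1:2] <- c("gene_a", "gene_b")
    if (any(cm$gene_a == cm$gene_b)) stopf("cross-mappability self-pairs are not allowed")
    cm <- unique(rbind(cm[, c("gene_a", "gene_b")],
                       data.frame(gene_a = cm$gene_b, gene_b = cm$gene_a)))
    rownames(cm) <- NULL
  }
  list(annotation = check_annotation(ann), crossmap = cm)
}

#' Generate a synthetic cohort with planted trans effects
#'
#' Dosages are Hardy-Weinberg `Binomial(2, maf)` draws (optionally with
#' AR(1)-correlated adjacent SNPs to support LD-clumping tests); expression
#' is `G B + E` with rows of `E ~ N(0, Sigma)`, so a planted effect `beta`
#' explains `beta^2 2 maf (1 - maf)` variance of its gene.
#'
#' @param n_samples cohort size.
#' @param sigma gene correlation matrix (defines genes and their noise
#'   covariance).
#' @param snp_count number of SNPs.
#' @param planted optional data.frame (snp, gene, beta) of trans effects;
#'   `snp` indexes or names SNPs, `gene` names genes.
#' @param maf_range minor allele frequency range (default 0.05-0.5).
#' @param gene_chroms chromosomes for genes (recycled; default chr1/chr2).
#' @param snp_chrom chromosome for SNPs (default chr3, i.e. trans to all
#'   genes).
#' @param ld_rho AR(1) correlation between adjacent SNP latent draws
#'   (default 0, independent SNPs).
#' @param seed integer seed.
#' @return a `cohort_fixture` list: genotypes, expression (stage residual),
#'   annotation, planted effects, seed.
#' @export
generate_cohort <- function(n_samples, sigma, snp_count, planted = NULL,
                            maf_range = c(0.05, 0.5),
                            gene_chroms = c("chr1", "chr2"),
                            snp_chrom = "chr3", ld_rho = 0, seed = 1L) {
  sigma <- as_correlation_matrix(sigma, rownames(sigma))
  genes <- rownames(sigma)
  K <- length(genes)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  ann <- make_annotation_and_crossmap(genes, gene_chroms)$annotation
  out <- with_seed(seed, {
    maf <- stats::runif(snp_count, maf_range[1], maf_range[2])
    if (ld_rho > 0) {
      # latent AR(1) gaussians thresholded to Hardy-Weinberg genotypes
      L1 <- matrix(stats::rnorm(n_samples * snp_count), n_samples, snp_count)
      L2 <- matrix(stats::rnorm(n_samples * snp_count), n_samples, snp_count)
      for (j in 2:snp_count) {
        L1[, j] <- ld_rho * L1[, j - 1] + sqrt(1 - ld_rho^2) * L1[, j]
        L2[, j] <- ld_rho * L2[, j - 1] + sqrt(1 - ld_rho^2) * L2[, j]
      }
      thr <- stats::qnorm(rep(maf, each = n_samples))
      D <- (L1 < thr) + (L2 < thr)
      D <- matrix(as.numeric(D), n_samples, snp_count)
    } else {
      D <- matrix(stats::rbinom(n_samples * snp_count, 2, rep(maf, each = n_samples)),
                  n_samples, snp_count)
    }
    # guard the (improbable) monomorphic column
    for (j in which(apply(D, 2, stats::sd) < 1e-12)) {
      D[seq_len(2), j] <- c(1, 2)
    }
    E <- matrix(stats::rnorm(n_samples * K), n_samples, K) %*% chol(sigma)
    list(D = D, E = E, maf = maf)
  })
  snps <- data.frame(snp_id = sprintf("rs%04d", seq_len(snp_count)),
                     chrom = snp_chrom, pos = 1e4 + (seq_len(snp_count) - 1) * 5e4)
  X <- out$E
  colnames(X) <- genes
  rownames(X) <- rownames(out$D) <- sprintf("sample%03d", seq_len(n_samples))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    sj_all <- if (is.numeric(planted$snp)) as.integer(planted$snp)
              else match(as.character(planted$snp), snps$snp_id)
    gj_all <- match(as.character(planted$gene), genes)
    if (anyNA(sj_all) || anyNA(gj_all)) stopf("planted effects refer to unknown SNP or gene")
    for (i in seq_len(nrow(planted))) {
      X[, gj_all[i]] <- X[, gj_all[i]] + planted$beta[i] * out$D[, sj_all[i]]
    }
    planted$snp <- snps$snp_id[sj_all]
  }
  structure(
    list(genotypes = genotype_matrix(out$D, snps),
         expression = set_stage(X, "residual"),
         annotation = ann, maf = out$maf,
         planted = planted, seed = seed),
    class = "cohort_fixture"
  )
}

#' @export
print.cohort_fixture <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d SNPs, %d genes, %d planted effect(s)\n",
              nrow(x$expression), ncol(x$genotypes$dosages), ncol(x$expression),
              if (is.null(x$planted)) 0L else nrow(x$planted)))
  invisible(x)
}
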