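mk_expr <- function(m, samples = NULL, genes = NULL) {
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- genes %||% paste0("g", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TPM normalisation conserves per-sample totals", {
  counts <- mk_expr(matrix(c(10, 20), 1, 2))
  tpm <- tpm_normalize(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[1, ]), c(5e5, 5e5))

  one <- mk_expr(matrix(7, 1, 1))
  expect_equal(unname(tpm_normalize(one, 500)[1, 1]), 1e6)

  set.seed(3)
  counts <- mk_expr(matrix(rpois(20, 50), 5, 4))
  tpm <- tpm_normalize(counts, runif(4, 200, 5000))
  expect_equal(unname(rowSums(tpm)), rep(1e6, 5), tolerance = 1e-6)

  zero <- mk_expr(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE))
  expect_error(tpm_normalize(zero, c(1000, 1000)), "s1")
})

test_that("quantile + inverse-normal normalisation has standard-normal gene margins", {
  set.seed(4)
  # many genes relative to samples, as in RNA-seq: rank ties are rare
  x <- mk_expr(matrix(rexp(100 * 1500), 100, 1500))
  nx <- quantile_then_inverse_normal(x)
  expect_equal(unname(colMeans(nx)), rep(0, 1500), tolerance = 1e-3)
  v <- apply(nx, 2, var)
  expect_equal(unname(v), rep(1, 1500), tolerance = 0.05)
  expect_equal(mean(nx^3), 0, tolerance = 1e-3)   # symmetric margins

  # two samples that are permutations of each other share sorted values after step 1
  y <- mk_expr(rbind(c(5, 1, 3, 2), c(2, 3, 1, 5)))
  qy <- t(limma::normalizeQuantiles(t(y), ties = TRUE))
  expect_equal(unname(sort(qy[1, ])), unname(sort(qy[2, ])))

  # N = 4 closed-form quantiles: a Latin square keeps the quantile step an
  # identity (every sample has the same value multiset) and gene columns
  # tie-free, exposing the exact inverse-normal grid
  lat <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 1), c(3, 4, 1, 2), c(4, 1, 2, 3))
  n4 <- quantile_then_inverse_normal(mk_expr(lat))
  for (j in 1:4) {
    expect_equal(unname(sort(n4[, j])), qnorm(c(0.125, 0.375, 0.625, 0.875)),
                 tolerance = 1e-9)
  }

  # renormalising keeps every gene on (nearly) the same grid and ranks
  nx2 <- quantile_then_inverse_normal(nx)
  expect_true(all(diag(cor(nx2, nx)) > 0.99))
})

test_that("covariate regression removes exactly the modelled structure", {
  set.seed(5)
  n <- 500
  x <- mk_expr(matrix(rnorm(n * 3), n, 3))
  centered <- regress_out_covariates(x, NULL)
  expect_equal(unname(centered), unname(scale(x, scale = FALSE)), ignore_attr = TRUE)

  cov1 <- matrix(rnorm(n), n, 1, dimnames = list(rownames(x), "c1"))
  xx <- x; xx[, 2] <- cov1[, 1]
  res <- regress_out_covariates(xx, cov1)
  expect_lt(max(abs(res[, 2])), 1e-10)
  expect_lt(max(abs(crossprod(cov1, res))), 1e-8)

  e <- rnorm(n)
  xx[, 3] <- 2 * cov1[, 1] + e
  res <- regress_out_covariates(xx, cov1)
  expect_gt(cor(res[, 3], e), 0.99)

  expect_error(regress_out_covariates(x, cbind(cov1, c2 = 2 * cov1[, 1])), "collinear")
})

test_that("residualisation preserves covariate-free gene-gene correlation", {
  set.seed(6)
  n <- 400
  sigma <- make_block_sigma(c(5, 5), 0.6)
  E <- matrix(rnorm(n * 10), n) %*% chol(sigma)
  shared <- rnorm(n)
  x <- mk_expr(E + outer(shared, rep(1.5, 10)))
  res <- regress_out_covariates(x, matrix(shared, n, 1, dimnames = list(rownames(x), "c")))
  expect_equal(cor(res)[1, 2], 0.6, tolerance = 0.1)
  expect_equal(cor(res)[1, 6], 0, tolerance = 0.12)
})

test_that("biotype and mappability filters apply both rules", {
  ann <- make_annotation_and_crossmap(
    genes = c("proteinA", "pseudoB", "lincC"), chroms = "chr1",
    biotype = c("protein_coding", "pseudogene", "lincRNA"),
    mappability = c(1, 1, 0.8))$annotation
  expect_equal(filter_genes(ann), "proteinA")
  expect_equal(filter_genes(ann, character(0)), character(0))
  expect_setequal(filter_genes(ann, min_mappability = 0.8), c("proteinA", "lincC"))
  ann$biotype[2] <- "mystery_type"
  expect_warning(out <- filter_genes(ann, min_mappability = 0), "unknown biotype")
  expect_setequal(out, c("proteinA", "lincC"))
})

test_that("genotype QC applies call-rate, MAF and HWE rules", {
  # exact HWE proportions at MAF 0.10: kept
  d_ok <- c(rep(0, 810), rep(1, 180), rep(2, 10))
  # MAF 0.04: dropped
  d_maf <- c(rep(0, 920), rep(1, 80), rep(2, 0))
  # 2% missing: dropped by call rate
  d_miss <- d_ok; d_miss[1:20] <- NA
  # HWE catastrophically violated: all heterozygotes
  d_hwe <- rep(1, 1000)
  D <- cbind(ok = d_ok, maf = d_maf, miss = d_miss, hwe = d_hwe)
  rownames(D) <- paste0("s", 1:1000)
  g <- genotype_matrix(D, data.frame(snp_id = colnames(D), chrom = "chr1",
                                     pos = 1:4))
  out <- genotype_qc(g)
  expect_equal(colnames(out$dosages), "ok")
  rep <- attr(out, "qc_report")
  expect_equal(unname(rep[c("dropped_maf", "dropped_call_rate", "dropped_hwe")]),
               c(1, 1, 1))
  expect_error(genotype_qc(genotype_matrix(D[, 2, drop = FALSE],
                                           data.frame(snp_id = "maf", chrom = "chr1", pos = 1))),
               "all SNPs dropped")
})

test_that("exact HWE test agrees with the chi-square test at large counts", {
  # balanced case: both tests near 1
  expect_gt(transpco:::hwe_exact(810, 180, 10), 0.5)
  # compare exact and chi-square on moderate deviation
  p_ex <- transpco:::hwe_exact(300, 500, 200)
  p_ch <- {
    n <- 1000; p <- (2 * 300 + 500) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    pchisq(sum((c(300, 500, 200) - e)^2 / e), 1, lower.tail = FALSE)
  }
  expect_equal(p_ex, p_ch, tolerance = 0.25)
  expect_lt(transpco:::hwe_exact(500, 0, 500), 1e-100)
})

test_that("module detection recovers planted blocks and respects the size floor", {
  set.seed(7)
  sigma <- make_block_sigma(c(15, 15), 0.8)
  x <- mk_expr(matrix(rnorm(300 * 30), 300) %*% chol(sigma))
  mods <- detect_coexpression_modules(x)
  expect_length(mods, 2)
  expect_setequal(mods[[1]]$gene_ids, colnames(x)[1:15])
  expect_setequal(mods[[2]]$gene_ids, colnames(x)[16:30])

  xi <- mk_expr(matrix(rnorm(300 * 30), 300))
  expect_length(detect_coexpression_modules(xi), 0)

  set.seed(8)
  s9 <- make_block_sigma(9, 0.8)
  x9 <- mk_expr(matrix(rnorm(300 * 9), 300) %*% chol(s9))
  expect_error(detect_coexpression_modules(x9), "fewer genes")
  expect_length(detect_coexpression_modules(x9, on_too_few = "single"), 1)
})

test_that("module detection is permutation-equivariant", {
  set.seed(9)
  sigma <- make_block_sigma(c(12, 12), 0.8)
  x <- mk_expr(matrix(rnorm(250 * 24), 250) %*% chol(sigma))
  perm <- sample(ncol(x))
  mods_a <- detect_coexpression_modules(x)
  mods_b <- detect_coexpression_modules(x[, perm])
  sets_a <- lapply(mods_a, function(m) sort(m$gene_ids))
  sets_b <- lapply(mods_b, function(m) sort(m$gene_ids))
  expect_setequal(vapply(sets_a, paste, "", collapse = ","),
                  vapply(sets_b, paste, "", collapse = ","))
})

test_that("GMT import validates, deduplicates, and drops unannotated genes", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tgA\tgB\tgC",
               "setB\tdesc\tgA\tgB\tgC\tgD",
               "setC\tdesc\tgB\tgB",
               "setD\tdesc\tzz1\tzz2"), path)
  ann <- make_annotation_and_crossmap(c("gA", "gB", "gC", "gD"), "chr1")$annotation
  expect_warning(expect_warning(
    mods <- load_gene_sets(path, ann), "duplicated"), "no annotated genes")
  expect_setequal(names(mods), c("setA", "setB", "setC"))
  expect_length(mods$setA$gene_ids, 3)
  expect_length(mods$setB$gene_ids, 4)
  expect_equal(mods$setC$gene_ids, "gB")
  expect_equal(mods$setA$provenance, "gene_set")

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tgA", "broken_line_only_name"), bad)
  expect_error(load_gene_sets(bad), "line 2")
})
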