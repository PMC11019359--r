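mk_zpanel <- function(Z, chrom = NA_character_, pos = NA_integer_) {
  sn <- paste0("s", seq_len(nrow(Z)))
  rownames(Z) <- sn
  structure(list(Z = Z, snps = data.frame(snp_id = sn, chrom = chrom, pos = pos),
                 gene_ids = colnames(Z), n = NA_integer_), class = "zpanel")
}

test_that("null-SNP selection excludes any SNP significant on any module gene", {
  sigma <- make_block_sigma(4, 0.3)
  zp <- simulate_null_z(sigma, 200, seed = 1)
  mod <- gene_module("M", rownames(sigma), "gene_set")
  zp$Z[5, 2] <- 8
  sel <- select_null_snps(zp, mod)
  expect_false("s5" %in% sel)
  expect_equal(select_null_snps(zp, mod, abs_z_max = Inf), zp$snps$snp_id)
  # retention rate matches the binomial expectation under the null
  keep_rate <- length(select_null_snps(zp, mod)) / 200
  p_keep <- (1 - 0.05)^4   # approximately, for weakly correlated genes
  expect_equal(keep_rate, p_keep, tolerance = 0.12)
})

test_that("sigma estimation is consistent and gated by the SNP-to-gene ratio", {
  sigma <- make_block_sigma(c(10, 10), 0.5)
  zp <- simulate_null_z(sigma, 10000, seed = 2)
  mod <- gene_module("M", rownames(sigma), "gene_set")
  est <- estimate_sigma(zp, mod)
  expect_true(est$gated)
  rel_frob <- norm(est$sigma - sigma, "F") / norm(sigma, "F")
  expect_lt(rel_frob, 0.05)

  # 4000 null SNPs for 101 genes: ratio < 50, excluded
  s101 <- make_block_sigma(c(50, 51), 0.3)
  zp101 <- simulate_null_z(s101, 4000, seed = 3)
  est101 <- estimate_sigma(zp101, gene_module("M", rownames(s101), "gene_set"))
  expect_equal(est101$ratio, 4000 / 101, tolerance = 1e-12)
  expect_false(est101$gated)

  # two identical rows: degenerate estimate repaired to a valid matrix
  zdeg <- mk_zpanel(rbind(c(1, 2, 0.5), c(1, 2, 0.5)),
                    chrom = "chr9", pos = c(1, 2))
  colnames(zdeg$Z) <- paste0("g", 1:3)
  zdeg$gene_ids <- colnames(zdeg$Z)
  est_deg <- estimate_sigma(zdeg, gene_module("M", colnames(zdeg$Z), "gene_set"),
                            min_ratio = 0)
  ev <- eigen(est_deg$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= 0)
  expect_equal(unname(diag(est_deg$sigma)), rep(1, 3))
  expect_error(estimate_sigma(mk_zpanel(matrix(1, 1, 2)), gene_module("M", 1:2)),
               "at least 2")
})

test_that("cross-mappability exclusion removes homolog partners of cis genes", {
  ann <- rbind(
    make_annotation_and_crossmap("cisA", "chr1", spacing_bp = 1,
                                 gene_length_bp = 10000)$annotation,
    make_annotation_and_crossmap(c("gB", "gC"), c("chr5", "chr7"))$annotation)
  ann$start[1] <- 450000; ann$end[1] <- 460000
  cm <- data.frame(gene_a = "cisA", gene_b = "gB")
  cm <- rbind(cm, data.frame(gene_a = "gB", gene_b = "cisA"))
  mod <- gene_module("M", c("gB", "gC"), "gene_set")
  snp <- data.frame(chrom = "chr1", pos = 500000)
  red <- crossmap_exclude(snp, mod, ann, cm)
  expect_equal(red$gene_ids, "gC")

  # no cis genes in window: module unchanged (minus same-chromosome genes)
  far <- data.frame(chrom = "chr1", pos = 5e7)
  expect_setequal(crossmap_exclude(far, mod, ann, cm)$gene_ids, c("gB", "gC"))

  # closed-interval boundary: gene ending exactly at pos - 100000 is cis
  edge <- data.frame(chrom = "chr1", pos = ann$end[1] + 100000)
  expect_equal(crossmap_exclude(edge, mod, ann, cm)$gene_ids, "gC")
  just_out <- data.frame(chrom = "chr1", pos = ann$end[1] + 100001)
  expect_setequal(crossmap_exclude(just_out, mod, ann, cm)$gene_ids, c("gB", "gC"))
})

test_that("summary-statistics scan finds a planted signal and reports gating", {
  sigma <- make_block_sigma(c(8, 8), 0.5)
  genes <- rownames(sigma)
  ann <- make_annotation_and_crossmap(genes, c("chr1", "chr2"))$annotation
  mod <- list(gene_module("M1", genes, "gene_set"))
  zp <- simulate_null_z(sigma, 2500, seed = 5)
  zp$snps$chrom <- "chr9"; zp$snps$pos <- seq_len(2500)
  zp$Z[100, 1:6] <- zp$Z[100, 1:6] + 5   # planted multi-gene signal
  res <- sumstats_scan(zp, mod, ann, seed = 5)
  expect_equal(res$snp_id[which.min(res$p_pco)], "s100")
  expect_true(res$significant[which.min(res$p_pco)])
  gat <- attr(res, "gating")
  expect_true(gat$gated[1])
  expect_gt(gat$ratio[1], 50)

  # ungated module: error when nothing is scannable
  zp_small <- simulate_null_z(sigma, 300, seed = 6)
  zp_small$snps$chrom <- "chr9"; zp_small$snps$pos <- seq_len(300)
  expect_error(sumstats_scan(zp_small, mod, ann, seed = 6), "ratio gate")
})

test_that("estimated-sigma scans converge to true-sigma scans as the ratio grows", {
  # generic correlation with distinct eigenvalues (degenerate equicorrelated
  # blocks leave eigenvectors unidentifiable, which no estimator can fix)
  set.seed(3)
  L <- matrix(rnorm(12 * 3), 12)
  sigma <- as_correlation_matrix(cov2cor(tcrossprod(L) + diag(runif(12, 0.5, 2))),
                                 paste0("g", 1:12))
  mod <- gene_module("M1", rownames(sigma), "gene_set")
  model_t <- pco_model(sigma)
  ct <- pco_calibrate(model_t, draws = 5e4, seed = 8)
  cfg <- simulation_config(n = 500, gamma = 0.4, sigma_b2 = 0.003,
                           n_snps = 400, n_reps = 1, seed = 9)
  alt <- simulate_alt_z(sigma, cfg)
  pt <- pco_test_panel(alt$zpanel$Z, model_t, ct)$p_pco
  frac <- vapply(c(100, 600), function(ratio) {
    big <- simulate_null_z(sigma, 12 * ratio, seed = 7)
    est <- estimate_sigma(big, mod, min_ratio = 50)
    expect_true(est$gated)
    ce <- pco_calibrate(pco_model(est$sigma), draws = 5e4, seed = 8)
    pe <- pco_test_panel(alt$zpanel$Z, pco_model(est$sigma), ce)$p_pco
    sel <- pt <= 0.01
    mean(abs(log10(pe[sel]) - log10(pt[sel])) / abs(log10(pt[sel])) < 0.10)
  }, numeric(1))
  expect_gt(frac[2], frac[1] - 0.05)   # agreement non-decreasing in ratio
  expect_gte(frac[1], 0.60)
  expect_gte(frac[2], 0.80)
})
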