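test_that("univariate Z scores match the r-to-Z closed form and null moments", {
  # closed form: r = 0.1, n = 500
  n <- 500
  r <- 0.1
  tt <- r * sqrt((n - 2) / (1 - r^2))
  z_expected <- qnorm(pt(tt, n - 2, lower.tail = FALSE), lower.tail = FALSE)
  expect_equal(z_expected, 2.24, tolerance = 0.01)
  set.seed(21)
  # null calibration over many SNP-gene pairs
  D <- matrix(rbinom(n * 100, 2, 0.3), n, 100,
              dimnames = list(paste0("s", 1:n), paste0("snp", 1:100)))
  X <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:100)))
  g <- genotype_matrix(D, data.frame(snp_id = colnames(D), chrom = "chr1",
                                     pos = seq_len(100)))
  zp <- univariate_zscores(g, X)
  expect_equal(mean(zp$Z), 0, tolerance = 3 * sqrt(1 / 1e4))
  expect_equal(var(as.vector(zp$Z)), 1, tolerance = 3 * sqrt(2 / 1e4))

  # perfect correlation is capped, not infinite
  Xp <- X; Xp[, 1] <- D[, 1]
  zp2 <- univariate_zscores(g, Xp)
  expect_true(is.finite(zp2$Z[1, 1]) && zp2$Z[1, 1] > 30)

  # monomorphic SNP excluded with a warning
  Dm <- D; Dm[, 2] <- 0
  gm <- genotype_matrix(Dm, g$snps)
  expect_warning(zpm <- univariate_zscores(gm, X), "monomorphic")
  expect_equal(nrow(zpm$Z), 99)
})

test_that("same-chromosome exclusion drives per-SNP module reduction", {
  sigma <- make_block_sigma(3, 0.4, gene_ids = c("g1", "g2", "g3"))
  ann <- make_annotation_and_crossmap(c("g1", "g2", "g3"),
                                      c("chr1", "chr2", "chr2"))$annotation
  mod <- gene_module("M1", c("g1", "g2", "g3"), "gene_set")
  Z <- matrix(rnorm(3), 1, 3, dimnames = list("rs1", c("g1", "g2", "g3")))
  zp <- structure(list(Z = Z, snps = data.frame(snp_id = "rs1", chrom = "chr1",
                                                pos = 100), gene_ids = colnames(Z), n = 100),
                  class = "zpanel")
  r <- test_snp_module("rs1", mod, zp, sigma, ann, calib_draws = 5000)
  expect_equal(r$n_genes_tested, 2)   # g1 on chr1 excluded

  # module entirely on the SNP's chromosome: skipped
  ann_all1 <- make_annotation_and_crossmap(c("g1", "g2", "g3"), "chr1")$annotation
  expect_message(r2 <- test_snp_module("rs1", mod, zp, sigma, ann_all1,
                                       calib_draws = 5000), "skipped")
  expect_null(r2)
})

test_that("a planted multi-gene signal is overwhelmingly significant", {
  # 30% of 50 genes with sqrt(n) sigma_b scale effects at n = 500
  sigma <- make_block_sigma(c(25, 25), 0.5)
  model <- pco_model(sigma)
  calib <- pco_calibrate(model, draws = 2e4, seed = 31)
  set.seed(32)
  hits <- 0
  for (rep in 1:50) {
    beta <- numeric(50)
    idx <- sample(50, 15)
    beta[idx] <- rnorm(15, 0, sqrt(0.01))
    z <- drop(rnorm(50) %*% chol(sigma)) + sqrt(500) * beta
    hits <- hits + (pco_test(z, model, calib)$p_pco < 1e-4)
  }
  expect_gte(hits / 50, 0.9)
})

test_that("a null genome scan is calibrated and a planted scan finds its SNP", {
  fx <- three_block_cohort_modules()
  coh <- generate_cohort(400, fx$sigma, 100, seed = 51)
  scan <- genome_scan(coh$genotypes, coh$expression, fx$modules,
                      coh$annotation, permutations = 0, seed = 51)
  expect_equal(nrow(scan), 300)
  expect_gt(suppressWarnings(ks.test(scan$p_pco, "punif"))$p.value, 0.01)

  # planted trans-SNP attains the minimum p of its module's scan
  genes <- rownames(fx$sigma)
  planted <- data.frame(snp = 7L, gene = genes[1:8], beta = 0.5)
  coh2 <- generate_cohort(400, fx$sigma, 100, planted = planted, seed = 52)
  scan2 <- genome_scan(coh2$genotypes, coh2$expression, fx$modules,
                       coh2$annotation, permutations = 0, seed = 52)
  m1 <- scan2[scan2$module == "M1", ]
  expect_equal(m1$snp_id[which.min(m1$p_pco)], "rs0007")

  expect_error(genome_scan(coh$genotypes, coh$expression, list(),
                           coh$annotation), "empty module list")
})

test_that("permutation null pools are deterministic and calibrated", {
  fx <- three_block_cohort_modules()
  coh <- generate_cohort(300, fx$sigma, 40, seed = 53)
  p1 <- permutation_null(coh$genotypes, coh$expression, fx$modules,
                         coh$annotation, n_perm = 2, seed = 99)
  p2 <- permutation_null(coh$genotypes, coh$expression, fx$modules,
                         coh$annotation, n_perm = 2, seed = 99)
  expect_identical(p1, p2)
  expect_length(p1, 2 * 40 * 3)
  # permuted-null p-values look like the observed null scan's
  scan <- genome_scan(coh$genotypes, coh$expression, fx$modules,
                      coh$annotation, permutations = 0, seed = 53)
  expect_gt(suppressWarnings(ks.test(p1, scan$p_pco))$p.value, 0.01)
  expect_error(permutation_null(coh$genotypes, coh$expression, fx$modules,
                                coh$annotation, n_perm = 0), "n_perm")
})

test_that("empirical FDR matches hand enumeration and controls the null", {
  # toy: null pool of 300 uniforms from 3 permutations
  set.seed(61)
  pool <- runif(300)
  obs <- c(0.001, 0.2, 0.5)
  fdr <- empirical_fdr(obs, pool, n_perm = 3)
  expect_equal(fdr$q[1], (sum(pool <= 0.001) / 3) / 1)
  expect_equal(fdr$q[2], min(1, (sum(pool <= 0.2) / 3) / 2, (sum(pool <= 0.5) / 3) / 3))
  # monotone in p
  expect_true(all(diff(fdr$q[order(fdr$p)]) >= 0))

  # null observed: about level * n significant on average (here: few)
  set.seed(62)
  calls <- replicate(50, {
    o <- runif(100); np <- runif(1000)
    sum(empirical_fdr(o, np, n_perm = 10, level = 0.1)$significant)
  })
  expect_lt(mean(calls), 0.1 * 100 * 2)

  # no null value at or below the minimum observed: q = 0
  fdr0 <- empirical_fdr(c(1e-6, 0.5), runif(100, 0.1, 1), n_perm = 1)
  expect_equal(fdr0$q[1], 0)
  expect_error(empirical_fdr(obs, numeric(0), 1), "empty null pool")
})

test_that("greedy LD clumping follows the stated semantics", {
  set.seed(71)
  base <- rbinom(300, 2, 0.4)
  D <- cbind(A = base, B = base, C = base)   # pairwise R2 = 1
  snps <- data.frame(snp_id = c("A", "B", "C"), chrom = "chr1",
                     pos = 1:3, p = c(0.001, 0.01, 0.05))
  cl <- ld_clump(snps, D)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$lead, "A")
  expect_setequal(cl[[1]]$members, c("A", "B", "C"))

  Di <- cbind(A = rbinom(300, 2, .4), B = rbinom(300, 2, .4), C = rbinom(300, 2, .4))
  cli <- ld_clump(snps, Di)
  expect_length(cli, 3)

  # chain: A-B r2 = 0.5, B-C r2 = 0.5, A-C r2 ~ 0; p(A) best -> {A,B}, {C}
  n <- 4000
  lat <- matrix(rnorm(n * 3), n)
  a <- lat[, 1]
  b <- sqrt(0.5) * scale(a)[, 1] + sqrt(0.5) * lat[, 2]
  cc <- sqrt(0.5) * scale(lat[, 2])[, 1] + sqrt(0.5) * lat[, 3]
  Dc <- cbind(A = a, B = b, C = cc)
  expect_lt(cor(Dc[, "A"], Dc[, "C"])^2, 0.2)
  expect_gt(cor(Dc[, "A"], Dc[, "B"])^2, 0.2)
  expect_gt(cor(Dc[, "B"], Dc[, "C"])^2, 0.2)
  clc <- ld_clump(snps, Dc)
  expect_length(clc, 2)
  expect_setequal(clc[[1]]$members, c("A", "B"))
  expect_equal(clc[[2]]$members, "C")
})
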