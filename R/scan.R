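# Individual-level genome-wide trans-eQTL scan.

#' Genotype container
#'
#' @param dosages samples x SNPs numeric matrix of dosages in `[0, 2]`
#'   (sample rownames, SNP colnames; NA = missing).
#' @param snps data.frame with columns snp_id, chrom, pos matching the
#'   dosage columns.
#' @return an object of class `genotypes`.
#' @export
genotype_matrix <- function(dosages, snps) {
  if (!is.matrix(dosages)) stopf("dosages must be a matrix")
  snps <- as.data.frame(snps)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snps))) stopf("snps needs columns: %s", paste(need, collapse = ", "))
  if (nrow(snps) != ncol(dosages)) stopf("snps rows must match dosage columns")
  colnames(dosages) <- snps$snp_id
  structure(list(dosages = dosages, snps = snps), class = "genotypes")
}

#' @noRd
as_genotypes <- function(x) {
  if (inherits(x, "genotypes")) return(x)
  if (is.matrix(x)) {
    sn <- colnames(x) %||% paste0("snp", seq_len(ncol(x)))
    return(genotype_matrix(x, data.frame(snp_id = sn, chrom = NA_character_,
                                         pos = NA_integer_)))
  }
  stopf("cannot interpret genotypes of class %s", paste(class(x), collapse = "/"))
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs\n", nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Univariate association Z scores
#'
#' For every SNP-gene pair, the Wald Z of the simple linear regression of
#' residual expression on dosage, computed through the correlation:
#' `t = r sqrt((n-2)/(1-r^2))` mapped through the t-to-normal quantile
#' bridge. Monomorphic SNPs are excluded with a warning.
#'
#' @param genotypes a [genotype_matrix()] (samples aligned with expression).
#' @param expression samples x genes residual expression matrix.
#' @return an object of class `zpanel`: list with `Z` (SNPs x genes),
#'   `snps`, `gene_ids` and sample size `n`.
#' @export
univariate_zscores <- function(genotypes, expression) {
  g <- as_genotypes(genotypes)
  check_expression(expression)
  D <- g$dosages
  if (nrow(D) != nrow(expression)) stopf("genotypes and expression have different sample counts")
  n <- nrow(D)
  sdv <- apply(D, 2, stats::sd)
  mono <- !is.finite(sdv) | sdv < 1e-12
  if (any(mono)) {
    warnf("excluding %d monomorphic SNP(s)", sum(mono))
    D <- D[, !mono, drop = FALSE]
    g$snps <- g$snps[!mono, , drop = FALSE]
  }
  r <- stats::cor(D, expression)                    # SNPs x genes
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p1 <- stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  Z <- sign(tt) * stats::qnorm(pmax(p1, .P_FLOOR / 2), lower.tail = FALSE)
  dimnames(Z) <- list(g$snps$snp_id, colnames(expression))
  structure(list(Z = Z, snps = g$snps, gene_ids = colnames(expression), n = n),
            class = "zpanel")
}

#' @export
print.zpanel <- function(x, ...) {
  cat(sprintf("Z panel: %d SNPs x %d genes (n = %s)\n",
              nrow(x$Z), length(x$gene_ids), x$n %||% "?"))
  invisible(x)
}

#' Test one SNP against one gene module
#'
#' Applies the scan exclusion rules (module genes on the SNP's chromosome,
#' plus cross-mappable genes when a cross-mappability table is supplied),
#' re-derives the PC model and omnibus calibration on the surviving genes,
#' and returns the omnibus test result.
#'
#' @param snp_id SNP identifier present in `zpanel`.
#' @param module a [gene_module()].
#' @param zpanel a [univariate_zscores()] panel covering the module genes.
#' @param sigma module gene correlation matrix (covering the module genes).
#' @param annotation gene annotation data.frame.
#' @param crossmap optional cross-mappability table (see [read_crossmap()]).
#' @param lambda_min eigenvalue retention threshold.
#' @param calib_draws,calib_seed omnibus calibration settings.
#' @return a `pco_result`, or NULL (with a message) when no gene survives.
#' @export
test_snp_module <- function(snp_id, module, zpanel, sigma, annotation,
                            crossmap = NULL, lambda_min = 0.1,
                            calib_draws = 2e4, calib_seed = 1L) {
  i <- match(snp_id, zpanel$snps$snp_id)
  if (is.na(i)) stopf("SNP '%s' not in the Z panel", snp_id)
  snp <- zpanel$snps[i, ]
  keep <- surviving_genes(snp, module, annotation, crossmap)
  if (length(keep) < 1) {
    message(sprintf("SNP %s x module %s skipped: no genes survive exclusions", snp_id, module$module_id))
    return(NULL)
  }
  sig <- as_correlation_matrix(sigma, rownames(sigma))
  sub <- sig[keep, keep, drop = FALSE]
  model <- pco_model(sub, lambda_min = lambda_min)
  calib <- pco_calibrate(model, draws = calib_draws, seed = calib_seed)
  z <- zpanel$Z[i, keep]
  res <- pco_test(z, model, calib)
  res$n_genes_tested <- length(keep)
  res
}

# Genes of `module` surviving same-chromosome and cross-mappability
# exclusion for a given SNP (a row of a snps data.frame).
#' @noRd
surviving_genes <- function(snp, module, annotation, crossmap = NULL,
                            window_bp = 1e5) {
  ann <- annotation[match(module$gene_ids, annotation$gene_id), ]
  if (anyNA(ann$gene_id)) stopf("module '%s' has unannotated genes", module$module_id)
  keep <- is.na(snp$chrom) | ann$chrom != snp$chrom
  if (!is.null(crossmap) && !is.na(snp$chrom)) {
    cis <- annotation$gene_id[annotation$chrom == snp$chrom &
                                annotation$start <= snp$pos + window_bp &
                                annotation$end >= snp$pos - window_bp]
    if (length(cis)) {
      xm <- unique(c(crossmap$gene_b[crossmap$gene_a %in% cis],
                     crossmap$gene_a[crossmap$gene_b %in% cis]))
      keep <- keep & !(module$gene_ids %in% xm)
    }
  }
  module$gene_ids[keep]
}

# Shared scan engine: evaluate every SNP x module pair of a Z panel, with
# exclusion rules, grouping SNPs by identical surviving gene sets so each
# subset model is eigendecomposed and calibrated once (and cached).
#' @noRd
scan_engine <- function(zpanel, modules, sigma_for, annotation, crossmap = NULL,
                        lambda_min = 0.1, calib_draws = 2e4, seed = 1L,
                        cache = new.env(parent = emptyenv())) {
  recs <- list()
  for (mod in modules) {
    have <- mod$gene_ids %in% zpanel$gene_ids
    if (!all(have)) stopf("module '%s': %d gene(s) missing from the Z panel",
                          mod$module_id, sum(!have))
    sigma <- sigma_for(mod)
    n_snp <- nrow(zpanel$snps)
    keys <- character(n_snp)
    keeps <- vector("list", n_snp)
    if (is.null(crossmap)) {
      # without a cross-map table the exclusion depends only on the SNP's
      # chromosome, so compute one surviving set per chromosome
      chr <- as.character(zpanel$snps$chrom)
      chr[is.na(chr)] <- "<na>"
      for (cc in unique(chr)) {
        idx <- which(chr == cc)
        kp <- surviving_genes(zpanel$snps[idx[1], ], mod, annotation, NULL)
        for (i in idx) keeps[[i]] <- kp
        keys[idx] <- paste(kp, collapse = "|")
      }
    } else {
      for (i in seq_len(n_snp)) {
        keeps[[i]] <- surviving_genes(zpanel$snps[i, ], mod, annotation, crossmap)
        keys[i] <- paste(keeps[[i]], collapse = "|")
      }
    }
    for (key in unique(keys)) {
      idx <- which(keys == key)
      keep <- keeps[[idx[1]]]
      if (length(keep) < 1) {
        recs[[length(recs) + 1]] <- data.frame(
          snp_id = zpanel$snps$snp_id[idx], chrom = zpanel$snps$chrom[idx],
          pos = zpanel$snps$pos[idx], module = mod$module_id,
          n_genes_tested = 0L, p_pco = NA_real_,
          skip_reason = "no_genes_after_exclusion")
        next
      }
      ck <- paste(mod$module_id, key, sep = "##")
      ent <- cache[[ck]]
      if (is.null(ent)) {
        sub <- sigma[keep, keep, drop = FALSE]
        model <- pco_model(sub, lambda_min = lambda_min)
        calib <- pco_calibrate(model, draws = calib_draws,
                               seed = child_seed(seed, "calib", mod$module_id, key))
        ent <- list(model = model, calib = calib)
        cache[[ck]] <- ent
      }
      # the tested gene set must never intersect the SNP's chromosome
      chroms <- annotation$chrom[match(keep, annotation$gene_id)]
      stopifnot(!any(chroms %in% zpanel$snps$chrom[idx]))
      Z <- zpanel$Z[idx, keep, drop = FALSE]
      pp <- pco_test_panel(Z, ent$model, ent$calib)
      recs[[length(recs) + 1]] <- data.frame(
        snp_id = zpanel$snps$snp_id[idx], chrom = zpanel$snps$chrom[idx],
        pos = zpanel$snps$pos[idx], module = mod$module_id,
        n_genes_tested = length(keep), p_pco = pp$p_pco,
        skip_reason = NA_character_)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Genome-wide trans-eQTL scan with empirical FDR
#'
#' Computes univariate Z scores for every SNP-gene pair, tests each SNP
#' against each module with the omnibus test (excluding module genes on the
#' SNP's chromosome), establishes an empirical null by re-running the scan
#' on permuted genotype sample labels, and converts p-values to empirical
#' q-values.
#'
#' @param genotypes QC'd [genotype_matrix()].
#' @param expression samples x genes residual expression matrix.
#' @param modules list of [gene_module()] objects.
#' @param annotation gene annotation data.frame.
#' @param crossmap optional cross-mappability table.
#' @param fdr_level FDR threshold for significance calls (default 0.10).
#' @param permutations permutation passes for the empirical null
#'   (default 10); 0 skips FDR and returns raw p-values.
#' @param lambda_min,calib_draws omnibus settings.
#' @param seed integer seed controlling permutations and calibrations.
#' @return object of class `transpco_scan`: a data.frame of records (snp_id,
#'   chrom, pos, module, n_genes_tested, p_pco, q, significant) with the
#'   null pool and configuration attached as attributes.
#' @export
genome_scan <- function(genotypes, expression, modules, annotation,
                        crossmap = NULL, fdr_level = 0.10, permutations = 10,
                        lambda_min = 0.1, calib_draws = 2e4, seed = 1L) {
  if (!length(modules)) stopf("empty module list")
  g <- as_genotypes(genotypes)
  zp <- univariate_zscores(g, expression)
  sigma_cache <- new.env(parent = emptyenv())
  sigma_for <- function(mod) {
    s <- sigma_cache[[mod$module_id]]
    if (is.null(s)) {
      s <- stats::cor(expression[, mod$gene_ids, drop = FALSE])
      s <- as_correlation_matrix(s, mod$gene_ids)
      sigma_cache[[mod$module_id]] <- s
    }
    s
  }
  cache <- new.env(parent = emptyenv())
  obs <- scan_engine(zp, modules, sigma_for, annotation, crossmap,
                     lambda_min, calib_draws, seed, cache)
  null_pool <- NULL
  if (permutations > 0) {
    null_pool <- permutation_null(g, expression, modules, annotation,
                                  crossmap = crossmap, n_perm = permutations,
                                  seed = seed, lambda_min = lambda_min,
                                  calib_draws = calib_draws, cache = cache,
                                  sigma_for = sigma_for)
    tested <- !is.na(obs$p_pco)
    fdr <- empirical_fdr(obs$p_pco[tested], null_pool, n_perm = permutations,
                         level = fdr_level)
    obs$q <- NA_real_; obs$significant <- NA
    obs$q[tested] <- fdr$q
    obs$significant[tested] <- fdr$significant
  }
  structure(obs, class = c("transpco_scan", "data.frame"),
            null_pool = null_pool,
            config = list(fdr_level = fdr_level, permutations = permutations,
                          lambda_min = lambda_min, calib_draws = calib_draws,
                          seed = seed, n = zp$n))
}

#' @export
print.transpco_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  tested <- sum(!is.na(x$p_pco))
  cat(sprintf("trans-eQTL scan: %d SNP-module records (%d tested, %d skipped)\n",
              nrow(x), tested, nrow(x) - tested))
  if (!is.null(x$significant)) {
    cat(sprintf("  significant at %d%% empirical FDR (%d permutations): %d\n",
                round(100 * cfg$fdr_level), cfg$permutations,
                sum(x$significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' Permutation null p-value pool
#'
#' Re-runs the full scan with genotype sample labels permuted (one shared
#' permutation per pass across all SNPs), breaking genotype-expression links
#' while preserving the expression correlation the test conditions on.
#'
#' @inheritParams genome_scan
#' @param n_perm number of permutation passes (default 10).
#' @param cache,sigma_for internal reuse of subset calibrations.
#' @return numeric vector pooling the p-values of all passes.
#' @export
permutation_null <- function(genotypes, expression, modules, annotation,
                             crossmap = NULL, n_perm = 10, seed = 1L,
                             lambda_min = 0.1, calib_draws = 2e4,
                             cache = NULL, sigma_for = NULL) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  g <- as_genotypes(genotypes)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(sigma_for)) {
    sigma_for <- function(mod) {
      as_correlation_matrix(stats::cor(expression[, mod$gene_ids, drop = FALSE]),
                            mod$gene_ids)
    }
  }
  pool <- list()
  for (b in seq_len(n_perm)) {
    perm <- with_seed(child_seed(seed, "perm", b),
                      sample.int(nrow(g$dosages)))
    gp <- genotype_matrix(g$dosages[perm, , drop = FALSE], g$snps)
    rownames(gp$dosages) <- rownames(g$dosages)
    zp <- suppressWarnings(univariate_zscores(gp, expression))
    rec <- scan_engine(zp, modules, sigma_for, annotation, crossmap,
                       lambda_min, calib_draws, seed, cache)
    pool[[b]] <- rec$p_pco[!is.na(rec$p_pco)]
  }
  unlist(pool)
}

#' Empirical FDR from a permutation or simulation null pool
#'
#' `q(t) = [#null p <= t / n_perm] / max(1, #observed p <= t)`, monotonised
#' by a running minimum from the largest observed p-value downward, so q is
#' non-decreasing in p.
#'
#' @param observed observed p-values.
#' @param null_pool pooled null p-values from `n_perm` matched passes.
#' @param n_perm number of passes that produced the pool.
#' @param level significance level on the q scale (default 0.10).
#' @return data.frame with columns p, q, significant, in the input order.
#' @export
empirical_fdr <- function(observed, null_pool, n_perm, level = 0.10) {
  if (!length(null_pool)) stopf("empty null pool")
  ord <- order(observed)
  p_sorted <- observed[ord]
  n_null <- findInterval(p_sorted, sort(null_pool))
  q_raw <- (n_null / n_perm) / seq_along(p_sorted)
  q_sorted <- rev(cummin(rev(pmin(q_raw, 1))))
  q <- numeric(length(observed))
  q[ord] <- q_sorted
  data.frame(p = observed, q = q, significant = q <= level)
}

#' Greedy LD clumping of significant SNPs
#'
#' Groups SNPs into LD-independent loci: the best-p SNP becomes a clump
#' lead and absorbs every remaining SNP with squared dosage correlation
#' `R^2 >=` the threshold; the process repeats on the remainder. Ties on p
#' are broken by genomic order.
#'
#' @param snps data.frame with columns snp_id, chrom, pos, p.
#' @param dosages samples x SNPs dosage matrix covering `snps$snp_id`.
#' @param r2_threshold clumping threshold (default 0.2).
#' @return list of clumps, each `list(lead, members)`.
#' @export
ld_clump <- function(snps, dosages, r2_threshold = 0.2) {
  snps <- as.data.frame(snps)
  if (!nrow(snps)) return(list())
  ord <- order(snps$p, snps$chrom, snps$pos)
  pending <- snps$snp_id[ord]
  D <- dosages[, snps$snp_id, drop = FALSE]
  clumps <- list()
  while (length(pending)) {
    lead <- pending[1]
    r2 <- drop(stats::cor(D[, lead], D[, pending, drop = FALSE]))^2
    members <- pending[r2 >= r2_threshold | pending == lead]
    clumps[[length(clumps) + 1]] <- list(lead = lead, members = members)
    pending <- setdiff(pending, members)
  }
  clumps
}
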