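# Summary-statistics-only mode: module correlation matrices approximated
# from null SNPs, SNP-to-gene ratio gating, cross-mappability exclusion.

#' Select null SNPs for a module
#'
#' SNPs insignificantly associated with every gene of the module
#' (`|Z| < abs_z_max` for all module genes). Their Z-score rows carry the
#' inter-gene correlation structure without association signal and are used
#' to approximate the module's correlation matrix.
#'
#' @param zpanel a `zpanel` covering the module genes.
#' @param module a [gene_module()].
#' @param abs_z_max exclusion threshold on `|Z|`; the default corresponds to
#'   per-gene two-sided p > 0.05.
#' @return character vector of null SNP ids (possibly empty).
#' @export
select_null_snps <- function(zpanel, module, abs_z_max = stats::qnorm(0.975)) {
  miss <- setdiff(module$gene_ids, zpanel$gene_ids)
  if (length(miss)) stopf("Z panel does not cover module gene(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  Z <- zpanel$Z[, module$gene_ids, drop = FALSE]
  ok <- rowSums(abs(Z) >= abs_z_max) == 0L
  zpanel$snps$snp_id[ok]
}

#' Approximate a module correlation matrix from null SNP Z scores
#'
#' Pearson correlation of Z scores across null SNPs per gene pair, with PSD
#' repair (eigenvalue floor 1e-6, rescaled to unit diagonal). A low ratio of
#' null SNPs to module size produces a noisy estimate and inflates the test
#' statistics, so modules are gated on `ratio > min_ratio`.
#'
#' @param zpanel a `zpanel` restricted (or restrictable) to null SNP rows.
#' @param module a [gene_module()].
#' @param null_snps SNP ids to use (e.g. from [select_null_snps()]); default
#'   all panel rows.
#' @param min_ratio gating threshold on `n_null_snps / module size`
#'   (default 50).
#' @return object of class `sigma_estimate`: list with `sigma`,
#'   `n_null_snps`, `ratio`, `gated`.
#' @export
estimate_sigma <- function(zpanel, module, null_snps = NULL, min_ratio = 50) {
  if (is.null(null_snps)) null_snps <- zpanel$snps$snp_id
  idx <- match(null_snps, zpanel$snps$snp_id)
  if (anyNA(idx)) stopf("unknown null SNP ids")
  if (length(idx) < 2) stopf("need at least 2 null SNPs to estimate a correlation matrix")
  Z <- zpanel$Z[idx, module$gene_ids, drop = FALSE]
  sig <- suppressWarnings(stats::cor(Z))
  sig[!is.finite(sig)] <- 0
  diag(sig) <- 1
  sig <- psd_repair(sig, floor = 1e-6)
  ratio <- length(idx) / length(module$gene_ids)
  structure(list(sigma = sig, n_null_snps = length(idx), ratio = ratio,
                 gated = ratio > min_ratio, min_ratio = min_ratio),
            class = "sigma_estimate")
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf("sigma estimate from %d null SNPs (%d genes): ratio %.1f -> %s\n",
              x$n_null_snps, nrow(x$sigma), x$ratio,
              if (x$gated) "usable" else sprintf("excluded (ratio <= %g)", x$min_ratio)))
  invisible(x)
}

#' Cross-mappability exclusion around a tested SNP
#'
#' Finds genes whose span intersects the closed window `pos +/- window_bp`
#' on the SNP's chromosome (its potential cis genes), removes module genes
#' cross-mappable to any of them, and also removes module genes on the
#' SNP's chromosome. Reads mis-assigned from a cis gene to a homologous
#' trans gene would otherwise masquerade as a trans association.
#'
#' @param snp one-row data.frame (or list) with chrom and pos.
#' @param module a [gene_module()].
#' @param annotation gene annotation data.frame.
#' @param crossmap cross-mappability pair table (symmetric; see
#'   [read_crossmap()]).
#' @param window_bp cis window half-width in bp (default 100000).
#' @return the reduced [gene_module()] (possibly with zero genes, as a
#'   plain character vector of survivors via `$gene_ids`).
#' @export
crossmap_exclude <- function(snp, module, annotation, crossmap,
                             window_bp = 1e5) {
  keep <- surviving_genes(snp, module, annotation, crossmap, window_bp)
  structure(list(module_id = module$module_id, gene_ids = keep,
                 provenance = module$provenance),
            class = "gene_module")
}

#' Summary-statistics trans-eQTL scan
#'
#' For each module: selects null SNPs, approximates the correlation matrix,
#' gates on the SNP-to-gene ratio, then tests every panel SNP with
#' cross-mappability and same-chromosome exclusion (the module-level
#' correlation estimate is subset to the surviving genes). Significance uses
#' Bonferroni correction across the tests performed, or empirical FDR when a
#' null pool is supplied.
#'
#' @param zpanel SNP x gene Z-score panel.
#' @param modules list of [gene_module()] objects.
#' @param annotation gene annotation data.frame.
#' @param crossmap optional cross-mappability table.
#' @param min_ratio SNP-to-gene ratio gate (default 50).
#' @param abs_z_max null-SNP selection threshold.
#' @param alpha family-wise level for the Bonferroni calls (default 0.05).
#' @param null_pool,n_perm optional empirical-FDR inputs replacing
#'   Bonferroni.
#' @param fdr_level empirical FDR level when a null pool is supplied.
#' @param lambda_min,calib_draws,seed omnibus settings.
#' @return object of class `transpco_scan` with per-record p-values and
#'   significance calls; gating decisions in attribute `gating`.
#' @export
sumstats_scan <- function(zpanel, modules, annotation, crossmap = NULL,
                          min_ratio = 50, abs_z_max = stats::qnorm(0.975),
                          alpha = 0.05, null_pool = NULL, n_perm = NULL,
                          fdr_level = 0.10, lambda_min = 0.1,
                          calib_draws = 2e4, seed = 1L) {
  if (!length(modules)) stopf("empty module list")
  gating <- list()
  usable <- list()
  sigmas <- list()
  for (mod in modules) {
    ns <- select_null_snps(zpanel, mod, abs_z_max)
    est <- if (length(ns) >= 2) estimate_sigma(zpanel, mod, ns, min_ratio) else NULL
    gating[[mod$module_id]] <- data.frame(
      module = mod$module_id, n_genes = length(mod$gene_ids),
      n_null_snps = length(ns),
      ratio = if (is.null(est)) NA_real_ else est$ratio,
      gated = !is.null(est) && est$gated)
    if (!is.null(est) && est$gated) {
      usable[[mod$module_id]] <- mod
      sigmas[[mod$module_id]] <- est$sigma
    }
  }
  gating <- do.call(rbind, gating); rownames(gating) <- NULL
  if (!length(usable)) stopf("no module passes the SNP-to-gene ratio gate")
  sigma_for <- function(mod) sigmas[[mod$module_id]]
  rec <- scan_engine(zpanel, usable, sigma_for, annotation, crossmap,
                     lambda_min, calib_draws, seed)
  tested <- !is.na(rec$p_pco)
  if (!is.null(null_pool)) {
    if (is.null(n_perm)) stopf("n_perm required with a null pool")
    fdr <- empirical_fdr(rec$p_pco[tested], null_pool, n_perm, fdr_level)
    rec$q <- NA_real_; rec$significant <- NA
    rec$q[tested] <- fdr$q; rec$significant[tested] <- fdr$significant
  } else {
    rec$significant <- NA
    rec$significant[tested] <- rec$p_pco[tested] <= alpha / sum(tested)
  }
  structure(rec, class = c("transpco_scan", "data.frame"), gating = gating,
            config = list(min_ratio = min_ratio, abs_z_max = abs_z_max,
                          alpha = alpha, seed = seed))
}
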