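# Power / type-I simulation framework: null and alternative Z panels under a
# point-normal trans effect model, with PC1 and MinP comparators.

#' Simulation configuration
#'
#' Defaults mirror the reference study conditions: sample size 500, 30%
#' causal genes, per-SNP trans genetic variance 0.001, 10,000 SNPs per
#' replicate and 1,000 replicates, 10% empirical FDR. Desk-scale runs
#' typically reduce `n_snps`/`n_reps`.
#'
#' @param n sample size behind the Z scores.
#' @param gamma causal gene proportion in `[0, 1]`.
#' @param sigma_b2 trans genetic variance per SNP (effect prior variance).
#' @param n_snps SNPs per replicate.
#' @param n_reps replicates.
#' @param fdr_level FDR level for significance (default 0.10).
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n = 500, gamma = 0.3, sigma_b2 = 0.001,
                              n_snps = 10000, n_reps = 1000,
                              fdr_level = 0.10, seed = 1L) {
  stopifnot(n > 0, gamma >= 0, gamma <= 1, sigma_b2 >= 0,
            n_snps >= 1, n_reps >= 1)
  structure(list(n = n, gamma = gamma, sigma_b2 = sigma_b2, n_snps = n_snps,
                 n_reps = n_reps, fdr_level = fdr_level, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate null Z-score panels
#'
#' Rows are i.i.d. draws from `N(0, Sigma)`: the summary statistics of SNPs
#' with no trans effect on a module with gene correlation `Sigma`.
#'
#' @param sigma gene correlation matrix.
#' @param n_snps number of SNP rows.
#' @param seed integer seed (deterministic given it).
#' @return a `zpanel` with synthetic SNP metadata.
#' @export
simulate_null_z <- function(sigma, n_snps, seed = 1L) {
  sigma <- as_correlation_matrix(sigma, rownames(sigma))
  K <- nrow(sigma)
  Z <- with_seed(seed, matrix(stats::rnorm(n_snps * K), n_snps, K) %*% chol(sigma))
  colnames(Z) <- rownames(sigma)
  snps <- data.frame(snp_id = paste0("s", seq_len(n_snps)),
                     chrom = NA_character_, pos = NA_integer_)
  rownames(Z) <- snps$snp_id
  structure(list(Z = Z, snps = snps, gene_ids = rownames(sigma), n = NA_integer_),
            class = "zpanel")
}

#' Simulate alternative Z-score panels with point-normal effects
#'
#' Per SNP, `round(gamma K)` causal genes (minimum 1 when `gamma > 0`,
#' with a warning if `gamma K < 1`) are placed uniformly at random; causal
#' effects are `beta ~ N(0, sigma_b2)` and the Z means are `sqrt(n) beta`,
#' the score-statistic scale of a per-allele effect at sample size n. Noise
#' is `N(0, Sigma)`. With `gamma = 0` the panel is bit-identical to
#' [simulate_null_z()] under the same seed.
#'
#' @param sigma gene correlation matrix.
#' @param config a [simulation_config()].
#' @return list with `zpanel`, logical `causal` mask (SNPs x genes) and
#'   `beta` matrix of planted effects.
#' @export
simulate_alt_z <- function(sigma, config) {
  stopifnot(inherits(config, "simulation_config"))
  sigma <- as_correlation_matrix(sigma, rownames(sigma))
  K <- nrow(sigma)
  S <- config$n_snps
  n_causal <- if (config$gamma == 0) 0L else max(1L, round(config$gamma * K))
  if (config$gamma > 0 && config$gamma * K < 1)
    warnf("gamma * K = %.2f < 1; using exactly 1 causal gene per SNP", config$gamma * K)
  out <- with_seed(config$seed, {
    E <- matrix(stats::rnorm(S * K), S, K) %*% chol(sigma)
    beta <- matrix(0, S, K)
    if (n_causal > 0) {
      for (i in seq_len(S)) {
        pos <- sample.int(K, n_causal)
        beta[i, pos] <- stats::rnorm(n_causal, 0, sqrt(config$sigma_b2))
      }
    }
    list(Z = E + sqrt(config$n) * beta, beta = beta)
  })
  colnames(out$Z) <- rownames(sigma)
  snps <- data.frame(snp_id = paste0("s", seq_len(S)),
                     chrom = NA_character_, pos = NA_integer_)
  rownames(out$Z) <- snps$snp_id
  zp <- structure(list(Z = out$Z, snps = snps, gene_ids = rownames(sigma),
                       n = config$n), class = "zpanel")
  list(zpanel = zp, causal = out$beta != 0, beta = out$beta)
}

# p-values of all requested methods for one Z panel
#' @noRd
method_pvalues <- function(Z, model, calib, methods) {
  out <- list()
  if ("transPCO" %in% methods) out$transPCO <- pco_test_panel(Z, model, calib)$p_pco
  if ("PC1" %in% methods) out$PC1 <- pc1_test_panel(Z, model)
  if ("MinP" %in% methods) out$MinP <- minp_test_panel(Z)
  out
}

#' Power study
#'
#' For each configuration and replicate: simulate an alternative panel,
#' compute per-method p-values, adjust them against matched null panels with
#' the same empirical-FDR machinery as the genome scan, and record the
#' proportion of SNPs called significant. Power is averaged over replicates
#' with a normal-approximation 95% CI.
#'
#' @param sigma gene correlation matrix.
#' @param configs a [simulation_config()] or list of them.
#' @param methods subset of `c("transPCO", "PC1", "MinP")`.
#' @param n_null_panels matched null panels per replicate (default 10).
#' @param calib_draws omnibus calibration draws (default 1e5; the
#'   calibration is shared across replicates).
#' @param lambda_min eigenvalue retention threshold.
#' @return a `power_table` data.frame: one row per config x method with
#'   power, ci_lo, ci_hi, and the config echo.
#' @export
run_power_study <- function(sigma, configs, methods = c("transPCO", "PC1", "MinP"),
                            n_null_panels = 10, calib_draws = 1e5,
                            lambda_min = 0.1) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  methods <- match.arg(methods, c("transPCO", "PC1", "MinP"), several.ok = TRUE)
  sigma <- as_correlation_matrix(sigma, rownames(sigma))
  model <- pco_model(sigma, lambda_min = lambda_min)
  calib <- NULL
  rows <- list()
  for (cfg in configs) {
    if (is.null(calib) && "transPCO" %in% methods)
      calib <- pco_calibrate(model, draws = calib_draws,
                             seed = child_seed(cfg$seed, "calib"))
    pw <- matrix(NA_real_, cfg$n_reps, length(methods),
                 dimnames = list(NULL, methods))
    for (r in seq_len(cfg$n_reps)) {
      rcfg <- cfg
      rcfg$seed <- child_seed(cfg$seed, "alt", r)
      alt <- simulate_alt_z(sigma, rcfg)
      p_obs <- method_pvalues(alt$zpanel$Z, model, calib, methods)
      p_null <- lapply(seq_len(n_null_panels), function(j) {
        zn <- simulate_null_z(sigma, cfg$n_snps, seed = child_seed(cfg$seed, "null", r, j))
        method_pvalues(zn$Z, model, calib, methods)
      })
      for (m in methods) {
        pool <- unlist(lapply(p_null, `[[`, m))
        fdr <- empirical_fdr(p_obs[[m]], pool, n_perm = n_null_panels,
                             level = cfg$fdr_level)
        pw[r, m] <- mean(fdr$significant)
      }
    }
    for (m in methods) {
      mu <- mean(pw[, m]); se <- stats::sd(pw[, m]) / sqrt(cfg$n_reps)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, power = mu,
        ci_lo = max(0, mu - 1.96 * se), ci_hi = min(1, mu + 1.96 * se),
        mc_se = se, n = cfg$n, gamma = cfg$gamma, sigma_b2 = cfg$sigma_b2,
        n_snps = cfg$n_snps, n_reps = cfg$n_reps, fdr_level = cfg$fdr_level,
        seed = cfg$seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_table", "data.frame")
  out
}

#' @export
print.power_table <- function(x, ...) {
  cat("power study (mean over replicates, 95% CI):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  n=%d gamma=%.2f sb2=%g  %-8s %.3f [%.3f, %.3f]\n",
                x$n[i], x$gamma[i], x$sigma_b2[i], x$method[i],
                x$power[i], x$ci_lo[i], x$ci_hi[i]))
  }
  invisible(x)
}

#' @export
plot.power_table <- function(x, by = c("n", "gamma"), ...) {
  by <- match.arg(by)
  methods <- unique(x$method)
  cols <- stats::setNames(seq_along(methods) + 1, methods)
  graphics::plot(range(x[[by]]), c(0, 1), type = "n", xlab = by,
                 ylab = "power", ...)
  for (m in methods) {
    sub <- x[x$method == m, ]
    sub <- sub[order(sub[[by]]), ]
    graphics::lines(sub[[by]], sub$power, type = "b", col = cols[m], pch = 16)
  }
  graphics::legend("topleft", legend = methods, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Type-I error study
#'
#' Rejection rates of each method at nominal levels on null panels, with
#' Clopper-Pearson 99% intervals.
#'
#' @param sigma gene correlation matrix.
#' @param config a [simulation_config()] (gamma/sigma_b2 ignored).
#' @param alphas nominal levels (default 0.05 and 0.01).
#' @param methods subset of `c("transPCO", "PC1", "MinP")`.
#' @param calib_draws,lambda_min omnibus settings.
#' @return data.frame with method, alpha, rate, ci_lo, ci_hi, n_tests.
#' @export
run_type1_study <- function(sigma, config, alphas = c(0.05, 0.01),
                            methods = c("transPCO", "PC1", "MinP"),
                            calib_draws = 1e5, lambda_min = 0.1) {
  methods <- match.arg(methods, c("transPCO", "PC1", "MinP"), several.ok = TRUE)
  sigma <- as_correlation_matrix(sigma, rownames(sigma))
  model <- pco_model(sigma, lambda_min = lambda_min)
  calib <- if ("transPCO" %in% methods)
    pco_calibrate(model, draws = calib_draws, seed = child_seed(config$seed, "calib"))
  ntot <- config$n_snps * config$n_reps
  pv <- lapply(stats::setNames(methods, methods), function(m) numeric(0))
  for (r in seq_len(config$n_reps)) {
    zn <- simulate_null_z(sigma, config$n_snps, seed = child_seed(config$seed, "t1", r))
    pr <- method_pvalues(zn$Z, model, calib, methods)
    for (m in methods) pv[[m]] <- c(pv[[m]], pr[[m]])
  }
  rows <- list()
  for (m in methods) for (a in alphas) {
    k <- sum(pv[[m]] <= a)
    ci <- c(stats::qbeta(0.005, k, ntot - k + 1),
            stats::qbeta(0.995, k + 1, ntot - k))
    rows[[length(rows) + 1]] <- data.frame(
      method = m, alpha = a, rate = k / ntot,
      ci_lo = ci[1], ci_hi = ci[2], n_tests = ntot)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
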