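# The PC-based omnibus (PCO) test: PC statistics, the six component tests,
# Monte-Carlo calibration of their joint null, and the final omnibus p-value.

.COMPONENTS <- c("PCMinP", "PCFisher", "PCLC", "WI", "Wald", "VC")

#' PC statistics of a Z-score vector
#'
#' Projects the module's univariate Z scores onto the retained eigenvectors:
#' `TPC_k = mu_k' z`. Under the null each statistic is `N(0, lambda_k)`, and
#' the retained statistics are mutually independent because eigenvectors are
#' orthogonal.
#'
#' @param z numeric vector of Z scores in the model's gene order.
#' @param model a [pco_model()].
#' @return named numeric vector of `TPC_k` for the retained PCs.
#' @export
pc_statistics <- function(z, model) {
  stopifnot(inherits(model, "pco_model"))
  if (length(z) != length(model$gene_ids))
    stopf("z has length %d but the model has %d genes",
          length(z), length(model$gene_ids))
  if (!all(is.finite(z))) stopf("z contains non-finite entries")
  tpc <- drop(crossprod(model$vectors[, model$retained, drop = FALSE], z))
  names(tpc) <- paste0("PC", model$retained)
  tpc
}

# Vectorised component machinery: Z is an n x K matrix (rows = SNPs).
# Returns list(stats = n x 6, pvalues = n x 6, t_pco = n).
#' @noRd
pco_components <- function(Z, model, warn_underflow = TRUE) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != length(model$gene_ids))
    stopf("Z has %d columns but the model has %d genes",
          ncol(Z), length(model$gene_ids))
  mu <- model$vectors[, model$retained, drop = FALSE]
  lam <- model$values[model$retained]
  m <- length(lam)
  TPC <- Z %*% mu                               # n x m
  T2 <- TPC^2
  # per-PC two-sided p-values under N(0, lambda_k)
  PK <- 2 * stats::pnorm(-abs(sweep(TPC, 2, sqrt(lam), "/")))
  PK <- pmin(pmax(PK, .P_FLOOR), 1)

  tmin <- row_mins(PK)
  stats <- cbind(
    PCMinP   = tmin,
    PCFisher = -2 * rowSums(log(PK)),
    PCLC     = drop(TPC %*% lam) / sqrt(sum(lam^2 * lam)),
    WI       = rowSums(T2),
    Wald     = drop(T2 %*% (1 / lam)),
    VC       = drop(T2 %*% lam)
  )
  pv <- cbind(
    # exact minimum of m independent uniforms: 1 - (1 - t)^m
    PCMinP   = -expm1(m * log1p(-tmin)),
    PCFisher = stats::pchisq(stats[, "PCFisher"], df = 2 * m, lower.tail = FALSE),
    PCLC     = 2 * stats::pnorm(-abs(stats[, "PCLC"])),
    WI       = pwchisq_batch(stats[, "WI"], lam, model$cache, "wi"),
    Wald     = stats::pchisq(stats[, "Wald"], df = m, lower.tail = FALSE),
    VC       = pwchisq_batch(stats[, "VC"], lam^2, model$cache, "vc")
  )
  pv <- clamp_p(pv, warn = warn_underflow)
  list(stats = stats, pvalues = pv, t_pco = row_mins(pv))
}

#' Six PC-based component tests
#'
#' Computes the six statistics combined by the omnibus test and their
#' p-values. PCMinP takes the best single-PC p-value (corrected exactly for
#' the minimum of independent PCs); PCFisher sums log p-values (chi-square
#' with `2m` df); Wald is `sum TPC_k^2 / lambda_k` (chi-square, `m` df,
#' equal to `z' Sigma^{-1} z` when all PCs are retained); WI is
#' `sum TPC_k^2` (`= z'z` when all PCs are retained) and VC is
#' `sum lambda_k TPC_k^2`, both referred to weighted sums of chi-square(1)
#' variables; PCLC is the eigenvalue-weighted linear combination
#' `sum lambda_k TPC_k`, standardised by its null SD.
#'
#' @param z numeric vector of Z scores in the model's gene order.
#' @param model a [pco_model()].
#' @return list with `statistics` and `pvalues`, both named by component.
#' @export
component_tests <- function(z, model) {
  cmp <- pco_components(matrix(z, nrow = 1), model)
  list(statistics = drop(cmp$stats)[.COMPONENTS],
       pvalues = drop(cmp$pvalues)[.COMPONENTS])
}

#' Calibrate the joint null of the six component tests
#'
#' Draws `draws` null Z vectors from `N(0, Sigma)`, computes the six
#' component p-values for each, transforms them through the standard-normal
#' quantile function, and records their empirical 6x6 correlation matrix.
#' The omnibus p-value treats the transformed components as multivariate
#' normal with this correlation. Components that are numerically comonotone
#' (correlation > 0.9999, e.g. Wald/WI/VC under an identity Sigma) are merged
#' so the correlation matrix stays non-singular.
#'
#' @param model a [pco_model()].
#' @param draws Monte-Carlo draws (default 1e5; fewer than 1000 triggers a
#'   warning about unstable calibration).
#' @param seed integer seed; calibration is deterministic given it.
#' @return an object of class `pco_calibration`.
#' @export
pco_calibrate <- function(model, draws = 1e5, seed = 1L) {
  stopifnot(inherits(model, "pco_model"))
  if (draws < 1000) warnf("calibration with %d draws is unstable; >= 10000 recommended", draws)
  K <- length(model$gene_ids)
  R_chol <- chol(model$sigma)
  P <- with_seed(seed, {
    Z <- matrix(stats::rnorm(draws * K), draws, K) %*% R_chol
    pco_components(Z, model, warn_underflow = FALSE)$pvalues
  })
  X <- stats::qnorm(pmin(pmax(P, .P_FLOOR), 1 - 1e-16))
  R_full <- stats::cor(X)
  groups <- collapse_groups(R_full, 0.9999)
  reps <- vapply(groups, `[`, integer(1), 1L)
  R <- R_full[reps, reps, drop = FALSE]
  R <- psd_repair_corr(R)
  obj <- structure(
    list(R_full = R_full, R = R, groups = groups, representatives = reps,
         null_t = sort(row_mins(P)),
         draws = draws, seed = seed,
         fingerprint = model_fingerprint(model, draws, seed),
         cache = new.env(parent = emptyenv())),
    class = "pco_calibration"
  )
  obj
}

#' @export
print.pco_calibration <- function(x, ...) {
  cat(sprintf("PCO omnibus calibration: %d draws, seed %d\n", x$draws, x$seed))
  cat(sprintf("  effective components after merge: %d of 6\n", nrow(x$R)))
  invisible(x)
}

# Merge indices whose pairwise correlation exceeds `thr` (graph components).
#' @noRd
collapse_groups <- function(R, thr) {
  d <- nrow(R)
  parent <- seq_len(d)
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    if (is.finite(R[i, j]) && R[i, j] > thr) {
      ri <- i; while (parent[ri] != ri) ri <- parent[ri]
      rj <- j; while (parent[rj] != rj) rj <- parent[rj]
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(d), function(i) { while (parent[i] != i) i <- parent[i]; i }, integer(1))
  split(seq_len(d), root)
}

# Light PSD repair for small correlation matrices (keeps unit diagonal).
#' @noRd
psd_repair_corr <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 1e-8) return(R)
  v <- pmax(e$values, 1e-8)
  rep <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(rep))
  rep <- rep / tcrossprod(d)
  diag(rep) <- 1
  dimnames(rep) <- dimnames(R)
  rep
}

#' @noRd
model_fingerprint <- function(model, draws, seed) {
  sig <- model$sigma
  paste(length(model$gene_ids),
        format(sum(sig) + sum(sig^2 * 3) + sum(model$values * seq_along(model$values)),
               digits = 15),
        draws, seed, sep = ":")
}

# ---- omnibus tail machinery -------------------------------------------------

# P(min_j X_j <= q) for X ~ N(0, R) by inclusion-exclusion truncated at
# triples, every term a deterministic TVPACK orthant probability. Only used
# deep in the tail (q well below qnorm(1e-3)), where quadruple terms are
# negligible and the alternating series brackets the truth.
#' @noRd
p_min_tail_series <- function(q, R) {
  d <- nrow(R)
  t1 <- stats::pnorm(q)
  if (d == 1L) return(t1)
  total <- d * t1
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    total <- total - as.numeric(mvtnorm::pmvnorm(
      upper = c(q, q), corr = R[c(i, j), c(i, j)],
      algorithm = mvtnorm::TVPACK(abseps = 1e-14)))
  }
  if (d >= 3) {
    for (i in seq_len(d - 2)) for (j in (i + 1):(d - 1)) for (k in (j + 1):d) {
      total <- total + as.numeric(mvtnorm::pmvnorm(
        upper = rep(q, 3), corr = R[c(i, j, k), c(i, j, k)],
        algorithm = mvtnorm::TVPACK(abseps = 1e-14)))
    }
  }
  min(max(total, t1), d * t1)
}

# Observed minimum component p-value -> omnibus p-value, vectorised.
#
# The calibration draws sample the exact joint null of the six components, so
# in the bulk the omnibus p-value is the empirical tail probability
# P(t_null <= t_obs) over those draws. Beyond the resolution of the draws
# (fewer than ~100 null draws at or below t_obs) the multivariate-normal
# inclusion-exclusion series over the calibrated correlation takes over,
# ratio-matched to the empirical curve at the splice rank so the two regimes
# agree there. Every value is clamped into the sandwich
# [t_obs, min(1, 6 t_obs)].
#' @noRd
omnibus_p_from_t <- function(t, calib) {
  d <- nrow(calib$R)
  t <- pmin(pmax(t, .P_FLOOR), 1)
  if (d == 1L) return(t)
  nt <- calib$null_t
  B <- length(nt)
  r0 <- min(100L, max(10L, B %/% 50L))
  cnt <- findInterval(t, nt)
  out <- (cnt + 1) / (B + 1)
  tail <- cnt < r0
  if (any(tail)) {
    f <- calib$cache$tail_spline
    if (is.null(f)) {
      # ratio-matched tail: monotone spline through the inclusion-exclusion
      # series, scaled to meet the empirical curve at the splice rank
      q_spl <- stats::qnorm(nt[r0])
      ser_spl <- p_min_tail_series(q_spl, calib$R)
      cc <- ((r0 + 1) / (B + 1)) / ser_spl
      qs <- seq(stats::qnorm(.P_FLOOR), q_spl, length.out = 60)
      lp <- log(pmax(vapply(qs, p_min_tail_series, numeric(1), R = calib$R) * cc,
                     .P_FLOOR))
      lp <- cummax(lp)
      keep <- !duplicated(lp)
      f <- stats::splinefun(qs[keep], lp[keep], method = "hyman")
      calib$cache$tail_spline <- f
      calib$cache$q_splice <- q_spl
    }
    qv <- pmax(stats::qnorm(t[tail]), stats::qnorm(.P_FLOOR))
    out[tail] <- exp(f(pmin(qv, calib$cache$q_splice)))
  }
  pmin(pmax(out, t), pmin(1, 6 * t))
}

#' Omnibus PCO test of one SNP against a gene module
#'
#' Computes the six component tests, takes the minimum p-value as the omnibus
#' statistic, and corrects it for selection through the joint null
#' distribution of the inverse-normal-transformed components:
#' `p = P(min_j Phi^{-1}(p_j) <= Phi^{-1}(t_obs))` under the calibrated
#' multivariate-normal null.
#'
#' @param z numeric vector of univariate Z scores in the model's gene order.
#' @param model a [pco_model()].
#' @param calib a matching [pco_calibrate()] object.
#' @return object of class `pco_result` with `pc_stats`, `component_pvalues`,
#'   `t_pco`, `p_pco` and `n_genes_tested`.
#' @export
#' @examples
#' sigma <- make_block_sigma(3, 0.5)
#' model <- pco_model(sigma)
#' calib <- pco_calibrate(model, draws = 2e4, seed = 7)
#' pco_test(c(1.5, -0.3, 2.1), model, calib)
pco_test <- function(z, model, calib) {
  if (missing(calib) || is.null(calib))
    stopf("no omnibus calibration supplied; run pco_calibrate(model) first")
  stopifnot(inherits(calib, "pco_calibration"))
  cmp <- pco_components(matrix(z, nrow = 1), model)
  t_pco <- cmp$t_pco
  p <- omnibus_p_from_t_exact(t_pco, calib)
  structure(
    list(pc_stats = pc_statistics(z, model),
         component_stats = drop(cmp$stats)[.COMPONENTS],
         component_pvalues = drop(cmp$pvalues)[.COMPONENTS],
         t_pco = t_pco, p_pco = p,
         n_genes_tested = length(model$gene_ids)),
    class = "pco_result"
  )
}

# single-value evaluation shares the batched machinery so that pco_test and
# pco_test_panel agree bit-for-bit
#' @noRd
omnibus_p_from_t_exact <- function(t, calib) {
  omnibus_p_from_t(t, calib)
}

#' @export
print.pco_result <- function(x, ...) {
  cat(sprintf("PCO omnibus test over %d genes\n", x$n_genes_tested))
  cat(sprintf("  p_pco = %.3g (t_pco = %.3g)\n", x$p_pco, x$t_pco))
  pv <- signif(x$component_pvalues, 3)
  cat("  component p-values:\n")
  for (nm in names(pv)) cat(sprintf("    %-9s %g\n", nm, pv[[nm]]))
  invisible(x)
}

#' Batch PCO p-values for a panel of Z-score rows
#'
#' Vectorised equivalent of [pco_test()] for many SNPs against one module;
#' used by the genome scans and the simulation framework.
#'
#' @param Z numeric matrix, SNPs x genes, in the model's gene order.
#' @param model a [pco_model()].
#' @param calib a matching [pco_calibrate()] object.
#' @return data.frame with the six component p-values, `t_pco` and `p_pco`.
#' @export
pco_test_panel <- function(Z, model, calib) {
  stopifnot(inherits(calib, "pco_calibration"))
  cmp <- pco_components(Z, model)
  p <- omnibus_p_from_t(cmp$t_pco, calib)
  out <- as.data.frame(cmp$pvalues)
  out$t_pco <- cmp$t_pco
  out$p_pco <- p
  out
}

#' PC1 comparator test
#'
#' Association test on the first principal component only:
#' `TPC1 = mu_1' z ~ N(0, lambda_1)` under the null, two-sided.
#'
#' @inheritParams pc_statistics
#' @return two-sided p-value.
#' @export
pc1_test <- function(z, model) {
  stopifnot(inherits(model, "pco_model"))
  if (length(z) != length(model$gene_ids))
    stopf("z has length %d but the model has %d genes",
          length(z), length(model$gene_ids))
  tpc1 <- sum(model$vectors[, 1] * z)
  2 * stats::pnorm(-abs(tpc1) / sqrt(model$values[1]))
}

#' @noRd
pc1_test_panel <- function(Z, model) {
  tpc1 <- drop(Z %*% model$vectors[, 1])
  2 * stats::pnorm(-abs(tpc1) / sqrt(model$values[1]))
}

#' MinP comparator test
#'
#' Univariate per-gene testing with Bonferroni correction:
#' `p = min(1, K * min_k p_k)`.
#'
#' @param gene_pvalues per-gene two-sided p-values.
#' @param K number of genes tested (defaults to the vector length).
#' @return Bonferroni-corrected minimum p-value.
#' @export
minp_test <- function(gene_pvalues, K = length(gene_pvalues)) {
  if (!length(gene_pvalues)) stopf("empty p-value vector")
  min(1, K * min(gene_pvalues))
}

#' @noRd
minp_test_panel <- function(Z) {
  pg <- 2 * stats::pnorm(-abs(Z))
  pmin(1, ncol(Z) * apply(pg, 1, min))
}
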