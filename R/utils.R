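# Internal helpers shared across modules.

# Smallest p-value we report; quieter numerics below this are meaningless.
.P_FLOOR <- 1e-300

#' @noRd
clamp_p <- function(p, warn = TRUE) {
  bad <- is.finite(p) & p < .P_FLOOR
  if (any(bad)) {
    if (warn) warning("p-value underflow: clamped ", sum(bad), " value(s) at 1e-300")
    p[bad] <- .P_FLOOR
  }
  pmin(pmax(p, .P_FLOOR), 1)
}

# Evaluate expr with a private RNG stream, restoring the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed below 2^31 from a base seed and a stream tag.
#' @noRd
child_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  # simple deterministic string hash folded into [1, 2^31 - 2]
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1L)
}

#' @noRd
is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

# column-wise pmin scan; much faster than apply(x, 1, min) on tall matrices
#' @noRd
row_mins <- function(x) {
  out <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) out <- pmin(out, x[, j])
  out
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Genomic inflation factor of a p-value vector
#'
#' Median chi-square statistic of the one-df quantile transform of `p`,
#' relative to its null median. Values near 1 indicate a well-calibrated
#' scan; values above ~1.1 indicate inflation.
#'
#' @param p numeric vector of p-values.
#' @return the inflation factor (lambda GC), a single number.
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) stopf("no finite p-values supplied")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
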