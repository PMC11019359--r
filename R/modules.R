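# Gene modules: co-expression detection and curated gene-set import.

#' Construct a gene module
#'
#' @param module_id module identifier.
#' @param gene_ids ordered, unique gene identifiers (>= 1).
#' @param provenance `"coexpression"` or `"gene_set"`.
#' @return an object of class `gene_module`.
#' @export
gene_module <- function(module_id, gene_ids, provenance = c("coexpression", "gene_set")) {
  provenance <- match.arg(provenance)
  if (!length(gene_ids)) stopf("module '%s' has no genes", module_id)
  if (anyDuplicated(gene_ids)) stopf("module '%s' has duplicated genes", module_id)
  structure(list(module_id = as.character(module_id),
                 gene_ids = as.character(gene_ids),
                 provenance = provenance),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene module '%s' (%s): %d genes\n",
              x$module_id, x$provenance, length(x$gene_ids)))
  invisible(x)
}

#' Detect co-expression modules by correlation clustering
#'
#' Average-linkage hierarchical clustering of genes on the distance
#' `1 - |cor|`, with the tree cut at `cut_height`; clusters smaller than
#' `min_module_size` go to an unclustered pool. This is a deliberately plain
#' correlation-network clustering: module definitions are an exchangeable
#' input to the association test, and curated sets can be supplied through
#' [load_gene_sets()] instead.
#'
#' @param x samples x genes residual expression matrix.
#' @param min_module_size smallest reported module (default 10).
#' @param cut_height tree cut height on the `1 - |cor|` scale (default 0.5).
#' @param on_too_few behaviour when fewer than `min_module_size` genes are
#'   supplied: `"error"` or `"single"` (one module with everything).
#' @return list of [gene_module()] objects ordered by decreasing size, with
#'   attribute `unclustered` naming pooled leftover genes.
#' @export
detect_coexpression_modules <- function(x, min_module_size = 10, cut_height = 0.5,
                                        on_too_few = c("error", "single")) {
  check_expression(x)
  on_too_few <- match.arg(on_too_few)
  genes <- colnames(x)
  if (length(genes) < min_module_size) {
    if (on_too_few == "error") stopf("fewer genes (%d) than min_module_size (%d)",
                                     length(genes), min_module_size)
    return(structure(list(gene_module("M1", genes, "coexpression")),
                     unclustered = character(0)))
  }
  C <- stats::cor(x)
  d <- stats::as.dist(1 - abs(C))
  cl <- stats::cutree(stats::hclust(d, method = "average"), h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # stable ordering: by decreasing size, ties by first gene position
  keep <- keep[order(-sizes[keep], vapply(keep, function(k) min(which(cl == k)), integer(1)))]
  mods <- lapply(seq_along(keep), function(i) {
    gene_module(paste0("M", i), genes[cl == keep[i]], "coexpression")
  })
  structure(mods, unclustered = genes[!(cl %in% keep)])
}

#' Load gene sets from a GMT file
#'
#' Standard MSigDB-style GMT: one set per line, `name TAB description TAB
#' gene TAB gene ...`. Duplicated genes within a set are dropped with a
#' warning; genes absent from `annotation` are dropped with a logged count;
#' sets left empty are dropped with a warning.
#'
#' @param path GMT file path.
#' @param annotation optional gene annotation data.frame; when supplied,
#'   unannotated genes are removed from the sets.
#' @return list of [gene_module()] objects with provenance `"gene_set"`.
#' @export
load_gene_sets <- function(path, annotation = NULL) {
  lines <- readLines(path, warn = FALSE)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nzchar(lines) & nf < 3)
  if (length(bad)) stopf("malformed GMT line %d in %s (need name, description, >= 1 gene)",
                         bad[1], path)
  sets <- fgsea::gmtPathways(path)
  known <- if (is.null(annotation)) NULL else annotation$gene_id
  out <- list()
  n_unannotated <- 0L
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (anyDuplicated(g)) {
      warnf("gene set '%s': %d duplicated gene(s) removed", nm, sum(duplicated(g)))
      g <- unique(g)
    }
    if (!is.null(known)) {
      drop <- !(g %in% known)
      n_unannotated <- n_unannotated + sum(drop)
      g <- g[!drop]
    }
    if (!length(g)) {
      warnf("gene set '%s' has no annotated genes; dropped", nm)
      next
    }
    out[[nm]] <- gene_module(nm, g, "gene_set")
  }
  if (n_unannotated > 0)
    message(sprintf("load_gene_sets: dropped %d unannotated gene occurrence(s)", n_unannotated))
  out
}
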