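# Readers and writers for the on-disk formats. Canonical tabular dialect is
# TSV, UTF-8, '.' for missing; genomic coordinates are 1-based inclusive
# everywhere. Output files carry a header comment with the tool version and
# a configuration hash.

#' @noRd
check_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "start", "end", "biotype", "mappability")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(annotation$end < annotation$start))
    stopf("annotation has end < start for gene(s): %s",
          paste(utils::head(annotation$gene_id[annotation$end < annotation$start], 5),
                collapse = ", "))
  if (anyDuplicated(annotation$gene_id)) stopf("duplicated gene ids in annotation")
  annotation
}

#' @noRd
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' @noRd
write_with_header <- function(df, path, config = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# transpco %s; config=%s",
                     as.character(utils::packageVersion("transpco")),
                     config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", "."), quote = "", ...)
}

#' Read / write a samples x genes expression matrix
#'
#' TSV with a header row of gene ids and the first column holding sample
#' ids.
#'
#' @param path file path.
#' @return numeric matrix with sample rownames and gene colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_expression(m)
  m
}

#' @rdname read_expression
#' @param x expression matrix to write.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write_with_header(df, path, list(genes = ncol(x)))
  invisible(path)
}

#' Read / write gene annotation
#'
#' TSV with columns gene_id, chrom, start, end, biotype, mappability;
#' 1-based inclusive coordinates.
#'
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  check_annotation(read_tsv(path))
}

#' @rdname read_annotation
#' @param annotation annotation data.frame to write.
#' @export
write_annotation <- function(annotation, path) {
  write_with_header(check_annotation(annotation), path, list())
  invisible(path)
}

#' Read / write a cross-mappability table
#'
#' TSV with columns gene_a, gene_b; the symmetric closure is applied on
#' load and self-pairs are rejected.
#'
#' @param path file path.
#' @return data.frame with gene_a, gene_b (symmetric).
#' @export
read_crossmap <- function(path) {
  cm <- read_tsv(path)
  if (!all(c("gene_a", "gene_b") %in% names(cm)))
    stopf("crossmap file needs columns gene_a, gene_b")
  if (any(cm$gene_a == cm$gene_b)) stopf("crossmap contains self-pairs")
  out <- unique(rbind(cm[, c("gene_a", "gene_b")],
                      data.frame(gene_a = cm$gene_b, gene_b = cm$gene_a)))
  rownames(out) <- NULL
  out
}

#' @rdname read_crossmap
#' @param crossmap pair data.frame to write.
#' @export
write_crossmap <- function(crossmap, path) {
  write_with_header(crossmap, path, list())
  invisible(path)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF: the DS (dosage) FORMAT field is preferred; GT hard calls are used
#' otherwise. Dosage TSV: columns snp_id, chrom, pos, then one column per
#' sample. Missing genotypes are preserved as NA.
#'
#' @param path file path (`.vcf` / `.vcf.gz` or TSV).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_genotypes_vcf(path))
  }
  df <- read_tsv(path)
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("dosage file missing column(s): %s", paste(miss, collapse = ", "))
  D <- t(as.matrix(df[, setdiff(names(df), need), drop = FALSE]))
  storage.mode(D) <- "double"
  if (any(D < -1e-9 | D > 2 + 1e-9, na.rm = TRUE)) stopf("dosages outside [0, 2] in %s", path)
  genotype_matrix(D, df[, need])
}

#' @noRd
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  snps <- data.frame(snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                     fix[, "ID"]),
                     chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    D <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    D[clean == "0/0"] <- 0; D[clean %in% c("0/1", "1/0")] <- 1; D[clean == "1/1"] <- 2
    if (any(!is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1"))))
      stopf("unsupported GT record(s) in %s (only biallelic diploid calls)", path)
  }
  genotype_matrix(t(D), snps)
}

#' Read / write SNP x gene Z-score panels
#'
#' Wide dialect: columns snp_id, chrom, pos, then one column per gene. Long
#' dialect: columns snp (or snp_id), gene, z, with optional chrom/pos. Both
#' produce the same `zpanel`.
#'
#' @param path file path.
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @return a `zpanel`.
#' @export
read_zpanel <- function(path, format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  df <- read_tsv(path)
  nm <- names(df)
  if (format == "auto") {
    format <- if (all(c("gene", "z") %in% nm)) "long" else "wide"
  }
  if (format == "long") {
    snp_col <- intersect(c("snp", "snp_id"), nm)[1]
    if (is.na(snp_col)) stopf("long Z panel needs a snp/snp_id column")
    genes <- sort(unique(df$gene))
    snp_ids <- unique(df[[snp_col]])
    Z <- matrix(NA_real_, length(snp_ids), length(genes),
                dimnames = list(snp_ids, genes))
    Z[cbind(match(df[[snp_col]], snp_ids), match(df$gene, genes))] <- df$z
    if (anyNA(Z)) stopf("long Z panel is not a complete SNP x gene grid")
    info <- df[!duplicated(df[[snp_col]]), , drop = FALSE]
    snps <- data.frame(snp_id = info[[snp_col]],
                       chrom = if ("chrom" %in% nm) info$chrom else NA_character_,
                       pos = if ("pos" %in% nm) info$pos else NA_integer_)
  } else {
    need <- c("snp_id", "chrom", "pos")
    miss <- setdiff(need, nm)
    if (length(miss)) stopf("wide Z panel missing column(s): %s", paste(miss, collapse = ", "))
    genes <- setdiff(nm, need)
    Z <- as.matrix(df[, genes, drop = FALSE])
    storage.mode(Z) <- "double"
    rownames(Z) <- df$snp_id
    snps <- df[, need]
  }
  if (!all(is.finite(Z))) stopf("Z panel contains non-finite values")
  structure(list(Z = Z, snps = snps, gene_ids = colnames(Z), n = NA_integer_),
            class = "zpanel")
}

#' @rdname read_zpanel
#' @param zpanel panel to write (wide dialect).
#' @export
write_zpanel <- function(zpanel, path) {
  df <- data.frame(zpanel$snps, zpanel$Z, check.names = FALSE)
  write_with_header(df, path, list(genes = length(zpanel$gene_ids)))
  invisible(path)
}

#' Write / read scan results
#'
#' Results are sorted by (module, p) on write; the significance flag is the
#' q-value (or Bonferroni) call from the scan.
#'
#' @param scan a `transpco_scan` (or compatible data.frame).
#' @param path file path.
#' @export
write_results <- function(scan, path) {
  df <- as.data.frame(scan)
  df <- df[order(df$module, df$p_pco), ]
  write_with_header(df, path, attr(scan, "config") %||% list())
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read_tsv(path)
}

#' Write gene modules to a GMT file
#'
#' @param modules list of [gene_module()] objects.
#' @param path file path.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(c(m$module_id, m$provenance, m$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
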