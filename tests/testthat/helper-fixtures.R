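# Shared small fixtures built in code.

sigma3 <- function(rho = 0.5) make_block_sigma(3, rho)

three_block_cohort_modules <- function() {
  sigma <- make_block_sigma(c(15, 15, 12), 0.5)
  genes <- rownames(sigma)
  list(sigma = sigma,
       modules = list(gene_module("M1", genes[1:15], "gene_set"),
                      gene_module("M2", genes[16:30], "gene_set"),
                      gene_module("M3", genes[31:42], "gene_set")))
}

tiny_annotation <- function() {
  make_annotation_and_crossmap(
    genes = c("gA", "gB", "gC", "gD"),
    chroms = c("chr1", "chr5", "chr7", "chr1"),
    crossmap_pairs = data.frame(gene_a = "gA", gene_b = "gB"))
}
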