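# Small in-code fixtures shared across tests.

# annotation with evenly spaced genes: one chromosome per element of
# `n_genes`, gene i starting at (i-1)*spacing + 1 with the given length
mk_ann <- function(n_genes, spacing = 1000L, len = 200L, chrom_extra = 5000L) {
  rows <- list()
  for (c_i in seq_along(n_genes)) {
    n <- n_genes[c_i]
    starts <- (seq_len(n) - 1L) * spacing + 1L
    rows[[c_i]] <- data.frame(
      gene_id = sprintf("c%d_g%03d", c_i, seq_len(n)),
      chrom = sprintf("chr%d", c_i),
      start = starts, end = starts + len - 1L,
      strand = "+", stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  lens <- tapply(tab$end, tab$chrom, max) + chrom_extra
  genome_annotation(tab, lens)
}

gene_by_rank <- function(ann, chrom, rank) {
  ann$genes$gene_id[ann$genes$chrom == chrom & ann$genes$rank == rank]
}

# generator configuration scaled down to a two-chromosome toy genome, with
# event counts that fit it
small_sim <- function(seed, genes_per_chrom = 50L, ...) {
  sim_config(seed = seed, n_chroms = 2L, genes_per_chrom = genes_per_chrom,
             n_planted_islands = 2L, n_tandem = 4L, n_proximal = 4L,
             n_block_dup = 1L, n_trd = 5L, n_dsd = 4L, n_module_genes = 10L,
             ...)
}

# expression matrix from an explicit value matrix under the default design
mk_expr <- function(values, kind = "TPM", lengths = NULL) {
  design <- sample_design()[seq_len(ncol(values)), , drop = FALSE]
  expression_matrix(values, design, kind = kind, gene_lengths = lengths)
}
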