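# Module-eigengene scoring of hub genes ("WGCNA-lite"): module labels are
# an input; only the eigengene, the membership/significance thresholds and
# the adjacent-hub grouping are computed here.

#' Module eigengene of a gene set
#'
#' Rows (genes) are z-scored, zero-variance rows are dropped with a
#' warning, and the eigengene is the first right singular vector of the
#' standardized module matrix: the per-sample scores of the first principal
#' component. The sign is fixed so that the mean gene-eigengene correlation
#' is non-negative, and the vector is scaled to unit variance.
#'
#' @param tpm an [expression_matrix()] (counts are TPM-normalised first).
#' @param module_genes gene ids of one module.
#' @return numeric vector with one score per sample.
#' @export
module_eigengene <- function(tpm, module_genes) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$kind == "counts") tpm <- counts_to_tpm(tpm)
  module_genes <- intersect(module_genes, rownames(tpm$values))
  if (!length(module_genes)) stop("empty module")
  x <- tpm$values[module_genes, , drop = FALSE]
  v <- apply(x, 1L, stats::sd)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(module_genes[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
    if (!nrow(x)) stop("no variable genes left in module")
  }
  xz <- t(scale(t(x)))
  sv <- svd(xz, nu = 0L, nv = 1L)
  eig <- sv$v[, 1L]
  corr <- suppressWarnings(stats::cor(t(xz), eig))
  if (mean(corr, na.rm = TRUE) < 0) eig <- -eig
  eig <- eig / stats::sd(eig)
  stats::setNames(eig, colnames(tpm$values))
}

# Two-sided p-value of a Pearson correlation via the t distribution with
# n - 2 degrees of freedom (the cor.test statistic).
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), n - 2)
}

#' Score genes for module membership and trait significance
#'
#' Module membership (MM) is the Pearson correlation of a gene's expression
#' with its module eigengene; gene significance (GS) is the correlation
#' with a binary stage-indicator trait (1 for samples of `trait_stage`,
#' else 0). Both thresholds apply to the signed correlations. A gene is a
#' hub when `MM >= mm_min`, `GS >= gs_min` and the GS correlation test
#' (t distribution, n - 2 df) gives `p < p_max`.
#'
#' @param tpm an [expression_matrix()] (counts are TPM-normalised first).
#' @param modules data.frame `gene_id`, `module` (one module per gene).
#' @param trait_stage stage label defining the trait indicator.
#' @param mm_min,gs_min,p_max hub thresholds (defaults 0.6, 0.5, 0.05).
#' @return data.frame `gene_id`, `module`, `MM`, `GS`, `gs_pvalue`, `is_hub`.
#' @export
hub_select <- function(tpm, modules, trait_stage,
                       mm_min = 0.6, gs_min = 0.5, p_max = 0.05) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$kind == "counts") tpm <- counts_to_tpm(tpm)
  n <- ncol(tpm$values)
  if (n < 5L) stop("need at least 5 samples")
  trait <- as.numeric(tpm$design$stage == trait_stage)
  if (length(unique(trait)) < 2L) stop("constant trait vector (unknown stage?)")
  modules <- modules[modules$gene_id %in% rownames(tpm$values), , drop = FALSE]
  if (anyDuplicated(modules$gene_id)) stop("a gene has more than one module")
  out <- list()
  for (m in sort(unique(modules$module))) {
    ids <- modules$gene_id[modules$module == m]
    eig <- module_eigengene(tpm, ids)
    x <- tpm$values[ids, , drop = FALSE]
    mm <- suppressWarnings(as.numeric(stats::cor(t(x), eig)))
    gs <- suppressWarnings(as.numeric(stats::cor(t(x), trait)))
    p <- cor_pvalue(gs, n)
    out[[m]] <- data.frame(
      gene_id = ids, module = m, MM = mm, GS = gs, gs_pvalue = p,
      is_hub = !is.na(mm) & !is.na(gs) &
        mm >= mm_min & gs >= gs_min & p < p_max,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group hub genes that are chromosome neighbors
#'
#' Finds maximal runs (length >= 2) of hub genes at consecutive chromosome
#' ranks, the signature of expression piggybacking, and reports the
#' intergenic spacers inside each run together with the members' duplication
#' modes so that the association with (non-)duplicated genes can be
#' inspected rather than assumed.
#'
#' @param hubs hub table from [hub_select()] (only `is_hub` rows are used).
#' @param ann a [genome_annotation()].
#' @param dup optional duplication calls from [classify_duplicates()].
#' @return data.frame `chrom`, `genes` (comma-joined), `n_genes`, `spacers`
#'   (comma-joined bp), `modes` (comma-joined), `all_non_duplicated`.
#' @export
neighbor_groups <- function(hubs, ann, dup = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  hub_ids <- hubs$gene_id[hubs$is_hub]
  g <- ann$genes
  modes <- if (is.null(dup)) NULL else stats::setNames(dup$mode, dup$gene_id)
  out <- list()
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, , drop = FALSE]
    gc <- gc[order(gc$rank), , drop = FALSE]
    is_hub <- gc$gene_id %in% hub_ids
    r <- rle(is_hub)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      run <- gc[starts[k]:ends[k], , drop = FALSE]
      spacers <- vapply(seq_len(nrow(run) - 1L), function(i) {
        as.integer(intergenic_spacer(run[i, ], run[i + 1L, ]))
      }, 0L)
      run_modes <- if (is.null(modes)) rep(NA_character_, nrow(run)) else
        unname(modes[run$gene_id])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        genes = paste(run$gene_id, collapse = ","),
        n_genes = nrow(run),
        spacers = paste(spacers, collapse = ","),
        modes = paste(run_modes, collapse = ","),
        all_non_duplicated = !is.null(modes) && all(run_modes == "singleton"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), genes = character(),
                      n_genes = integer(), spacers = character(),
                      modes = character(), all_non_duplicated = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
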