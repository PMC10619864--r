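#' Sample design for the staged heat-stress experiment
#'
#' The default design mirrors the study layout: a control stage `H0` and
#' heat-stress stages `H1`, `H3`, `H6`, `H12` (hours at stress temperature),
#' three biological replicates each, 15 samples in total.
#'
#' @param stages character vector of stage labels (control first).
#' @param replicates replicates per stage.
#' @return data.frame with `sample_id`, `stage`, `replicate`.
#' @export
sample_design <- function(stages = c("H0", "H1", "H3", "H6", "H12"),
                          replicates = 3L) {
  d <- expand.grid(replicate = seq_len(replicates), stage = stages,
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_R%d", d$stage, d$replicate),
    stage = d$stage,
    replicate = as.integer(d$replicate),
    stringsAsFactors = FALSE
  )
}

#' Construct an expression matrix
#'
#' @param values numeric gene-by-sample matrix with rownames = gene ids and
#'   colnames = sample ids; non-negative.
#' @param design sample design (see [sample_design()]); row order must match
#'   the matrix columns.
#' @param kind `"counts"` or `"TPM"`.
#' @param gene_lengths named vector of gene lengths in bp; required for
#'   `kind = "counts"` (used for TPM normalisation).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, design, kind = c("counts", "TPM"),
                              gene_lengths = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in matrix")
  if (any(values < 0)) stop("negative expression values")
  if (nrow(design) != ncol(values)) stop("design rows must match matrix columns")
  if (anyDuplicated(paste(design$stage, design$replicate))) {
    stop("(stage, replicate) pairs must be unique")
  }
  if (kind == "counts") {
    if (is.null(gene_lengths)) stop("gene_lengths required for kind = 'counts'")
    miss <- setdiff(rownames(values), names(gene_lengths))
    if (length(miss)) stop("missing gene length for ", miss[1L])
    gene_lengths <- gene_lengths[rownames(values)]
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  } else {
    cs <- colSums(values)
    ok <- cs == 0 | abs(cs - 1e6) <= 1e-6 * 1e6
    if (!all(ok)) stop("TPM columns must sum to 1e6")
  }
  structure(
    list(values = values, design = design, kind = kind,
         gene_lengths = gene_lengths),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Normalise counts to TPM
#'
#' TPM for gene g in sample s is
#' `(count_gs / length_g) / sum_g(count_gs / length_g) * 1e6`, so every
#' non-degenerate sample column sums to one million. An all-zero column
#' stays all-zero, with a warning.
#'
#' @param m an [expression_matrix()] of kind `"counts"`.
#' @return An [expression_matrix()] of kind `"TPM"`.
#' @export
counts_to_tpm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$kind != "counts") stop("input must be a counts matrix")
  rate <- m$values / m$gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero sample column(s): ",
            paste(colnames(m$values)[tot == 0], collapse = ", "))
  }
  tot[tot == 0] <- 1 # leaves the column at zero
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  expression_matrix(tpm, m$design, kind = "TPM")
}

# Vectorised Welch two-sample t-test on rows of two matrices.
# Returns two-sided p-values; degenerate rows (zero variance in both groups)
# get p = 1 when the means agree and p = 0 otherwise.
welch_row_p <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(m1))
  deg <- se2 == 0
  p[deg] <- ifelse(m1[deg] == m2[deg], 1, 0)
  i <- !deg
  tt <- (m1[i] - m2[i]) / sqrt(se2[i])
  df <- se2[i]^2 / ((v1[i] / n1)^2 / (n1 - 1) + (v2[i] / n2)^2 / (n2 - 1))
  p[i] <- 2 * stats::pt(-abs(tt), df)
  p
}

# Exact label-permutation p-values (two-sided, |difference of means|) over
# all choose(n1 + n2, n1) relabelings of the pooled columns. At 3 vs 3 the
# 20 assignments pair up by sign, so attainable p-values lie on the grid
# 1/10, 2/10, ..., 1.
perm_row_p <- function(x, y) {
  pool <- cbind(x, y)
  n1 <- ncol(x); n <- ncol(pool)
  sets <- utils::combn(n, n1)
  obs <- abs(rowMeans(x) - rowMeans(y))
  hits <- integer(nrow(pool))
  for (k in seq_len(ncol(sets))) {
    idx <- sets[, k]
    stat <- abs(rowMeans(pool[, idx, drop = FALSE]) -
                  rowMeans(pool[, -idx, drop = FALSE]))
    hits <- hits + (stat >= obs - 1e-12)
  }
  hits / ncol(sets)
}

#' Call differentially expressed genes per contrast
#'
#' Each heat stage is contrasted against the control `H0`. The fold change
#' is computed on TPM with a pseudocount:
#' `log2fc = log2((mean treated TPM + c) / (mean control TPM + c))`, c = 1.
#' A gene is `up` when `log2fc > 1` and `pvalue < 0.05`, `down` when
#' `log2fc < -1` and `pvalue < 0.05`, otherwise `ns` (the "fold change > 2
#' and p < 0.05" rule).
#'
#' Internal p-value methods are a Welch t-test on `log2(TPM + 1)` and an
#' exact label-permutation test (whose p-value grid at 3 vs 3 bottoms out at
#' 1/10, i.e. it can never satisfy p < 0.05 with default replication; it is
#' provided for designs with more replicates). The canonical route for
#' model-based results is `method = "plugin"` with an externally computed
#' table of `gene_id`, `contrast`, `log2fc`, `pvalue`.
#'
#' @param m an [expression_matrix()] (counts are TPM-normalised first).
#' @param method `"welch"`, `"permutation"` or `"plugin"`.
#' @param contrasts contrast labels, `"<stage>vsH0"`.
#' @param plugin_table data.frame or TSV path for `method = "plugin"`.
#' @param pseudocount pseudocount for the fold change (default 1).
#' @param adjust if `TRUE`, add a Benjamini-Hochberg `padj` column per
#'   contrast (status still uses the raw p-value rule).
#' @return data.frame `gene_id`, `contrast`, `log2fc`, `pvalue`, `status`.
#' @export
call_degs <- function(m, method = c("welch", "permutation", "plugin"),
                      contrasts = c("H1vsH0", "H3vsH0", "H6vsH0", "H12vsH0"),
                      plugin_table = NULL, pseudocount = 1, adjust = FALSE) {
  method <- match.arg(method)

  if (method == "plugin") {
    if (is.character(plugin_table)) {
      plugin_table <- utils::read.delim(plugin_table, stringsAsFactors = FALSE)
    }
    need <- c("gene_id", "contrast", "log2fc", "pvalue")
    miss <- setdiff(need, names(plugin_table))
    if (length(miss)) {
      stop("plugin DE table is missing column(s): ", paste(miss, collapse = ", "))
    }
    bad <- setdiff(unique(plugin_table$contrast), contrasts)
    if (length(bad)) stop("unknown contrast label: ", bad[1L])
    de <- plugin_table[need]
  } else {
    stopifnot(inherits(m, "expression_matrix"))
    if (m$kind == "counts") m <- counts_to_tpm(m)
    stages <- sub("vsH0$", "", contrasts)
    bad <- setdiff(stages, m$design$stage)
    if (length(bad)) stop("unknown contrast label: ", bad[1L], "vsH0")
    ctl <- m$values[, m$design$stage == "H0", drop = FALSE]
    if (ncol(ctl) < 2L) stop("need >= 2 control replicates")
    lt_ctl <- log2(ctl + 1)
    out <- vector("list", length(contrasts))
    for (i in seq_along(contrasts)) {
      trt <- m$values[, m$design$stage == stages[i], drop = FALSE]
      if (ncol(trt) < 2L) stop("need >= 2 replicates for stage ", stages[i])
      lfc <- log2((rowMeans(trt) + pseudocount) / (rowMeans(ctl) + pseudocount))
      p <- switch(method,
        welch = welch_row_p(log2(trt + 1), lt_ctl),
        permutation = perm_row_p(log2(trt + 1), lt_ctl)
      )
      out[[i]] <- data.frame(
        gene_id = rownames(m$values), contrast = contrasts[i],
        log2fc = lfc, pvalue = p, stringsAsFactors = FALSE, row.names = NULL
      )
    }
    de <- do.call(rbind, out)
  }

  de$status <- "ns"
  de$status[de$log2fc > 1 & de$pvalue < 0.05] <- "up"
  de$status[de$log2fc < -1 & de$pvalue < 0.05] <- "down"
  if (adjust) {
    de$padj <- stats::ave(de$pvalue, de$contrast,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  }
  rownames(de) <- NULL
  de
}

#' Build per-stage up/down pattern gene sets
#'
#' `H1UP` is the set of genes upregulated in the H1-vs-H0 contrast, and so
#' on for the other stages and for the DOWN sets. `anyUP` / `anyDOWN` are
#' the unions "regulated in one or more conditions"; a gene that is up at
#' one stage and down at another belongs to both unions, so the union sizes
#' may sum to more than the number of distinct regulated genes.
#'
#' @param de differential-expression table from [call_degs()].
#' @return named list of sorted gene-id vectors.
#' @export
pattern_sets <- function(de) {
  stages <- c("H1", "H3", "H6", "H12")
  sets <- list()
  for (s in stages) {
    co <- paste0(s, "vsH0")
    sets[[paste0(s, "UP")]] <-
      sort(unique(de$gene_id[de$contrast == co & de$status == "up"]))
    sets[[paste0(s, "DOWN")]] <-
      sort(unique(de$gene_id[de$contrast == co & de$status == "down"]))
  }
  sets$anyUP <- sort(unique(unlist(sets[paste0(stages, "UP")], use.names = FALSE)))
  sets$anyDOWN <- sort(unique(unlist(sets[paste0(stages, "DOWN")], use.names = FALSE)))
  sets
}

#' Percentage of differentially expressed genes
#'
#' @param n_deg number of DEGs.
#' @param n_total total annotated genes.
#' @return percentage, rounded to 2 decimals.
#' @export
deg_summary <- function(n_deg, n_total) {
  if (length(n_total) != 1L || is.na(n_total) || n_total <= 0) {
    stop("n_total must be a positive count")
  }
  if (any(n_deg < 0) || any(n_deg > n_total)) stop("n_deg must lie in [0, n_total]")
  round(100 * n_deg / n_total, 2)
}

#' Build a plug-in DE table with DESeq2
#'
#' Convenience for the canonical plug-in route of [call_degs()]: fits the
#' count model across all stages and extracts one Wald contrast per heat
#' stage against the control. Requires the DESeq2 package.
#'
#' @param m an [expression_matrix()] of kind `"counts"`.
#' @param contrasts contrast labels, `"<stage>vsH0"`.
#' @return data.frame `gene_id`, `contrast`, `log2fc`, `pvalue` suitable
#'   for `call_degs(method = "plugin")`.
#' @export
deseq2_plugin_table <- function(m, contrasts = c("H1vsH0", "H3vsH0",
                                                 "H6vsH0", "H12vsH0")) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$kind != "counts") stop("DESeq2 needs raw counts")
  if (!requireNamespace("DESeq2", quietly = TRUE)) {
    stop("the DESeq2 package is required for deseq2_plugin_table()")
  }
  stages <- unique(m$design$stage)
  coldata <- data.frame(stage = factor(m$design$stage, levels = stages))
  dds <- DESeq2::DESeqDataSetFromMatrix(round(m$values), coldata, ~stage)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  out <- lapply(contrasts, function(co) {
    s <- sub("vsH0$", "", co)
    r <- DESeq2::results(dds, contrast = c("stage", s, "H0"))
    data.frame(gene_id = rownames(r), contrast = co,
               log2fc = r$log2FoldChange, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a counts matrix and design from TSV files
#'
#' @param counts_path TSV with gene ids in the first column and one column
#'   per sample.
#' @param design_path TSV with `sample_id`, `stage`, `replicate`.
#' @param gene_lengths named vector of gene lengths in bp.
#' @return An [expression_matrix()] of kind `"counts"`.
#' @export
read_counts <- function(counts_path, design_path, gene_lengths) {
  tab <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("design does not cover all count columns")
  expression_matrix(values, design, kind = "counts", gene_lengths = gene_lengths)
}
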