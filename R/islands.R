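#' Parameters of the expression-island scan
#'
#' A genomic region qualifies as an island when at least
#' `min_pattern_genes` pattern genes make up strictly more than
#' `min_pattern_fraction` of the expressed genes in a `window_bp` window
#' (defaults: >= 3 genes, > 60%, 50 kb). The expressed-gene background
#' defaults to genes with mean TPM above `expressed_min_tpm` across all
#' samples (default 2), the same filter used for co-expression input.
#'
#' @param window_bp window size in bp.
#' @param min_pattern_genes minimum pattern genes in a qualifying window.
#' @param min_pattern_fraction strict lower bound on the pattern fraction.
#' @param expressed_min_tpm mean-TPM threshold defining "expressed".
#' @return list of class `island_params`.
#' @export
island_params <- function(window_bp = 50000L, min_pattern_genes = 3L,
                          min_pattern_fraction = 0.60,
                          expressed_min_tpm = 2) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (min_pattern_fraction <= 0 || min_pattern_fraction >= 1) {
    stop("min_pattern_fraction must lie in (0, 1)")
  }
  structure(
    list(window_bp = as.integer(window_bp),
         min_pattern_genes = as.integer(min_pattern_genes),
         min_pattern_fraction = min_pattern_fraction,
         expressed_min_tpm = expressed_min_tpm),
    class = "island_params"
  )
}

#' Expressed genes under the mean-TPM filter
#'
#' @param tpm an [expression_matrix()] (counts are TPM-normalised first).
#' @param min_tpm mean-TPM threshold (strict).
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(tpm, min_tpm = 2) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$kind == "counts") tpm <- counts_to_tpm(tpm)
  rownames(tpm$values)[rowMeans(tpm$values) > min_tpm]
}

#' Scan a genome for islands of co-localised pattern genes
#'
#' Candidate windows `[s, s + window_bp - 1]` are anchored at the start
#' coordinate of every expressed gene; a gene belongs to a window when its
#' start lies inside it. A window qualifies when it holds at least
#' `min_pattern_genes` pattern genes and the pattern genes exceed
#' `min_pattern_fraction` of its expressed genes (strict). Overlapping
#' qualifying windows on a chromosome are merged transitively; each merged
#' region becomes one island spanning from the minimum start to the maximum
#' end of the pattern genes inside it, so island sizes are data-driven
#' rather than multiples of the window.
#'
#' @param ann a [genome_annotation()].
#' @param pattern_genes gene ids with the pattern (e.g. the H1UP set).
#' @param expressed gene ids forming the expressed background
#'   (`pattern_genes` must be a subset).
#' @param de optional DE table from [call_degs()]; with `contrast`, fills
#'   the member log2 fold-change summaries.
#' @param dup optional duplication calls from [classify_duplicates()]; fills
#'   the duplicated-member count (mode != singleton).
#' @param params an [island_params()].
#' @param contrast contrast label whose log2fc annotates members.
#' @return data.frame with one row per island: `chrom`, `start`, `end`,
#'   `n_pattern_genes`, `members` (comma-joined ids), `expressed_in_span`,
#'   `mean_log2fc`, `median_log2fc`, `n_duplicated`, plus a `member_log2fc`
#'   list column used by [summarize_islands()].
#' @export
scan_islands <- function(ann, pattern_genes, expressed, de = NULL, dup = NULL,
                         params = island_params(), contrast = NULL) {
  stopifnot(inherits(ann, "genome_annotation"), inherits(params, "island_params"))
  g <- ann$genes
  missing_ann <- setdiff(expressed, g$gene_id)
  if (length(missing_ann)) {
    stop("expressed gene absent from annotation: ", missing_ann[1L])
  }
  stray <- setdiff(pattern_genes, expressed)
  if (length(stray)) {
    stop("pattern gene not in the expressed background: ", stray[1L])
  }

  lfc <- NULL
  if (!is.null(de) && !is.null(contrast)) {
    dd <- de[de$contrast == contrast, , drop = FALSE]
    lfc <- stats::setNames(dd$log2fc, dd$gene_id)
  }
  dup_genes <- if (is.null(dup)) character() else
    dup$gene_id[dup$mode != "singleton"]

  W <- params$window_bp
  islands <- list()
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr & g$gene_id %in% expressed, , drop = FALSE]
    gc <- gc[order(gc$start, gc$end, gc$gene_id), , drop = FALSE]
    if (!nrow(gc)) next
    is_pat <- gc$gene_id %in% pattern_genes
    starts <- gc$start
    n <- nrow(gc)
    cum <- c(0L, cumsum(is_pat))
    qual_s <- integer(0)
    for (i in seq_len(n)) {
      hi <- starts[i] + W - 1L
      j <- i
      while (j < n && starts[j + 1L] <= hi) j <- j + 1L
      n_exp <- j - i + 1L
      n_pat <- cum[j + 1L] - cum[i]
      if (n_pat >= params$min_pattern_genes &&
          n_pat / n_exp > params$min_pattern_fraction) {
        qual_s <- c(qual_s, starts[i])
      }
    }
    if (!length(qual_s)) next
    merged <- IRanges::reduce(IRanges::IRanges(qual_s, qual_s + W - 1L))
    for (k in seq_along(merged)) {
      lo <- IRanges::start(merged)[k]
      hi <- IRanges::end(merged)[k]
      mem <- gc[is_pat & starts >= lo & starts <= hi, , drop = FALSE]
      if (!nrow(mem)) next
      mlfc <- if (is.null(lfc)) rep(NA_real_, nrow(mem)) else
        unname(lfc[mem$gene_id])
      islands[[length(islands) + 1L]] <- data.frame(
        chrom = chr,
        start = min(mem$start),
        end = max(mem$end),
        n_pattern_genes = nrow(mem),
        members = paste(mem$gene_id, collapse = ","),
        expressed_in_span = sum(starts >= min(mem$start) & starts <= max(mem$end)),
        mean_log2fc = mean(mlfc),
        median_log2fc = stats::median(mlfc),
        n_duplicated = sum(mem$gene_id %in% dup_genes),
        stringsAsFactors = FALSE
      )
      islands[[length(islands)]]$member_log2fc <- I(list(mlfc))
    }
  }
  if (!length(islands)) {
    out <- data.frame(
      chrom = character(), start = integer(), end = integer(),
      n_pattern_genes = integer(), members = character(),
      expressed_in_span = integer(), mean_log2fc = numeric(),
      median_log2fc = numeric(), n_duplicated = integer(),
      stringsAsFactors = FALSE
    )
    out$member_log2fc <- I(list())
    return(out)
  }
  res <- do.call(rbind, islands)
  rownames(res) <- NULL
  res
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Summarise islands for one pattern set
#'
#' Reproduces the per-pattern island statistics row: totals, island count,
#' mean island size and mean member log2 fold change with their standard
#' errors (and the member-log2fc median), mean pattern genes per island
#' (with the maximum), and the duplicated-member count with its percentage
#' of island genes.
#'
#' @param islands island table from [scan_islands()] for a single pattern.
#' @param pattern pattern label (e.g. `"H1UP"`).
#' @param n_pattern_total number of pattern genes genome-wide.
#' @return one-row data.frame; size and fold-change fields are `NA` when no
#'   island exists.
#' @export
summarize_islands <- function(islands, pattern, n_pattern_total) {
  n_isl <- nrow(islands)
  if (n_isl == 0L) {
    return(data.frame(
      pattern = pattern, n_pattern_genes_total = n_pattern_total,
      n_pattern_genes_in_islands = 0L, n_islands = 0L,
      mean_island_size_bp = NA_real_, sem_island_size_bp = NA_real_,
      mean_log2fc = NA_real_, sem_log2fc = NA_real_, median_log2fc = NA_real_,
      mean_genes_per_island = NA_real_, sem_genes_per_island = NA_real_,
      max_genes_per_island = NA_integer_,
      n_duplicated_in_islands = 0L, duplicated_pct = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  sizes <- islands$end - islands$start + 1L
  member_lfc <- unlist(islands$member_log2fc, use.names = FALSE)
  n_in <- sum(islands$n_pattern_genes)
  n_dup <- sum(islands$n_duplicated)
  data.frame(
    pattern = pattern, n_pattern_genes_total = n_pattern_total,
    n_pattern_genes_in_islands = n_in, n_islands = n_isl,
    mean_island_size_bp = mean(sizes), sem_island_size_bp = sem(sizes),
    mean_log2fc = mean(member_lfc), sem_log2fc = sem(member_lfc),
    median_log2fc = stats::median(member_lfc),
    mean_genes_per_island = mean(islands$n_pattern_genes),
    sem_genes_per_island = sem(islands$n_pattern_genes),
    max_genes_per_island = max(islands$n_pattern_genes),
    n_duplicated_in_islands = n_dup,
    duplicated_pct = round(100 * n_dup / n_in, 2),
    stringsAsFactors = FALSE
  )
}

#' Write islands as a BED file
#'
#' Output intervals are 0-based half-open (`start - 1`, `end`), the BED
#' convention; internal coordinates stay 1-based inclusive.
#'
#' @param islands island table from [scan_islands()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
islands_to_bed <- function(islands, path) {
  lines <- sprintf("%s\t%d\t%d\tisland_%d\t%d\t.",
                   islands$chrom, islands$start - 1L, islands$end,
                   seq_len(nrow(islands)), islands$n_pattern_genes)
  writeLines(lines, path)
  invisible(path)
}
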