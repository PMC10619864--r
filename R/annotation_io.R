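#' Build a genome annotation from a gene table
#'
#' The annotation is the coordinate backbone shared by the island scanner,
#' the duplication classifier and the neighbor-group analysis. Coordinates
#' are 1-based and inclusive (GFF3 native) throughout the package; any
#' conversion (e.g. BED output) is explicit at the boundary.
#'
#' Each gene receives a `rank`: its 0-based index along its chromosome when
#' genes are ordered by ascending start, ties broken by ascending end and
#' then lexicographic gene id. Ranks are the unit of "distance" for tandem
#' and proximal duplicate calls and for collinearity chaining.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`). Extra columns are dropped.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to the maximum gene end per chromosome.
#' @return An object of class `genome_annotation`: a list with `genes`
#'   (data.frame incl. `rank`) and `chrom_lengths`.
#' @export
genome_annotation <- function(genes, chrom_lengths = NULL) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(genes)) stop("`genes` must be a data.frame")
  miss <- setdiff(required, names(genes))
  if (length(miss)) stop("`genes` is missing columns: ", paste(miss, collapse = ", "))
  genes <- data.frame(
    gene_id = as.character(genes$gene_id),
    chrom   = as.character(genes$chrom),
    start   = as.integer(genes$start),
    end     = as.integer(genes$end),
    strand  = as.character(genes$strand),
    stringsAsFactors = FALSE
  )
  if (anyNA(genes$start) || anyNA(genes$end)) {
    stop("non-numeric gene coordinates")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene ID: ", dup[1L])
  bad <- which(genes$start > genes$end)
  if (length(bad)) stop("start > end for gene ", genes$gene_id[bad[1L]])
  if (any(genes$start < 1L)) stop("gene start below 1 (coordinates are 1-based)")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- as.integer(
    stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)
  ) - 1L
  rownames(genes) <- NULL

  if (is.null(chrom_lengths)) {
    cl <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(cl), names(cl))
  } else {
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  miss_chr <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(miss_chr)) stop("no chromosome length for: ", paste(miss_chr, collapse = ", "))
  over <- genes$end > chrom_lengths[genes$chrom]
  if (any(over)) {
    stop("gene ", genes$gene_id[which(over)[1L]], " extends beyond its chromosome length")
  }

  structure(
    list(genes = genes, chrom_lengths = chrom_lengths),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d genes on %d chromosome(s)\n",
    nrow(x$genes), length(x$chrom_lengths)
  ))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Only features of type `gene` are used; each must carry an `ID` attribute.
#' A light structural pre-check reports the first malformed line by number
#' before the file is handed to the GFF3 parser. Chromosome lengths are taken
#' from `##sequence-region` directives when present.
#'
#' @param path path to a GFF3 file.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L ||
        is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      stop(sprintf("malformed GFF3 line %d in %s", i, path))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  if (!length(gr)) stop("no gene features found in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("gene feature without an ID attribute in ", path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  genes <- data.frame(
    gene_id = as.character(ids),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = BiocGenerics::start(gr),
    end     = BiocGenerics::end(gr),
    strand  = strand,
    stringsAsFactors = FALSE
  )

  chrom_lengths <- NULL
  sr <- lines[startsWith(lines, "##sequence-region")]
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    ok <- vapply(parts, length, 1L) >= 4L
    parts <- parts[ok]
    if (length(parts)) {
      chrom_lengths <- stats::setNames(
        vapply(parts, function(p) as.numeric(p[4L]), 0),
        vapply(parts, function(p) p[2L], "")
      )
      chrom_lengths <- chrom_lengths[names(chrom_lengths) %in% genes$chrom]
      if (!length(chrom_lengths)) chrom_lengths <- NULL
    }
  }
  genome_annotation(genes, chrom_lengths)
}

#' Write a genome annotation as GFF3
#'
#' Emits `##sequence-region` directives and one `gene` feature per gene so
#' that `read_gff3(write_gff3(ann))` reproduces `ann` exactly.
#'
#' @param ann a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  header <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d",
            names(ann$chrom_lengths), as.integer(ann$chrom_lengths))
  )
  rows <- sprintf("%s\tmossheat\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$chrom, g$start, g$end, g$strand, g$gene_id)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Validate the invariants of a genome annotation
#'
#' Checks rank/start monotonicity per chromosome, uniqueness of gene ids and
#' containment of every gene within its chromosome. Used after any
#' programmatic edit of the gene table.
#'
#' @param ann a [genome_annotation()].
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids")
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, , drop = FALSE]
    gc <- gc[order(gc$rank), , drop = FALSE]
    if (!identical(gc$rank, seq_len(nrow(gc)) - 1L)) {
      stop("ranks on ", chr, " are not 0..n-1")
    }
    if (is.unsorted(gc$start)) stop("rank order disagrees with start order on ", chr)
  }
  if (any(g$end > ann$chrom_lengths[g$chrom])) stop("gene beyond chromosome end")
  invisible(TRUE)
}

#' Intergenic spacer between two rank-adjacent genes
#'
#' The spacer is the number of bases strictly between the two gene bodies,
#' `b$start - a$end - 1`. Overlapping gene bodies yield 0 with the
#' `"overlap"` attribute set to `TRUE`.
#'
#' @param a,b single gene records (one-row data.frames or lists with fields
#'   `chrom`, `rank`, `start`, `end`); `b` must directly follow `a` in rank
#'   on the same chromosome.
#' @return integer bp, with attribute `overlap` (logical).
#' @export
intergenic_spacer <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) {
    stop("contract violation: genes are on different chromosomes")
  }
  if (a$rank + 1L != b$rank) {
    stop("contract violation: genes are not rank-adjacent (",
         a$rank, " then ", b$rank, ")")
  }
  sp <- as.integer(b$start) - as.integer(a$end) - 1L
  structure(max(sp, 0L), overlap = sp < 0L)
}

# Look up one gene row by id (internal convenience for spacer arithmetic).
gene_row <- function(ann, gene_id) {
  i <- match(gene_id, ann$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  ann$genes[i, , drop = FALSE]
}
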