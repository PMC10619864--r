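#' Read a homolog-pair table
#'
#' Pairs are unordered; each is canonicalised so `gene_a < gene_b`
#' lexicographically and duplicates collapse to the highest score.
#'
#' @param x data.frame or TSV path with columns `gene_a`, `gene_b`, `score`.
#' @return data.frame `gene_a`, `gene_b`, `score`.
#' @export
read_homolog_pairs <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("homolog pair table missing column(s): ",
                         paste(miss, collapse = ", "))
  a <- as.character(x$gene_a); b <- as.character(x$gene_b)
  if (any(a == b)) stop("self-pair not allowed: ", a[a == b][1L])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, score = as.numeric(x$score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, -out$score), , drop = FALSE]
  out <- out[!duplicated(paste(out$gene_a, out$gene_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest orientation-consistent chain through a dot table (ra, rb sorted by
# ra then rb). Steps must advance strictly on both axes with rank gaps
# <= max_gap; rb ascends for "same" orientation and descends for "inverted".
# Returns indices into the dot table, or integer(0).
best_chain_one <- function(ra, rb, max_gap, inverted) {
  n <- length(ra)
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[i] <= ra[j] || ra[i] - ra[j] > max_gap) next
      ok <- if (inverted) rb[i] < rb[j] && rb[j] - rb[i] <= max_gap
            else          rb[i] > rb[j] && rb[i] - rb[j] <= max_gap
      if (ok && len[j] + 1L > len[i]) { # first best predecessor wins (deterministic)
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(len) # ties resolve to the earliest (leftmost) end
  chain <- integer(0)
  while (end != 0L) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  chain
}

#' Chain homolog pairs into collinear blocks
#'
#' Deterministic dynamic-programming chaining on the gene-rank dot plot: for
#' each chromosome pair, homolog dots are chained with per-step rank gaps of
#' at most `max_gap` on both axes and a single orientation (both ranks
#' ascending, or the second descending for inverted blocks). Chains are
#' extracted greedily by anchor count (ties: leftmost start, then same
#' orientation first); every dot joins at most one block; chains shorter
#' than `min_block` are discarded.
#'
#' @param pairs homolog pairs (see [read_homolog_pairs()]).
#' @param ann a [genome_annotation()].
#' @param min_block minimum anchors per block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @return list of blocks, each a list with `chrom_a`, `chrom_b`,
#'   `orientation` and an `anchors` data.frame (`gene_a`, `gene_b`,
#'   `rank_a`, `rank_b`).
#' @export
chain_collinear_blocks <- function(pairs, ann, min_block = 5L, max_gap = 25L) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (min_block < 2L) stop("config error: min_block must be >= 2")
  pairs <- read_homolog_pairs(pairs)
  if (!nrow(pairs)) return(list())
  g <- ann$genes
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), g$gene_id)
  if (length(unknown)) stop("unknown gene in pair table: ", unknown[1L])
  ia <- match(pairs$gene_a, g$gene_id)
  ib <- match(pairs$gene_b, g$gene_id)
  dots <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    ca = g$chrom[ia], ra = g$rank[ia],
    cb = g$chrom[ib], rb = g$rank[ib],
    stringsAsFactors = FALSE
  )
  # canonical axis order per dot: (chrom, rank) of the first axis <= second
  swap <- dots$ca > dots$cb | (dots$ca == dots$cb & dots$ra > dots$rb)
  dots[swap, c("gene_a", "gene_b", "ca", "ra", "cb", "rb")] <-
    dots[swap, c("gene_b", "gene_a", "cb", "rb", "ca", "ra")]
  # local (tandem/proximal) dots hug the self-comparison diagonal and are
  # not collinearity evidence; filter them before chaining, as synteny
  # pipelines do with tandem hits
  local <- dots$ca == dots$cb & (dots$rb - dots$ra) <= max_gap
  dots <- dots[!local, , drop = FALSE]
  if (!nrow(dots)) return(list())
  key <- paste(dots$ca, dots$cb)

  blocks <- list()
  for (k in sort(unique(key))) {
    d <- dots[key == k, , drop = FALSE]
    d <- d[order(d$ra, d$rb), , drop = FALSE]
    repeat {
      if (nrow(d) < min_block) break
      ch_same <- best_chain_one(d$ra, d$rb, max_gap, inverted = FALSE)
      ch_inv <- best_chain_one(d$ra, d$rb, max_gap, inverted = TRUE)
      pick_same <- length(ch_same) > length(ch_inv) ||
        (length(ch_same) == length(ch_inv) &&
           d$ra[ch_same[1L]] <= d$ra[ch_inv[1L]])
      chain <- if (pick_same) ch_same else ch_inv
      if (length(chain) < min_block) break
      anchors <- d[chain, c("gene_a", "gene_b", "ra", "rb"), drop = FALSE]
      names(anchors) <- c("gene_a", "gene_b", "rank_a", "rank_b")
      rownames(anchors) <- NULL
      blocks[[length(blocks) + 1L]] <- list(
        chrom_a = d$ca[1L], chrom_b = d$cb[1L],
        orientation = if (pick_same) "same" else "inverted",
        anchors = anchors
      )
      d <- d[-chain, , drop = FALSE]
    }
  }
  blocks
}

# All genes participating as anchors in any block.
block_anchor_genes <- function(blocks) {
  unique(unlist(lapply(blocks, function(b) c(b$anchors$gene_a, b$anchors$gene_b)),
                use.names = FALSE))
}

#' Classify genes into duplication modes
#'
#' Fixed per-gene precedence:
#' 1. **WGD** - the gene anchors an intra-genomic collinear block;
#' 2. **TD** (tandem) - a homolog at the adjacent rank on the same chromosome;
#' 3. **PD** (proximal) - a homolog within `proximal_window` ranks;
#' 4. **TRD** (transposed) - exactly one member of the gene's best-scoring
#'    pair sits at a syntenic (ancestral) locus, i.e. is a block anchor or is
#'    listed in `interspecies_anchors`; the syntenic member is the
#'    `ancestral` copy, the other the `novel` copy (a gene can only reach
#'    this rule as the ancestral copy via inter-species evidence, since
#'    intra-genomic anchors are already WGD);
#' 5. **DSD** (dispersed) - any remaining homolog;
#' 6. **singleton** - no homolog.
#'
#' The best-scoring pair is the one with the highest score, ties broken by
#' smaller rank distance and then lexicographic partner id.
#'
#' @param pairs homolog pairs (see [read_homolog_pairs()]).
#' @param blocks collinear blocks from [chain_collinear_blocks()].
#' @param ann a [genome_annotation()].
#' @param proximal_window maximum rank distance for proximal duplicates
#'   (default 10).
#' @param interspecies_anchors gene ids with inter-species synteny evidence.
#' @return data.frame `gene_id`, `mode`, `partner`, `trd_role` covering
#'   every annotated gene.
#' @export
classify_duplicates <- function(pairs, blocks, ann, proximal_window = 10L,
                                interspecies_anchors = character()) {
  stopifnot(inherits(ann, "genome_annotation"))
  pairs <- read_homolog_pairs(pairs)
  g <- ann$genes
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), g$gene_id)
  if (length(unknown)) stop("unknown gene in pair table: ", unknown[1L])
  anchors <- block_anchor_genes(blocks)
  syntenic <- union(anchors, interspecies_anchors)

  # per-gene partner list (both directions)
  half <- function(a, b, s) data.frame(gene = a, partner = b, score = s,
                                       stringsAsFactors = FALSE)
  links <- rbind(half(pairs$gene_a, pairs$gene_b, pairs$score),
                 half(pairs$gene_b, pairs$gene_a, pairs$score))
  ig <- match(links$gene, g$gene_id)
  ip <- match(links$partner, g$gene_id)
  links$same_chrom <- g$chrom[ig] == g$chrom[ip]
  links$rank_dist <- ifelse(links$same_chrom, abs(g$rank[ig] - g$rank[ip]), Inf)
  split_links <- split(links, links$gene)

  n <- nrow(g)
  mode <- rep("singleton", n)
  partner <- rep(NA_character_, n)
  trd_role <- rep("n/a", n)

  for (i in seq_len(n)) {
    id <- g$gene_id[i]
    lk <- split_links[[id]]
    if (id %in% anchors) {
      mode[i] <- "WGD"
      if (!is.null(lk)) {
        best <- lk[order(-lk$score, lk$rank_dist, lk$partner), , drop = FALSE][1L, ]
        partner[i] <- best$partner
      }
      next
    }
    if (is.null(lk)) next
    best <- lk[order(-lk$score, lk$rank_dist, lk$partner), , drop = FALSE][1L, ]
    td <- lk[lk$rank_dist == 1, , drop = FALSE]
    if (nrow(td)) {
      mode[i] <- "TD"
      partner[i] <- td[order(-td$score, td$partner), "partner"][1L]
      next
    }
    pd <- lk[lk$rank_dist >= 2 & lk$rank_dist <= proximal_window, , drop = FALSE]
    if (nrow(pd)) {
      mode[i] <- "PD"
      partner[i] <- pd[order(-pd$score, pd$rank_dist, pd$partner), "partner"][1L]
      next
    }
    self_syn <- id %in% syntenic
    partner_syn <- best$partner %in% syntenic
    if (xor(self_syn, partner_syn)) {
      mode[i] <- "TRD"
      partner[i] <- best$partner
      trd_role[i] <- if (self_syn) "ancestral" else "novel"
      next
    }
    mode[i] <- "DSD"
    partner[i] <- best$partner
  }

  data.frame(gene_id = g$gene_id, mode = mode, partner = partner,
             trd_role = trd_role, stringsAsFactors = FALSE)
}

#' Census of duplication modes
#'
#' @param calls classification table from [classify_duplicates()].
#' @return list with `counts` (named vector over WGD/TD/PD/TRD/DSD/singleton),
#'   `duplicated_total`, `n_genes` and `duplicated_pct` (2 decimals).
#' @export
mode_census <- function(calls) {
  modes <- c("WGD", "TD", "PD", "TRD", "DSD", "singleton")
  bad <- setdiff(unique(calls$mode), modes)
  if (length(bad)) stop("unknown mode: ", bad[1L])
  counts <- vapply(modes, function(m) sum(calls$mode == m), 0L)
  dup <- sum(counts[setdiff(modes, "singleton")])
  n <- nrow(calls)
  list(counts = counts, duplicated_total = dup, n_genes = n,
       duplicated_pct = deg_summary(dup, n))
}
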