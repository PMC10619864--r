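# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (plain loops, no sharing of code with the
# package internals) so that agreement is evidence of correctness.

GC_TABLE <- Biostrings::GENETIC_CODE

# --- literal Nei-Gojobori (1986) -------------------------------------------

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

oracle_syn_fraction <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (nt == chars[pos]) next
      alt <- chars
      alt[pos] <- nt
      if (GC_TABLE[[paste(alt, collapse = "")]] == GC_TABLE[[codon]]) {
        syn <- syn + 1
      }
    }
  }
  syn / 3
}

oracle_pair_diffs <- function(c1, c2) {
  x <- strsplit(c1, "")[[1]]
  y <- strsplit(c2, "")[[1]]
  pos <- which(x != y)
  if (!length(pos)) return(c(0, 0))
  syn_tot <- 0
  non_tot <- 0
  n_valid <- 0
  for (path in oracle_perms(pos)) {
    cur <- x
    syn <- 0
    non <- 0
    valid <- TRUE
    for (k in seq_along(path)) {
      nxt <- cur
      nxt[path[k]] <- y[path[k]]
      if (GC_TABLE[[paste(nxt, collapse = "")]] == "*" && k < length(path)) {
        valid <- FALSE
        break
      }
      if (GC_TABLE[[paste(nxt, collapse = "")]] ==
          GC_TABLE[[paste(cur, collapse = "")]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    if (valid) {
      syn_tot <- syn_tot + syn
      non_tot <- non_tot + non
      n_valid <- n_valid + 1
    }
  }
  if (n_valid == 0) c(0, 0) else c(syn_tot / n_valid, non_tot / n_valid)
}

oracle_ng86 <- function(codons_a, codons_b) {
  L <- length(codons_a)
  S_a <- 0
  S_b <- 0
  for (i in seq_len(L)) {
    S_a <- S_a + oracle_syn_fraction(codons_a[i])
    S_b <- S_b + oracle_syn_fraction(codons_b[i])
  }
  S <- (S_a + S_b) / 2
  N <- 3 * L - S
  Sd <- 0
  Nd <- 0
  for (i in seq_len(L)) {
    d <- oracle_pair_diffs(codons_a[i], codons_b[i])
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- if (ps >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * ps / 3)
  Ka <- if (pn >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * pn / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ka = Ka, Ks = Ks)
}

# random gap-free codon pair for oracle comparisons
random_codon_pair <- function(n_codons, n_mut = 6) {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (k in seq_len(n_mut)) {
    i <- sample(n_codons, 1)
    repeat {
      chars <- strsplit(b[i], "")[[1]]
      p <- sample(3, 1)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      cand <- paste(chars, collapse = "")
      if (GC_TABLE[[cand]] != "*") {
        b[i] <- cand
        break
      }
    }
  }
  list(a = a, b = b)
}

# --- per-position boolean coverage oracle ----------------------------------

oracle_coverage <- function(hits, class_filter) {
  if (!nrow(hits)) return(0)
  qlen <- hits$query_len[1]
  covered <- logical(qlen)
  for (i in seq_len(nrow(hits))) {
    if (hits$taxon_class[i] != class_filter) next
    covered[hits$q_start[i]:hits$q_end[i]] <- TRUE
  }
  sum(covered) / qlen
}

# --- literal per-gene duplication-rule enumerator --------------------------

oracle_classify <- function(pairs, blocks, ann, proximal_window = 10,
                            interspecies_anchors = character()) {
  g <- ann$genes
  anchor_genes <- character(0)
  for (b in blocks) anchor_genes <- c(anchor_genes, b$anchors$gene_a, b$anchors$gene_b)
  anchor_genes <- unique(anchor_genes)
  syntenic <- unique(c(anchor_genes, interspecies_anchors))
  res <- data.frame(gene_id = g$gene_id, mode = "singleton",
                    partner = NA_character_, trd_role = "n/a",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    # collect this gene's partners with scores and rank distances
    partners <- character(0); scores <- numeric(0); dists <- numeric(0)
    for (k in seq_len(nrow(pairs))) {
      other <- NULL
      if (pairs$gene_a[k] == id) other <- pairs$gene_b[k]
      if (pairs$gene_b[k] == id) other <- pairs$gene_a[k]
      if (is.null(other)) next
      gi <- g[g$gene_id == id, ]
      go <- g[g$gene_id == other, ]
      partners <- c(partners, other)
      scores <- c(scores, pairs$score[k])
      dists <- c(dists, if (gi$chrom == go$chrom) abs(gi$rank - go$rank) else Inf)
    }
    if (id %in% anchor_genes) {
      res$mode[i] <- "WGD"
      if (length(partners)) {
        o <- order(-scores, dists, partners)
        res$partner[i] <- partners[o[1]]
      }
      next
    }
    if (!length(partners)) next
    o <- order(-scores, dists, partners)
    if (any(dists == 1)) {
      res$mode[i] <- "TD"
      cand <- which(dists == 1)
      cand <- cand[order(-scores[cand], partners[cand])]
      res$partner[i] <- partners[cand[1]]
      next
    }
    if (any(dists >= 2 & dists <= proximal_window)) {
      res$mode[i] <- "PD"
      cand <- which(dists >= 2 & dists <= proximal_window)
      cand <- cand[order(-scores[cand], dists[cand], partners[cand])]
      res$partner[i] <- partners[cand[1]]
      next
    }
    best <- partners[o[1]]
    me_syn <- id %in% syntenic
    best_syn <- best %in% syntenic
    if (me_syn != best_syn) {
      res$mode[i] <- "TRD"
      res$partner[i] <- best
      res$trd_role[i] <- if (me_syn) "ancestral" else "novel"
      next
    }
    res$mode[i] <- "DSD"
    res$partner[i] <- best
  }
  res
}

# --- direct eigendecomposition oracle for the module eigengene -------------

oracle_eigengene <- function(x) {
  xz <- t(scale(t(x)))
  ev <- eigen(t(xz) %*% xz, symmetric = TRUE)
  e <- ev$vectors[, 1]
  if (mean(cor(t(xz), e)) < 0) e <- -e
  e / sd(e)
}

# --- every-bp island window oracle -----------------------------------------

# returns TRUE/FALSE per bp offset: does the window starting there qualify?
oracle_island_windows <- function(starts_expressed, is_pattern, chrom_len,
                                  window_bp, min_genes, min_frac) {
  qualifies <- function(s) {
    inside <- starts_expressed >= s & starts_expressed <= s + window_bp - 1
    n_exp <- sum(inside)
    n_pat <- sum(inside & is_pattern)
    n_pat >= min_genes && n_exp > 0 && n_pat / n_exp > min_frac
  }
  vapply(seq_len(max(1, chrom_len - window_bp + 1)), qualifies, TRUE)
}
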