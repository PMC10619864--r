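# Nei-Gojobori (1986) Ka/Ks on codon alignments, with a protein-guided
# codon pairing step and the Ks > 5 saturation filter.

# Two-sided rank-sum p; fully tied degenerate samples carry no evidence
# against the null and report p = 1 (wilcox.test's normal approximation
# yields NaN there).
wilcox_p <- function(x, y) {
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  if (is.nan(p)) 1 else p
}

.ng86 <- new.env(parent = emptyenv())

ng86_code <- function() {
  if (is.null(.ng86$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .ng86$aa <- stats::setNames(unname(gc), names(gc))
  }
  .ng86$aa
}

codon_aa <- function(codon) {
  aa <- ng86_code()[codon]
  if (anyNA(aa)) stop("invalid codon: ", codon[is.na(aa)][1L])
  unname(aa)
}

# Synonymous-site count for one codon: over the three positions, the number
# of the three possible single-nucleotide changes that preserve the amino
# acid, divided by 3. Changes producing a stop codon are non-synonymous.
syn_sites <- function(codon) {
  key <- paste0("S", codon)
  hit <- .ng86[[key]]
  if (!is.null(hit)) return(hit)
  aa <- ng86_code()
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  s <- 0L
  for (pos in 1:3) {
    for (nt in setdiff(nts, chars[pos])) {
      alt <- chars
      alt[pos] <- nt
      if (aa[paste(alt, collapse = "")] == aa[codon]) s <- s + 1L
    }
  }
  out <- s / 3
  assign(key, out, envir = .ng86)
  out
}

# Synonymous/non-synonymous difference counts for one aligned codon pair,
# averaged with equal weight over all shortest substitution pathways that do
# not traverse a stop codon. If every pathway hits a stop, the codon
# contributes sites but no differences.
codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("D", c1, c2)
  hit <- .ng86[[key]]
  if (!is.null(hit)) return(hit)
  aa <- ng86_code()
  a1 <- strsplit(c1, "")[[1L]]
  a2 <- strsplit(c2, "")[[1L]]
  pos <- which(a1 != a2)
  orders <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  )
  tot_s <- 0; tot_n <- 0; n_ok <- 0L
  for (ord in orders) {
    cur <- a1
    s <- 0L; n <- 0L
    ok <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- a2[ord[k]]
      cod_cur <- paste(cur, collapse = "")
      cod_nxt <- paste(nxt, collapse = "")
      if (aa[cod_nxt] == "*" && k < length(ord)) { # stop-traversing pathway
        ok <- FALSE
        break
      }
      if (aa[cod_nxt] == aa[cod_cur]) s <- s + 1L else n <- n + 1L
      cur <- nxt
    }
    if (ok) {
      tot_s <- tot_s + s
      tot_n <- tot_n + n
      n_ok <- n_ok + 1L
    }
  }
  out <- if (n_ok == 0L) c(sd = 0, nd = 0) else c(sd = tot_s / n_ok, nd = tot_n / n_ok)
  assign(key, out, envir = .ng86)
  out
}

# Global Needleman-Wunsch on two character vectors with linear gap cost.
# Traceback is deterministic: on ties, diagonal beats a gap in `b` beats a
# gap in `a` (leftmost high-road path).
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[1L, ] <- (0:m) * gap
  S[, 1L] <- (0:n) * gap
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j], S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      ai <- c(i, ai); bi <- c(j, bi)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ai <- c(i, ai); bi <- c(NA_integer_, bi)
      i <- i - 1L
    } else {
      ai <- c(NA_integer_, ai); bi <- c(j, bi)
      j <- j - 1L
    }
  }
  list(ai = ai, bi = bi)
}

split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  }
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Pair codons of two coding sequences via protein alignment
#'
#' Both sequences are translated, the proteins are globally aligned with a
#' fixed toy scorer (match 1, mismatch -1, gap -2, deterministic traceback)
#' and the alignment is back-mapped to codons. Gapped columns and columns
#' containing a stop codon are dropped; a trailing stop codon on either
#' input is removed before alignment.
#'
#' @param cds_a,cds_b coding sequences (character or `DNAString`), lengths
#'   divisible by 3.
#' @param gene_a,gene_b optional ids carried into the result.
#' @return An object of class `codon_alignment`: list with `gene_a`,
#'   `gene_b`, `codons_a`, `codons_b` (equal-length codon vectors).
#' @export
align_codons <- function(cds_a, cds_b, gene_a = "a", gene_b = "b") {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  aa_a <- codon_aa(ca)
  aa_b <- codon_aa(cb)
  if (length(aa_a) && aa_a[length(aa_a)] == "*") {
    ca <- ca[-length(ca)]; aa_a <- aa_a[-length(aa_a)]
  }
  if (length(aa_b) && aa_b[length(aa_b)] == "*") {
    cb <- cb[-length(cb)]; aa_b <- aa_b[-length(aa_b)]
  }
  if (!length(ca) || !length(cb)) stop("empty coding sequence")
  aln <- nw_align(aa_a, aa_b)
  keep <- !is.na(aln$ai) & !is.na(aln$bi)
  ka <- aln$ai[keep]; kb <- aln$bi[keep]
  stopfree <- aa_a[ka] != "*" & aa_b[kb] != "*"
  ka <- ka[stopfree]; kb <- kb[stopfree]
  if (!length(ka)) stop("no aligned stop-free codon columns remain")
  structure(
    list(gene_a = gene_a, gene_b = gene_b,
         codons_a = ca[ka], codons_b = cb[kb]),
    class = "codon_alignment"
  )
}

#' Nei-Gojobori (1986) Ka and Ks for a codon alignment
#'
#' Synonymous sites per sequence are summed over codons (see the package
#' vignette for the counting rule) and averaged between the two sequences
#' (S; N = 3 x codons - S). Differences are counted per aligned codon pair,
#' averaging over all shortest substitution pathways with equal weights and
#' excluding pathways that traverse a stop codon. Proportions p_s = Sd/S and
#' p_n = Nd/N receive the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`. A pair is flagged `saturated` when a
#' proportion reaches 3/4 (correction undefined) or when Ks > 5; saturated
#' pairs are excluded from downstream mode summaries.
#'
#' @param aln a [align_codons()] result.
#' @return list with `gene_a`, `gene_b`, `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`,
#'   `ratio` (NaN when Ks = 0) and `saturated`.
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ca <- aln$codons_a
  cb <- aln$codons_b
  L <- length(ca)
  Sa <- sum(vapply(ca, syn_sites, 0))
  Sb <- sum(vapply(cb, syn_sites, 0))
  S <- (Sa + Sb) / 2
  N <- 3 * L - S
  d <- vapply(seq_len(L), function(i) codon_diffs(ca[i], cb[i]), c(sd = 0, nd = 0))
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])

  saturated <- FALSE
  prop <- function(num, den) {
    if (den > 0) return(num / den)
    if (num > 0) saturated <<- TRUE
    0
  }
  p_s <- prop(Sd, S)
  p_n <- prop(Nd, N)
  jc <- function(p) {
    if (p >= 0.75) {
      saturated <<- TRUE
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(p_s)
  Ka <- jc(p_n)
  if (!is.na(Ks) && Ks > 5) saturated <- TRUE
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NaN

  list(gene_a = aln$gene_a, gene_b = aln$gene_b,
       S = S, N = N, Sd = Sd, Nd = Nd,
       Ka = Ka, Ks = Ks, ratio = ratio, saturated = saturated)
}

#' Ka/Ks for a table of gene pairs
#'
#' @param cds named character vector or `DNAStringSet` of coding sequences.
#' @param pairing data.frame (or TSV path) with `gene_a`, `gene_b` and
#'   optionally `mode`.
#' @return data.frame with one row per pair: ids, mode (or `NA`), `Ka`,
#'   `Ks`, `ratio`, `saturated`.
#' @export
kaks_pairs <- function(cds, pairing) {
  if (is.character(pairing) && length(pairing) == 1L && file.exists(pairing)) {
    pairing <- utils::read.delim(pairing, stringsAsFactors = FALSE)
  }
  nm <- names(cds)
  cds <- as.character(cds)
  names(cds) <- nm
  miss <- setdiff(unique(c(pairing$gene_a, pairing$gene_b)), names(cds))
  if (length(miss)) stop("no CDS for gene ", miss[1L])
  mode <- if ("mode" %in% names(pairing)) pairing$mode else NA_character_
  out <- vector("list", nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    a <- pairing$gene_a[i]; b <- pairing$gene_b[i]
    r <- ng86(align_codons(cds[[a]], cds[[b]], a, b))
    out[[i]] <- data.frame(
      gene_a = a, gene_b = b, mode = mode[min(i, length(mode))],
      Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, saturated = r$saturated,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-mode Ka/Ks distribution summaries and rank tests
#'
#' Saturated pairs and pairs with undefined ratio are excluded. Modes with
#' fewer than two usable pairs are omitted with a warning. When two or more
#' modes remain, all pairwise two-sided Wilcoxon rank-sum tests on the
#' Ka/Ks ratios are reported.
#'
#' @param results table from [kaks_pairs()] (needs a `mode` column).
#' @return list with `summary` (mode, n, median, q25, q75) and `tests`
#'   (mode_a, mode_b, pvalue; NULL with < 2 modes).
#' @export
mode_divergence_summary <- function(results) {
  ok <- !results$saturated & is.finite(results$ratio) & !is.na(results$mode)
  d <- results[ok, , drop = FALSE]
  tab <- table(d$mode)
  drop <- names(tab)[tab < 2L]
  if (length(drop)) {
    warning("mode(s) with < 2 unsaturated pairs omitted: ",
            paste(drop, collapse = ", "))
    d <- d[!d$mode %in% drop, , drop = FALSE]
  }
  modes <- sort(unique(d$mode))
  summ <- do.call(rbind, lapply(modes, function(m) {
    r <- d$ratio[d$mode == m]
    data.frame(mode = m, n = length(r),
               median = stats::median(r),
               q25 = unname(stats::quantile(r, 0.25)),
               q75 = unname(stats::quantile(r, 0.75)),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(modes) >= 2L) {
    cmb <- utils::combn(modes, 2L)
    tests <- data.frame(
      mode_a = cmb[1L, ], mode_b = cmb[2L, ],
      pvalue = vapply(seq_len(ncol(cmb)), function(k) {
        wilcox_p(d$ratio[d$mode == cmb[1L, k]],
                 d$ratio[d$mode == cmb[2L, k]])
      }, 0),
      stringsAsFactors = FALSE
    )
  }
  list(summary = summ, tests = tests)
}

#' Expression contrast between ancestral and novel transposed duplicates
#'
#' For each stage, gene-level expression is `log2(mean TPM + 1)` across that
#' stage's replicates, and the ancestral and novel transposed-duplicate
#' groups are compared with a two-sided Wilcoxon rank-sum test. Stages where
#' either group has fewer than two genes are skipped with a warning.
#'
#' @param calls duplication calls from [classify_duplicates()].
#' @param tpm an [expression_matrix()] (counts are TPM-normalised first).
#' @return data.frame `stage`, `n_ancestral`, `n_novel`, `median_ancestral`,
#'   `median_novel`, `pvalue` (zero rows when no transposed genes exist).
#' @export
trd_expression_contrast <- function(calls, tpm) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$kind == "counts") tpm <- counts_to_tpm(tpm)
  anc <- calls$gene_id[calls$mode == "TRD" & calls$trd_role == "ancestral"]
  nov <- calls$gene_id[calls$mode == "TRD" & calls$trd_role == "novel"]
  anc <- intersect(anc, rownames(tpm$values))
  nov <- intersect(nov, rownames(tpm$values))
  empty <- data.frame(stage = character(), n_ancestral = integer(),
                      n_novel = integer(), median_ancestral = numeric(),
                      median_novel = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(anc) && !length(nov)) return(empty)
  out <- list()
  for (s in unique(tpm$design$stage)) {
    if (length(anc) < 2L || length(nov) < 2L) {
      warning("stage ", s, " skipped: < 2 genes in a TRD role group")
      next
    }
    cols <- tpm$design$stage == s
    expr <- log2(rowMeans(tpm$values[, cols, drop = FALSE]) + 1)
    x <- expr[anc]; y <- expr[nov]
    p <- wilcox_p(x, y)
    out[[s]] <- data.frame(
      stage = s, n_ancestral = length(x), n_novel = length(y),
      median_ancestral = stats::median(x), median_novel = stats::median(y),
      pvalue = p, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
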