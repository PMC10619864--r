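# Seeded generator of a small multi-chromosome genome with planted
# duplication events, staged negative-binomial expression with planted
# effects, physical islands of co-upregulated genes, a trait-linked
# co-expression module and contaminant scaffolds. Planted truth is emitted
# alongside the data and is never consumed by the pipeline.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study design the package targets: a compact
#' multi-chromosome plant genome (about 14 genes per 100 kb), five stages
#' (H0 control, H1/H3/H6/H12 heat) with three replicates, planted islands
#' of 4-8 co-upregulated genes within 40 kb, duplication events of every
#' mode, a 4x ancestral:novel expression asymmetry for transposed
#' duplicates, negative-binomial counts at dispersion 0.1 with planted
#' |log2FC| = 2 effects, and contaminant scaffolds whose non-target
#' coverage exceeds 50%.
#'
#' @param seed integer seed; fully determines the bundle.
#' @param n_chroms,genes_per_chrom genome layout.
#' @param mean_gene_len,mean_intergenic bp scales of genes and gaps.
#' @param n_planted_islands,island_genes_min,island_genes_max,island_span_bp,island_log2fc
#'   planted-island layout and effect.
#' @param n_tandem,n_proximal,n_block_dup,block_len,n_trd,n_dsd planted
#'   duplication events (pairs, or anchor runs for blocks).
#' @param proximal_offset_max maximum rank offset of proximal events.
#' @param de_fraction,planted_log2fc per-contrast planted DE genes.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression.
#' @param trd_expr_ratio ancestral over novel expression ratio.
#' @param n_module_genes,module_stage,module_fold planted co-expression
#'   module (shared spike at `module_stage`).
#' @param n_cds_codons sense codons per generated CDS.
#' @param syn_rate,nonsyn_rate per-mode per-codon mutation probabilities
#'   for the CDS of the second copy of each pair.
#' @param n_contaminant_queries,n_clean_queries,contaminant_query_len
#'   contamination-screen fixtures.
#' @param stages,replicates expression design.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 6L, genes_per_chrom = 150L,
                       mean_gene_len = 1500, mean_intergenic = 2500,
                       n_planted_islands = 5L, island_genes_min = 4L,
                       island_genes_max = 8L, island_span_bp = 40000L,
                       island_log2fc = 3,
                       n_tandem = 20L, n_proximal = 20L,
                       n_block_dup = 2L, block_len = 6L,
                       n_trd = 35L, n_dsd = 25L,
                       proximal_offset_max = 10L,
                       de_fraction = 0.05, planted_log2fc = 2,
                       de_min_baseline = 50,
                       nb_dispersion = 0.1,
                       baseline_meanlog = log(200), baseline_sdlog = 1,
                       trd_expr_ratio = 4,
                       n_module_genes = 60L, module_stage = "H1",
                       module_fold = 8,
                       n_cds_codons = 60L,
                       syn_rate = c(WGD = 0.30, TD = 0.30, PD = 0.30,
                                    TRD = 0.30, DSD = 0.30),
                       nonsyn_rate = c(WGD = 0.04, TD = 0.20, PD = 0.20,
                                       TRD = 0.08, DSD = 0.08),
                       n_contaminant_queries = 5L, n_clean_queries = 15L,
                       contaminant_query_len = 10000L,
                       stages = c("H0", "H1", "H3", "H6", "H12"),
                       replicates = 3L) {
  cfg <- as.list(environment())
  counts <- c("n_chroms", "genes_per_chrom", "n_planted_islands", "n_tandem",
              "n_proximal", "n_block_dup", "block_len", "n_trd", "n_dsd",
              "n_module_genes", "n_contaminant_queries", "n_clean_queries")
  for (k in counts) if (cfg[[k]] < 0) stop(k, " must be >= 0")
  if (island_genes_min < 1L || island_genes_max < island_genes_min) {
    stop("invalid island gene-count range")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  est_span <- island_genes_max * (1.4 * mean_gene_len + 800)
  if (est_span > island_span_bp) {
    stop("config error: island span ", round(est_span),
         " bp cannot fit within island_span_bp = ", island_span_bp)
  }
  structure(cfg, class = "sim_config")
}

# ---- codon helpers ---------------------------------------------------------

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

single_nt_variants <- function(codon) {
  chars <- strsplit(codon, "")[[1L]]
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      alt <- chars
      alt[pos] <- nt
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

mutate_cds <- function(codons, syn_rate, nonsyn_rate) {
  gc <- Biostrings::GENETIC_CODE
  n <- length(codons)
  do_syn <- stats::runif(n) < syn_rate
  do_non <- stats::runif(n) < nonsyn_rate
  for (i in seq_len(n)) {
    if (do_syn[i]) {
      v <- single_nt_variants(codons[i])
      v <- v[gc[v] == gc[codons[i]] & gc[v] != "*"]
      if (length(v)) codons[i] <- v[sample.int(length(v), 1L)]
    }
    if (do_non[i]) {
      v <- single_nt_variants(codons[i])
      v <- v[gc[v] != gc[codons[i]] & gc[v] != "*"]
      if (length(v)) codons[i] <- v[sample.int(length(v), 1L)]
    }
  }
  codons
}

random_cds <- function(n_codons) {
  body <- sample(setdiff(sense_codons(), "ATG"), n_codons - 1L, replace = TRUE)
  c("ATG", body)
}

# ---- generator -------------------------------------------------------------

#' Generate a full synthetic input bundle with planted truth
#'
#' See [sim_config()] for the study conditions. The returned bundle holds
#' every pipeline input in memory (annotation, counts, design, CDS and
#' pairing, homolog pairs, inter-species anchors, module labels, alignment
#' hits) plus a `truth` list describing everything that was planted.
#' [write_bundle()] serialises it to plain-text files.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nC <- config$n_chroms
  G <- config$genes_per_chrom
  chroms <- sprintf("chr%02d", seq_len(nC))

  # -- island slot layout (round-robin over chromosomes) --
  island_chrom <- rep(seq_len(nC), length.out = config$n_planted_islands)
  island_sizes <- if (config$n_planted_islands > 0) {
    sample(seq(config$island_genes_min, config$island_genes_max),
           config$n_planted_islands, replace = TRUE)
  } else integer(0)
  # slot role per chromosome: 0 background, island id > 0
  slot_island <- matrix(0L, nrow = nC, ncol = G)
  for (i in seq_along(island_chrom)) {
    c_i <- island_chrom[i]
    k <- island_sizes[i]
    # place the run inside an even segment of the chromosome, away from ends
    n_on_c <- sum(island_chrom == c_i)
    seg <- ceiling(G / (n_on_c + 1L))
    pos_in_c <- which(island_chrom[seq_len(i)] == c_i)
    pos_in_c <- length(pos_in_c) # 1-based index of this island on its chrom
    lo <- max(2L, (pos_in_c - 1L) * seg + 2L)
    hi <- min(G - k - 1L, pos_in_c * seg - k)
    if (hi < lo) stop("config error: planted islands do not fit on chromosome ",
                      chroms[c_i])
    s <- sample(lo:hi, 1L)
    slot_island[c_i, s:(s + k - 1L)] <- i
  }

  # -- coordinates --
  genes <- list()
  chrom_lengths <- numeric(0)
  iso_gap <- config$window_isolation_bp
  if (is.null(iso_gap)) iso_gap <- 60000L
  for (c_i in seq_len(nC)) {
    pos <- 0L
    rows <- vector("list", G)
    for (s in seq_len(G)) {
      isl <- slot_island[c_i, s]
      prev_isl <- if (s > 1L) slot_island[c_i, s - 1L] else 0L
      gap <- if (isl > 0L && prev_isl == isl) {
        round(stats::runif(1L, 200, 800))
      } else if (isl > 0L || prev_isl > 0L) {
        iso_gap # isolate island boundaries beyond one window
      } else {
        20L + round(stats::rexp(1L, 1 / config$mean_intergenic))
      }
      len <- round(stats::runif(1L, 0.6, 1.4) * config$mean_gene_len)
      start <- pos + gap + 1L
      end <- start + len - 1L
      pos <- end
      rows[[s]] <- data.frame(
        gene_id = sprintf("g%02d_%04d", c_i, s),
        chrom = chroms[c_i], start = start, end = end,
        strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE
      )
    }
    genes[[c_i]] <- do.call(rbind, rows)
    chrom_lengths[chroms[c_i]] <- pos + 5000L
  }
  gene_tab <- do.call(rbind, genes)
  ann <- genome_annotation(gene_tab, chrom_lengths)

  # -- duplication events on background (non-island) slots --
  free <- slot_island == 0L
  gene_at <- function(c_i, s) sprintf("g%02d_%04d", c_i, s)
  take_run <- function(c_i, len) {
    cand <- which(vapply(seq_len(G - len + 1L), function(s) {
      all(free[c_i, s:(s + len - 1L)])
    }, TRUE))
    if (!length(cand)) return(NULL)
    s <- cand[sample.int(length(cand), 1L)]
    free[c_i, s:(s + len - 1L)] <<- FALSE
    s
  }
  take_offset_pair <- function(c_i, d) {
    cand <- which(vapply(seq_len(G - d), function(s) {
      free[c_i, s] && free[c_i, s + d]
    }, TRUE))
    if (!length(cand)) return(NULL)
    s <- cand[sample.int(length(cand), 1L)]
    free[c_i, c(s, s + d)] <<- FALSE
    s
  }

  pairing <- list()
  truth_dup <- list()
  add_pair <- function(a, b, mode, role_a = "n/a", role_b = "n/a") {
    pairing[[length(pairing) + 1L]] <<- data.frame(
      gene_a = a, gene_b = b, mode = mode,
      score = round(stats::runif(1L, 80, 200), 1),
      stringsAsFactors = FALSE
    )
    truth_dup[[length(truth_dup) + 1L]] <<- data.frame(
      gene_id = c(a, b), mode = mode, trd_role = c(role_a, role_b),
      partner = c(b, a), stringsAsFactors = FALSE
    )
  }

  for (e in seq_len(config$n_block_dup)) {
    cc <- sample(nC, 2L)
    sA <- take_run(cc[1L], config$block_len)
    sB <- take_run(cc[2L], config$block_len)
    if (is.null(sA) || is.null(sB)) stop("config error: no room for block event")
    for (k in seq_len(config$block_len) - 1L) {
      add_pair(gene_at(cc[1L], sA + k), gene_at(cc[2L], sB + k), "WGD")
    }
  }
  for (e in seq_len(config$n_tandem)) {
    c_i <- sample(nC, 1L)
    s <- take_offset_pair(c_i, 1L)
    if (is.null(s)) stop("config error: no room for tandem event")
    add_pair(gene_at(c_i, s), gene_at(c_i, s + 1L), "TD")
  }
  for (e in seq_len(config$n_proximal)) {
    c_i <- sample(nC, 1L)
    d <- sample(2:config$proximal_offset_max, 1L)
    s <- take_offset_pair(c_i, d)
    if (is.null(s)) stop("config error: no room for proximal event")
    add_pair(gene_at(c_i, s), gene_at(c_i, s + d), "PD")
  }
  interspecies_anchors <- character(0)
  for (e in seq_len(config$n_trd)) {
    cc <- sample(nC, 2L)
    sA <- take_run(cc[1L], 1L)
    sB <- take_run(cc[2L], 1L)
    if (is.null(sA) || is.null(sB)) stop("config error: no room for TRD event")
    a <- gene_at(cc[1L], sA)
    b <- gene_at(cc[2L], sB)
    interspecies_anchors <- c(interspecies_anchors, a)
    add_pair(a, b, "TRD", role_a = "ancestral", role_b = "novel")
  }
  for (e in seq_len(config$n_dsd)) {
    cc <- sample(nC, 2L)
    sA <- take_run(cc[1L], 1L)
    sB <- take_run(cc[2L], 1L)
    if (is.null(sA) || is.null(sB)) stop("config error: no room for DSD event")
    add_pair(gene_at(cc[1L], sA), gene_at(cc[2L], sB), "DSD")
  }
  pairing <- if (length(pairing)) do.call(rbind, pairing) else
    data.frame(gene_a = character(), gene_b = character(),
               mode = character(), score = numeric(), stringsAsFactors = FALSE)
  truth_dup <- if (length(truth_dup)) do.call(rbind, truth_dup) else
    data.frame(gene_id = character(), mode = character(),
               trd_role = character(), partner = character(),
               stringsAsFactors = FALSE)

  # -- CDS per gene; second pair member mutated at per-mode rates --
  all_ids <- ann$genes$gene_id
  cds_codons <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (id in all_ids) cds_codons[[id]] <- random_cds(config$n_cds_codons)
  for (i in seq_len(nrow(pairing))) {
    m <- pairing$mode[i]
    cds_codons[[pairing$gene_b[i]]] <- mutate_cds(
      cds_codons[[pairing$gene_a[i]]],
      config$syn_rate[[m]], config$nonsyn_rate[[m]]
    )
  }
  cds <- vapply(cds_codons, function(cc) paste(c(cc, "TAA"), collapse = ""), "")

  # -- expression --
  design <- sample_design(config$stages, config$replicates)
  nG <- length(all_ids)
  mu <- stats::rlnorm(nG, config$baseline_meanlog, config$baseline_sdlog)
  names(mu) <- all_ids

  trd_anc <- truth_dup$gene_id[truth_dup$mode == "TRD" &
                                 truth_dup$trd_role == "ancestral"]
  trd_nov <- truth_dup$gene_id[truth_dup$mode == "TRD" &
                                 truth_dup$trd_role == "novel"]
  for (k in seq_along(trd_nov)) {
    base <- max(stats::rlnorm(1L, config$baseline_meanlog, config$baseline_sdlog), 50)
    mu[trd_nov[k]] <- base
    mu[trd_anc[k]] <- config$trd_expr_ratio * base
  }

  island_ids <- lapply(seq_along(island_chrom), function(i) {
    slots <- which(slot_island[island_chrom[i], ] == i)
    gene_at(island_chrom[i], slots)
  })
  island_genes_all <- unlist(island_ids, use.names = FALSE)
  mu[island_genes_all] <- pmax(mu[island_genes_all], 100)

  de_stages <- setdiff(config$stages, config$stages[1L])
  island_pattern <- rep(paste0(de_stages, "UP"),
                        length.out = length(island_ids))

  module_pool <- setdiff(all_ids, c(island_genes_all, trd_anc, trd_nov))
  module_genes <- sort(sample(module_pool, min(config$n_module_genes,
                                               length(module_pool))))
  mu[module_genes] <- pmax(mu[module_genes], 50)

  stage_mult <- matrix(1, nrow = nG, ncol = length(config$stages),
                       dimnames = list(all_ids, config$stages))
  for (i in seq_along(island_ids)) {
    st <- sub("UP$", "", island_pattern[i])
    stage_mult[island_ids[[i]], st] <- 2^config$island_log2fc
  }
  stage_mult[module_genes, config$module_stage] <-
    stage_mult[module_genes, config$module_stage] * config$module_fold

  # plant expression effects only on solidly expressed genes: recovery of a
  # fold change is only meaningful where the baseline carries signal
  de_pool <- setdiff(module_pool, module_genes)
  de_pool <- de_pool[mu[de_pool] >= config$de_min_baseline]
  truth_de <- list()
  for (st in de_stages) {
    n_de <- round(config$de_fraction * length(de_pool))
    if (n_de == 0L) next
    picked <- sample(de_pool, n_de)
    up <- picked[seq_len(ceiling(n_de / 2))]
    down <- setdiff(picked, up)
    stage_mult[up, st] <- stage_mult[up, st] * 2^config$planted_log2fc
    stage_mult[down, st] <- stage_mult[down, st] * 2^(-config$planted_log2fc)
    truth_de[[st]] <- data.frame(
      gene_id = c(up, down), contrast = paste0(st, "vsH0"),
      log2fc = c(rep(config$planted_log2fc, length(up)),
                 rep(-config$planted_log2fc, length(down))),
      stringsAsFactors = FALSE
    )
  }
  truth_de <- if (length(truth_de)) do.call(rbind, truth_de) else
    data.frame(gene_id = character(), contrast = character(),
               log2fc = numeric(), stringsAsFactors = FALSE)
  rownames(truth_de) <- NULL

  counts <- matrix(0L, nrow = nG, ncol = nrow(design),
                   dimnames = list(all_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    counts[, j] <- stats::rnbinom(nG, mu = mu * stage_mult[, design$stage[j]],
                                  size = 1 / config$nb_dispersion)
  }
  gene_lengths <- stats::setNames(ann$genes$end - ann$genes$start + 1L,
                                  ann$genes$gene_id)
  expr <- expression_matrix(counts, design, kind = "counts",
                            gene_lengths = gene_lengths[all_ids])

  # -- module labels: planted module M1, remaining genes spread over M2-M4 --
  other <- setdiff(all_ids, module_genes)
  modules <- data.frame(
    gene_id = c(module_genes, other),
    module = c(rep("M1", length(module_genes)),
               sample(c("M2", "M3", "M4"), length(other), replace = TRUE)),
    stringsAsFactors = FALSE
  )
  modules <- modules[order(modules$gene_id), , drop = FALSE]
  rownames(modules) <- NULL

  # -- contamination fixtures --
  hits <- list()
  qlens <- list()
  add_hit <- function(q, qlen, s, e, class) {
    hits[[length(hits) + 1L]] <<- data.frame(
      qseqid = q, sseqid = sprintf("subj_%04d", length(hits) + 1L),
      pident = round(stats::runif(1L, 75, 99), 2), length = e - s + 1L,
      mismatch = sample(0:50, 1L), gapopen = sample(0:5, 1L),
      qstart = s, qend = e,
      sstart = 1L, send = e - s + 1L,
      evalue = signif(stats::runif(1L, 1e-50, 1e-6), 3),
      bitscore = round(stats::runif(1L, 50, 2000), 1),
      taxon_class = class, stringsAsFactors = FALSE
    )
  }
  contaminants <- character(0)
  for (i in seq_len(config$n_contaminant_queries)) {
    q <- sprintf("scaffold_contam_%02d", i)
    qlen <- config$contaminant_query_len
    frac <- stats::runif(1L, 0.55, 0.9)
    u <- round(frac * qlen)
    a <- round(u * stats::runif(1L, 0.4, 0.6))
    add_hit(q, qlen, 1L, a, "non_target")
    add_hit(q, qlen, max(1L, a - 500L), u, "non_target")
    add_hit(q, qlen, 1L, round(0.2 * qlen), "target")
    qlens[[q]] <- qlen
    contaminants <- c(contaminants, q)
  }
  for (i in seq_len(config$n_clean_queries)) {
    q <- sprintf("scaffold_clean_%02d", i)
    qlen <- round(stats::runif(1L, 0.5, 2) * config$contaminant_query_len)
    add_hit(q, qlen, 1L, round(stats::runif(1L, 0.3, 0.9) * qlen), "target")
    nt <- round(stats::runif(1L, 0.05, 0.45) * qlen)
    add_hit(q, qlen, 1L, max(1L, nt), "non_target")
    qlens[[q]] <- qlen
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(matrix(nrow = 0, ncol = length(OUTFMT6_COLS) + 1L,
                      dimnames = list(NULL, c(OUTFMT6_COLS, "taxon_class"))))
  query_lens <- data.frame(query_id = names(qlens),
                           query_len = as.integer(unlist(qlens)),
                           stringsAsFactors = FALSE)

  truth_islands <- if (length(island_ids)) do.call(rbind, lapply(
    seq_along(island_ids), function(i) {
      gi <- ann$genes[match(island_ids[[i]], ann$genes$gene_id), , drop = FALSE]
      data.frame(island_id = i, chrom = gi$chrom[1L],
                 start = min(gi$start), end = max(gi$end),
                 pattern = island_pattern[i],
                 genes = paste(island_ids[[i]], collapse = ","),
                 stringsAsFactors = FALSE)
    })) else data.frame(island_id = integer(), chrom = character(),
                        start = integer(), end = integer(),
                        pattern = character(), genes = character(),
                        stringsAsFactors = FALSE)

  null_genes <- setdiff(de_pool, truth_de$gene_id)

  structure(list(
    config = config,
    ann = ann,
    counts = expr,
    design = design,
    cds = cds,
    pairing = pairing[, c("gene_a", "gene_b", "mode")],
    homolog_pairs = pairing[, c("gene_a", "gene_b", "score")],
    interspecies_anchors = interspecies_anchors,
    modules = modules,
    hits = hits,
    query_lens = query_lens,
    truth = list(
      dup = truth_dup,
      de = truth_de,
      islands = truth_islands,
      module_genes = module_genes,
      null_genes = null_genes,
      contaminants = contaminants
    )
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> seed %d: %d genes, %d homolog pairs, %d planted islands, %d queries\n",
    x$config$seed, nrow(x$ann$genes), nrow(x$pairing),
    nrow(x$truth$islands), nrow(x$query_lens)
  ))
  invisible(x)
}

write_tsv <- function(d, path) {
  old <- options(scipen = 15)
  on.exit(options(old))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a synthetic bundle to plain-text files
#'
#' Writes GFF3, CDS FASTA, counts/design/pairing/homolog/anchor/module/hit
#' tables and the planted-truth tables into `dir`. Byte-identical output
#' for identical configurations.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gff3(bundle$ann, p("genome.gff3"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$cds), p("cds.fasta"))
  counts_tab <- data.frame(gene_id = rownames(bundle$counts$values),
                           bundle$counts$values, check.names = FALSE,
                           stringsAsFactors = FALSE)
  write_tsv(counts_tab, p("counts.tsv"))
  write_tsv(bundle$design, p("design.tsv"))
  write_tsv(bundle$pairing, p("pairing.tsv"))
  write_tsv(bundle$homolog_pairs, p("homolog_pairs.tsv"))
  write_tsv(data.frame(gene_id = bundle$interspecies_anchors,
                       stringsAsFactors = FALSE), p("anchors.tsv"))
  write_tsv(bundle$modules, p("modules.tsv"))
  write_tsv(bundle$hits, p("hits.tsv"))
  write_tsv(bundle$query_lens, p("query_lens.tsv"))
  write_tsv(bundle$truth$dup, p("truth_dup.tsv"))
  write_tsv(bundle$truth$de, p("truth_de.tsv"))
  write_tsv(bundle$truth$islands, p("truth_islands.tsv"))
  write_tsv(data.frame(gene_id = bundle$truth$module_genes,
                       stringsAsFactors = FALSE), p("truth_module_genes.tsv"))
  write_tsv(data.frame(query_id = bundle$truth$contaminants,
                       stringsAsFactors = FALSE), p("truth_contaminants.tsv"))
  files <- c("genome.gff3", "cds.fasta", "counts.tsv", "design.tsv",
             "pairing.tsv", "homolog_pairs.tsv", "anchors.tsv", "modules.tsv",
             "hits.tsv", "query_lens.tsv", "truth_dup.tsv", "truth_de.tsv",
             "truth_islands.tsv", "truth_module_genes.tsv",
             "truth_contaminants.tsv")
  invisible(stats::setNames(file.path(dir, files), files))
}
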