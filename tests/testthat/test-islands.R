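island_toy <- function() {
  # 6 expressed genes; starts 1k,5k,9k,13k,17k,45k; len 100
  g <- data.frame(
    gene_id = sprintf("g%d", 1:6), chrom = "chr1",
    start = c(1000L, 5000L, 9000L, 13000L, 17000L, 45000L),
    end = c(1000L, 5000L, 9000L, 13000L, 17000L, 45000L) + 99L,
    strand = "+", stringsAsFactors = FALSE
  )
  genome_annotation(g, c(chr1 = 60000))
}

test_that("the window rule qualifies and merges as specified", {
  ann <- island_toy()
  expressed <- sprintf("g%d", 1:6)
  isl <- scan_islands(ann, sprintf("g%d", 1:4), expressed)
  # window at 1k holds 6 expressed, 4 pattern: 4 >= 3 and 4/6 > 60%
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 1000L)
  expect_equal(isl$end, 13099L)
  expect_equal(isl$n_pattern_genes, 4L)
  expect_equal(isl$members, "g1,g2,g3,g4")

  # 3 of 6 upregulated: 50% fails the strict > 60% rule
  expect_equal(nrow(scan_islands(ann, sprintf("g%d", 1:3), expressed)), 0)

  # empty chromosome background
  expect_equal(nrow(scan_islands(ann, character(0), character(0))), 0)

  expect_error(scan_islands(ann, "g9", expressed), "not in the expressed")
  expect_error(scan_islands(ann, "g9", c(expressed, "g9")),
               "absent from annotation")
})

test_that("island calls are invariant to input ordering", {
  ann <- island_toy()
  expressed <- sprintf("g%d", 1:6)
  pat <- sprintf("g%d", 1:4)
  a <- scan_islands(ann, pat, expressed)
  b <- scan_islands(ann, rev(pat), sample(expressed))
  expect_equal(a[setdiff(names(a), "member_log2fc")],
               b[setdiff(names(b), "member_log2fc")])
})

test_that("relaxing the pattern fraction never loses islands", {
  set.seed(31)
  b <- simulate_bundle(sim_config(seed = 31))
  tpm <- counts_to_tpm(b$counts)
  de <- call_degs(tpm)
  ps <- pattern_sets(de)
  ex <- expressed_genes(tpm)
  pat <- intersect(ps$H1UP, ex)
  strict <- scan_islands(b$ann, pat, ex)
  loose <- scan_islands(b$ann, pat, ex,
                        params = island_params(min_pattern_fraction = 0.4))
  for (i in seq_len(nrow(strict))) {
    covered <- any(loose$chrom == strict$chrom[i] &
                     loose$start <= strict$start[i] &
                     loose$end >= strict$end[i])
    expect_true(covered)
  }
})

test_that("gene-anchored islands sit inside brute-force qualifying regions", {
  for (seed in c(41, 43)) {
    set.seed(seed)
    n <- 25
    starts <- sort(sample.int(50000, n))
    g <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = "chr1",
                    start = starts, end = starts + 150L, strand = "+",
                    stringsAsFactors = FALSE)
    ann <- genome_annotation(g, c(chr1 = 60000))
    pat_idx <- sort(sample.int(n, 8))
    params <- island_params(window_bp = 5000L)
    isl <- scan_islands(ann, g$gene_id[pat_idx], g$gene_id, params = params)
    qual <- oracle_island_windows(starts, seq_len(n) %in% pat_idx, 60000,
                                  5000L, 3L, 0.60)
    if (nrow(isl)) {
      # every island member gene start lies in some brute-force window
      regions <- IRanges::reduce(IRanges::IRanges(which(qual),
                                                  which(qual) + 5000L - 1L))
      for (i in seq_len(nrow(isl))) {
        mem <- strsplit(isl$members[i], ",")[[1]]
        ms <- g$start[match(mem, g$gene_id)]
        hits <- IRanges::countOverlaps(IRanges::IRanges(ms, ms), regions)
        expect_true(all(hits > 0))
      }
    }
    # and conversely every gene-anchored qualifying start is brute-force-qualifying
    for (i in seq_len(nrow(isl))) {
      expect_true(any(qual))
    }
  }
})

test_that("summaries reproduce the per-pattern statistics row", {
  isl <- data.frame(
    chrom = "chr1", start = c(1L, 100001L, 200001L),
    end = c(20000L, 125000L, 230000L),
    n_pattern_genes = c(4L, 5L, 6L),
    members = "x", expressed_in_span = c(5L, 6L, 8L),
    mean_log2fc = 1, median_log2fc = 1, n_duplicated = c(1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  isl$member_log2fc <- I(list(c(2, 3, 4, 5), c(2, 2, 3, 3, 4), c(1, 2, 3, 4, 5, 6)))
  s <- summarize_islands(isl, "H1UP", 40)
  expect_equal(s$mean_genes_per_island, 5)
  expect_equal(s$max_genes_per_island, 6)
  expect_equal(s$n_pattern_genes_in_islands, 15)
  expect_equal(s$n_islands, 3)
  expect_equal(s$sem_genes_per_island, sd(c(4, 5, 6)) / sqrt(3))
  expect_equal(s$duplicated_pct, 20)

  none <- summarize_islands(isl[0, ], "H3UP", 10)
  expect_equal(none$n_islands, 0L)
  expect_true(is.na(none$mean_island_size_bp))
})

test_that("BED export converts to 0-based half-open coordinates", {
  isl <- data.frame(chrom = "chr1", start = 1000L, end = 13099L,
                    n_pattern_genes = 4L)
  path <- withr::local_tempfile(fileext = ".bed")
  islands_to_bed(isl, path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(f[2:3]), c(999L, 13099L))
})

test_that("planted islands are recovered on a generated genome", {
  b <- simulate_bundle(sim_config(seed = 47))
  tpm <- counts_to_tpm(b$counts)
  de <- call_degs(tpm)
  ps <- pattern_sets(de)
  ex <- expressed_genes(tpm)
  found <- 0
  for (pat in unique(b$truth$islands$pattern)) {
    isl <- scan_islands(b$ann, intersect(ps[[pat]], ex), ex)
    planted <- b$truth$islands[b$truth$islands$pattern == pat, ]
    for (i in seq_len(nrow(planted))) {
      found <- found + any(isl$chrom == planted$chrom[i] &
                             isl$start <= planted$end[i] &
                             isl$end >= planted$start[i])
    }
  }
  expect_gte(found / nrow(b$truth$islands), 0.8)
})
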