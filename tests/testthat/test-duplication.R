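test_that("a clean run of anchors chains into a single same-orientation block", {
  ann <- mk_ann(c(30, 130))
  pairs <- data.frame(
    gene_a = vapply(10:14, function(r) gene_by_rank(ann, "chr1", r), ""),
    gene_b = vapply(110:114, function(r) gene_by_rank(ann, "chr2", r), ""),
    score = 100
  )
  blocks <- chain_collinear_blocks(pairs, ann)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 5)
  expect_equal(blocks[[1]]$orientation, "same")
  expect_equal(blocks[[1]]$anchors$rank_a, 10:14)
  expect_equal(blocks[[1]]$anchors$rank_b, 110:114)
})

test_that("a rank gap beyond max_gap splits the chain below min_block", {
  ann <- mk_ann(c(30, 520))
  rb <- c(110, 111, 500, 113, 114) # third partner far away on chr2
  pairs <- data.frame(
    gene_a = vapply(10:14, function(r) gene_by_rank(ann, "chr1", r), ""),
    gene_b = vapply(rb, function(r) gene_by_rank(ann, "chr2", r), ""),
    score = 100
  )
  expect_length(chain_collinear_blocks(pairs, ann, min_block = 5), 0)
  # the 4 collinear dots still chain when min_block allows
  blocks <- chain_collinear_blocks(pairs, ann, min_block = 4)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 4)
})

test_that("inverted runs are chained with descending partner ranks", {
  ann <- mk_ann(c(30, 130))
  pairs <- data.frame(
    gene_a = vapply(10:14, function(r) gene_by_rank(ann, "chr1", r), ""),
    gene_b = vapply(114:110, function(r) gene_by_rank(ann, "chr2", r), ""),
    score = 100
  )
  blocks <- chain_collinear_blocks(pairs, ann)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "inverted")
})

test_that("empty input and bad configuration are handled", {
  ann <- mk_ann(10)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric())
  expect_length(chain_collinear_blocks(empty, ann), 0)
  pairs <- data.frame(gene_a = "c1_g001", gene_b = "nope", score = 1)
  expect_error(chain_collinear_blocks(pairs, ann), "unknown gene")
  expect_error(chain_collinear_blocks(empty, ann, min_block = 1),
               "min_block")
})

test_that("mode precedence resolves tandem, proximal, transposed, dispersed", {
  ann <- mk_ann(c(40, 40))
  g <- function(c_i, r) gene_by_rank(ann, paste0("chr", c_i), r)
  pairs <- data.frame(
    gene_a = c(g(1, 5), g(1, 10), g(1, 20), g(1, 30)),
    gene_b = c(g(1, 6), g(1, 14), g(2, 20), g(2, 30)),
    score = c(90, 80, 70, 60)
  )
  calls <- classify_duplicates(pairs, list(), ann,
                               interspecies_anchors = g(1, 20))
  md <- setNames(calls$mode, calls$gene_id)
  role <- setNames(calls$trd_role, calls$gene_id)
  expect_equal(unname(md[c(g(1, 5), g(1, 6))]), c("TD", "TD"))
  expect_equal(unname(md[c(g(1, 10), g(1, 14))]), c("PD", "PD"))
  # inter-species ancestral locus: syntenic member ancestral, partner novel
  expect_equal(unname(md[c(g(1, 20), g(2, 20))]), c("TRD", "TRD"))
  expect_equal(unname(role[c(g(1, 20), g(2, 20))]), c("ancestral", "novel"))
  expect_equal(unname(md[c(g(1, 30), g(2, 30))]), c("DSD", "DSD"))
  expect_equal(unname(md[g(1, 1)]), "singleton")
  expect_true(all(is.na(calls$partner[calls$mode == "singleton"])))
  expect_true(all(calls$trd_role[calls$mode != "TRD"] == "n/a"))
})

test_that("block anchors take WGD precedence over adjacency", {
  ann <- mk_ann(c(30, 130))
  anchor_pairs <- data.frame(
    gene_a = vapply(10:14, function(r) gene_by_rank(ann, "chr1", r), ""),
    gene_b = vapply(110:114, function(r) gene_by_rank(ann, "chr2", r), ""),
    score = 100
  )
  # gene at rank 10 also has a tandem partner at rank 9
  pairs <- rbind(anchor_pairs,
                 data.frame(gene_a = gene_by_rank(ann, "chr1", 10),
                            gene_b = gene_by_rank(ann, "chr1", 9),
                            score = 200))
  blocks <- chain_collinear_blocks(pairs, ann)
  calls <- classify_duplicates(pairs, blocks, ann)
  md <- setNames(calls$mode, calls$gene_id)
  expect_equal(unname(md[gene_by_rank(ann, "chr1", 10)]), "WGD")
  # its non-anchor partner is tandem to an anchor
  expect_equal(unname(md[gene_by_rank(ann, "chr1", 9)]), "TD")
})

test_that("every gene receives exactly one mode and counts partition", {
  b <- simulate_bundle(sim_config(seed = 11))
  blocks <- chain_collinear_blocks(b$homolog_pairs, b$ann)
  calls <- classify_duplicates(b$homolog_pairs, blocks, b$ann,
                               interspecies_anchors = b$interspecies_anchors)
  expect_equal(sort(calls$gene_id), sort(b$ann$genes$gene_id))
  cen <- mode_census(calls)
  expect_equal(sum(cen$counts), cen$n_genes)
  expect_equal(cen$duplicated_total, sum(cen$counts) - cen$counts[["singleton"]])
  # determinism / idempotence: identical rerun gives identical calls
  calls2 <- classify_duplicates(b$homolog_pairs, blocks, b$ann,
                                interspecies_anchors = b$interspecies_anchors)
  expect_identical(calls, calls2)
})

test_that("classifier agrees with the literal rule enumerator on small genomes", {
  for (seed in 1:4) {
    set.seed(seed)
    ann <- mk_ann(c(25, 25))
    ids <- ann$genes$gene_id
    k <- 12
    a <- sample(ids, k)
    b <- sample(setdiff(ids, a), k)
    pairs <- read_homolog_pairs(
      data.frame(gene_a = a, gene_b = b, score = round(runif(k, 50, 150), 1))
    )
    anchors <- sample(ids, 3)
    blocks <- chain_collinear_blocks(pairs, ann)
    got <- classify_duplicates(pairs, blocks, ann,
                               interspecies_anchors = anchors)
    want <- oracle_classify(pairs, blocks, ann,
                            interspecies_anchors = anchors)
    expect_equal(got, want)
  }
})
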