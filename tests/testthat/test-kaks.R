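codons_to_cds <- function(codons) paste(c(codons, "TAA"), collapse = "")

test_that("codon pairing keeps identical sequences intact and drops deletions", {
  set.seed(2)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  cod <- c("ATG", sample(setdiff(sense, "ATG"), 29, replace = TRUE))
  aln <- align_codons(codons_to_cds(cod), codons_to_cds(cod))
  expect_length(aln$codons_a, 30)
  expect_identical(aln$codons_a, aln$codons_b)

  # b = a with one internal codon deleted: exactly that column is dropped
  b <- cod[-12]
  aln2 <- align_codons(codons_to_cds(cod), codons_to_cds(b))
  expect_length(aln2$codons_a, 29)
  expect_identical(aln2$codons_a, cod[-12])
  expect_identical(aln2$codons_b, b)

  expect_error(align_codons(paste(rep("A", 31), collapse = ""),
                            codons_to_cds(cod)),
               "not divisible by 3")
})

test_that("identical sequences give Ka = Ks = 0 with undefined ratio", {
  set.seed(3)
  p <- random_codon_pair(30, n_mut = 0)
  r <- ng86(align_codons(codons_to_cds(p$a), codons_to_cds(p$a)))
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.nan(r$ratio))
  expect_false(r$saturated)
})

test_that("a single synonymous change matches the literal estimator", {
  set.seed(7)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  a <- sample(sense, 30, replace = TRUE)
  # find a codon with a synonymous third-position variant and apply it
  b <- a
  for (i in seq_along(a)) {
    chars <- strsplit(a[i], "")[[1]]
    for (nt in setdiff(c("A", "C", "G", "T"), chars[3])) {
      cand <- paste(c(chars[1:2], nt), collapse = "")
      if (Biostrings::GENETIC_CODE[[cand]] == Biostrings::GENETIC_CODE[[a[i]]]) {
        b[i] <- cand
        break
      }
    }
    if (b[i] != a[i]) break
  }
  expect_false(identical(a, b))
  r <- ng86(align_codons(codons_to_cds(a), codons_to_cds(b)))
  want <- oracle_ng86(a, b)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, want$Ks, tolerance = 1e-12)
  expect_gt(r$Ks, 0)
})

test_that("sites are conserved and the estimator is symmetric", {
  set.seed(13)
  for (k in 1:10) {
    p <- random_codon_pair(25, n_mut = 5)
    ab <- ng86(align_codons(codons_to_cds(p$a), codons_to_cds(p$b)))
    ba <- ng86(align_codons(codons_to_cds(p$b), codons_to_cds(p$a)))
    expect_equal(ab$S + ab$N, 3 * 25, tolerance = 1e-12)
    expect_equal(ab$Ka, ba$Ka, tolerance = 1e-12)
    expect_equal(ab$Ks, ba$Ks, tolerance = 1e-12)
  }
})

test_that("the Jukes-Cantor correction approaches identity for small p", {
  # one synonymous difference among 2500 glycine codons: p_s = 4e-4
  a <- rep("GGG", 2500)
  b <- a
  b[1] <- "GGT"
  r <- ng86(align_codons(codons_to_cds(a), codons_to_cds(b)))
  p <- r$Sd / r$S
  expect_lt(abs(r$Ks / p - 1), 1e-3)
})

test_that("saturation is flagged at p >= 3/4 and at Ks > 5", {
  # all synonymous sites differ: p_s = 1 -> correction undefined
  a <- rep("GGT", 30)
  b <- rep("GGG", 30)
  r <- ng86(align_codons(codons_to_cds(a), codons_to_cds(b)))
  expect_true(r$saturated)
  expect_true(is.na(r$Ks))

  # p_s just below 3/4 gives a finite Ks above 5: still saturated
  n <- 4000
  a <- rep("GGG", n)
  b <- c(rep("GGT", 2999), rep("GGG", n - 2999))
  r <- ng86(align_codons(codons_to_cds(a), codons_to_cds(b)))
  expect_false(is.na(r$Ks))
  expect_gt(r$Ks, 5)
  expect_true(r$saturated)
})

test_that("production NG86 equals the brute-force estimator on random pairs", {
  set.seed(101)
  for (k in 1:100) {
    p <- random_codon_pair(30, n_mut = sample(1:8, 1))
    r <- ng86(align_codons(codons_to_cds(p$a), codons_to_cds(p$b)))
    want <- oracle_ng86(p$a, p$b)
    expect_equal(r$S, want$S, tolerance = 1e-10)
    expect_equal(r$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(r$Nd, want$Nd, tolerance = 1e-10)
    expect_equal(r$Ka, want$Ka, tolerance = 1e-10)
    expect_equal(r$Ks, want$Ks, tolerance = 1e-10)
  }
})

test_that("mode summaries recover the planted divergence ordering", {
  b <- simulate_bundle(sim_config(seed = 23))
  kk <- kaks_pairs(b$cds, b$pairing)
  ms <- mode_divergence_summary(kk)
  med <- setNames(ms$summary$median, ms$summary$mode)
  expect_gt(med[["TD"]], med[["WGD"]])
  expect_gt(med[["PD"]], med[["WGD"]])
  expect_true(all(c("mode_a", "mode_b", "pvalue") %in% names(ms$tests)))

  # single mode: summaries only
  solo <- mode_divergence_summary(kk[kk$mode == "TD", ])
  expect_null(solo$tests)

  # degenerate identical ratios: rank test p = 1
  flat <- data.frame(gene_a = letters[1:6], gene_b = LETTERS[1:6],
                     mode = rep(c("TD", "WGD"), each = 3),
                     Ka = 0.1, Ks = 0.5, ratio = 0.2, saturated = FALSE)
  expect_equal(mode_divergence_summary(flat)$tests$pvalue, 1)

  # saturated pairs are excluded from summaries
  sat <- flat
  sat$saturated <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(mode_divergence_summary(sat)$summary$n, c(2L, 3L))
})

test_that("TRD expression contrast recovers a planted asymmetry", {
  b <- simulate_bundle(sim_config(seed = 29))
  tpm <- counts_to_tpm(b$counts)
  blocks <- chain_collinear_blocks(b$homolog_pairs, b$ann)
  calls <- classify_duplicates(b$homolog_pairs, blocks, b$ann,
                               interspecies_anchors = b$interspecies_anchors)
  rep <- trd_expression_contrast(calls, tpm)
  expect_equal(nrow(rep), 5)
  expect_true(all(rep$n_ancestral >= 30))
  expect_true(all(rep$median_ancestral > rep$median_novel))
  expect_true(all(rep$pvalue < 0.05))

  none <- calls[calls$mode != "TRD", ]
  expect_equal(nrow(trd_expression_contrast(none, tpm)), 0)
})
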