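test_that("degenerate modules give eigengene = profile and MM = 1", {
  set.seed(51)
  raw <- matrix(abs(rnorm(15, 100, 30)), 1, 15,
                dimnames = list("g1", sample_design()$sample_id))
  # g2 is perfectly proportional to g1; g3 keeps the columns non-degenerate
  raw <- rbind(raw, g2 = 2 * raw[1, ], g3 = abs(rnorm(15, 80, 25)))
  m <- expression_matrix(sweep(raw, 2, colSums(raw), "/") * 1e6,
                         sample_design(), kind = "TPM")
  e1 <- module_eigengene(m, "g1")
  z <- as.numeric(scale(m$values["g1", ]))
  expect_equal(unname(e1), z, tolerance = 1e-8)
  both <- module_eigengene(m, c("g1", "g2"))
  expect_equal(unname(abs(cor(m$values["g1", ], both))), 1, tolerance = 1e-8)
  expect_equal(unname(abs(cor(m$values["g2", ], both))), 1, tolerance = 1e-8)
  expect_error(module_eigengene(m, character(0)), "empty module")
})

test_that("eigengene matches a direct eigendecomposition and ignores gene order", {
  set.seed(11)
  x <- matrix(rexp(3 * 15, 1 / 200), 3, 15,
              dimnames = list(c("gA", "gB", "gC"), sample_design()$sample_id))
  tpm <- sweep(x, 2, colSums(x), "/") * 1e6
  m <- expression_matrix(tpm, sample_design(), kind = "TPM")
  e <- module_eigengene(m, c("gA", "gB", "gC"))
  expect_equal(unname(e), unname(oracle_eigengene(tpm)), tolerance = 1e-8)
  e2 <- module_eigengene(m, c("gC", "gA", "gB"))
  expect_equal(e, e2, tolerance = 1e-10)
})

test_that("hub selection applies the MM/GS/p rule to signed correlations", {
  set.seed(53)
  design <- sample_design()
  trait <- as.numeric(design$stage == "H1")
  base <- abs(rnorm(15, 50, 5))
  mk <- function(f) pmax(base + f, 1)
  raw <- rbind(
    hubby1 = mk(300 * trait + rnorm(15, 0, 8)),
    hubby2 = mk(280 * trait + rnorm(15, 0, 8)),
    anti   = mk(-40 * trait + rnorm(15, 0, 2)),
    noise1 = abs(rnorm(15, 60, 20)),
    noise2 = abs(rnorm(15, 60, 20))
  )
  colnames(raw) <- design$sample_id
  tpm <- sweep(raw, 2, colSums(raw), "/") * 1e6
  m <- expression_matrix(tpm, design, kind = "TPM")
  mods <- data.frame(gene_id = rownames(raw),
                     module = c("M1", "M1", "M2", "M2", "M2"))
  hs <- hub_select(m, mods, "H1")
  got <- setNames(hs$is_hub, hs$gene_id)
  expect_true(got[["hubby1"]] && got[["hubby2"]])
  expect_false(got[["anti"]]) # GS threshold is signed
  expect_lt(hs$GS[hs$gene_id == "anti"], 0)
  # the invariant: is_hub equals the rule applied to the reported scores
  expect_equal(hs$is_hub,
               hs$MM >= 0.6 & hs$GS >= 0.5 & hs$gs_pvalue < 0.05)
  expect_error(hub_select(m, mods, "H7"), "constant trait")
})

test_that("GS p-values equal cor.test and scores ignore sample order", {
  set.seed(59)
  b <- simulate_bundle(small_sim(59, genes_per_chrom = 40L))
  tpm <- counts_to_tpm(b$counts)
  hs <- hub_select(tpm, b$modules, "H1")
  trait <- as.numeric(tpm$design$stage == "H1")
  for (i in sample(nrow(hs), 5)) {
    ct <- cor.test(tpm$values[hs$gene_id[i], ], trait)
    expect_equal(hs$GS[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(hs$gs_pvalue[i], ct$p.value, tolerance = 1e-12)
  }
  perm <- sample(ncol(tpm$values))
  m2 <- expression_matrix(tpm$values[, perm], tpm$design[perm, ], kind = "TPM")
  hs2 <- hub_select(m2, b$modules, "H1")
  expect_equal(hs[order(hs$gene_id), c("MM", "GS", "gs_pvalue")],
               hs2[order(hs2$gene_id), c("MM", "GS", "gs_pvalue")],
               tolerance = 1e-10)
})

test_that("neighbor groups are maximal runs of rank-adjacent hubs", {
  ann <- mk_ann(30)
  g <- function(r) gene_by_rank(ann, "chr1", r)
  mk_hubs <- function(ranks) data.frame(
    gene_id = vapply(ranks, g, ""), module = "M1",
    MM = 0.9, GS = 0.8, gs_pvalue = 0.001, is_hub = TRUE,
    stringsAsFactors = FALSE
  )
  grp <- neighbor_groups(mk_hubs(c(10, 11, 12)), ann)
  expect_equal(nrow(grp), 1)
  expect_equal(grp$n_genes, 3)
  expect_length(strsplit(grp$spacers, ",")[[1]], 2)

  expect_equal(nrow(neighbor_groups(mk_hubs(c(10, 12)), ann)), 0)
  expect_equal(nrow(neighbor_groups(mk_hubs(10), ann)), 0)

  dup <- data.frame(gene_id = ann$genes$gene_id, mode = "singleton",
                    partner = NA, trd_role = "n/a")
  grp2 <- neighbor_groups(mk_hubs(c(5, 6)), ann, dup)
  expect_true(grp2$all_non_duplicated)
})

test_that("planted module genes pass MM and null genes rarely pass GS", {
  b <- simulate_bundle(sim_config(seed = 61))
  tpm <- counts_to_tpm(b$counts)
  hs <- hub_select(tpm, b$modules, "H1")
  planted <- hs[hs$gene_id %in% b$truth$module_genes, ]
  expect_gte(mean(planted$MM >= 0.6), 0.9)
  null_ids <- setdiff(b$truth$null_genes, b$truth$module_genes)
  nulls <- hs[hs$gene_id %in% null_ids, ]
  expect_lte(mean(nulls$GS >= 0.5, na.rm = TRUE), 0.05)
})
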