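# mossheat

Downstream analyses for a staged heat-stress transcriptome (control `H0`,
then 1/3/6/12 h of stress: `H1`–`H12`, three replicates each) on a
compact, duplication-rich plant genome — the kind of study design used to
dissect thermotolerance in resilient mosses. The package asks, and
answers quantitatively, four questions about such a genome:

* **How did its genes duplicate?** Homologous gene pairs are chained into
  collinear blocks on the gene-rank dot plot, and every gene is
  classified by fixed precedence into whole-genome (WGD), tandem (TD),
  proximal (PD), transposed (TRD, with ancestral/novel locus roles) or
  dispersed (DSD) duplicates, or singleton.
* **How diverged are the duplicates?** Ka, Ks and Ka/Ks per pair by the
  Nei–Gojobori (1986) counting estimator on protein-guided codon
  alignments, with Jukes–Cantor correction and a Ks > 5 saturation
  filter; per-mode distribution summaries and Wilcoxon contrasts,
  including ancestral-versus-novel TRD expression.
* **Which genes respond, and where do they sit?** TPM normalisation,
  DEG calls by the fold-change > 2 and p < 0.05 rule per contrast
  (plug-in model-based tables, e.g. DESeq2, or self-contained stand-ins),
  per-stage pattern sets, and physical "islands": regions where at least
  3 upregulated genes exceed 60% of the expressed genes in a 50-kb
  window.
* **Which genes organise the response?** Module-eigengene scoring of
  externally supplied co-expression modules, hub selection by module
  membership ≥ 0.6 and gene significance ≥ 0.5 (p < 0.05) against a
  stage trait, and grouping of hub genes at consecutive chromosome ranks
  with their intergenic spacers ("expression piggybacking").

It also implements the assembly decontamination rule used upstream of
such analyses (remove queries whose non-target alignment coverage,
counted as an interval union, exceeds 50%) and a seeded synthetic-data
generator that plants duplication events, expression effects, islands,
modules and contaminants with known truth, so the whole pipeline is
testable without any external data.

## Worked example

```r
library(mossheat)

b     <- simulate_bundle(sim_config(seed = 1))  # 900 genes, 15 samples
tpm   <- counts_to_tpm(b$counts)
de    <- call_degs(tpm)                          # Welch stand-in
ps    <- pattern_sets(de)

blocks <- chain_collinear_blocks(b$homolog_pairs, b$ann)
calls  <- classify_duplicates(b$homolog_pairs, blocks, b$ann,
                              interspecies_anchors = b$interspecies_anchors)
mode_census(calls)$counts
#>       WGD        TD        PD       TRD       DSD singleton
#>        24        40        40        70        50       676

ex  <- expressed_genes(tpm)                      # mean TPM > 2
isl <- scan_islands(b$ann, intersect(ps$H1UP, ex), ex,
                    de = de, dup = calls, contrast = "H1vsH0")
summarize_islands(isl, "H1UP", length(ps$H1UP))[, 1:5]
#>   pattern n_pattern_genes_total n_pattern_genes_in_islands n_islands mean_island_size_bp
#> 1    H1UP                    80                         11         2             11605.5
```

Of the 80 genes upregulated one hour into stress, 11 sit in 2 physical
islands (mean span ≈ 11.6 kb): exactly the clustering signature the
island rule is designed to expose — here by construction, since the
generator planted those clusters. The duplication census likewise
recovers the planted 24 WGD anchors, 40 tandem, 40 proximal, 70
transposed and 50 dispersed duplicates. Per-mode divergence shows the
expected ordering (median Ka/Ks of TD/PD pairs ≈ 0.16–0.18 versus
≈ 0.03 for WGD anchors on this seed):

```r
mode_divergence_summary(kaks_pairs(b$cds, b$pairing))$summary
```

An end-to-end run with plain-file handoff and a JSON manifest:

```r
run_pipeline(sim_config(seed = 1), "out/")   # simulate ... contam, 8 stages
```

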