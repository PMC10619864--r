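---
title: "Methods: duplication modes, expression islands and hub genes under heat stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication modes, expression islands and hub genes under heat stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossheat)
```

## Scope

`mossheat` implements the downstream computational analyses used to study
how a stress-tolerant moss reorganises its transcriptome under heat: a
five-stage time series (control `H0`, then 1, 3, 6 and 12 hours at stress
temperature: `H1`–`H12`, three biological replicates each) on a compact
multi-chromosome genome. The package covers six analysis stages plus a
synthetic-data generator and an orchestrator:

1. **Annotation backbone** — gene models with per-chromosome rank order;
2. **Expression** — TPM normalisation, per-contrast DEG calls, pattern sets;
3. **Duplication modes** — collinear-block chaining and the
   WGD/TD/PD/TRD/DSD classification;
4. **Ka/Ks** — Nei–Gojobori (1986) estimation on codon alignments with a
   saturation filter;
5. **Islands** — physical clusters of co-localised upregulated genes by a
   50-kb window rule;
6. **Hubs** — module-eigengene scoring, the MM/GS hub rule, and
   adjacent-hub ("piggybacking") groups;
7. **Contamination screen** — interval-union coverage of assembly queries
   by non-target alignment hits.

Genome assembly, annotation, orthology, full WGCNA network construction
and GO enrichment are out of scope; where such a step produces an input
(module labels, model-based DE tables, taxon-classified hits) the package
reads it from a plain table instead.

## Coordinate model

Coordinates are 1-based and inclusive throughout (the GFF3 convention);
BED output converts to 0-based half-open at the boundary, and nowhere
else. Each gene carries a `rank`, its 0-based index along its chromosome
ordered by start (ties: ascending end, then gene id). Ranks are the
distance unit for tandem/proximal calls and for collinearity chaining.

The *intergenic spacer* between rank-adjacent genes is the number of bases
strictly between the two gene bodies (`b$start - a$end - 1`), clamped at
zero with an overlap flag when gene bodies overlap. Published spacer
ranges are compatible with several endpoint conventions; this one is fixed
and documented rather than inferred. Strand is stored but deliberately
ignored by the island scanner and adjacency analyses, which are
strand-agnostic procedures.

## Expression and DEG calling

Counts are normalised to TPM per sample:
$\mathrm{TPM}_{gs} = \frac{c_{gs}/\ell_g}{\sum_h c_{hs}/\ell_h}\times 10^6$.
A gene is **up** in a contrast when `log2fc > 1` and `p < 0.05`, **down**
when `log2fc < -1` and `p < 0.05` — the "fold change > 2 and p < 0.05"
rule, applied to `log2((mean treated TPM + 1)/(mean control TPM + 1))`.
The pseudocount of 1 avoids division by zero and is standard practice; no
multiple-testing correction is applied by default, mirroring the raw-p
rule (a Benjamini–Hochberg column is available via `adjust = TRUE` but
never drives status).

Three p-value routes exist:

* **plugin** (canonical): a table of externally computed `log2fc` and
  `pvalue` per gene and contrast, e.g. from DESeq2;
  `deseq2_plugin_table()` builds one when DESeq2 is installed. Count-model
  Wald inference is the field standard at n = 3 and is what the published
  DEG lists used.
* **welch**: a Welch t-test on `log2(TPM + 1)`, self-contained and
  download-free. At 3 vs 3 its ~4 degrees of freedom cap power: at a
  planted fourfold change and dispersion 0.1 its recall tops out near
  0.91 even at high expression, which is why it is a stand-in rather than
  the canonical route.
* **permutation**: the exact label-permutation distribution of the
  absolute mean difference over all $\binom{6}{3} = 20$ assignments.
  Assignments pair up by sign, so attainable p-values are
  $\{0.1, 0.2, \dots, 1\}$ — with three replicates this method can never
  satisfy `p < 0.05`; it is provided for larger designs and as a
  distribution-free check.

Pattern sets `H1UP` … `H12UP` (and DOWN) collect the genes regulated in
each stage-versus-control contrast; the `anyUP`/`anyDOWN` unions count a
gene in both when it is up at one stage and down at another, which is why
union tallies may exceed the number of distinct regulated genes.

## Duplication-mode classification

Homolog pairs (an input table; the generator emits them, or they come from
tabular alignment output) are chained on the gene-rank dot plot per
chromosome pair: dynamic-programming chains with per-step rank gaps of at
most `max_gap = 25` on both axes, a single orientation (partner ranks
ascending, or descending for inverted blocks), greedy extraction by anchor
count, and a minimum of `min_block = 5` anchors. These defaults are the
ones commonly used by duplication-classification workflows and are
configurable. Intra-chromosomal dots within `max_gap` ranks of the
self-comparison diagonal are filtered before chaining: they are local
(tandem/proximal) duplications, not collinearity evidence, and synteny
pipelines likewise remove tandem hits before block detection. On small
genomes this filter is what keeps scattered local duplications from
masquerading as blocks.

Each gene then receives exactly one mode by fixed precedence:

1. **WGD** — anchors an intra-genomic collinear block;
2. **TD** — homolog at the adjacent rank on the same chromosome;
3. **PD** — homolog within `proximal_window = 10` ranks;
4. **TRD** — exactly one member of the gene's best-scoring pair sits at a
   syntenic (ancestral) locus, where syntenic means "block anchor or
   listed in a supplied inter-species anchor table". The syntenic member
   is the *ancestral* copy, the other the *novel* copy. Because
   intra-genomic anchors are already WGD by rule 1, a gene can only be
   classified TRD/ancestral through inter-species evidence — consistent
   with ancestral loci being recognisable either by intra-genomic or by
   inter-species synteny.
5. **DSD** — any remaining homolog; else **singleton**.

Multi-homolog genes use their best-scoring pair (highest score, ties by
smaller rank distance, then lexicographic partner id) — a declared
convention, since published workflows do not state one. No inter-species
synteny is computed internally; the anchor table is an input.

## Ka/Ks by Nei–Gojobori (1986)

Model-averaged maximum-likelihood estimation (the published route) is a
large dependency; the package instead implements the classic NG86
counting estimator, which is deterministic, fully specified and
oracle-checkable, and labels its output accordingly:

* **Sites.** For each codon, each of the nine single-nucleotide changes is
  classified; the synonymous-site count is (synonymous changes)/3 summed
  over positions, totalled per sequence and averaged between the two
  sequences ($S$; $N = 3L - S$). Changes creating stop codons are
  non-synonymous by this accounting.
* **Differences.** Codon pairs differing at $k$ positions average the
  synonymous/non-synonymous step counts over all $k!$ orderings with equal
  weights, excluding orderings that pass through a stop codon; if every
  ordering does, the codon contributes sites but no differences.
* **Correction.** $p_s = S_d/S$ and $p_n = N_d/N$ receive the
  Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac43 p)$. A pair is
  flagged *saturated* when $p \ge 3/4$ (correction undefined) or when
  $K_s > 5$; saturated pairs are excluded from all mode summaries.

Codon pairing uses a protein-guided global alignment with a fixed toy
scorer (match 1, mismatch −1, linear gap −2) and a deterministic
traceback (diagonal over gap-in-second over gap-in-first on ties),
back-mapped to codons with gapped and stop-containing columns dropped.
Only the universal genetic code is wired in, behind a single lookup.

Per-mode divergence summaries report n, median and quartiles of Ka/Ks for
unsaturated pairs and all pairwise two-sided Wilcoxon rank-sum tests;
fully tied groups report p = 1 (the normal approximation is undefined
there). The ancestral-versus-novel transposed-duplicate contrast compares
`log2(mean TPM + 1)` between role groups per stage, again by Wilcoxon.

## Island detection

A window of `window_bp = 50000` is anchored at the start coordinate of
every expressed gene; a gene belongs to a window when its start lies
inside it. A window qualifies when it contains at least 3 pattern genes
**and** pattern genes exceed 60% of its expressed genes (both bounds
exactly as published: `>= 3`, strictly `> 60%`). Overlapping qualifying
windows merge transitively; each merged region becomes one island spanning
from the minimum start to the maximum end of its member pattern genes.

Declared conventions, where the source procedure is silent: windows are
anchored at expressed-gene starts rather than every base (deterministic;
a brute-force every-bp oracle in the test suite bounds what this can
miss); membership is by gene start; island size is the member-gene span,
not the window span, so mean island sizes are data-driven rather than
multiples of 50 kb. The expressed-gene background defaults to mean TPM
> 2 across all samples — the same filter used to select co-expression
input — and is configurable.

## Eigengene, hub rule and neighbor groups

Module labels are an input (full network construction — soft threshold,
topological overlap, tree cutting — is intentionally not reimplemented;
the implementable contribution is the hub rule and the neighbor
analysis). The module eigengene is the first right singular vector of the
per-gene z-scored module submatrix: per-sample scores, sign-fixed so the
mean gene–eigengene correlation is non-negative, scaled to unit variance.
Zero-variance genes are dropped with a warning.

Module membership (MM) is the Pearson correlation of a gene with its
module eigengene; gene significance (GS) is its correlation with a binary
stage indicator (1 for samples of the trait stage). A gene is a hub when
`MM >= 0.6`, `GS >= 0.5` and the GS correlation test (t distribution,
n − 2 df) gives `p < 0.05`. Thresholds apply to *signed* correlations —
the hub usage in the source analysis is positive association — and both
the encoding and the signedness are configurable conventions.

Neighbor groups are maximal runs (length ≥ 2) of hub genes at consecutive
chromosome ranks, reported with their intergenic spacers and their
duplication modes, so the observation that such groups tend to consist of
non-duplicated genes is checkable from the output rather than enforced by
it.

## Contamination screen

Tabular alignment hits (the standard 12-column format plus a
`taxon_class` column and a query-length sidecar) are grouped per query;
coverage by a class is the length of the union of its query intervals
divided by query length, overlaps counted once. A query is removed when
non-target coverage strictly exceeds 50%; exactly 50% keeps it. Positions
covered by both classes count fully toward each class — the published
rule mentions no subtraction — and this inclusive convention is fixed and
flagged in the documentation. Organelle-fragment removal is the same
screen with organelle references as the non-target class. Taxon classing
itself is an input: no taxonomy database is bundled.

## The synthetic-data generator

`simulate_bundle()` emits every pipeline input plus planted-truth tables
from a single seed (same seed, byte-identical files). It emulates:

* a compact genome — 6 chromosomes × 150 genes, mean gene 1.5 kb,
  exponential intergenic gaps of mean 2.5 kb (≈ 14 genes per 100 kb, the
  density of a compact moss genome);
* planted islands — 5 runs of 4–8 genes within 40 kb, spaced small
  (0.2–0.8 kb) inside the run and isolated by 60-kb flanks so that the
  planted cluster, not its neighborhood, determines the window outcome;
  each island's genes are upregulated (log2FC = 3) at one pattern stage;
* duplication events — 20 tandem, 20 proximal, 2 blocks × 6 anchors,
  35 transposed (ancestral copy listed as an inter-species anchor,
  expression 4× the novel copy), 25 dispersed; paired CDS are mutated at
  per-mode synonymous/non-synonymous rates so tandem/proximal pairs carry
  higher Ka/Ks than block anchors;
* expression — negative-binomial counts (dispersion 0.1) over log-normal
  baselines (meanlog = log 200, sdlog = 1) with 5% of eligible genes per
  contrast given |log2FC| = 2 effects. Planted DE genes are drawn from
  genes with baseline mean ≥ 50 counts: fold-change recovery is only
  meaningful on expressed genes, and the study's DEG universe is likewise
  quantified, expressed genes;
* a 60-gene trait module spiking 8× at H1, plus random labels for the
  remaining genes, for the MM/GS analyses;
* 5 contaminant scaffolds (non-target union coverage 55–90%) and 15 clean
  ones.

What it does **not** emulate: sequence-level realism beyond codons, read
mapping, batch effects, gene-family structure beyond isolated events, or
correlated noise between replicates. Passing planted-truth tests therefore
demonstrates the correctness of the detectors under the stated generative
model, not performance on real libraries.

## Numerical choices and problem sizes

Deterministic tie-breaks are fixed everywhere randomness could creep in:
rank ties by end then id; chain extraction by score, then leftmost start,
then same orientation; best pairs by score, rank distance, partner id;
alignment traceback by a fixed preference order. All randomness in the
generator flows from one `set.seed()` call.

The shipped tests and the acceptance script run the generator at its
defaults (900 genes, 15 samples) over 20 replicate seeds for the
recovery experiments, and use smaller two-chromosome genomes for unit
fixtures — sizes chosen so the whole suite completes in a few minutes
while keeping ≥ 30 transposed pairs (the sample size at which the
ancestral-versus-novel Wilcoxon contrast is assessed) and ≥ 100 planted
islands in the recovery averages.

## Known limitations

* NG86 differs from model-averaged ML estimates, especially at high
  divergence; results are labelled NG86 and saturated pairs are excluded
  rather than corrected.
* The Welch stand-in is underpowered at three replicates (see above); use
  the plugin route for model-based calls.
* Gene-anchored island scanning can in principle miss a qualifying window
  anchored strictly between gene starts; the brute-force oracle property
  in the test suite bounds this on small chromosomes.
* Inter-species synteny, taxonomy resolution and network construction are
  inputs, not computations.

## A worked run

```{r run, eval = FALSE}
out <- file.path(tempdir(), "demo")
man <- run_pipeline(sim_config(seed = 1), out)
names(man$stages)
read.delim(file.path(out, "island_summary.tsv"))
```

Every stage writes plain TSV/GFF3/FASTA/BED files under `out` and the
manifest records parameters, checksums and timings, so any stage can be
re-run or replaced independently.
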