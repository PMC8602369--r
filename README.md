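# epromoter

Identification of **Epromoters** — gene promoters that also act as distal
enhancers — and of **Epromoter-regulated gene clusters** from promoter
activity screens, written for regulatory genomicists analysing
stimulus-response experiments (the motivating case is the type I
interferon response, where clusters of co-induced genes can be driven by a
single promoter recruiting the ISGF3 complex).

The package implements the full analysis chain:

1. **Activity quantification** — fragment counts over captured promoter
   windows (−200/+50 bp around the TSS) are FPKM-normalized and enhancer
   activity is the fold-change of the reporter library over the input,
   FC = FPKM<sub>STARR</sub>/FPKM<sub>input</sub>. Windows with input
   FPKM < 1 are removed. The activity threshold τ is the inflection point
   (knee) of the ranked (rank, log₂ FC) curve: the point of maximum
   perpendicular distance to the chord joining its endpoints. A promoter
   is an Epromoter in a condition when its mean FC ≥ τ; it is an *induced*
   Epromoter when additionally mean<sub>i</sub>(FC<sub>stim,i</sub> /
   FC<sub>ns,i</sub>) > 2 (strict) with ≥ 1 active stimulated replicate.
2. **Expression classes** — genes are induced when log₂FC > 1 and
   adjusted p < 0.001 (both strict); crossing gene classes with Epromoter
   calls yields the three response-locus sets (*induced gene only*,
   *induced gene & Epromoter*, *induced Epromoter only*).
3. **Binding analyses** — composite peaks bound by all of STAT1/STAT2/IRF9,
   nearest-peak positional categories per induced gene (same promoter /
   another promoter / intergenic, ±1 kb), promoter×TF binding matrices,
   and 0/1/≥2 ISRE-site classes per promoter (all sites, and a
   high-confidence tier with motif p < 1e-4).
4. **Cluster calling** — single-linkage clustering of response-locus TSSs
   at ≤ 100 kb, cluster typing, TAD status (Y/N/O against merged TADs),
   and prediction of Epromoter-regulated clusters: exactly one member
   promoter bound by ≥ 1 key TF, all others unbound.
5. **Statistics** — two-sample KS test, 2×2 chi-square, random-gene
   controls, and region-shuffling overlap enrichment with a
   negative-binomial null fitted by moments to 100 within-chromosome
   shuffles, p = P(X ≥ observed).
6. **Synthetic data** — a seeded generator that plants all of the above
   structure (clusters, hub Epromoters, motif tiers, TADs) with ground
   truth, so the whole chain is testable offline.

## Worked example

Generate a synthetic study (2,000 genes, 40 planted clusters) and run the
pipeline end to end:

```r
library(epromoter)

cfg <- sim_config(seed = 0)
dir <- file.path(tempdir(), "fixtures")
fx  <- simulate_fixture_set(dir, cfg)

rc <- run_config(
  counts      = file.path(dir, "counts.tsv"),
  tss         = file.path(dir, "tss.tsv"),
  de          = file.path(dir, "de.tsv"),
  tf_peaks    = setNames(file.path(dir, paste0("peaks_", cfg$tf_names, ".bed")),
                         cfg$tf_names),
  isre_sites  = file.path(dir, "isre_sites.bed"),
  tads        = file.path(dir, "tads.bed"),
  chrom_sizes = file.path(dir, "chrom.sizes"),
  out_dir     = file.path(dir, "out"))
res <- run_all(rc)
```

The run log records every threshold used:

```
activity thresholds (inflection): ns=1.109 stim=0.9707; input FPKM floor 1, induction ratio > 2
DE thresholds: |log2FC| > 1, p < 0.001
ISRE high-confidence tier: p < 0.0001
cluster linkage: TSS distance <= 100000 bp, >= 2 members
```

and `res$summary` (also written as `out/summary.json`) holds the headline
counts. For this seed:

* 2,088 promoters quantified, 0 removed by the input filter; activity
  thresholds τ<sub>ns</sub> = 1.109, τ<sub>stim</sub> = 0.971 — the knee
  between the background bulk (FC ≈ 1) and the planted actives (FC ≥ 5);
* 28 induced, 6 repressed and 57 constitutive Epromoters; 184 induced and
  54 repressed genes — the three response sets contain 175 / 9 / 19 genes;
* 40 clusters (matching the 40 planted), 19 containing an Epromoter, 19
  predicted Epromoter-regulated; TAD status Y/N/O = 25/8/7;
* nearest-peak categories of induced-only genes: 5.71% same promoter,
  45.14% another promoter, 49.14% intergenic;
* composite-peak enrichment in promoter windows: 30 observed overlaps vs
  a shuffle mean of 2.09 (p ≈ 2e-24).

Each number is recomputable from the stage tables written next to the
summary (`activity.tsv`, `gene_sets.tsv`, `peak_annotation.tsv`,
`isre_counts.tsv`, `clusters.tsv`), and reruns with the same config are
byte-identical.

Because the generator returns its ground truth (`fx$genome$truth`),
recovery is directly measurable — on the default conditions the induced
Epromoter calls reach precision and recall 1.0 and cluster membership
matches the planted clusters exactly (see the acceptance script below).

## Vignette

`vignettes/epromoter-methods.Rmd` documents the model and its assumptions:
the inflection-threshold construction, the strict/inclusive boundary
semantics of every call, the shuffle-null design and its calibration, the
Gamma–Poisson count model of the generator, and known limitations.
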