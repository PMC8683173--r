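# cncnet

Linking differentially expressed long noncoding RNAs (lncRNAs) to candidate
target mRNAs in two-group transcriptome studies.

Many case–control microarray and RNA-seq studies ask the same downstream
question: which lncRNAs change between groups, and which coding genes do
they plausibly regulate? `cncnet` implements the standard inference chain
used to answer it, as a tested, reproducible R pipeline:

1. **Differential expression screening.** Per-probe log2 fold change
   (difference of group means on the log2 scale) combined with an
   empirical-Bayes *moderated t-test*: the pooled residual variance of each
   probe is shrunk toward a prior, `s²_post = (d₀·s₀² + d·s²)/(d₀ + d)`,
   with the hyperparameters `(d₀, s₀²)` estimated from all probes by
   matching the moments of the log sample variances to a scaled
   F-distribution. The statistic `t = Δlog2FC / (s_post·√(1/n₁ + 1/n₂))` is
   referred to a t distribution with `d + d₀` degrees of freedom. Probes
   with `|FC| ≥ 1.5` (linear scale) and raw `P < 0.05` are flagged;
   Benjamini–Hochberg FDR is reported alongside.
2. **Coding–noncoding coexpression network (CNC).** Pearson correlation for
   every DE-lncRNA × DE-mRNA pair across all samples; edges kept at
   `|PCC| > 0.7` and `P < 0.05` (P from `t = r·√(n−2)/√(1−r²)` on `n−2`
   df). Degree centrality (raw edge count) identifies hubs (`degree > 60`),
   and the top 30 lowest-P edges summarize the strongest pairs.
3. **Cis-target prediction.** A coding gene is a candidate *cis* target of
   a lncRNA when the two genes lie on the same chromosome within 300 kb
   (span gap, boundary inclusive) *and* the pair is a CNC edge. Interval
   queries run on a GenomicRanges index and are provably identical to a
   brute-force scan.
4. **Over-representation analysis.** Hypergeometric upper-tail test
   `P[X ≥ k]` of up- and downregulated DE mRNAs (separately) against
   user-supplied GMT gene-set collections.
5. **qPCR validation.** Relative quantification by the 2^−ΔΔCt method with
   a housekeeping reference, per-gene group tests on ΔCt (Welch t or exact
   Mann–Whitney), and direction concordance with the array calls.

A seeded synthetic-data generator emulates the target study design (13
case / PDC vs 9 control / BC arrays; a 9 vs 12 validation cohort) with
planted fold changes, planted lncRNA–mRNA correlations and planted cis
co-location, and writes a machine-readable truth table, so every stage of
the chain can be benchmarked for recovery.

## Worked example

```r
library(cncnet)

cfg <- synthetic_config(n_lnc = 150, n_mrna = 250, n_de_lnc = 12,
                        n_de_mrna = 16, n_linked_pairs = 8, n_cis_pairs = 4,
                        planted_log2fc = 2, noise_sd = 0.3,
                        genome = setNames(rep(8e7, 5), paste0("chr", 1:5)),
                        seed = 7)
b <- simulate_bundle(cfg, "demo_data")
pc <- pipeline_config(b$expression_tsv, b$metadata_csv, b$bed,
                      gmt = b$gmt, qpcr_csv = b$qpcr_csv)
res <- run_pipeline(pc, "demo_run")
head(res$cis_coexpressed, 3)
```

which prints the per-stage log and the intersected cis-coexpressed pairs:

```
diffexpr: 28 / 400 probes pass |FC| >= 1.5 & P < 0.05 (12 lncRNA, 16 mRNA)
coexpression: 192 edges, 28 nodes, 0 hubs (degree > 60)
cis_targets: 4 pairs within 3e+05 bp; 4 also coexpressed
enrichment: 1 sets (up), 1 sets (down) at P < 0.05
qpcr: direction concordance 100% over 8 gene(s)
    lnc_id   mrna_id chrom distance_bp       pcc      p_value
1 LNC00001 MRNA00001  chr1        5852 0.9829967 3.398707e-16
2 LNC00002 MRNA00002  chr1      191877 0.9930498 4.612402e-20
3 LNC00003 MRNA00003  chr1      165223 0.9898801 1.949973e-18
```

All 12 planted lncRNA and 16 planted mRNA effects pass the screen, the 4
planted cis pairs are recovered with their genomic distances and
correlations, and the qPCR round-trip reproduces the planted directions for
all 8 assayed genes. `demo_run/` holds every stage table as CSV, the
network as SIF and GraphML (Cytoscape-ready), figures, and a JSON manifest
recording the config, thresholds and row counts; re-running the same config
reproduces the tables byte for byte.

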