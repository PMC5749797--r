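# tfsig

Transcription factor (TF) motif signatures for cross-study phenotype
meta-analysis, aimed at regulatory-genomics researchers who need to compare
heterogeneous expression studies — different tissues, platforms and designs
— at the level of transcriptional regulation rather than individual
transcripts.

Each study contributes a sign-less trimmed gene set (by default its 75 most
up- and 75 most down-regulated genes). `tfsig` then:

1. scans promoter windows (−450 bp to +50 bp around the TSS, in the
   direction of transcription) against JASPAR / TRANSFAC position weight
   matrices, scoring each gene by its min-max-normalised best hit
   (maximum summed log-odds over all windows and both strands);
2. scores motif over-/under-representation per sample with a one-sided
   z-test against the genomic background,
   `z = (x̄_set − μ_bg) / (σ_bg / √n)`, with Benjamini–Hochberg FDR across
   motifs (enriched: FDR < 0.05; avoided: p > 0.25);
3. assembles a samples × motifs signature matrix, removes motifs never
   significant anywhere or with p-score variance ≤ 0.08, and
   rank-transforms within samples;
4. groups samples by Spearman-distance complete-linkage clustering,
   k-means and PCA, and screens motifs with a multiclass SAM statistic;
5. detects **switching motifs** between two phenotypes — enriched
   (p < 0.05) in one, avoided (p > 0.25) in the other, with an opposing
   > 15-fold score ratio and a rank change;
6. seeds a minimum protein-interaction network with the switching TFs
   (confidence-filtered STRING-style edges) and probes stress-sensor
   connectivity to each subnetwork.

A synthetic-data module generates promoters with planted motifs, multi-
sample panels with planted phenotype groups, and interactomes with planted
modules, so every stage is testable with known ground truth and no
downloads.

## Worked example

Simulate a two-phenotype panel, profile it, and ask which motifs switch
between a sample of each group:

```r
library(tfsig)

panel <- simulate_panel(n_groups = 2, samples_per_group = 3,
                        motifs_per_group = 3, n_bg_genes = 600,
                        set_size = 60, promoter_length = 250,
                        set_rate = 1.0, seed = 91)
profs <- profile_panel(panel)
sig <- rank_transform(filter_motifs(assemble_signature(profs)))
kmeans_classify(sig, k = 2)$assignments
#> grp1_s1 grp1_s2 grp1_s3 grp2_s1 grp2_s2 grp2_s3
#>       1       1       1       2       2       2

mk <- function(sid) data.frame(motif_id = sig$motifs, p = sig$p[sid, ],
                               rank = sig$ranks[sid, ])
detect_switching(mk("grp1_s1"), mk("grp2_s1"),
                 labels = c("grp1_s1", "grp2_s1"))
#> <switch_table> 6 switching motifs (A = grp1_s1, B = grp2_s1; fold > 15, enriched < 0.05, avoided > 0.25)
#>   motif_id name       p_a       p_b rank_a rank_b     fold     direction
#> 1   SYN002      4.873e-22 9.998e-01      1      5 2.05e+21 enriched_in_A
#> 2   SYN004      9.994e-01 1.134e-21      4      1 8.81e+20 enriched_in_B
#> ...
```

The k-means labels reproduce the planted groups exactly, and the switching
table recovers precisely the planted motifs: group-1 motifs are enriched in
the group-1 sample (tiny `p_a`, rank near 1) and avoided in the group-2
sample (`p_b` near 1), and vice versa; `fold` is the max/min ratio of the
two p-scores.

The package also bundles the published reference score pairs for the two
fibroblast aging phenotypes (energy restriction in quiescence vs replicative
senescence). Running the same detector on them:

```r
ref <- reference_switch_scores()
detect_switching(ref$a, ref$b, labels = ref$labels)
#> <switch_table> 14 switching motifs (A = ERiQ, B = senescence; fold > 15, enriched < 0.05, avoided > 0.25)
#>    motif_id      name    p_a    p_b rank_a rank_b   fold     direction
#> 1  MA0106.2      TP53 0.9909 0.0002    279      1 4950.0 enriched_in_B
#> 2    M00516  V$E2F_03 0.0002 0.5325     11     86 2660.0 enriched_in_A
#> ...
#> 14 MA0018.1     CREB1 0.0498 0.8563     85    258   17.2 enriched_in_A
```

All 14 motifs pass the filter: 8 enriched in ERiQ and avoided in
senescence, 6 the opposite — the E2F/NFY/EGR cluster marks energy
restriction while TP53, FOXH1 and TP73 mark senescence.

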