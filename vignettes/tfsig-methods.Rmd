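---
title: "Transcription factor signature analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription factor signature analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsig)
```

## The problem

Gene expression studies of aging are notoriously hard to compare: tissues,
platforms and study designs differ, and the overlap of individual
differentially expressed transcripts between studies is small. `tfsig`
abstracts away from transcripts to *transcriptional regulation*: each study
contributes only a trimmed list of its most differentially expressed genes,
and the question becomes which transcription factor (TF) binding motifs are
over- or under-represented in the promoters of those genes. Per-sample motif
profiles are then rank-transformed and compared across samples, which is
robust to any monotone distortion introduced by platform or analysis
choices.

## The statistic: best-hit promoter scores and a z-test

Each motif is a position frequency matrix (PFM) over A, C, G, T, converted
to a log-odds scoring matrix against a background distribution $q$ with a
pseudocount $s$:

$$W_{ib} = \log \frac{(c_{ib} + s\,q_b) / (\sum_b c_{ib} + s)}{q_b}.$$

A gene's score for a motif is its *best hit*: the maximum of the summed
log-odds over all windows of its promoter (both strands by default), min-max
normalised by the attainable score range so 1 is a perfect consensus site.
Promoter windows run from 450 bp upstream to 50 bp downstream of the
transcription start site, read in the direction of transcription.

Over-representation in a gene set of size $n$ is scored against the moments
of the best-hit distribution over the whole gene universe:

$$z = \frac{\bar x_{set} - \mu_{bg}}{\sigma_{bg} / \sqrt n},
  \qquad p = P(Z > z).$$

The p-score is one-sided: enriched motifs get small $p$, avoided
(under-represented) motifs get $p$ near 1. This moment-based test is
deterministic — no resampling — and its null calibration is verified in the
test suite (the fraction of null tests below 0.05 sits inside binomial
bounds). Within each sample, Benjamini–Hochberg q-values are computed across
motifs and a motif is called *enriched* at FDR < 0.05, *avoided* at
$p > 0.25$. Multiple-testing control is within-sample only, because each
sample's signature is built independently. p-scores are floored at the
smallest normal double so that downstream fold ratios are always finite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_up` / `window_down` | 450 / 50 bp | promoter window around the TSS |
| `n_up` / `n_down` | 75 / 75 | trimmed genes per direction (sign-less 150-gene set) |
| `fdr_threshold` | 0.05 | BH level for the enriched call |
| `avoided_threshold` | 0.25 | p-score above which a motif is avoided |
| `var_threshold` | 0.08 | variance filter on p-scores across samples |
| `fold_threshold` | 15 | minimum opposing fold for a switching motif |
| `k_groups` | 3 | k-means phenotype groups |
| `pca_load_threshold` | 0.05 | absolute load for "high-load" motifs |
| `ppi_min_score` | 500 | minimum STRING-style combined confidence |
| background | uniform 0.25 | scanning background; override from promoter composition |
| pseudocount | 1.0 | distributed proportionally to the background |

p-scores live in $[0,1]$, so the variance filter's 0.08 is on a scale whose
maximum attainable variance is 0.25; it removes motifs whose profile barely
moves across samples. Variance is computed with the population ($n$)
normalisation on the p-scores themselves (not on z or ranks), and the
significance filter (enriched somewhere) is applied before the variance
filter.

## Signatures, clustering and the switching filter

The samples-by-motifs p-score matrix is built on the motif intersection of
the profiles, filtered as above, and rank-transformed within samples
(rank 1 = most enriched, midranks on ties). Sample similarity is Spearman
correlation of these rank rows; `1 - rho` feeds complete-linkage
hierarchical clustering (complete linkage emphasises dissimilarities, which
is what separates anti-correlating phenotypes). K-means (best of 25 random
starts, fixed seed 1234) and PCA (column-centered ranks, no unit-variance
scaling by default; a flag exposes the scaled variant because ordination
tools differ on this) provide complementary groupings. A multiclass SAM
screen flags motifs driving the grouping: the statistic is
$\sqrt{\mathrm{BSS}_j}/(s_j + s_0)$ with $s_0$ the median per-motif pooled
standard error, and q-values come from seeded group-label permutations. SAM
is implemented as this standard moderated statistic; it is used only as
supporting evidence for switching candidates, never as the primary filter.

A motif *switches* between two conditions when all four criteria hold: a
score below 0.05 in one condition, a score above 0.25 in the other, an
opposing fold ratio (max/min of the two scores) strictly above 15 on the
unrounded scores, and a change in within-sample rank. Motifs enriched in
both conditions are removed first. Fold ratios are always computed from
full-precision scores; published tables that round scores to four decimals
cannot always reproduce their own fold column, which is why the bundled
reference table carries the published folds separately.

The "change in rank" criterion is implemented as *any* rank difference: no
magnitude is imposed, since the filtered signatures make even small rank
moves meaningful and all reference rows satisfy it comfortably.

## The seeded minimum network

Switching TF proteins seed a protein-interaction subnetwork from a
user-supplied confidence-scored edge list (STRING-export style). Edges must
reach a combined confidence of 500 and carry experimental-channel evidence
(> 0; the column is configurable because export formats vary). The network
is the first-order neighbourhood of seeds and sensors, iteratively pruned of
non-seed, non-sensor nodes of degree ≤ 1 until a fixpoint — a deliberately
minimal, reproducible stand-in for interactive "minimum network" tools whose
exact algorithms are unpublished. Surviving non-anchor nodes are labelled
intermediates. Subnetwork groups are assigned per connected component of the
sensor-free graph by majority seed role, so a sensor bridging both modules
can never merge them into one label. Sensor probing then counts each
sensor's retained edges into the A- and B-derived node sets. ID mapping
between gene symbols and protein identifiers is the caller's responsibility;
no remote services are queried.

## What the synthetic data emulate — and what they do not

The generator exists so that every stage has ground truth without
downloads:

* **Motifs** are Dirichlet-multinomial PFMs; concentration 0.1–0.2 gives
  sharp, biologically plausible 8-mers.
* **Promoters** are order-0 i.i.d. sequence at a chosen GC content with
  consensus (or PFM-sampled) instances planted at exact per-gene rates,
  uniform positions and strands, never overlapping each other; every
  insertion is ledgered. An order-0 background is sufficient to calibrate a
  mean/SD z-test but does not reproduce dinucleotide structure, CpG islands
  or repeat content — motifs that resemble such features would behave
  differently on real promoters.
* **Panels** give each phenotype group a disjoint motif set planted at a
  genomic baseline rate (0.25) everywhere and at a high rate (0.8, times a
  fixed per-motif strength factor in [0.6, 1]) in its own group's target
  sets. The strength factor makes enrichment magnitudes differ between a
  group's motifs, as they do between real factors, which is what gives
  within-group rank orderings their consistency. Samples of 15 panels
  (3 groups × 5) with 150-gene sets over a 1,500-gene universe and 500 bp
  promoters are the packaged study-scale conditions.
* **Interactomes** plant two internally dense, never directly connected seed
  modules, per-module intermediates, sensors wired only to their designated
  module, and background noise edges that exercise the confidence filter.

Passing tests on these data show that the statistics recover planted truth
under the stated noise model; they cannot show that real aging tissues
separate into the same groups, which depends on the biological inputs.

## Numerical and design choices

* Coordinates are 0-based half-open internally; TSS tables are accepted
  1-based by default with an explicit flag.
* Both strands are scanned by default (a flag restricts to one): promoter
  orientation fixes the window, not the binding orientation.
* IUPAC ambiguity codes score as the position's background expectation, so a
  single N does not discard a gene; promoters with more than 10% ambiguous
  bases are recorded as missing and dropped from the affected gene sets.
* Degenerate matrices (equal min and max attainable score) cannot be min-max
  normalised and are excluded from scanning with a warning.
* Trimming ties are broken lexicographically by gene id; rank ties get
  midranks; the max over windows needs no tie-break because only the score
  is reported.
* k-means and SAM permutations take mandatory seeds (default 1234), making
  reruns bit-identical.
* The hierarchical merge tree is returned in the standard `hclust`
  encoding, whose leaf ordering convention is deterministic for fixed input.
* Test and example problem sizes (universe 1,500–3,000 genes, 500 bp
  promoters, 10–20 motifs, 50–200 replicates) were chosen as the smallest
  scales at which the calibration and power properties are stable.

## Known limitations

* The variance filter operates on p-scores; signatures dominated by avoided
  motifs (p near 1 everywhere) pass the filter only via their enriched
  samples.
* The minimum-network heuristic is one defensible reading of "minimum
  network"; published node/edge counts from interactive tools additionally
  depend on the interactome release and are not reproduced here.
* Motif variant grouping (merging JASPAR and TRANSFAC matrices of the same
  factor) is only applied when the user supplies a grouping table; by
  default every matrix is reported separately.
* The z-test treats gene scores as independent draws from the universe;
  finite-universe sampling makes it very slightly conservative.
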