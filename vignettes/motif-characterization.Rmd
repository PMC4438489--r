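---
title: "Characterizing a DNA sequence motif genome-wide with cismotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a DNA sequence motif genome-wide with cismotifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismotifs)
```

# The problem

A candidate DNA sequence motif — say, one that fell out of a ChIP
experiment's de novo motif search with no known match in the motif
databases — needs computational evidence before anyone spends bench time on
it. Four genome-wide signatures distinguish plausible functional
cis-regulatory elements from sequence-pattern noise:

1. the motif's genomic sites cluster together more than chance predicts;
2. the sites are enriched in promoter regions;
3. the sites are more phylogenetically conserved than matched controls;
4. the sites carry elevated DNase I hypersensitivity (open chromatin)
   across cell lines.

`cismotifs` implements this whole characterization as reusable, tested
components: a likelihood-ratio scanner, site clustering, enrichment
statistics with their implied false discovery rates, two null-control
families, conservation and DNase-seq signal analysis, and a synthetic-genome
generator that makes the entire pipeline testable end to end with planted
ground truth, without any external data.

# The model

## Motifs and information content

A motif of length $L$ is a position-specific probability matrix with
entries $p_{ij}$, the probability of nucleotide $j \in \{A,C,G,T\}$ at
position $i$. Its sequence specificity is summarized by the information
content. Position $i$ carries

$$ IC_i = 2 + \sum_j p_{ij} \log_2 p_{ij}, $$

i.e. two bits minus the Shannon entropy, with the convention
$0 \log_2 0 = 0$: an equiprobable position carries 0 bits, a deterministic
one the maximum of 2. The total IC is $\sum_i IC_i$ and the per-nucleotide
IC is the total divided by $L$. IC is computed on the published matrix as
is — the scanner's pseudocount (below) is deliberately kept out of this
module so that the reported specificity reflects the matrix itself.

## Likelihood-ratio scanning

Every $L$-bp window $W$ of the genome, on both strands, is scored with

$$ LR(W) = \frac{P(W \mid \text{motif})}{P(W \mid \text{background})}, $$

where $P(W \mid \text{motif}) = \prod_i p'_{i,W_i}$ uses the matrix after
adding a pseudocount $\varepsilon = 10^{-4}$ to every cell and
renormalizing rows (so a zero cell cannot veto a window), and the
background is a $k$-th order Markov chain (default $k = 3$) trained on both
strands of the scanned genome with add-one pseudocounts per context.
$P(W \mid \text{background})$ is the chain probability of the window given
its actual upstream genomic context; at sequence starts and after runs of
non-ACGT characters, where no complete context exists, the trained marginal
nucleotide frequencies stand in. Windows containing a non-ACGT base are
skipped. Sites with $LR$ at or above a cutoff (default 1000) are reported;
overlapping sites are deduplicated greedily by descending $LR$, with ties
broken by coordinate and then `+` strand so the output is deterministic.

When a control motif must be mapped to a *target number* of sites rather
than a cutoff, `cutoff_for_count()` scans at a floor cutoff, deduplicates,
and truncates to the target by descending $LR$. This is exact, not
approximate, because thresholding commutes with $LR$-greedy deduplication:
a site can only ever be blocked by a stronger site, and raising the cutoff
never removes a blocker without removing the blocked site's competitors
above it. A motif that cannot reach the target even at the floor keeps all
its sites and is flagged as a shortfall rather than failing.

## Site clusters

Sites are chained into clusters by single linkage: two adjacent sites on a
chromosome join when the gap between them is at most $W$ bp (default 500),
and clusters with fewer than `min_sites` members (default 2) are dropped.
The implementation chains on a running maximum of interval ends, which
makes it exactly the transitive closure of the pairwise gap relation even
for staggered intervals — the property the test suite checks against an
$O(n^2)$ union-find oracle.

The gap is measured edge-to-edge (intervening bases) by default, because
"separated by $d$ bp" most naturally counts the bases between two sites; a
start-to-start variant is available via `gap_metric = "start"` for
sensitivity analysis. Strand is ignored throughout: sites on opposite
strands co-cluster.

## Promoter enrichment, folds, and implied FDR

Sites, cluster spans, and clustered sites are each classified against a
gene annotation into one of four exclusive categories: within `promoter_bp`
upstream of a TSS (strand-aware; default 1 kb), within 1 kb downstream of a
TES, intragenic, or intergenic, with precedence promoter > downstream >
intragenic when windows of different genes overlap (promoter assignment is
the analysis' focus, so it wins). The enrichment of the motif set over a
control set in a category is the ratio of proportions (fold), tested with a
pooled-variance one-sided two-proportion Z-test. A fold of $f$ implies a
false discovery rate of $100/f$ percent: of every $f$ motif items found in
promoters, one is expected by chance.

The related occurrence-rate statistic compares motif site counts per
non-repeat base pair between a test region set and matched controls,
$r = (n_1 L_2)/(n_2 L_1)$, with implied site-level FDR $100/r$ percent;
$r \ge 2$ (FDR $\le 50\%$) is the conventional reporting cutoff for de novo
motifs. Matched control regions are resampled so that their distances to
the nearest TSS reproduce, as a multiset, the distances of the positive
regions — each control is placed at the positive's signed, strand-oriented
TSS distance from a uniformly chosen *different* gene, which preserves the
distance distribution without trivially re-selecting the positive.

## Null controls

Two null families calibrate every signature:

* **Random genomic sites** — the same number of width-$L$ intervals drawn
  uniformly from non-repeat sequence.
* **Permuted motifs** — the motif's position rows shuffled into a random
  non-identity order. A permuted motif has exactly the same column multiset,
  total IC and per-nucleotide IC, but its genomic site landscape loses
  whatever made the original special; it is therefore the matched null for
  clustering, conservation, promoter and DHS comparisons. Each permuted
  motif is mapped count-matched to the motif under study.

At genome scale a battery of 500 permuted motifs is the conventional size;
the battery size is a parameter here, and this package's own tests use
3-20 permuted motifs, which is enough to exercise the machinery and rank the planted
motif against its nulls on desk-scale genomes.

## Conservation and DNase I hypersensitivity

Raw per-base conservation probabilities in $[0,1]$ (phastCons-style) are
scaled linearly to $[0,255]$ — 255 the most conserved state — and kept as
real numbers; the one-byte storage that motivates that range is an encoding
detail, not arithmetic. Around each site the track is averaged per offset
over a $\pm$1-kb flank, strand-aware so that offset 0 is always the motif's
5' start. The overall conservation of a motif is the average over sites of
the within-site average score.

DNase-seq read counts per window are normalized by each sample's total,
multiplied by the median total across samples, transformed as
$\log_2(y+1)$, and averaged across replicates of a cell line. Per site, a
200-bp window centered on the site midpoint (floor of the midpoint for
even widths; windows clipped at chromosome edges) is averaged, and groups
of sites are compared per cell line with a one-sided Welch $t$-test,
Bonferroni-corrected across cell lines. Welch rather than pooled-variance
was chosen because the compared groups differ in size and variance by
construction; on the synthetic data the choice is immaterial, and both
variants are standard.

# The synthetic-data generator

`synthetic_spec()` / `generate_bundle()` produce a fully self-contained
input bundle: genome FASTA, gene models, repeat mask, conservation track,
replicated DNase-seq count tracks, and truth tables. The generator's
defaults are the study conditions used throughout the package's validation:

* a 5-Mb single-chromosome genome with slightly AT-rich composition
  (A/T 0.30, C/G 0.20), 400 genes (one TSS per ~12.5 kb, chosen so promoter
  windows cover a stable few percent of the genome and enrichment
  denominators are well estimated at this scale);
* 2,000 planted motif instances, sampled column-wise from the matrix so
  the $LR$ distribution at true sites is realistic rather than
  consensus-perfect; instances land on either strand;
* `cluster_fraction = 0.5` of sites arranged in clusters of 2-5 with
  intra-cluster gaps of 20-200 bp; `promoter_fraction = 0.5` of clusters
  forced wholly into promoter windows; every planted element keeps at
  least 1 kb of isolation from every other, so clustered/unclustered truth
  is unambiguous at the 500-bp analysis window. Unforced elements place
  uniformly and may land in promoters by chance — promoter truth is read
  off the final coordinates, which is what lets an unbiased spec
  (`promoter_fraction = 0`) recover a promoter fold compatible with 1;
* conservation: Gaussian noise around a baseline of 0.10 (a typical
  genome-wide average), plus a boost of 0.6 over planted sites tapering
  linearly to zero over ±200 bp — the qualitative decay away from sites is
  the feature being emulated, the specific taper shape is a choice;
* DNase-seq: Poisson counts in 100-bp bins at rate 2, multiplied by 5 over
  planted sites, for 3 cell lines × 2 replicates with random per-sample
  depth factors in [0.5, 1.5] so normalization has real work to do;
* a repeat mask covering 20% of the genome, never overlapping planted
  sites, so "sample controls from non-repeat regions" is well defined.

The bundled 21-bp example matrix (`example_motif()`) is synthetic — an
artificial stand-in, not a published matrix. It carries a GC-rich core
(consensus `GCGCAC` + degenerate N + pyrimidine Y + `G`) flanked by
moderately specific positions, about 20 bits total. The sharpness was fixed
analytically before any test was run: with 2,000 count-matched sites on a
double-stranded 5-Mb genome (~10 million windows), planted-site recall
above 0.9 requires the background false-hit density near the planted 10th
percentile $LR$ to stay well under a couple hundred windows, which a
~20-bit matrix satisfies with margin while a ~13-bit matrix analytically
cannot at this site density. Users studying weaker motifs should expect
count-matched recall to degrade accordingly — that is a property of the
problem, not the implementation.

`recovery_report()` scores a pipeline run against the truth tables: site
recall and precision at 50% reciprocal overlap, cluster recall, clustered
percentage against the planted fraction, promoter fold against the fold of
the truth sites, and conservation/DHS contrasts. The estimated and planted
promoter folds are both computed against one shared, seeded random-site
control (10,000 sites) so that the fold error isolates what the pipeline
got wrong about the sites, not the sampling noise of two independent
controls.

# What the synthetic data does not emulate

The generator makes no attempt at repeat families, isochores or chromatin
domains, alignment artefacts in conservation scores, sequence-dependent
DNase cut bias, or the biological diversity of hundreds of real cell lines
(3-5 synthetic ones suffice to exercise replicate averaging and
per-cell-line testing). Passing recovery tests therefore demonstrates that
the pipeline's statistics do what they claim on data with the assumed
structure — not that a motif validated only in silico is functional.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open in all file formats (BED convention)
  and 1-based inclusive inside R (`GRanges` convention); converters are
  confined to the I/O layer.
* Motif rows are renormalized on read when they sum to 1 within $10^{-3}$,
  rejected otherwise; whole-number matrices are treated as counts and
  normalized by row sums.
* Dedup and count-matching tie-breaks are fully specified (LR, then
  coordinate, then `+` strand), so every pipeline output is reproducible
  bit for bit under a fixed seed.
* Degenerate statistics are defined rather than erroring where a
  convention exists: equal proportions give $Z = 0, p = 0.5$; a zero
  control proportion gives infinite fold and FDR 0; two constant
  equal-mean groups give $t = 0, p = 0.5$. Empty site sets error.
* The robustness sweep (`robustness_sweep()`) varies one parameter at a
  time — mapping cutoff 500/1000/2000, cluster window 250/500/1000,
  promoter width 0.5/1/1.5/2 kb, minimum cluster size 2/3 — holding the
  rest at defaults, re-matching controls at every setting, and scanning
  once at the lowest cutoff (valid by the commutation property above).

# Problem sizes used by the test suite

Module tests run on toy sequences (tens of bases to tens of kilobases) and
validate every vectorized path against independent brute-force oracles.
The end-to-end recovery checks use the full default spec — 5-Mb genome,
2,000 planted sites, three seeds — and the monotonicity sweep uses a 1-Mb,
400-site bundle; these sizes give stable statistics while keeping a full
run of the suite in the minutes range on a single CPU.

# Known limitations

* The scanner is a direct vectorized implementation; it scans megabase
  genomes in seconds but is not built for interactive whole-mammalian-
  genome work (no suffix-array or bit-parallel acceleration).
* $LR$ cutoffs are used raw, as in the original analysis; no p-value
  calibration of scores is attempted.
* The clustered-percentage contrast between a motif and random sites
  depends on site density: at desk-scale densities (a site per few kb)
  random sites co-cluster substantially by chance, so contrasts are
  smaller than at genome scale. The statistics remain valid; only their
  magnitudes differ.
* `matched_control_regions()` matches the TSS-distance distribution
  exactly but, with few genes, may fail to place some controls; failures
  are warned about and reported, not silently dropped.
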