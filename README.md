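# cismotifs

Genome-wide characterization of DNA sequence motifs in R.

When a de novo motif search turns up a sequence pattern with no match in
the motif databases, the question is whether it looks like a functional
cis-regulatory element or like noise. `cismotifs` implements the standard
computational case for (or against) such a motif, built around four
genome-wide signatures:

1. **Clustering** — motif sites group together more than chance predicts;
2. **Promoter enrichment** — sites concentrate upstream of transcription
   start sites;
3. **Phylogenetic conservation** — sites sit on elevated per-base
   conservation scores;
4. **DNase I hypersensitivity** — sites carry open-chromatin signal across
   cell lines.

## The method

A motif is a position-specific probability matrix $p_{ij}$ (position $i$,
nucleotide $j$), summarized by its information content
$\sum_i \left( 2 + \sum_j p_{ij}\log_2 p_{ij} \right)$ bits. The genome is
scanned on both strands with the likelihood ratio

$$LR(W) \;=\; \frac{P(W \mid \text{motif})}{P(W \mid \text{background})},$$

where the background is a 3rd-order Markov chain trained on the scanned
genome; windows with $LR \ge 1000$ (default) are motif sites, overlapping
sites are deduplicated keeping the higher $LR$. Sites separated by at most
500 bp chain into clusters (single linkage; singletons dropped). Sites,
clusters and clustered sites are classified against gene models (1-kb
promoter windows by default) and compared with matched controls: **random
genomic sites** drawn from non-repeat sequence, and **permuted motifs**
(position-shuffled matrices, which preserve information content exactly).
Enrichment is reported as fold = ratio of proportions, with implied
FDR = 100/fold percent, tested by a pooled one-sided two-proportion
Z-test; occurrence-rate enrichment between matched region sets uses
$r = (n_1 L_2)/(n_2 L_1)$ with site-level FDR $100/r$ percent.
Conservation tracks (scaled to 0–255) are profiled over ±1-kb flanks and
DNase-seq counts are depth-normalized (`log2(y+1)`, replicate-averaged)
and compared per cell line with one-sided Welch t-tests under Bonferroni
correction.

A synthetic-data generator (`synthetic_spec()` / `generate_bundle()`)
emulates all required inputs — genome, gene models, repeat mask,
conservation track, replicated DNase-seq counts — with planted motif
structure and exact truth tables, so the entire pipeline is testable end
to end and validated by parameter recovery. See the methods vignette
(`vignettes/motif-characterization.Rmd`) for the model, the defaults and
their rationale, and known limitations.

## Worked example

Characterize the bundled synthetic 21-bp motif on a 1-Mb planted genome:

```r
library(cismotifs)

motif <- example_motif()
information_content(motif)
#> total IC: 20.3959 bits; per-nucleotide IC: 0.9712 bits (21 positions)

spec   <- synthetic_spec(genome_length = c(chr1 = 1e6), n_genes = 80,
                         n_planted = 400, seed = 1)
bundle <- generate_bundle(spec)

report <- run_characterization(
  bundle$genome, motif, bundle$genes,
  conservation   = bundle$conservation,
  dhs_samples    = bundle$dhs$samples,
  dhs_cell_lines = bundle$dhs$cell_lines,
  repeats        = bundle$repeats,
  seed = 1)
report
#> summary by site category:
#>     set n_sites n_clusters n_clustered_sites pct_clustered pct_tssup_sites
#>   motif     417         65               212         50.84           27.58
#>  random     417         63               160         38.37           10.55
#>
#> clustering: 50.84% vs 38.37% random (Z=3.6, p=0.000146)
#> promoter enrichment (sites): test 27.58% vs control 10.55%: fold 2.61 (FDR 38.3%), Z=6.26, p=1.94e-10
#> overall conservation: 191.93 motif vs 86.41 random
#> target genes: 28 (35.0% of genes); relaxed: 43
```

Reading this: 417 sites passed $LR \ge 1000$; half of them chain into
clusters, against 38% for count-matched random sites at this site density
(at desk-scale densities random sites co-cluster substantially — the
Z-test is what matters). Motif sites are 2.6-fold enriched in 1-kb
promoter windows, so of every 2.6 promoter sites one is expected by
chance (FDR 38%); planted conservation and DNase signal separate cleanly
from random sites in all three synthetic cell lines.

Scoring the run against the generator's truth tables:

```r
recovery_report(bundle, report$sites, report$clusters,
                n_random = 10000, seed = 1)
#> site recall 0.955, precision 0.916 (400 truth / 417 detected)
#> pct clustered: 50.84% est vs 50.00% planted
#> promoter fold: 3.06 est vs 3.13 planted (error 2.4%)
#> conservation contrast +150.51; DHS contrast +1.103
```

A thin CLI over the same functions lives at `inst/cli/cismotifs.R`
(subcommands `simulate`, `scan`, `run`, `sweep`).

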