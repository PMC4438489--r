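suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# random valid motif matrix
random_motif <- function(L, seed = NULL, name = "rand") {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::rgamma(L * 4, shape = 1), nrow = L)
  motif_matrix(p / rowSums(p), name = name)
}

rand_dna <- function(n, seed = NULL,
                     probs = c(0.25, 0.25, 0.25, 0.25)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

uniform_background <- function(order = 0L) {
  markov_background(matrix(0.25, nrow = 4^order, ncol = 4),
                    rep(0.25, 4), order = order)
}

make_sites <- function(starts, width = 10L, lr = NULL, chrom = "chr1",
                       strand = "+", seqlen = NULL) {
  if (is.null(lr)) lr <- rep(1, length(starts))
  gr <- GRanges(chrom, IRanges(starts, width = width),
                strand = strand, lr = lr)
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- setNames(rep(seqlen,
      length(GenomeInfoDb::seqlevels(gr))), GenomeInfoDb::seqlevels(gr))
  gr
}

toy_genes <- function() {
  gene_models(data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom   = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    strand  = c("+", "-", "+", "+", "-"),
    txStart = c(5000, 20000, 40000, 8000, 30000),
    txEnd   = c(15000, 30000, 50000, 18000, 42000)))
}
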