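# small bundles keep the suite fast; the full-scale defaults are exercised
# in the acceptance tests

small_spec <- function(seed = 1, n_planted = 120, ...) {
  synthetic_spec(genome_length = c(chr1 = 3e5), n_genes = 30,
                 n_planted = n_planted, seed = seed, ...)
}

test_that("bundle generation is deterministic under the spec seed", {
  b1 <- generate_bundle(small_spec(seed = 9))
  b2 <- generate_bundle(small_spec(seed = 9))
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(start(b1$truth$sites), start(b2$truth$sites))
  expect_identical(b1$truth$clusters, b2$truth$clusters)
  expect_identical(b1$conservation$values, b2$conservation$values)
  expect_identical(lapply(b1$dhs$samples, `[[`, "values"),
                   lapply(b2$dhs$samples, `[[`, "values"))
  b3 <- generate_bundle(small_spec(seed = 10))
  expect_false(identical(as.character(b1$genome), as.character(b3$genome)))
})

test_that("planted sites are consistent with the written genome", {
  b <- generate_bundle(small_spec(seed = 11))
  m <- b$spec$motif
  # strand-aware re-extraction of each planted window from the genome
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(b$truth$sites),
    function(i) {
      gr <- b$truth$sites[i]
      s <- Biostrings::subseq(b$genome[[as.character(seqnames(gr))]],
                              start(gr), end(gr))
      if (as.vector(strand(gr)) == "-")
        s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1)))
  mat <- as.matrix(seqs)
  for (i in seq_len(nrow(mat))) {
    p <- m$probs[cbind(seq_len(ncol(mat)), match(mat[i, ], c("A", "C", "G", "T")))]
    expect_true(all(p > 0))
  }
  # planted instances look like the motif: mean per-position log-probability
  # beats the background composition decisively
  lp_motif <- mean(log(m$probs[cbind(rep(seq_len(ncol(mat)), nrow(mat)),
                                     match(t(mat), c("A", "C", "G", "T")))]))
  expect_gt(lp_motif, log(0.25) + 0.5)
})

test_that("truth tables honor the spec fractions and stay internally consistent", {
  b <- generate_bundle(small_spec(seed = 12))
  truth <- b$truth$sites
  expect_equal(length(truth), 120L)
  pct <- 100 * sum(!is.na(truth$cluster_id)) / length(truth)
  expect_equal(pct, 50, tolerance = 0.05)
  # cluster table and site table agree
  for (k in seq_len(nrow(b$truth$clusters))) {
    row <- b$truth$clusters[k, ]
    members <- truth[!is.na(truth$cluster_id) & truth$cluster_id == row$cluster_id]
    expect_equal(length(members), row$n_sites)
    expect_equal(min(start(members)), row$start)
    expect_equal(max(end(members)), row$end)
  }
  # repeats never cover planted sites
  expect_false(any(overlapsAny(truth, b$repeats, ignore.strand = TRUE)))
  # isolation: distinct elements farther than the clustering window apart
  cl <- cluster_sites(truth, window = 500)
  expect_true(same_partition(cl$membership, truth$cluster_id))
})

test_that("fully clustered, fully promoter-biased specs place every cluster in a promoter", {
  b <- generate_bundle(small_spec(seed = 13, n_planted = 60,
                                  cluster_fraction = 1,
                                  promoter_fraction = 1))
  expect_true(all(b$truth$clusters$in_promoter))
  expect_true(all(!is.na(b$truth$sites$cluster_id)))
  prom_bd <- classify_locations(
    GRanges(b$truth$clusters$chrom,
            IRanges(b$truth$clusters$start, b$truth$clusters$end)),
    b$genes, promoter_bp = b$spec$promoter_bp)
  expect_true(all(prom_bd$category == "TSSup"))
  expect_setequal(b$truth$target_genes,
                  unique(stats::na.omit(b$truth$clusters$gene_id)))
})

test_that("a zero-plant genome yields the analytic background hit count", {
  # 2-bp motif so P(LR >= c) can be enumerated over the 16 dinucleotides
  m <- motif_matrix(rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.7)),
                    name = "dinuc")
  spec <- synthetic_spec(genome_length = c(chr1 = 2e5), n_genes = 10,
                         n_planted = 0, motif = m, repeat_fraction = 0,
                         conservation_boost = 0, seed = 14)
  b <- generate_bundle(spec)
  bg <- train_background(b$genome, order = 0)
  q <- spec$background_probs
  eps <- 1e-4
  pm <- (m$probs + eps) / (1 + 4 * eps)
  dinucs <- expand.grid(a = 1:4, b = 1:4)
  lr_true <- pm[1, dinucs$a] * pm[2, dinucs$b] / (q[dinucs$a] * q[dinucs$b])
  p_true <- q[dinucs$a] * q[dinucs$b]
  # pick a cutoff well separated from every enumerated LR value
  cut <- exp(mean(log(sort(unique(lr_true), decreasing = TRUE)[2:3])))
  p_hit <- sum(p_true[lr_true >= cut])
  nwin <- 2 * (2e5 - 1)
  sites <- scan_motif(b$genome, m, bg, lr_cutoff = cut)
  expected <- nwin * p_hit
  sd <- sqrt(nwin * p_hit * (1 - p_hit))
  expect_gt(length(sites), expected - 6 * sd)
  expect_lt(length(sites), expected + 6 * sd)
})

test_that("pct_clustered recovered by the pipeline tracks the planted fraction", {
  est_for <- function(cf) {
    b <- generate_bundle(small_spec(seed = 15, cluster_fraction = cf))
    bg <- train_background(b$genome, order = 2)
    res <- cutoff_for_count(b$genome, b$spec$motif, bg,
                            target_count = length(b$truth$sites),
                            min_cutoff = 1)
    clustering_summary(res$sites, cluster_sites(res$sites))$pct_clustered
  }
  lo <- est_for(0.2); hi <- est_for(0.8)
  expect_gt(hi, lo + 30)   # 20% vs 80% planted must be clearly separated
})

test_that("recovery metrics respond to planted signal and vanish at the null", {
  b <- generate_bundle(small_spec(seed = 16))
  bg <- train_background(b$genome, order = 2)
  res <- cutoff_for_count(b$genome, b$spec$motif, bg,
                          target_count = length(b$truth$sites),
                          min_cutoff = 1)
  cl <- cluster_sites(res$sites)
  rep <- recovery_report(b, res$sites, cl, n_random = 3000, seed = 2)
  expect_gte(rep$site_recall, 0.9)
  expect_gte(rep$site_precision, 0.9)
  expect_gt(rep$cluster_recall, 0.9)
  expect_gt(rep$conservation_contrast, 0)
  expect_gt(rep$dhs_contrast, 0)
  expect_gt(rep$promoter_fold_planted, 1.5)
  # unbiased placement: planted promoter fold compatible with 1
  b0 <- generate_bundle(small_spec(seed = 17, promoter_fraction = 0))
  bg0 <- train_background(b0$genome, order = 2)
  r0 <- cutoff_for_count(b0$genome, b0$spec$motif, bg0,
                         target_count = length(b0$truth$sites),
                         min_cutoff = 1)
  rep0 <- recovery_report(b0, r0$sites, cluster_sites(r0$sites),
                          n_random = 3000, seed = 2)
  expect_lt(abs(rep0$promoter_fold_planted - 1), 0.75)
})

test_that("bundles round-trip through the on-disk formats", {
  b <- generate_bundle(synthetic_spec(genome_length = c(chr1 = 5e4),
                                      n_genes = 6, n_planted = 20,
                                      seed = 18))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(b$genome))
  genes <- read_genes(file.path(dir, "genes.tsv"))
  expect_identical(genes$gene_id, b$genes$gene_id)
  expect_identical(start(genes), start(b$genes))
  cons <- read_bedgraph(file.path(dir, "conservation.bedGraph"),
                        seqlengths = c(chr1 = 5e4))
  expect_equal(cons$values$chr1, b$conservation$values$chr1,
               tolerance = 1e-6)
  sites <- read.delim(file.path(dir, "planted_sites.tsv"))
  expect_equal(nrow(sites), 20L)
  expect_identical(sites$start + 1L, start(b$truth$sites))
})
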