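test_that("location classification follows the definitions and precedence", {
  genes <- toy_genes()
  # gA: + strand, TSS at 5001 (1-based); 200 bp upstream => promoter
  up <- GRanges("chr1", IRanges(4801, 4821))
  expect_equal(classify_locations(up, genes)$category, "TSSup")
  # minus-strand gene gB: TSS at 30000, upstream means higher coordinates
  up_minus <- GRanges("chr1", IRanges(30200, 30220))
  expect_equal(classify_locations(up_minus, genes)$category, "TSSup")
  mid <- GRanges("chr1", IRanges(10000, 10020))   # deep inside gA
  expect_equal(classify_locations(mid, genes)$category, "intragenic")
  far <- GRanges("chr1", IRanges(70000, 70020))
  expect_equal(classify_locations(far, genes)$category, "intergenic")
  # downstream of gA's TES (+ strand: after txEnd)
  down <- GRanges("chr1", IRanges(15200, 15220))
  expect_equal(classify_locations(down, genes)$category, "TESdown")
  expect_warning(
    bd <- classify_locations(GRanges("chrX", IRanges(1, 10)), genes),
    "absent")
  expect_equal(bd$category, "intergenic")
})

test_that("random sites classify identically to a per-item brute-force oracle", {
  genes <- toy_genes()
  gchr <- as.character(seqnames(genes))
  gstr <- as.vector(strand(genes))
  gs <- start(genes); ge <- end(genes)
  oracle_one <- function(chr, s, e, pb, db) {
    in_prom <- in_down <- in_body <- FALSE
    for (g in seq_along(gchr)) {
      if (gchr[g] != chr) next
      if (gstr[g] == "+") {
        ps <- gs[g] - pb; pe <- gs[g] - 1
        ds <- ge[g] + 1; de <- ge[g] + db
      } else {
        ps <- ge[g] + 1; pe <- ge[g] + pb
        ds <- gs[g] - db; de <- gs[g] - 1
      }
      if (s <= pe && e >= ps) in_prom <- TRUE
      if (s <= de && e >= ds) in_down <- TRUE
      if (s <= ge[g] && e >= gs[g]) in_body <- TRUE
    }
    if (in_prom) "TSSup" else if (in_down) "TESdown"
    else if (in_body) "intragenic" else "intergenic"
  }
  set.seed(600)
  n <- 50
  chr <- sample(c("chr1", "chr2"), n, TRUE)
  st <- sample(1:60000, n)
  items <- GRanges(chr, IRanges(st, width = 21))
  for (pb in c(500, 1000, 2000)) {
    bd <- classify_locations(items, genes, promoter_bp = pb)
    want <- vapply(seq_len(n), function(i)
      oracle_one(chr[i], st[i], st[i] + 20L, pb, 1000), character(1))
    expect_equal(bd$category, want)
    expect_equal(sum(bd$counts), n)
  }
})

test_that("widening the promoter never loses TSSup items", {
  genes <- toy_genes()
  set.seed(610)
  items <- GRanges("chr1", IRanges(sample(1:60000, 300), width = 21))
  cnt <- vapply(c(500, 1000, 1500, 2000), function(pb)
    classify_locations(items, genes, promoter_bp = pb)$counts[["TSSup"]],
    numeric(1))
  expect_true(all(diff(cnt) >= 0))
})

test_that("the pooled two-proportion Z-test matches hand evaluation", {
  z <- two_proportion_ztest(30, 100, 10, 100)
  expect_equal(z$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(z$z, 3.5355, tolerance = 1e-4)
  same <- two_proportion_ztest(25, 100, 25, 100)
  expect_equal(same$z, 0)
  expect_equal(same$p_one_sided, 0.5)
  expect_error(two_proportion_ztest(1, 0, 1, 10), ">= 1")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "<=")
  # cross-check against the chi-square relation of prop.test
  pt <- suppressWarnings(prop.test(c(30, 10), c(100, 100), correct = FALSE))
  expect_equal(z$z^2, unname(pt$statistic), tolerance = 1e-9)
})

test_that("Z-test p-value decreases as the proportion gap grows", {
  ps <- vapply(c(12, 20, 30, 45), function(x)
    two_proportion_ztest(x, 100, 10, 100)$p_one_sided, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("fold enrichment and implied FDR behave at the null and reciprocally", {
  eq <- enrichment_from_counts(10, 100, 10, 100)
  expect_equal(eq$fold, 1)
  expect_equal(eq$fdr_pct, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_one_sided, 0.5)
  a <- enrichment_from_counts(30, 100, 10, 200)
  b <- enrichment_from_counts(10, 200, 30, 100)
  expect_equal(a$fold * b$fold, 1, tolerance = 1e-12)
  zero <- enrichment_from_counts(5, 100, 0, 100)
  expect_equal(zero$fold, Inf)
  expect_equal(zero$fdr_pct, 0)
})

test_that("relative enrichment r = n1 L2 / (n2 L1) and the rate identity", {
  expect_equal(relative_enrichment(10, 1000, 5, 1000)$r, 2)
  expect_equal(relative_enrichment(10, 1000, 5, 1000)$fdr_pct, 50)
  for (seed in 1:10) {
    set.seed(700 + seed)
    n1 <- sample(1:500, 1); n2 <- sample(1:500, 1)
    L1 <- runif(1, 100, 1e5); L2 <- runif(1, 100, 1e5)
    re <- relative_enrichment(n1, L1, n2, L2)
    expect_equal(re$r, (n1 / L1) / (n2 / L2), tolerance = 1e-12)
  }
  expect_equal(relative_enrichment(5, 100, 0, 100)$r, Inf)
  expect_error(relative_enrichment(5, 0, 5, 100), "positive")
})

test_that("matched controls preserve the TSS-distance multiset", {
  # forced placement with exactly two genes: the control must sit at the
  # same strand-oriented TSS distance of the other gene
  two <- gene_models(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
    txStart = c(8000, 30000), txEnd = c(12000, 42000)))
  sl2 <- c(chr1 = 50000L)
  pos <- GRanges("chr1", IRanges(7500, 7520))  # d = -501 from g1's TSS
  ctrl <- matched_control_regions(pos, two, sl2, seed = 1)
  expect_equal(length(ctrl), 1L)
  # g2 is minus strand, TSS base 42000: same d means end = 42000 + 501
  expect_equal(start(ctrl), 42481)
  expect_equal(end(ctrl), 42501)
  expect_equal(ctrl$tss_distance, -501)

  genes <- toy_genes()
  sl <- c(chr1 = 60000L, chr2 = 50000L)
  set.seed(2)
  many <- GRanges("chr1", IRanges(sample(1:55000, 100), width = 21))
  c1 <- matched_control_regions(many, genes, sl, seed = 42)
  c2 <- matched_control_regions(many, genes, sl, seed = 42)
  expect_identical(start(c1), start(c2))
  # distance multiset equality by construction
  gstr <- as.vector(strand(genes)); tss <- tss_positions(genes)
  dist_of <- function(gr) {
    vapply(seq_along(gr), function(i) {
      same <- which(as.character(seqnames(genes)) ==
                    as.character(seqnames(gr))[i])
      d <- ifelse(gstr[same] == "+", start(gr)[i] - tss[same],
                  tss[same] - end(gr)[i])
      d[which.min(abs(d))]
    }, numeric(1))
  }
  expect_setequal(c1$tss_distance, dist_of(many)[c1$source])
  expect_false(any(overlapsAny(c1, many, ignore.strand = TRUE)))
})

test_that("target genes require a promoter cluster unless relaxed", {
  genes <- toy_genes()
  # cluster inside gA's promoter only
  sites <- make_sites(c(4500, 4700, 25000), width = 21, chrom = "chr1")
  cl <- cluster_sites(sites, window = 500)
  tg <- annotate_target_genes(sites, genes, clusters = cl)
  expect_equal(tg$gene_ids, "gA")
  expect_equal(tg$n_genes, 5L)
  expect_equal(tg$pct_genes, 20)
  relaxed <- annotate_target_genes(sites, genes, require_cluster = FALSE)
  expect_true(all(tg$gene_ids %in% relaxed$gene_ids))
  # site at 25000 is intragenic in gB, not promoter; relaxed adds nothing here
  expect_equal(relaxed$gene_ids, "gA")
})
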