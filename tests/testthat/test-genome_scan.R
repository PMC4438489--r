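test_that("order-0 training on 'AAAA' is strand symmetric", {
  bg <- train_background(c(chr1 = "AAAA"), order = 0)
  expect_equal(bg$marginal[1], bg$marginal[4])  # p(A) == p(T)
  expect_equal(bg$marginal[2], bg$marginal[3])  # p(C) == p(G)
  # counts: 4 A forward + 4 T reverse, +1 pseudocount each cell
  expect_equal(bg$trans[1, ], c(A = 5, C = 1, G = 1, T = 5) / 12)
})

test_that("order-0 training on long uniform sequence approaches 1/4", {
  bg <- train_background(c(chr1 = rand_dna(40000, seed = 11)), order = 0)
  expect_equal(unname(bg$trans[1, ]), rep(0.25, 4), tolerance = 0.02)
  expect_equal(unname(bg$marginal), rep(0.25, 4), tolerance = 0.02)
})

test_that("order-1 transition table equals a hand-tallied count oracle", {
  set.seed(21)
  s <- rand_dna(60)
  bg <- train_background(c(chr1 = s), order = 1)
  # independent tally over both strands
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T")))
  for (str in c(s, rc)) {
    v <- strsplit(str, "")[[1]]
    for (i in 2:length(v)) counts[v[i - 1], v[i]] <- counts[v[i - 1], v[i]] + 1
  }
  expect_equal(unname(bg$trans), unname(counts / rowSums(counts)),
               tolerance = 1e-12)
})

test_that("training skips masked intervals and N runs", {
  bg_all <- train_background(c(chr1 = "AAAAAAAAACGT"), order = 0)
  bg_m <- train_background(c(chr1 = "AAAAAAAAACGT"), order = 0,
                           mask = GRanges("chr1", IRanges(1, 8)))
  # masked training saw only ACGT (4 bases, both strands): uniform
  expect_equal(unname(bg_m$trans[1, ]), rep((2 + 1) / 12, 4))
  expect_false(isTRUE(all.equal(bg_all$trans, bg_m$trans)))
  bg_n <- train_background(c(chr1 = "NNNNNNNNACGT"), order = 0)
  expect_equal(unname(bg_n$trans[1, ]), unname(bg_m$trans[1, ]))
  expect_error(train_background(c(chr1 = "AC"), order = 3), "shorter")
})

test_that("a single-base motif against a uniform background gives LR ~ 4", {
  m <- motif_matrix(matrix(c(1, 0, 0, 0), 1, 4))
  bg <- uniform_background(0)
  s <- scan_motif(c(chr1 = "A"), m, bg, lr_cutoff = 1, strands = "forward")
  eps <- 1e-4
  expect_equal(s$lr, ((1 + eps) / (1 + 4 * eps)) / 0.25, tolerance = 1e-12)
  expect_equal(s$lr, 4, tolerance = 1e-3)
})

test_that("a vacuous cutoff reports one site per scannable window per strand", {
  m <- random_motif(3, seed = 5)
  bg <- uniform_background(0)
  n <- 30
  s <- scan_motif(c(chr1 = rand_dna(n, seed = 6)), m, bg, lr_cutoff = 1e-12)
  expect_equal(length(s), 2 * (n - 3 + 1))
  fw <- scan_motif(c(chr1 = rand_dna(n, seed = 6)), m, bg, lr_cutoff = 1e-12,
                   strands = "forward")
  expect_equal(length(fw), n - 3 + 1)
})

test_that("scanner matches the brute-force likelihood-ratio oracle", {
  for (case in 1:6) {
    set.seed(300 + case)
    ord <- (case - 1) %% 3
    L <- sample(2:4, 1)
    seq_str <- rand_dna(80)
    if (case %% 2 == 0)  # inject an N run
      substr(seq_str, 31, 33) <- "NNN"
    m <- random_motif(L)
    bg <- train_background(setNames(seq_str, "c1"), order = ord)
    got <- scan_motif(setNames(seq_str, "c1"), m, bg, lr_cutoff = 1e-12)
    want <- oracle_scan(seq_str, m, bg)
    expect_equal(length(got), nrow(want))
    key_got <- paste(start(got), as.vector(strand(got)))
    key_want <- paste(want$start, want$strand)
    expect_setequal(key_got, key_want)
    ord_w <- match(key_got, key_want)
    expect_equal(got$lr, want$lr[ord_w], tolerance = 1e-9)
  }
})

test_that("double-strand scan equals the coordinate-mapped scan of the reverse complement", {
  set.seed(33)
  s <- rand_dna(60)
  m <- random_motif(4)
  bg <- train_background(setNames(s, "c"), order = 1)
  L <- 4; n <- nchar(s)
  both <- scan_motif(setNames(s, "c"), m, bg, lr_cutoff = 1e-12)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  both_rc <- scan_motif(setNames(rc, "c"), m, bg, lr_cutoff = 1e-12)
  # map coordinates of the revcomp scan back and compare LR multisets per locus
  mapped_start <- n - end(both_rc) + 1
  expect_setequal(
    paste(start(both), round(log(both$lr), 9)),
    paste(mapped_start, round(log(both_rc$lr), 9)))
})

test_that("raising the cutoff never increases the site count", {
  m <- example_motif()
  g <- c(chr1 = rand_dna(20000, seed = 77))
  bg <- train_background(g, order = 2)
  cuts <- c(1, 10, 100, 1000)
  ns <- vapply(cuts, function(cc)
    length(scan_motif(g, m, bg, lr_cutoff = cc)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("windows overlapping N or the scan mask are skipped", {
  m <- random_motif(3, seed = 9)
  bg <- uniform_background(0)
  s <- scan_motif(c(chr1 = "ACGTNACGT"), m, bg, lr_cutoff = 1e-12,
                  strands = "forward")
  expect_equal(sort(start(s)), c(1, 2, 6, 7))
  masked <- scan_motif(c(chr1 = "ACGTAACGT"), m, bg, lr_cutoff = 1e-12,
                       strands = "forward",
                       mask = GRanges("chr1", IRanges(5, 5)),
                       mask_scan = TRUE)
  expect_equal(sort(start(masked)), c(1, 2, 6, 7))
})

test_that("deduplication keeps the stronger of overlapping sites", {
  two <- make_sites(c(100, 100), width = 10, lr = c(2000, 1500),
                    strand = c("+", "-"))
  d <- deduplicate_sites(two)
  expect_equal(length(d), 1L)
  expect_equal(d$lr, 2000)
  apart <- make_sites(c(1, 50, 100), width = 10, lr = c(5, 1, 3))
  expect_equal(length(deduplicate_sites(apart)), 3L)
})

test_that("deduplication matches the O(n^2) greedy oracle and leaves no overlaps", {
  for (seed in 1:5) {
    set.seed(400 + seed)
    n <- 20
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    st <- sample(1:60, n, replace = TRUE)
    gr <- GRanges(chrom, IRanges(st, width = 10),
                  strand = sample(c("+", "-"), n, TRUE),
                  lr = round(runif(n, 1, 50), 1))
    d <- deduplicate_sites(gr)
    kept <- oracle_dedup(chrom, st, st + 9L, as.vector(strand(gr)), gr$lr)
    expect_equal(length(d), length(kept))
    expect_setequal(paste(as.character(seqnames(d)), start(d), d$lr),
                    paste(chrom[kept], st[kept], gr$lr[kept]))
    ov <- findOverlaps(d, d, ignore.strand = TRUE)
    expect_true(all(queryHits(ov) == subjectHits(ov)))
  }
})

test_that("cutoff_for_count matches counts exactly and flags shortfalls", {
  m <- example_motif()
  g <- c(chr1 = rand_dna(60000, seed = 55))
  bg <- train_background(g, order = 1)
  all_dd <- deduplicate_sites(scan_motif(g, m, bg, lr_cutoff = 1))
  # boundary: target equal to everything available at the minimum cutoff
  res <- cutoff_for_count(g, m, bg, target_count = length(all_dd),
                          min_cutoff = 1)
  expect_false(res$shortfall)
  expect_equal(length(res$sites), length(all_dd))
  # strict truncation: every excluded site is no stronger than any retained
  res100 <- cutoff_for_count(g, m, bg, target_count = 100, min_cutoff = 1)
  expect_equal(length(res100$sites), 100L)
  expect_equal(res100$cutoff, min(res100$sites$lr))
  excluded <- all_dd[!paste(start(all_dd), strand(all_dd)) %in%
                       paste(start(res100$sites), strand(res100$sites))]
  expect_true(all(excluded$lr <= min(res100$sites$lr)))
  # shortfall: unreachable target
  expect_warning(
    short <- cutoff_for_count(g, m, bg,
                              target_count = length(all_dd) + 1000,
                              min_cutoff = 1),
    "shortfall|returning all|only")
  expect_true(short$shortfall)
  expect_equal(length(short$sites), length(all_dd))
  expect_equal(short$cutoff, 1)
})
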