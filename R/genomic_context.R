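#' Build gene models from a transcript table
#'
#' Accepts a data frame with columns `gene_id`, `chrom`, `strand`,
#' `txStart`, `txEnd` (0-based half-open transcript coordinates, refFlat
#' style) or an already-built `GRanges` with a `gene_id` metadata column.
#' The transcription start site (TSS) is `txStart` for `+` genes and
#' `txEnd` for `-` genes; the transcription end site (TES) is the other
#' end.  Several transcripts may share one `gene_id`; target-gene counting
#' collapses to unique ids.
#'
#' @param x data frame or `GRanges`.
#' @param seqlengths optional named chromosome lengths.
#' @return a `GRanges` of gene bodies with `gene_id`.
#' @export
gene_models <- function(x, seqlengths = NULL) {
  if (is(x, "GRanges")) {
    if (is.null(x$gene_id)) stop("gene GRanges must carry gene_id")
    gr <- x
  } else {
    x <- as.data.frame(x)
    need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
    if (!all(need %in% names(x)))
      stop("gene table needs columns: ", paste(need, collapse = ", "))
    if (any(x$txEnd <= x$txStart))
      stop("txEnd must exceed txStart (0-based half-open)")
    gr <- GRanges(x$chrom,
                  IRanges(x$txStart + 1L, x$txEnd),
                  strand = x$strand,
                  gene_id = as.character(x$gene_id))
  }
  if (!all(as.vector(strand(gr)) %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[seqlevels(gr)]
  gr
}

#' Read a tab-delimited gene annotation
#'
#' Expects a header with columns `gene_id`, `chrom`, `strand`, `txStart`,
#' `txEnd` (0-based half-open).
#'
#' @param path file path.
#' @return a `GRanges` of gene models.
#' @export
read_genes <- function(path) {
  gene_models(read.delim(path, stringsAsFactors = FALSE))
}

#' TSS positions of gene models (1-based base position)
#' @param genes gene `GRanges` from [gene_models()].
#' @return integer vector, parallel to `genes`.
#' @export
tss_positions <- function(genes) {
  ifelse(as.vector(strand(genes)) == "+", start(genes), end(genes))
}

.promoter_windows <- function(genes, promoter_bp) {
  p <- suppressWarnings(GenomicRanges::promoters(genes,
                                                 upstream = promoter_bp,
                                                 downstream = 0L))
  start(p) <- pmax(start(p), 1L)
  p[width(p) > 0L]
}

.downstream_windows <- function(genes, downstream_bp) {
  d <- suppressWarnings(GenomicRanges::flank(genes, width = downstream_bp,
                                             start = FALSE))
  start(d) <- pmax(start(d), 1L)
  d[width(d) > 0L]
}

#' Classify intervals by position relative to genes
#'
#' Each item is assigned exactly one category: `TSSup` if it overlaps (by at
#' least 1 bp) the `promoter_bp` window immediately upstream of any gene's
#' TSS (strand-aware); otherwise `TESdown` if it overlaps the
#' `downstream_bp` window immediately downstream of any TES; otherwise
#' `intragenic` if it overlaps a gene body; otherwise `intergenic`.  The
#' precedence TSSup > TESdown > intragenic resolves overlapping windows of
#' different genes.  Items on chromosomes absent from the annotation are
#' classified intergenic with a warning.
#'
#' @param items `GRanges` of sites or cluster spans.
#' @param genes gene `GRanges` from [gene_models()].
#' @param promoter_bp upstream promoter window (default 1000, the usual
#'   TSSup1k definition).
#' @param downstream_bp downstream window after the TES (default 1000).
#' @return An object of class `location_breakdown`: list with `counts`
#'   (named: TSSup, TESdown, intragenic, intergenic), `total`, per-item
#'   `category`, and the window sizes.
#' @export
classify_locations <- function(items, genes, promoter_bp = 1000,
                               downstream_bp = 1000) {
  if (length(genes) == 0L) stop("gene annotation is empty")
  unknown <- !(as.character(seqnames(items)) %in%
               as.character(unique(seqnames(genes))))
  if (any(unknown))
    warning(sum(unknown), " item(s) on chromosomes absent from the ",
            "annotation; classified intergenic")
  prom <- .promoter_windows(genes, promoter_bp)
  down <- .downstream_windows(genes, downstream_bp)
  cat_ <- rep("intergenic", length(items))
  # suppressed: disjoint-seqlevel merge warnings duplicate the explicit
  # unknown-chromosome warning above
  cat_[suppressWarnings(overlapsAny(items, genes, ignore.strand = TRUE))] <-
    "intragenic"
  cat_[suppressWarnings(overlapsAny(items, down, ignore.strand = TRUE))] <-
    "TESdown"
  cat_[suppressWarnings(overlapsAny(items, prom, ignore.strand = TRUE))] <-
    "TSSup"
  lv <- c("TSSup", "TESdown", "intragenic", "intergenic")
  counts <- table(factor(cat_, levels = lv))
  structure(list(counts = setNames(as.integer(counts), lv),
                 total = length(items),
                 category = cat_,
                 promoter_bp = promoter_bp,
                 downstream_bp = downstream_bp),
            class = "location_breakdown")
}

#' @export
print.location_breakdown <- function(x, ...) {
  pct <- 100 * x$counts / max(x$total, 1L)
  for (nm in names(x$counts))
    cat(sprintf("  %-11s %8d (%6.2f%%)\n", nm, x$counts[[nm]], pct[[nm]]))
  invisible(x)
}

#' Two-proportion Z-test (pooled variance, one-sided)
#'
#' `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2)/(n1 + n2)`; the one-sided p-value is the standard normal
#' upper tail (alternative: proportion 1 exceeds proportion 2).
#'
#' @param x1,n1 successes and trials in the first group.
#' @param x2,n2 successes and trials in the second group.
#' @return list with `z` and `p_one_sided`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("need 0 <= x <= n in both groups")
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (x1 / n1 - x2 / n2) / se
  list(z = z, p_one_sided = pnorm(z, lower.tail = FALSE))
}

#' Enrichment of a test set over a control set from raw counts
#'
#' Computes the fold enrichment `fold = prop_test / prop_ctrl`, the implied
#' false discovery rate `FDR = 100 / fold` percent (of every `fold` test
#' items in the category, one is expected by chance), and the pooled
#' one-sided two-proportion Z-test.  When the control proportion is zero the
#' fold is infinite and the FDR 0.
#'
#' @param x1,n1 category count and total in the test set.
#' @param x2,n2 category count and total in the control set.
#' @return An object of class `enrichment_result`: list with `prop_test`,
#'   `prop_ctrl`, `fold`, `fdr_pct`, `z`, `p_one_sided` and the inputs.
#' @export
enrichment_from_counts <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("both totals must be >= 1")
  p1 <- x1 / n1
  p2 <- x2 / n2
  fold <- if (p2 == 0) Inf else p1 / p2
  fdr <- if (is.finite(fold)) 100 / fold else 0
  zt <- two_proportion_ztest(x1, n1, x2, n2)
  structure(list(prop_test = p1, prop_ctrl = p2, fold = fold,
                 fdr_pct = fdr, z = zt$z, p_one_sided = zt$p_one_sided,
                 x1 = x1, n1 = n1, x2 = x2, n2 = n2),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("test %.2f%% vs control %.2f%%: fold %.2f (FDR %.1f%%), Z=%.2f, p=%.3g\n",
              100 * x$prop_test, 100 * x$prop_ctrl, x$fold, x$fdr_pct,
              x$z, x$p_one_sided))
  invisible(x)
}

#' Promoter (or other category) enrichment between two location breakdowns
#'
#' @param test,ctrl `location_breakdown` objects (see
#'   [classify_locations()]).
#' @param category one of `"TSSup"`, `"TESdown"`, `"intragenic"`,
#'   `"intergenic"` (default `"TSSup"`).
#' @return an `enrichment_result`.
#' @export
promoter_enrichment <- function(test, ctrl, category = "TSSup") {
  stopifnot(inherits(test, "location_breakdown"),
            inherits(ctrl, "location_breakdown"))
  if (!category %in% names(test$counts)) stop("unknown category ", category)
  enrichment_from_counts(test$counts[[category]], test$total,
                         ctrl$counts[[category]], ctrl$total)
}

#' Relative enrichment of motif occurrence rates
#'
#' The occurrence rate of a motif in a region set is the number of motif
#' sites per non-repeat base pair.  The relative enrichment of a test set
#' over a matched control set is the ratio of the two rates,
#' `r = (n1 * L2) / (n2 * L1)`, and implies a site-level FDR of `100 / r`
#' percent: among every `r` motif sites in the test regions, one is expected
#' by chance.
#'
#' @param n1 site count in the test regions.
#' @param L1 non-repeat length (bp) of the test regions.
#' @param n2 site count in the matched control regions.
#' @param L2 non-repeat length (bp) of the control regions.
#' @return list with `r`, `fdr_pct`, `rate_test`, `rate_ctrl`.
#' @export
relative_enrichment <- function(n1, L1, n2, L2) {
  if (L1 <= 0 || L2 <= 0) stop("region lengths must be positive")
  if (n1 < 0 || n2 < 0) stop("site counts must be non-negative")
  r <- if (n2 == 0) Inf else (n1 * L2) / (n2 * L1)
  structure(list(r = r,
                 fdr_pct = if (is.finite(r)) 100 / r else 0,
                 rate_test = n1 / L1,
                 rate_ctrl = n2 / L2),
            class = "relative_enrichment")
}

#' @export
print.relative_enrichment <- function(x, ...) {
  cat(sprintf("relative enrichment r = %.3f (implied FDR %.1f%%)\n",
              x$r, x$fdr_pct))
  invisible(x)
}

#' Sample control regions matched on distance to the nearest TSS
#'
#' For each positive region the signed, strand-oriented distance from its
#' nearest TSS is recorded; one control region of the same width is placed
#' at the same signed distance from a uniformly chosen *different* TSS.  A
#' placement is rejected and resampled (up to `max_tries` times) if it
#' overlaps a positive region, runs off the chromosome, or lands in the
#' mask.  By construction the multiset of control TSS-distances equals that
#' of the positives (minus any placement failures, which are reported in a
#' warning).
#'
#' @param positives `GRanges` of positive regions.
#' @param genes gene `GRanges` from [gene_models()].
#' @param seqlengths named chromosome lengths.
#' @param mask optional `GRanges` of excluded intervals.
#' @param seed optional integer seed for reproducibility.
#' @param max_tries placement attempts per positive (default 100).
#' @return `GRanges` of control regions with metadata `tss_distance` and
#'   `source` (index of the matched positive).
#' @export
matched_control_regions <- function(positives, genes, seqlengths,
                                    mask = NULL, seed = NULL,
                                    max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (length(genes) < 2L)
    stop("need at least two genes to place matched controls")
  tss <- tss_positions(genes)
  gchr <- as.character(seqnames(genes))
  gstr <- as.vector(strand(genes))
  pchr <- as.character(seqnames(positives))
  # plain interval vectors per chromosome for the rejection loop
  iv_of <- function(gr) {
    ch <- as.character(seqnames(gr))
    lapply(split(seq_along(gr), ch), function(i)
      list(s = start(gr)[i], e = end(gr)[i]))
  }
  pos_iv <- iv_of(positives)
  mask_iv <- if (!is.null(mask)) iv_of(mask)
  hits_iv <- function(iv, ch, s, e) {
    v <- iv[[ch]]
    !is.null(v) && any(v$s <= e & v$e >= s)
  }
  out_chr <- character(0); out_start <- numeric(0); out_w <- integer(0)
  out_d <- numeric(0); out_src <- integer(0)
  failed <- 0L
  for (i in seq_along(positives)) {
    same <- which(gchr == pchr[i])
    if (length(same) == 0L) { failed <- failed + 1L; next }
    # signed distance along the gene's strand from the nearest TSS
    d_all <- ifelse(gstr[same] == "+",
                    start(positives)[i] - tss[same],
                    tss[same] - end(positives)[i])
    j <- same[which.min(abs(d_all))]
    d <- d_all[match(j, same)]
    w <- width(positives)[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      jj <- sample(seq_along(genes)[-j], 1L)
      if (gstr[jj] == "+") {
        s <- tss[jj] + d
      } else {
        s <- tss[jj] - d - w + 1
      }
      e <- s + w - 1
      chr <- gchr[jj]
      if (s < 1 || is.na(seqlengths[chr]) || e > seqlengths[chr]) next
      if (hits_iv(pos_iv, chr, s, e)) next
      if (!is.null(mask) && hits_iv(mask_iv, chr, s, e)) next
      out_chr <- c(out_chr, chr); out_start <- c(out_start, s)
      out_w <- c(out_w, w); out_d <- c(out_d, d); out_src <- c(out_src, i)
      ok <- TRUE
      break
    }
    if (!ok) failed <- failed + 1L
  }
  if (failed > 0L)
    warning(failed, " positive(s) could not be matched after ",
            max_tries, " tries")
  gr <- GRanges(out_chr, IRanges(out_start, width = out_w),
                tss_distance = out_d, source = out_src)
  GenomeInfoDb::seqlengths(gr) <-
    seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Annotate target genes of a motif
#'
#' A gene is a potential target when its `promoter_bp` upstream window
#' contains at least one motif site cluster (default) or, with
#' `require_cluster = FALSE`, at least one motif site.  Genes are counted by
#' unique `gene_id` (a hit near any transcript of the gene counts).
#'
#' @param sites `GRanges` of motif sites.
#' @param genes gene `GRanges` from [gene_models()].
#' @param promoter_bp upstream window (default 1000).
#' @param clusters optional `site_clusters` object (required when
#'   `require_cluster = TRUE`).
#' @param require_cluster require a whole cluster in the promoter (default
#'   `TRUE`).
#' @return list with `gene_ids` (sorted unique targets), `n_targets`,
#'   `n_genes` (unique ids in the annotation) and `pct_genes`.
#' @export
annotate_target_genes <- function(sites, genes, promoter_bp = 1000,
                                  clusters = NULL, require_cluster = TRUE) {
  items <- if (require_cluster) {
    if (is.null(clusters)) stop("clusters required when require_cluster=TRUE")
    clusters$clusters
  } else {
    sites
  }
  prom <- .promoter_windows(genes, promoter_bp)
  hit <- overlapsAny(prom, items, ignore.strand = TRUE)
  ids <- sort(unique(genes$gene_id[hit]))
  n_genes <- length(unique(genes$gene_id))
  list(gene_ids = ids,
       n_targets = length(ids),
       n_genes = n_genes,
       pct_genes = round(100 * length(ids) / n_genes, 2))
}
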