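#' Specification of a synthetic genome bundle
#'
#' Collects every knob of the synthetic-data generator with defaults chosen
#' to emulate, at desk scale, the inputs the characterization pipeline
#' expects: a 5-Mb genome with 2,000 planted motif instances, half of them
#' arranged in clusters of 2-5 sites, half of the clusters placed inside
#' promoter windows; a conservation track whose signal is elevated over
#' planted sites and decays over the flanks; and Poisson DNase-seq read
#' counts with a rate multiplier over planted sites, for a few cell lines
#' with replicates.
#'
#' @param genome_length named numeric vector of chromosome lengths (default
#'   `c(chr1 = 5e6)`).
#' @param background_probs nucleotide probabilities (A, C, G, T) of the
#'   background sequence (default slightly AT-rich, 0.3/0.2/0.2/0.3).
#' @param n_genes number of genes (default 400; TSSs end up roughly 12.5 kb
#'   apart, a gene density that keeps promoter statistics stable at this
#'   genome size).
#' @param gene_length_range gene body length range in bp (default
#'   2000-10000).
#' @param promoter_bp promoter window upstream of the TSS (default 1000).
#' @param motif a `motif_matrix` (default [example_motif()]).
#' @param n_planted number of planted motif instances (default 2000).
#' @param cluster_fraction fraction of planted sites that belong to planted
#'   clusters (default 0.5).
#' @param cluster_size_range cluster sizes, inclusive (default 2-5).
#' @param planting_window maximum edge-to-edge gap between sites of one
#'   planted cluster (default 200 bp; gaps are drawn from 20 bp up to this).
#' @param promoter_fraction fraction of planted clusters placed wholly
#'   inside a promoter window (default 0.5).
#' @param isolation_bp minimum distance between distinct planted elements
#'   (default 1000, beyond the default clustering window, so the truth
#'   tables define clustered/unclustered status unambiguously).
#' @param conservation_baseline mean of the raw background conservation
#'   score in \[0, 1\] (default 0.10, a typical genome-wide average).
#' @param conservation_boost score boost over planted sites (default 0.6),
#'   tapering linearly to 0 over `conservation_taper_bp` flanks.
#' @param conservation_taper_bp taper width (default 200 bp).
#' @param dhs_binsize DNase-seq bin width in bp (default 100).
#' @param dhs_baseline_rate Poisson rate per bin away from planted sites
#'   (default 2).
#' @param dhs_multiplier rate multiplier over bins overlapping planted sites
#'   (default 5).
#' @param n_cell_lines,n_replicates synthetic cell lines and replicates per
#'   cell line (defaults 3 and 2).
#' @param repeat_fraction fraction of the genome covered by repeat-mask
#'   intervals (default 0.2; repeats never overlap planted sites).
#' @param seed integer seed (default 1).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = c(chr1 = 5e6),
                           background_probs = c(A = 0.3, C = 0.2,
                                                G = 0.2, T = 0.3),
                           n_genes = 400,
                           gene_length_range = c(2000, 10000),
                           promoter_bp = 1000,
                           motif = example_motif(),
                           n_planted = 2000,
                           cluster_fraction = 0.5,
                           cluster_size_range = c(2, 5),
                           planting_window = 200,
                           promoter_fraction = 0.5,
                           isolation_bp = 1000,
                           conservation_baseline = 0.10,
                           conservation_boost = 0.6,
                           conservation_taper_bp = 200,
                           dhs_binsize = 100,
                           dhs_baseline_rate = 2,
                           dhs_multiplier = 5,
                           n_cell_lines = 3,
                           n_replicates = 2,
                           repeat_fraction = 0.2,
                           seed = 1) {
  spec <- list(genome_length = genome_length,
               background_probs = background_probs / sum(background_probs),
               n_genes = as.integer(n_genes),
               gene_length_range = gene_length_range,
               promoter_bp = as.integer(promoter_bp),
               motif = motif,
               n_planted = as.integer(n_planted),
               cluster_fraction = cluster_fraction,
               cluster_size_range = as.integer(cluster_size_range),
               planting_window = as.integer(planting_window),
               promoter_fraction = promoter_fraction,
               isolation_bp = as.integer(isolation_bp),
               conservation_baseline = conservation_baseline,
               conservation_boost = conservation_boost,
               conservation_taper_bp = as.integer(conservation_taper_bp),
               dhs_binsize = as.integer(dhs_binsize),
               dhs_baseline_rate = dhs_baseline_rate,
               dhs_multiplier = dhs_multiplier,
               n_cell_lines = as.integer(n_cell_lines),
               n_replicates = as.integer(n_replicates),
               repeat_fraction = repeat_fraction,
               seed = as.integer(seed))
  if (is.null(names(spec$genome_length)))
    names(spec$genome_length) <- paste0("chr", seq_along(spec$genome_length))
  fr <- c(spec$cluster_fraction, spec$promoter_fraction,
          spec$repeat_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (spec$n_planted < 0) stop("n_planted must be >= 0")
  if (spec$dhs_baseline_rate <= 0 || spec$dhs_multiplier <= 0)
    stop("DHS rates must be positive")
  validate_motif_matrix(spec$motif)
  structure(spec, class = "synthetic_spec")
}

# sizes of planted clusters summing exactly to n_clustered (each >= smin)
.cluster_sizes <- function(n_clustered, smin, smax) {
  if (n_clustered < smin) return(integer(0))
  sizes <- integer(0)
  left <- n_clustered
  while (left >= smin) {
    s <- sample(seq.int(smin, smax), 1L)
    if (left - s != 0 && left - s < smin) s <- left  # absorb the remainder
    if (s > smax + smin) { s <- smin }               # keep sizes reasonable
    sizes <- c(sizes, min(s, left))
    left <- left - min(s, left)
  }
  if (left > 0) sizes[length(sizes)] <- sizes[length(sizes)] + left
  sizes
}

# place n_genes genes in equal slots along the concatenated genome
.place_genes <- function(glen, n_genes, len_range, promoter_bp) {
  chroms <- names(glen)
  share <- round(n_genes * glen / sum(glen))
  share[length(share)] <- n_genes - sum(share[-length(share)])
  rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ng <- share[ci]
    if (ng < 1) next
    slot <- floor(glen[ci] / ng)
    if (slot < len_range[1] + 2 * promoter_bp + 2)
      stop("infeasible packing: ", ng, " genes on a ", glen[ci],
           "-bp chromosome leaves slots of ", slot,
           " bp; reduce n_genes or gene lengths")
    for (s in seq_len(ng)) {
      gi <- gi + 1L
      len <- round(runif(1, len_range[1], min(len_range[2],
                                              slot - 2 * promoter_bp - 2)))
      lo <- (s - 1) * slot
      st0 <- lo + promoter_bp +
        floor(runif(1) * max(1, slot - len - 2 * promoter_bp))
      rows[[gi]] <- data.frame(gene_id = sprintf("g%04d", gi),
                               chrom = chroms[ci],
                               strand = sample(c("+", "-"), 1L),
                               txStart = st0, txEnd = st0 + len)
    }
  }
  do.call(rbind, rows)
}

.sample_motif_instance <- function(probs) {
  vapply(seq_len(nrow(probs)), function(i)
    sample.int(4L, 1L, prob = probs[i, ]) - 1L, integer(1))
}

#' Generate a synthetic genome bundle with planted motif structure
#'
#' Draws a background genome from the spec's nucleotide composition, plants
#' `n_planted` motif instances sampled column-wise from the motif matrix
#' (on either strand) with the requested clustering and promoter bias,
#' and synthesizes the companion data a characterization run needs: gene
#' models, a repeat mask avoiding planted sites, a raw conservation track
#' elevated over planted sites, replicated DNase-seq count tracks with
#' elevated rates at planted sites, and truth tables for every planted
#' site, cluster and targeted gene.  Output is byte-identical across runs
#' with the same spec (including its seed).
#'
#' @param spec a `synthetic_spec`.
#' @return An object of class `synthetic_bundle`: list with `genome`
#'   (`DNAStringSet`), `genes` (`GRanges`), `repeats` (`GRanges`),
#'   `conservation` (raw \[0, 1\] `signal_track`), `dhs` (list with
#'   `samples`, `cell_lines`), `truth` (list with `sites` `GRanges`
#'   carrying `cluster_id`, `in_promoter`, `gene_id`; `clusters` data
#'   frame; `target_genes` character vector) and `spec`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  glen <- spec$genome_length
  chroms <- names(glen)
  L <- motif_length(spec$motif)
  genes_df <- .place_genes(glen, spec$n_genes, spec$gene_length_range,
                           spec$promoter_bp)
  genes <- gene_models(genes_df, seqlengths = glen)
  prom <- .promoter_windows(genes, spec$promoter_bp)

  ## ---- plan planted elements -------------------------------------------
  n_clustered <- round(spec$n_planted * spec$cluster_fraction)
  sizes <- .cluster_sizes(n_clustered, spec$cluster_size_range[1],
                          spec$cluster_size_range[2])
  n_clustered <- sum(sizes)
  n_isolated <- spec$n_planted - n_clustered
  n_clusters <- length(sizes)
  n_prom_cl <- round(spec$promoter_fraction * n_clusters)
  if (n_prom_cl > length(genes))
    stop("infeasible packing: more promoter clusters than genes")

  # per-element layout: a cluster is a vector of site offsets within its span
  gaps_of <- function(size) {
    if (size == 1L) return(integer(0))
    sample(seq.int(20L, max(20L, spec$planting_window)), size - 1L,
           replace = TRUE)
  }
  elements <- vector("list", n_clusters + n_isolated)
  for (ei in seq_len(n_clusters)) {
    g <- gaps_of(sizes[ei])
    offs <- cumsum(c(0L, g + L))
    elements[[ei]] <- list(offsets = offs, span = offs[length(offs)] + L,
                           cluster = TRUE)
  }
  for (ei in seq_len(n_isolated))
    elements[[n_clusters + ei]] <- list(offsets = 0L, span = L,
                                        cluster = FALSE)

  # promoter placements first: distinct genes, cluster span inside the window
  prom_ok <- which(width(prom) >= spec$promoter_bp)
  spans <- vapply(elements, `[[`, numeric(1), "span")
  if (n_prom_cl > 0 && any(spans[seq_len(n_prom_cl)] > spec$promoter_bp))
    stop("infeasible packing: a planted cluster exceeds the promoter window")
  prom_genes <- if (n_prom_cl > 0)
    sample(prom_ok, n_prom_cl) else integer(0)

  occ_chr <- character(0); occ_s <- numeric(0); occ_e <- numeric(0)
  el_chr <- character(length(elements))
  el_start <- numeric(length(elements))
  el_gene <- rep(NA_character_, length(elements))
  el_in_prom <- logical(length(elements))
  for (ei in seq_along(elements)) {
    span <- elements[[ei]]$span
    if (ei <= n_prom_cl) {
      gidx <- prom_genes[ei]
      s <- start(prom)[gidx] + floor(runif(1) *
                                     (width(prom)[gidx] - span + 1))
      ch <- as.character(seqnames(prom))[gidx]
      el_gene[ei] <- genes$gene_id[gidx]
      el_in_prom[ei] <- TRUE
    } else {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        ci <- sample.int(length(chroms), 1L, prob = glen)
        s <- floor(runif(1) * (glen[ci] - span)) + 1
        ch <- chroms[ci]
        e <- s + span - 1
        same <- occ_chr == ch
        if (any(same & occ_s <= e + spec$isolation_bp &
                occ_e >= s - spec$isolation_bp)) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible packing: could not place planted element ", ei)
    }
    e <- s + span - 1
    occ_chr <- c(occ_chr, ch); occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
    el_chr[ei] <- ch; el_start[ei] <- s
  }

  # expand elements to sites
  site_chr <- character(0); site_st <- numeric(0)
  site_cl <- integer(0); site_gene <- character(0)
  for (ei in seq_along(elements)) {
    offs <- elements[[ei]]$offsets
    site_chr <- c(site_chr, rep(el_chr[ei], length(offs)))
    site_st <- c(site_st, el_start[ei] + offs)
    site_cl <- c(site_cl,
                 rep(if (elements[[ei]]$cluster) ei else NA_integer_,
                     length(offs)))
    site_gene <- c(site_gene, rep(el_gene[ei], length(offs)))
  }
  site_strand <- sample(c("+", "-"), length(site_st), replace = TRUE)

  ## ---- sequence --------------------------------------------------------
  codes <- lapply(glen, function(n)
    sample.int(4L, n, replace = TRUE, prob = spec$background_probs) - 1L)
  names(codes) <- chroms
  for (i in seq_along(site_st)) {
    inst <- .sample_motif_instance(spec$motif$probs)
    if (site_strand[i] == "-") inst <- 3L - rev(inst)
    codes[[site_chr[i]]][site_st[i]:(site_st[i] + L - 1L)] <- inst
  }
  genome <- Biostrings::DNAStringSet(vapply(codes, function(cd)
    paste(.NUCS[cd + 1L], collapse = ""), character(1)))
  names(genome) <- chroms

  truth_sites <- GRanges(site_chr, IRanges(site_st, width = L),
                         strand = site_strand,
                         cluster_id = site_cl,
                         gene_id = site_gene)
  GenomeInfoDb::seqlengths(truth_sites) <- glen[seqlevels(truth_sites)]
  truth_sites <- sort(truth_sites, ignore.strand = TRUE)
  # promoter status from actual positions: promoter-biased clusters are
  # forced into promoter windows, everything else may still land in one by
  # chance, so an unbiased spec recovers promoter fold ~1
  truth_sites$in_promoter <- overlapsAny(truth_sites, prom,
                                         ignore.strand = TRUE)

  ## ---- repeats ---------------------------------------------------------
  repeats <- GRanges()
  if (spec$repeat_fraction > 0) {
    target_bp <- spec$repeat_fraction * sum(glen)
    tchr <- as.character(seqnames(truth_sites))
    site_iv <- lapply(setNames(chroms, chroms), function(ch) {
      i <- tchr == ch
      list(s = start(truth_sites)[i], e = end(truth_sites)[i])
    })
    rep_chr <- character(0); rep_s <- numeric(0); rep_e <- numeric(0)
    covered <- 0
    guard <- 0L
    while (covered < target_bp && guard < 1e5) {
      guard <- guard + 1L
      len <- round(runif(1, 200, 2000))
      ci <- sample.int(length(chroms), 1L, prob = glen)
      s <- floor(runif(1) * (glen[ci] - len)) + 1
      e <- s + len - 1
      iv <- site_iv[[chroms[ci]]]
      if (any(iv$s <= e & iv$e >= s)) next
      rep_chr <- c(rep_chr, chroms[ci]); rep_s <- c(rep_s, s)
      rep_e <- c(rep_e, e)
      covered <- covered + len
    }
    repeats <- GenomicRanges::reduce(GRanges(rep_chr, IRanges(rep_s, rep_e)))
    GenomeInfoDb::seqlengths(repeats) <- glen[seqlevels(repeats)]
  }

  ## ---- conservation ----------------------------------------------------
  taper <- spec$conservation_taper_bp
  cons <- lapply(glen, function(n)
    pmin(1, pmax(0, rnorm(n, spec$conservation_baseline, 0.05))))
  names(cons) <- chroms
  ts_chr <- as.character(seqnames(truth_sites))
  ts_s <- start(truth_sites); ts_e <- end(truth_sites)
  if (spec$conservation_boost > 0 && length(truth_sites) > 0) {
    # plateau over the site, linear decay to 0 across the taper flanks
    for (i in seq_along(truth_sites)) {
      ch <- ts_chr[i]
      s <- ts_s[i]; e <- ts_e[i]
      lo <- max(1L, s - taper); hi <- min(glen[[ch]], e + taper)
      pos <- lo:hi
      w <- rep(1, length(pos))
      w[pos < s] <- 1 - (s - pos[pos < s]) / (taper + 1)
      w[pos > e] <- 1 - (pos[pos > e] - e) / (taper + 1)
      cons[[ch]][pos] <- pmin(1, cons[[ch]][pos] +
                                 spec$conservation_boost * w)
    }
  }
  conservation <- signal_track(cons, binsize = 1L)

  ## ---- DNase-seq -------------------------------------------------------
  bs <- spec$dhs_binsize
  lam <- lapply(glen, function(n) rep(spec$dhs_baseline_rate,
                                      ceiling(n / bs)))
  names(lam) <- chroms
  for (i in seq_along(truth_sites)) {
    b1 <- (ts_s[i] - 1L) %/% bs + 1L
    b2 <- (ts_e[i] - 1L) %/% bs + 1L
    lam[[ts_chr[i]]][b1:b2] <- spec$dhs_baseline_rate * spec$dhs_multiplier
  }
  samples <- list()
  cell_lines <- character(0)
  for (cl in seq_len(spec$n_cell_lines)) {
    for (rp in seq_len(spec$n_replicates)) {
      depth <- runif(1, 0.5, 1.5)       # library-size variation
      cnt <- lapply(lam, function(l) rpois(length(l), l * depth))
      nm <- sprintf("cell%d_rep%d", cl, rp)
      samples[[nm]] <- signal_track(cnt, binsize = bs)
      cell_lines <- c(cell_lines, sprintf("cell%d", cl))
    }
  }

  ## ---- truth tables ----------------------------------------------------
  cl_rows <- which(vapply(elements, `[[`, logical(1), "cluster"))
  if (length(cl_rows)) {
    cl_gr <- GRanges(el_chr[cl_rows],
                     IRanges(el_start[cl_rows],
                             el_start[cl_rows] + spans[cl_rows] - 1))
    ph <- findOverlaps(cl_gr, prom, ignore.strand = TRUE)
    cl_gene <- el_gene[cl_rows]
    cl_gene[queryHits(ph)] <- genes$gene_id[subjectHits(ph)]
    truth_clusters <- data.frame(
      cluster_id = cl_rows,
      chrom = el_chr[cl_rows],
      start = el_start[cl_rows],
      end = el_start[cl_rows] + spans[cl_rows] - 1,
      n_sites = sizes,
      in_promoter = overlapsAny(cl_gr, prom, ignore.strand = TRUE),
      gene_id = cl_gene)
    target_genes <- sort(unique(
      genes$gene_id[unique(subjectHits(ph))]))
  } else {
    truth_clusters <- data.frame(
      cluster_id = integer(0), chrom = character(0), start = numeric(0),
      end = numeric(0), n_sites = integer(0), in_promoter = logical(0),
      gene_id = character(0))
    target_genes <- character(0)
  }

  structure(list(genome = genome,
                 genes = genes,
                 repeats = repeats,
                 conservation = conservation,
                 dhs = list(samples = samples, cell_lines = cell_lines),
                 truth = list(sites = truth_sites,
                              clusters = truth_clusters,
                              target_genes = target_genes),
                 spec = spec),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", sum(.genome_seqlengths(x$genome)), "bp genome,",
      length(x$genes), "genes,", length(x$truth$sites), "planted sites (",
      nrow(x$truth$clusters), "clusters )\n")
  invisible(x)
}

#' Write a synthetic bundle to disk in standard formats
#'
#' FASTA genome, tab-delimited gene table, repeat BED, conservation
#' bedGraph, one bedGraph per DNase-seq sample plus a `dhs_samples.tsv`
#' replicate map, and the truth tables (`planted_sites.tsv`,
#' `planted_clusters.tsv`, `target_genes.tsv`).
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  g <- bundle$genes
  write.table(data.frame(gene_id = g$gene_id,
                         chrom = as.character(seqnames(g)),
                         strand = as.character(strand(g)),
                         txStart = start(g) - 1L, txEnd = end(g)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(bundle$repeats))
    rtracklayer::export(bundle$repeats, file.path(dir, "repeats.bed"),
                        format = "BED")
  write_bedgraph(bundle$conservation,
                 file.path(dir, "conservation.bedGraph"))
  for (nm in names(bundle$dhs$samples))
    write_bedgraph(bundle$dhs$samples[[nm]],
                   file.path(dir, paste0("dhs_", nm, ".bedGraph")))
  write.table(data.frame(sample = names(bundle$dhs$samples),
                         cell_line = bundle$dhs$cell_lines),
              file.path(dir, "dhs_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ts <- bundle$truth$sites
  write.table(data.frame(chrom = as.character(seqnames(ts)),
                         start = start(ts) - 1L, end = end(ts),
                         strand = as.character(strand(ts)),
                         cluster_id = ts$cluster_id,
                         in_promoter = ts$in_promoter,
                         gene_id = ts$gene_id),
              file.path(dir, "planted_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$clusters, file.path(dir, "planted_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = bundle$truth$target_genes),
              file.path(dir, "target_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_motif(bundle$spec$motif, file.path(dir, "motif.mat"))
  invisible(dir)
}

#' Compare a pipeline run against the planted ground truth
#'
#' Site recall and precision use 50% reciprocal overlap (for equal-width
#' sites this is an overlap of at least half the motif length).  Cluster
#' recall is the fraction of planted clusters whose span overlaps a
#' detected cluster span.  The promoter fold is computed for both the
#' recovered and the planted sites against one shared random-site control
#' (seeded, `n_random` sites drawn outside the repeat mask), so the fold
#' error isolates site-recovery fidelity from control-sampling noise.
#' Conservation and DHS contrasts are the differences between the recovered
#' sites and the random control on the byte-scaled conservation track and
#' the normalized DHS of the first cell line.
#'
#' @param bundle a `synthetic_bundle`.
#' @param sites recovered motif sites (`GRanges`).
#' @param clusters optional `site_clusters` from the recovered sites.
#' @param n_random random control size (default 10000).
#' @param seed seed for the control draw (default 1).
#' @return An object of class `recovery_report`: list of metrics.
#' @export
recovery_report <- function(bundle, sites, clusters = NULL,
                            n_random = 10000, seed = 1) {
  truth <- bundle$truth$sites
  L <- unique(width(truth))
  min_ov <- as.integer(ceiling(L / 2))
  hits <- findOverlaps(truth, sites, minoverlap = min_ov,
                       ignore.strand = TRUE)
  recall <- length(unique(queryHits(hits))) / max(1L, length(truth))
  precision <- length(unique(subjectHits(hits))) / max(1L, length(sites))

  sl <- .genome_seqlengths(bundle$genome)
  ctrl <- random_sites(sl, n = n_random, width = L,
                       mask = if (length(bundle$repeats)) bundle$repeats,
                       seed = seed)
  pb <- bundle$spec$promoter_bp
  bd_ctrl <- classify_locations(ctrl, bundle$genes, promoter_bp = pb)
  fold_est <- promoter_enrichment(
    classify_locations(sites, bundle$genes, promoter_bp = pb), bd_ctrl)$fold
  fold_planted <- promoter_enrichment(
    classify_locations(truth, bundle$genes, promoter_bp = pb), bd_ctrl)$fold
  fold_error <- if (is.finite(fold_planted) && fold_planted > 0)
    abs(fold_est - fold_planted) / fold_planted else NA_real_

  out <- list(site_recall = recall,
              site_precision = precision,
              n_truth = length(truth), n_detected = length(sites),
              promoter_fold_est = fold_est,
              promoter_fold_planted = fold_planted,
              promoter_fold_error = fold_error)

  if (!is.null(clusters)) {
    tc <- bundle$truth$clusters
    if (nrow(tc) > 0 && length(clusters$clusters) > 0) {
      tc_gr <- GRanges(tc$chrom, IRanges(tc$start, tc$end))
      out$cluster_recall <- mean(overlapsAny(tc_gr, clusters$clusters,
                                             ignore.strand = TRUE))
    } else {
      out$cluster_recall <- if (nrow(tc) == 0) NA_real_ else 0
    }
    est <- clustering_summary(sites, clusters)
    out$pct_clustered_est <- est$pct_clustered
    out$pct_clustered_planted <-
      round(100 * sum(!is.na(truth$cluster_id)) / length(truth), 2)
  }

  cons <- scale_conservation(bundle$conservation)
  out$conservation_contrast <-
    overall_conservation(sites, cons) - overall_conservation(ctrl, cons)
  norm <- normalize_dhs(bundle$dhs$samples, bundle$dhs$cell_lines)
  dtr <- norm[[1]]
  out$dhs_contrast <- dhs_at_sites(sites, dtr)$mean -
    dhs_at_sites(ctrl, dtr)$mean
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("site recall %.3f, precision %.3f (%d truth / %d detected)\n",
              x$site_recall, x$site_precision, x$n_truth, x$n_detected))
  if (!is.null(x$pct_clustered_est))
    cat(sprintf("pct clustered: %.2f%% est vs %.2f%% planted\n",
                x$pct_clustered_est, x$pct_clustered_planted))
  cat(sprintf("promoter fold: %.2f est vs %.2f planted (error %.1f%%)\n",
              x$promoter_fold_est, x$promoter_fold_planted,
              100 * x$promoter_fold_error))
  cat(sprintf("conservation contrast %+.2f; DHS contrast %+.3f\n",
              x$conservation_contrast, x$dhs_contrast))
  invisible(x)
}
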