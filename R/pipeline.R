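#' Default parameters of the characterization pipeline
#'
#' Defaults follow the standard analysis settings: motif mapping at
#' LR >= 1000, clusters chained at a 500-bp window with at least 2 sites,
#' promoters as the 1-kb window upstream of the TSS, 1-kb conservation
#' flanks, 200-bp DHS windows, and a 3rd-order Markov background.
#'
#' @param lr_cutoff LR cutoff for mapping the motif (default 1000).
#' @param cluster_window clustering gap window in bp (default 500).
#' @param min_sites minimum cluster size (default 2).
#' @param promoter_bp promoter window in bp (default 1000).
#' @param downstream_bp TES downstream window in bp (default 1000).
#' @param flank conservation profile flank in bp (default 1000).
#' @param dhs_window DHS extraction window in bp (default 200).
#' @param order Markov background order (default 3).
#' @param min_cutoff minimum LR cutoff used when count-matching control
#'   motifs (default 100).
#' @param n_permuted permuted control motifs in the battery (default 0:
#'   no battery; genome-scale analyses conventionally use 500).
#' @param pseudocount motif pseudocount for scanning (default 1e-4).
#' @return named list of parameters.
#' @export
characterization_params <- function(lr_cutoff = 1000, cluster_window = 500,
                                    min_sites = 2, promoter_bp = 1000,
                                    downstream_bp = 1000, flank = 1000,
                                    dhs_window = 200, order = 3,
                                    min_cutoff = 100, n_permuted = 0,
                                    pseudocount = 1e-4) {
  list(lr_cutoff = lr_cutoff, cluster_window = cluster_window,
       min_sites = min_sites, promoter_bp = promoter_bp,
       downstream_bp = downstream_bp, flank = flank,
       dhs_window = dhs_window, order = order, min_cutoff = min_cutoff,
       n_permuted = n_permuted, pseudocount = pseudocount)
}

.breakdowns <- function(sites, clusters, genes, params) {
  pb <- params$promoter_bp; db <- params$downstream_bp
  clustered <- sites[!is.na(clusters$membership)]
  list(sites = classify_locations(sites, genes, pb, db),
       clusters = if (length(clusters$clusters) > 0)
         classify_locations(clusters$clusters, genes, pb, db),
       clustered_sites = if (length(clustered) > 0)
         classify_locations(clustered, genes, pb, db))
}

.summary_row <- function(label, bd, summ) {
  data.frame(set = label,
             n_sites = summ$n_sites,
             n_clusters = summ$n_clusters,
             n_clustered_sites = summ$n_clustered_sites,
             pct_clustered = summ$pct_clustered,
             pct_tssup_sites = round(100 * bd$sites$counts[["TSSup"]] /
                                       bd$sites$total, 2),
             pct_tssup_clusters = if (!is.null(bd$clusters))
               round(100 * bd$clusters$counts[["TSSup"]] /
                       bd$clusters$total, 2) else NA_real_,
             pct_tssup_clustered_sites = if (!is.null(bd$clustered_sites))
               round(100 * bd$clustered_sites$counts[["TSSup"]] /
                       bd$clustered_sites$total, 2) else NA_real_)
}

#' Run the full motif characterization
#'
#' Orchestrates scan, deduplication, clustering, random-site control,
#' promoter enrichment, conservation, DHS comparisons, target-gene
#' annotation and (optionally) a permuted-motif control battery with
#' percentile summaries.  Every number in the report is a deterministic
#' function of the inputs, the parameters and the seed.
#'
#' @param genome genome (`DNAStringSet`, FASTA path, or named character).
#' @param motif `motif_matrix` under study.
#' @param genes gene `GRanges` from [gene_models()].
#' @param conservation optional raw \[0, 1\] `signal_track`.
#' @param dhs_samples optional named list of DNase-seq count
#'   `signal_track`s.
#' @param dhs_cell_lines cell-line labels parallel to `dhs_samples`.
#' @param repeats optional repeat-mask `GRanges` (controls are drawn
#'   outside it; the scan itself is not masked).
#' @param params parameter list from [characterization_params()].
#' @param known_motifs optional named list of external control motifs.
#' @param seed integer seed (default 1).
#' @return An object of class `characterization_report`.
#' @export
run_characterization <- function(genome, motif, genes,
                                 conservation = NULL, dhs_samples = NULL,
                                 dhs_cell_lines = NULL, repeats = NULL,
                                 params = characterization_params(),
                                 known_motifs = list(), seed = 1) {
  set.seed(seed)
  g <- .as_dnastringset(genome)
  sl <- .genome_seqlengths(g)
  L <- motif_length(motif)
  bg <- train_background(g, order = params$order)
  sites <- deduplicate_sites(
    scan_motif(g, motif, bg, lr_cutoff = params$lr_cutoff,
               pseudocount = params$pseudocount))
  if (length(sites) == 0L) stop("no motif sites at LR >= ",
                                params$lr_cutoff)
  cl <- cluster_sites(sites, window = params$cluster_window,
                      min_sites = params$min_sites)
  summ <- clustering_summary(sites, cl)

  rand <- random_sites(sl, n = length(sites), width = L, mask = repeats)
  rcl <- cluster_sites(rand, window = params$cluster_window,
                       min_sites = params$min_sites)
  rsumm <- clustering_summary(rand, rcl)
  clustering_test <- two_proportion_ztest(summ$n_clustered_sites,
                                          summ$n_sites,
                                          rsumm$n_clustered_sites,
                                          rsumm$n_sites)

  bd <- .breakdowns(sites, cl, genes, params)
  rbd <- .breakdowns(rand, rcl, genes, params)
  enrich <- list(
    sites = promoter_enrichment(bd$sites, rbd$sites),
    clusters = if (!is.null(bd$clusters) && !is.null(rbd$clusters))
      promoter_enrichment(bd$clusters, rbd$clusters),
    clustered_sites = if (!is.null(bd$clustered_sites) &&
                          !is.null(rbd$clustered_sites))
      promoter_enrichment(bd$clustered_sites, rbd$clustered_sites))

  conservation_block <- NULL
  cons_scaled <- NULL
  if (!is.null(conservation)) {
    cons_scaled <- scale_conservation(conservation)
    conservation_block <- list(
      profile = conservation_profile(sites, cons_scaled,
                                     flank = params$flank),
      overall = overall_conservation(sites, cons_scaled),
      overall_random = overall_conservation(rand, cons_scaled))
  }

  dhs_block <- NULL
  dhs_norm <- NULL
  if (!is.null(dhs_samples)) {
    dhs_norm <- normalize_dhs(dhs_samples, dhs_cell_lines)
    ncl <- length(dhs_norm)
    rows <- lapply(names(dhs_norm), function(cline) {
      a <- dhs_at_sites(sites, dhs_norm[[cline]],
                        window = params$dhs_window)$values
      b <- dhs_at_sites(rand, dhs_norm[[cline]],
                        window = params$dhs_window)$values
      cmp <- compare_dhs_groups(a, b, n_tests = ncl)
      data.frame(cell_line = cline, n = length(a),
                 mean_motif = cmp$mean_a, mean_random = cmp$mean_b,
                 t = cmp$t, p = cmp$p_one_sided,
                 p_bonferroni = cmp$p_bonferroni)
    })
    dhs_block <- do.call(rbind, rows)
  }

  targets <- annotate_target_genes(sites, genes, params$promoter_bp,
                                   clusters = cl, require_cluster = TRUE)
  targets_relaxed <- annotate_target_genes(sites, genes,
                                           params$promoter_bp,
                                           require_cluster = FALSE)

  battery <- NULL
  percentiles <- NULL
  if (params$n_permuted > 0 || length(known_motifs) > 0) {
    battery <- build_control_battery(motif, g, bg,
                                     target_count = length(sites),
                                     n_permuted = params$n_permuted,
                                     known_motifs = known_motifs,
                                     min_cutoff = params$min_cutoff,
                                     mask = repeats)
    ctrl_stats <- lapply(battery, function(ctl) {
      s <- ctl$sites
      ccl <- cluster_sites(s, window = params$cluster_window,
                           min_sites = params$min_sites)
      csum <- clustering_summary(s, ccl)
      cbd <- classify_locations(s, genes, params$promoter_bp,
                                params$downstream_bp)
      c(n_clusters = csum$n_clusters,
        n_clustered_sites = csum$n_clustered_sites,
        pct_tssup = 100 * cbd$counts[["TSSup"]] / cbd$total,
        overall_conservation = if (!is.null(cons_scaled))
          overall_conservation(s, cons_scaled) else NA_real_,
        mean_dhs = if (!is.null(dhs_norm))
          dhs_at_sites(s, dhs_norm[[1]],
                       window = params$dhs_window)$mean else NA_real_)
    })
    cs <- do.call(rbind, ctrl_stats)
    motif_stats <- c(n_clusters = summ$n_clusters,
                     n_clustered_sites = summ$n_clustered_sites,
                     pct_tssup = 100 * bd$sites$counts[["TSSup"]] /
                       bd$sites$total,
                     overall_conservation = if (!is.null(cons_scaled))
                       conservation_block$overall else NA_real_,
                     mean_dhs = if (!is.null(dhs_block))
                       dhs_at_sites(sites, dhs_norm[[1]],
                                    window = params$dhs_window)$mean
                     else NA_real_)
    # fraction of controls at least as extreme as the motif under study
    percentiles <- vapply(colnames(cs), function(m)
      mean(cs[, m] >= motif_stats[[m]]), numeric(1))
    battery <- list(stats = as.data.frame(cs),
                    shortfalls = names(battery)[
                      vapply(battery, `[[`, logical(1), "shortfall")])
  }

  summary_table <- rbind(.summary_row("motif", bd, summ),
                  .summary_row("random", rbd, rsumm))

  structure(list(params = params, seed = seed,
                 n_sites = length(sites),
                 sites = sites, clusters = cl,
                 summary = summ, random_summary = rsumm,
                 clustering_test = clustering_test,
                 summary_table = summary_table,
                 enrichment = enrich,
                 conservation = conservation_block,
                 dhs = dhs_block,
                 target_genes = targets,
                 target_genes_relaxed = targets_relaxed,
                 control_percentiles = percentiles,
                 control_battery = battery),
            class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("characterization_report (seed ", x$seed, ")\n", sep = "")
  cat("\nsummary by site category:\n")
  print(x$summary_table, row.names = FALSE)
  cat(sprintf("\nclustering: %.2f%% vs %.2f%% random (Z=%.1f, p=%.3g)\n",
              x$summary$pct_clustered, x$random_summary$pct_clustered,
              x$clustering_test$z, x$clustering_test$p_one_sided))
  cat("promoter enrichment (sites): ")
  print(x$enrichment$sites)
  if (!is.null(x$enrichment$clusters)) {
    cat("promoter enrichment (clusters): ")
    print(x$enrichment$clusters)
  }
  if (!is.null(x$conservation))
    cat(sprintf("overall conservation: %.2f motif vs %.2f random\n",
                x$conservation$overall, x$conservation$overall_random))
  if (!is.null(x$dhs)) {
    cat("DHS by cell line:\n")
    print(x$dhs, row.names = FALSE)
  }
  cat(sprintf("target genes: %d (%.1f%% of genes); relaxed: %d\n",
              x$target_genes$n_targets, x$target_genes$pct_genes,
              x$target_genes_relaxed$n_targets))
  if (!is.null(x$control_percentiles)) {
    cat("fraction of controls >= motif:\n")
    print(round(x$control_percentiles, 3))
  }
  invisible(x)
}

#' Parameter robustness sweep
#'
#' Re-runs the core statistics varying one parameter at a time while
#' holding the others at their defaults: the LR mapping cutoff, the
#' cluster window, the promoter width, and the minimum cluster size.  The
#' genome is scanned once at the smallest cutoff and filtered, which gives
#' results identical to independent scans because thresholding commutes
#' with LR-greedy deduplication.  The random control is re-matched to the
#' site count at every setting.
#'
#' @inheritParams run_characterization
#' @param lr_cutoffs LR cutoffs to sweep (default 500, 1000, 2000).
#' @param windows cluster windows in bp (default 250, 500, 1000).
#' @param promoters promoter widths in bp (default 500, 1000, 1500, 2000).
#' @param min_sites_values minimum cluster sizes (default 2, 3).
#' @return long-format data frame with columns `parameter`, `value`,
#'   `metric`, `estimate`.
#' @export
robustness_sweep <- function(genome, motif, genes, repeats = NULL,
                             params = characterization_params(),
                             lr_cutoffs = c(500, 1000, 2000),
                             windows = c(250, 500, 1000),
                             promoters = c(500, 1000, 1500, 2000),
                             min_sites_values = c(2, 3),
                             seed = 1) {
  set.seed(seed)
  g <- .as_dnastringset(genome)
  sl <- .genome_seqlengths(g)
  L <- motif_length(motif)
  bg <- train_background(g, order = params$order)
  base_cut <- min(c(lr_cutoffs, params$lr_cutoff))
  all_sites <- deduplicate_sites(
    scan_motif(g, motif, bg, lr_cutoff = base_cut,
               pseudocount = params$pseudocount))
  rows <- list()
  add <- function(parameter, value, metric, estimate)
    rows[[length(rows) + 1L]] <<-
      data.frame(parameter = parameter, value = value, metric = metric,
                 estimate = estimate)
  stats_for <- function(sites, window, min_sites, promoter_bp) {
    cl <- cluster_sites(sites, window = window, min_sites = min_sites)
    summ <- clustering_summary(sites, cl)
    bd <- classify_locations(sites, genes, promoter_bp,
                             params$downstream_bp)
    rand <- random_sites(sl, n = length(sites), width = L, mask = repeats)
    rbd <- classify_locations(rand, genes, promoter_bp,
                              params$downstream_bp)
    enr <- promoter_enrichment(bd, rbd)
    list(n_sites = length(sites), n_clusters = summ$n_clusters,
         n_clustered_sites = summ$n_clustered_sites,
         n_tssup_sites = bd$counts[["TSSup"]], fold = enr$fold)
  }
  emit <- function(parameter, value, st) {
    for (m in names(st)) add(parameter, value, m, as.numeric(st[[m]]))
  }
  for (cut in sort(lr_cutoffs)) {
    sites <- all_sites[all_sites$lr >= cut]
    emit("lr_cutoff", cut,
         stats_for(sites, params$cluster_window, params$min_sites,
                   params$promoter_bp))
  }
  default_sites <- all_sites[all_sites$lr >= params$lr_cutoff]
  for (w in sort(windows))
    emit("cluster_window", w,
         stats_for(default_sites, w, params$min_sites, params$promoter_bp))
  for (p in sort(promoters))
    emit("promoter_bp", p,
         stats_for(default_sites, params$cluster_window, params$min_sites,
                   p))
  for (ms in sort(min_sites_values))
    emit("min_sites", ms,
         stats_for(default_sites, params$cluster_window, ms,
                   params$promoter_bp))
  do.call(rbind, rows)
}
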