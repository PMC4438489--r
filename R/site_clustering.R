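#' Group motif sites into clusters by single-linkage chaining
#'
#' Adjacent sites on the same chromosome are chained into one cluster when
#' the gap between them is at most `window` bp; clusters with fewer than
#' `min_sites` members are discarded.  With the default `gap_metric =
#' "edge"` the gap is the number of intervening bases between two sites
#' (end-to-start distance); `"start"` measures start-to-start instead, for
#' sensitivity analysis.  Chaining is transitive: any two sites within the
#' gap threshold of each other always end up in the same cluster, and
#' distinct clusters on a chromosome are separated by more than `window`.
#' Strand is ignored.
#'
#' @param sites deduplicated [GenomicRanges::GRanges] of motif sites.
#' @param window maximum gap in bp (default 500).
#' @param min_sites minimum cluster size kept (default 2; use 3 for the
#'   stricter robustness variant).
#' @param gap_metric `"edge"` (intervening bases, default) or `"start"`.
#' @return An object of class `site_clusters`: list with
#'   \describe{
#'     \item{clusters}{`GRanges` of cluster spans with metadata `cluster_id`
#'       and `n_sites`,}
#'     \item{membership}{integer vector parallel to `sites`: the cluster id
#'       of each site, `NA` for unclustered sites,}
#'     \item{window, min_sites, gap_metric}{the parameters used.}
#'   }
#' @export
cluster_sites <- function(sites, window = 500, min_sites = 2,
                          gap_metric = c("edge", "start")) {
  gap_metric <- match.arg(gap_metric)
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 0)
    stop("window must be a single non-negative number")
  if (min_sites < 1) stop("min_sites must be >= 1")
  n <- length(sites)
  membership <- rep(NA_integer_, n)
  empty <- GRanges(cluster_id = integer(0), n_sites = integer(0))
  res <- structure(list(clusters = empty, membership = membership,
                        window = window, min_sites = min_sites,
                        gap_metric = gap_metric),
                   class = "site_clusters")
  if (n == 0L) return(res)
  o <- order(as.integer(seqnames(sites)), start(sites), end(sites))
  chr <- as.integer(seqnames(sites))[o]
  st <- start(sites)[o]
  en <- end(sites)[o]
  # running max end within chromosome so nested/staggered intervals chain
  # exactly like the transitive closure of the pairwise gap relation
  cmax <- en
  new_chr <- c(TRUE, chr[-1L] != chr[-n])
  for (i in seq_len(n)[-1L])
    if (!new_chr[i]) cmax[i] <- max(cmax[i - 1L], en[i])
  gap <- if (gap_metric == "edge") {
    c(Inf, st[-1L] - cmax[-n] - 1L)     # intervening bases, 1-based closed
  } else {
    c(Inf, st[-1L] - st[-n])
  }
  brk <- new_chr | gap > window
  raw_id <- cumsum(brk)
  sizes <- tabulate(raw_id)
  kept <- which(sizes >= min_sites)
  if (length(kept) == 0L) return(res)
  newid <- rep(NA_integer_, length(sizes))
  newid[kept] <- seq_along(kept)
  membership[o] <- newid[raw_id]
  cl_chr <- as.character(seqnames(sites))[o][!duplicated(raw_id)][kept]
  cl_start <- vapply(kept, function(k) min(st[raw_id == k]), numeric(1))
  cl_end <- vapply(kept, function(k) max(en[raw_id == k]), numeric(1))
  clusters <- GRanges(cl_chr, IRanges(cl_start, cl_end),
                      cluster_id = seq_along(kept),
                      n_sites = sizes[kept])
  sl <- seqlengths(sites)
  if (!all(is.na(sl)))
    GenomeInfoDb::seqlengths(clusters) <- sl[seqlevels(clusters)]
  res$clusters <- clusters
  res$membership <- membership
  res
}

#' Summarize the clustering tendency of a site set
#'
#' @param sites the `GRanges` of motif sites that were clustered.
#' @param clusters the `site_clusters` object produced from `sites`.
#' @return An object of class `clustering_summary`: list with `n_sites`,
#'   `n_clusters`, `n_clustered_sites` and `pct_clustered` (percentage of
#'   sites in clusters, reported to 2 decimals).
#' @export
clustering_summary <- function(sites, clusters) {
  n <- length(sites)
  if (n == 0L) stop("cannot summarize clustering of an empty site set")
  if (length(clusters$membership) != n)
    stop("clusters were not produced from these sites")
  ncs <- sum(!is.na(clusters$membership))
  structure(list(n_sites = n,
                 n_clusters = length(clusters$clusters),
                 n_clustered_sites = ncs,
                 pct_clustered = round(100 * ncs / n, 2)),
            class = "clustering_summary")
}

#' @export
print.clustering_summary <- function(x, ...) {
  cat(sprintf("%d sites; %d clusters covering %d sites (%.2f%%)\n",
              x$n_sites, x$n_clusters, x$n_clustered_sites,
              x$pct_clustered))
  invisible(x)
}

#' @export
print.site_clusters <- function(x, ...) {
  cat(sprintf("site_clusters: %d clusters (window=%g bp, min_sites=%d, %s gap)\n",
              length(x$clusters), x$window, x$min_sites, x$gap_metric))
  invisible(x)
}

#' Write cluster spans as BED and the site membership as TSV
#'
#' @param clusters a `site_clusters` object.
#' @param bed_path output BED6 path (name `cluster_<k>`, score = n_sites).
#' @param tsv_path optional membership table path (cluster_id, site_index).
#' @return `bed_path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, bed_path, tsv_path = NULL) {
  cl <- clusters$clusters
  df <- data.frame(chrom = as.character(seqnames(cl)),
                   start = start(cl) - 1L, end = end(cl),
                   name = paste0("cluster_", cl$cluster_id),
                   score = cl$n_sites, strand = ".")
  write.table(df, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    mem <- which(!is.na(clusters$membership))
    write.table(data.frame(cluster_id = clusters$membership[mem],
                           site_index = mem),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}
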