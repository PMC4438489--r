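#' Sample random genomic control sites
#'
#' Start positions are drawn uniformly over all placements whose width-L
#' interval fits the chromosome and avoids the mask — random sites from
#' non-repeat regions, when the mask is a repeat annotation.  Sampling is with replacement of positions, but exact
#' duplicates are re-drawn so the control set is non-redundant like a
#' deduplicated site list.
#'
#' @param seqlengths named chromosome lengths.
#' @param n number of sites.
#' @param width site width in bp.
#' @param mask optional `GRanges` of excluded intervals.
#' @param seed optional integer seed.
#' @param max_batches rejection-sampling batches before giving up (default
#'   100).
#' @return `GRanges` of `n` control sites (strand `*`), coordinate-sorted,
#'   with `lr = NA`.
#' @export
random_sites <- function(seqlengths, n, width, mask = NULL, seed = NULL,
                         max_batches = 100) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  avail <- pmax(as.numeric(seqlengths) - width + 1, 0)
  if (sum(avail) <= 0) stop("no chromosome can hold a width-", width, " site")
  chroms <- names(seqlengths)
  got_chr <- character(0); got_st <- numeric(0)
  for (b in seq_len(max_batches)) {
    need <- n - length(got_st)
    if (need <= 0L) break
    m <- max(2L * need, 10L) * b      # grow batches under heavy rejection
    ci <- sample.int(length(chroms), m, replace = TRUE, prob = avail)
    st <- floor(runif(m) * avail[ci]) + 1
    cand <- GRanges(chroms[ci], IRanges(st, width = width))
    if (!is.null(mask))
      cand <- cand[!overlapsAny(cand, mask, ignore.strand = TRUE)]
    key <- paste0(as.character(seqnames(cand)), ":", start(cand))
    fresh <- !(key %in% paste0(got_chr, ":", got_st)) & !duplicated(key)
    cand <- cand[fresh]
    take <- min(length(cand), need)
    if (take > 0L) {
      got_chr <- c(got_chr, as.character(seqnames(cand))[seq_len(take)])
      got_st <- c(got_st, start(cand)[seq_len(take)])
    }
  }
  if (length(got_st) < n)
    stop("could not place ", n, " unmasked sites after ", max_batches,
         " batches (unmasked space too fragmented?)")
  gr <- GRanges(got_chr, IRanges(got_st, width = width), strand = "*",
                lr = NA_real_)
  GenomeInfoDb::seqlengths(gr) <- seqlengths[seqlevels(gr)]
  sort(gr, ignore.strand = TRUE)
}

#' Permute the position order of a motif
#'
#' Rows (positions) of the probability matrix are reordered by a uniform
#' random permutation, excluding the identity when the motif has at least
#' two positions, so every control differs from the original.  The column
#' multiset — and therefore the total and per-nucleotide information
#' content — is preserved exactly, which is what makes permuted motifs a
#' matched null for clustering, conservation and promoter-enrichment
#' comparisons.
#'
#' @param motif a `motif_matrix`.
#' @param seed optional integer seed.
#' @return a `motif_matrix` (name suffixed `_perm`).
#' @export
permute_motif <- function(motif, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_motif_matrix(motif)
  L <- motif_length(motif)
  if (L < 2L) return(motif)
  repeat {
    perm <- sample.int(L)
    if (any(perm != seq_len(L))) break
  }
  motif_matrix(motif$probs[perm, , drop = FALSE],
               name = paste0(motif$name, "_perm"))
}

#' Build a battery of null controls for a motif
#'
#' Generates `n_permuted` permuted-matrix motifs plus any supplied external
#' motifs, maps each to the genome with a cutoff adjusted to yield the same
#' number of sites as the motif under study ([cutoff_for_count()]; motifs
#' that cannot reach the target at `min_cutoff` keep all their sites and are
#' flagged as shortfalls), and samples one random-site control of the same
#' count from unmasked sequence.
#'
#' @param motif the motif under study (`motif_matrix`).
#' @param genome genome (see [scan_motif()]).
#' @param background a `markov_background`.
#' @param target_count site count to match (normally the motif's own
#'   deduplicated site count).
#' @param n_permuted number of permuted motifs (default 500).
#' @param known_motifs optional named list of external `motif_matrix`
#'   objects.
#' @param min_cutoff minimum LR cutoff for control mapping (default 100).
#' @param mask optional repeat `GRanges` (used for the random-site control;
#'   see `mask_scan` of [scan_motif()] for masking the scans themselves).
#' @param seed integer seed (default 1).
#' @return An object of class `control_battery`: named list of controls,
#'   each a list with `type` (`"permuted"`, `"known"` or `"random"`),
#'   `sites`, `cutoff`, `shortfall` and (for matrix controls) `motif`.
#' @export
build_control_battery <- function(motif, genome, background, target_count,
                                  n_permuted = 500, known_motifs = list(),
                                  min_cutoff = 100, mask = NULL, seed = 1) {
  set.seed(seed)
  controls <- list()
  for (i in seq_len(n_permuted)) {
    pm <- permute_motif(motif)
    res <- cutoff_for_count(genome, pm, background, target_count,
                            min_cutoff = min_cutoff)
    controls[[paste0("permuted_", i)]] <-
      list(type = "permuted", motif = pm, sites = res$sites,
           cutoff = res$cutoff, shortfall = res$shortfall)
  }
  for (nm in names(known_motifs)) {
    res <- cutoff_for_count(genome, known_motifs[[nm]], background,
                            target_count, min_cutoff = min_cutoff)
    controls[[nm]] <- list(type = "known", motif = known_motifs[[nm]],
                           sites = res$sites, cutoff = res$cutoff,
                           shortfall = res$shortfall)
  }
  sl <- .genome_seqlengths(genome)
  controls[["random"]] <- list(
    type = "random",
    sites = random_sites(sl, n = target_count,
                         width = motif_length(motif), mask = mask),
    cutoff = NA_real_, shortfall = FALSE)
  structure(controls, class = "control_battery")
}

#' @export
print.control_battery <- function(x, ...) {
  types <- vapply(x, `[[`, character(1), "type")
  cat("control_battery:", sum(types == "permuted"), "permuted,",
      sum(types == "known"), "known,", sum(types == "random"),
      "random-site control(s)\n")
  sf <- names(x)[vapply(x, `[[`, logical(1), "shortfall")]
  if (length(sf)) cat("  shortfall:", paste(sf, collapse = ", "), "\n")
  invisible(x)
}
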