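#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
NULL

# byte -> nucleotide code lookup (A=0 C=1 G=2 T=3, anything else NA)
.CODE_LUT <- local({
  l <- rep(NA_integer_, 256L)
  l[utf8ToInt("A") + 1L] <- 0L; l[utf8ToInt("a") + 1L] <- 0L
  l[utf8ToInt("C") + 1L] <- 1L; l[utf8ToInt("c") + 1L] <- 1L
  l[utf8ToInt("G") + 1L] <- 2L; l[utf8ToInt("g") + 1L] <- 2L
  l[utf8ToInt("T") + 1L] <- 3L; l[utf8ToInt("t") + 1L] <- 3L
  l
})

# encode one sequence string as integer codes (NA for non-ACGT)
.encode_dna <- function(x) {
  .CODE_LUT[as.integer(charToRaw(x)) + 1L]
}

.as_dnastringset <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(genome)
    if (is.null(names(g))) names(g) <- paste0("chr", seq_along(g))
    return(g)
  }
  stop("genome must be a DNAStringSet, a FASTA path, or named character vector")
}

#' Read a genome FASTA file
#'
#' @param path FASTA file (multi-record; case-insensitive; N allowed).
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

.genome_seqlengths <- function(genome) {
  g <- .as_dnastringset(genome)
  setNames(Biostrings::width(g), names(g))
}

# context index at each position i: the k preceding bases, the base at i-1
# being the least-significant base-4 digit.  NA where the context runs off
# the sequence start or crosses a non-ACGT character.
.context_index <- function(codes, k) {
  n <- length(codes)
  if (k == 0L) return(rep(0, n))
  ctx <- rep(0, n)
  for (j in seq_len(k)) {
    prev <- if (j >= n) rep(NA_integer_, n)
            else c(rep(NA_integer_, j), codes[seq_len(n - j)])
    ctx <- ctx + prev * 4^(j - 1)
  }
  ctx
}

.context_labels <- function(k) {
  if (k == 0L) return("")
  idx <- 0:(4^k - 1)
  sapply(idx, function(i) {
    digits <- integer(k)
    for (j in seq_len(k)) {          # digit j = base at offset -j
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    # context string 5'->3' is offsets -k .. -1
    paste(.NUCS[rev(digits) + 1L], collapse = "")
  })
}

#' Construct a Markov background model directly
#'
#' Mostly useful for tests and toy examples; [train_background()] is the
#' normal entry point.
#'
#' @param trans `4^k x 4` matrix of conditional probabilities
#'   P(base | preceding k bases); each row must sum to 1.
#' @param marginal length-4 vector of marginal nucleotide probabilities,
#'   used for the first k bases of a sequence (and after runs of N) where no
#'   complete upstream context exists.
#' @param order non-negative integer k.
#' @return an object of class `markov_background`.
#' @export
markov_background <- function(trans, marginal, order) {
  order <- as.integer(order)
  stopifnot(order >= 0L)
  trans <- as.matrix(trans)
  if (nrow(trans) != 4^order || ncol(trans) != 4L)
    stop("trans must be a 4^order x 4 matrix")
  if (any(abs(rowSums(trans) - 1) > 1e-6))
    stop("each conditional distribution must sum to 1 within 1e-6")
  marginal <- as.numeric(marginal)
  if (length(marginal) != 4L || abs(sum(marginal) - 1) > 1e-6)
    stop("marginal must be 4 probabilities summing to 1")
  rownames(trans) <- .context_labels(order)
  colnames(trans) <- .NUCS
  structure(list(order = order, trans = trans, marginal = marginal),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("markov_background: order", x$order, "\n")
  cat("  marginal:", paste(sprintf("%s=%.3f", .NUCS, x$marginal),
                           collapse = " "), "\n")
  invisible(x)
}

#' Train a k-th order Markov background model on a genome
#'
#' Transition counts are accumulated over both strands of every unmasked
#' sequence; one pseudocount is added to every (context, nucleotide) cell
#' before normalization.  Non-ACGT characters are skipped and interrupt the
#' context (a (k+1)-mer containing an N contributes nothing).  Masked
#' intervals are excluded from counting.
#'
#' @param genome a [Biostrings::DNAStringSet], FASTA path, or named
#'   character vector.
#' @param order non-negative integer k (default 3).
#' @param mask optional [GenomicRanges::GRanges] of intervals to exclude.
#' @return a `markov_background`.
#' @export
train_background <- function(genome, order = 3L, mask = NULL) {
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  g <- .as_dnastringset(genome)
  if (length(g) == 0L) stop("empty genome")
  if (max(.genome_seqlengths(g)) < order + 1)
    stop("genome shorter than order + 1")
  k <- order
  ncell <- 4^(k + 1)
  counts <- numeric(ncell)
  marg <- numeric(4L)
  usable <- 0
  for (si in seq_along(g)) {
    codes <- .encode_dna(as.character(g[[si]]))
    if (!is.null(mask)) {
      mm <- mask[as.character(seqnames(mask)) == names(g)[si]]
      if (length(mm) > 0) {
        for (r in seq_along(mm)) {
          lo <- max(1L, start(mm)[r]); hi <- min(length(codes), end(mm)[r])
          if (lo <= hi) codes[lo:hi] <- NA_integer_
        }
      }
    }
    for (cd in list(codes, 3L - rev(codes))) {     # both strands
      ok <- !is.na(cd)
      marg <- marg + tabulate(cd[ok] + 1L, nbins = 4L)
      ctx <- .context_index(cd, k)
      idx <- ctx + 4^k * cd               # 0-based cell index
      idx <- idx[!is.na(idx)]
      counts <- counts + tabulate(idx + 1L, nbins = ncell)
      usable <- usable + length(idx)
    }
  }
  if (usable == 0 && k > 0)
    stop("no usable (order+1)-mers in genome after masking")
  counts <- matrix(counts + 1, nrow = 4^k, ncol = 4L)   # add-one pseudocount
  trans <- counts / rowSums(counts)
  marg <- (marg + 1) / sum(marg + 1)
  markov_background(trans, marg, order = k)
}

# per-base log conditional probability under the background.  NA at non-ACGT
# positions; where the upstream context is incomplete (sequence start, N run)
# the marginal nucleotide probability is used instead.
.bg_logprob <- function(codes, bg) {
  n <- length(codes)
  k <- bg$order
  lb <- rep(NA_real_, n)
  code_ok <- !is.na(codes)
  lt <- log(bg$trans)
  if (k == 0L) {
    lb[code_ok] <- lt[1L, codes[code_ok] + 1L]
    return(lb)
  }
  ctx <- .context_index(codes, k)
  use_ctx <- !is.na(ctx) & code_ok
  ltv <- as.vector(lt)                       # column-major: [ctx+1, base+1]
  lb[use_ctx] <- ltv[ctx[use_ctx] + 4^k * codes[use_ctx] + 1]
  fb <- code_ok & !use_ctx
  lb[fb] <- log(bg$marginal)[codes[fb] + 1L]
  lb
}

# log LR for every window start on one oriented code vector; NA where the
# window touches a non-ACGT base
.scan_codes <- function(codes, lpm, bg) {
  n <- length(codes)
  L <- nrow(lpm)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  S <- rep(0, nw)
  for (o in seq_len(L))
    S <- S + lpm[o, ][codes[o:(nw + o - 1L)] + 1L]
  lb <- .bg_logprob(codes, bg)
  lb0 <- ifelse(is.na(lb), 0, lb)
  cs <- c(0, cumsum(lb0))
  B <- cs[(L + 1L):(n + 1L)] - cs[seq_len(nw)]
  unname(S - B)                              # NA propagates from S
}

#' Scan a genome for motif sites by likelihood ratio
#'
#' Every length-L window on the requested strand(s) is scored with the
#' likelihood ratio `LR = P(window | motif) / P(window | background)`, where
#' the motif probability is the product of per-position probabilities (after
#' adding pseudocount `pseudocount` to each cell and renormalizing rows, so
#' zero cells do not forbid matches) and the background probability is the
#' Markov-chain probability of the window given its upstream genomic
#' context.  Windows containing a non-ACGT base are skipped.  Sites with
#' `LR >= lr_cutoff` are returned.
#'
#' @param genome a [Biostrings::DNAStringSet], FASTA path, or named
#'   character vector.
#' @param motif a `motif_matrix`.
#' @param background a `markov_background` (see [train_background()]).
#' @param lr_cutoff positive likelihood-ratio cutoff (default 1000, i.e.
#'   a window must be 1000 times more likely under the motif model).
#' @param strands `"both"` (default) or `"forward"`.
#' @param mask optional [GenomicRanges::GRanges]; when `mask_scan = TRUE`,
#'   windows overlapping the mask are skipped.
#' @param mask_scan apply `mask` to the scan itself (default `FALSE`: the
#'   mask is left to control-site sampling).
#' @param pseudocount probability added to every motif cell before scoring
#'   (default `1e-4`).
#' @return a [GenomicRanges::GRanges] of motif sites (1-based, inclusive
#'   coordinates), sorted by position, with metadata column `lr`.
#' @export
scan_motif <- function(genome, motif, background, lr_cutoff = 1000,
                       strands = c("both", "forward"), mask = NULL,
                       mask_scan = FALSE, pseudocount = 1e-4) {
  strands <- match.arg(strands)
  validate_motif_matrix(motif)
  if (!is.numeric(lr_cutoff) || length(lr_cutoff) != 1L ||
      is.na(lr_cutoff) || lr_cutoff <= 0)
    stop("lr_cutoff must be a single positive number")
  g <- .as_dnastringset(genome)
  L <- motif_length(motif)
  pm <- motif$probs + pseudocount
  pm <- pm / rowSums(pm)
  lpm <- log(pm)
  lcut <- log(lr_cutoff)
  out <- vector("list", length(g))
  for (si in seq_along(g)) {
    codes <- .encode_dna(as.character(g[[si]]))
    if (mask_scan && !is.null(mask)) {
      mm <- mask[as.character(seqnames(mask)) == names(g)[si]]
      for (r in seq_along(mm)) {
        lo <- max(1L, start(mm)[r]); hi <- min(length(codes), end(mm)[r])
        if (lo <= hi) codes[lo:hi] <- NA_integer_
      }
    }
    n <- length(codes)
    starts <- integer(0); strand <- character(0); llr <- numeric(0)
    fw <- .scan_codes(codes, lpm, background)
    hit <- which(!is.na(fw) & fw >= lcut)
    if (length(hit)) {
      starts <- hit; strand <- rep("+", length(hit)); llr <- fw[hit]
    }
    if (strands == "both" && n >= L) {
      rc <- 3L - rev(codes)
      rv <- .scan_codes(rc, lpm, background)
      hit <- which(!is.na(rv) & rv >= lcut)
      if (length(hit)) {
        starts <- c(starts, n - hit - L + 2L)
        strand <- c(strand, rep("-", length(hit)))
        llr <- c(llr, rv[hit])
      }
    }
    out[[si]] <- GRanges(rep(names(g)[si], length(starts)),
                         IRanges(start = starts, width = L),
                         strand = strand, lr = exp(llr))
  }
  gr <- do.call(c, out)
  GenomeInfoDb::seqlengths(gr) <- .genome_seqlengths(g)[seqlevels(gr)]
  sort(gr, ignore.strand = TRUE)
}

#' Remove overlapping motif sites, keeping the stronger one
#'
#' Greedy deduplication by descending likelihood ratio: a site is accepted
#' iff it shares no base with an already-accepted site on the same
#' chromosome (strand is ignored).  Ties on LR are broken by lower
#' coordinate, then `+` strand, making the output deterministic.
#'
#' @param sites [GenomicRanges::GRanges] with an `lr` metadata column.
#' @return deduplicated `GRanges`, sorted by coordinate.
#' @export
deduplicate_sites <- function(sites) {
  if (length(sites) < 2L) return(sites)
  if (is.null(sites$lr)) stop("sites must carry an 'lr' metadata column")
  red <- GenomicRanges::reduce(sites, ignore.strand = TRUE,
                               min.gapwidth = 0L)
  ol <- findOverlaps(sites, red, ignore.strand = TRUE)
  comp <- integer(length(sites))
  comp[queryHits(ol)] <- subjectHits(ol)
  pr <- order(-sites$lr, as.integer(seqnames(sites)), start(sites),
              as.vector(strand(sites)) != "+")
  keep <- logical(length(sites))
  by_comp <- split(pr, comp[pr])
  st_all <- start(sites); en_all <- end(sites)
  for (ids in by_comp) {
    if (length(ids) == 1L) { keep[ids] <- TRUE; next }
    acc_s <- numeric(0); acc_e <- numeric(0)
    for (i in ids) {
      s <- st_all[i]; e <- en_all[i]
      if (!any(acc_s <= e & acc_e >= s)) {
        keep[i] <- TRUE
        acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      }
    }
  }
  sort(sites[keep], ignore.strand = TRUE)
}

#' Choose an LR cutoff that yields a target number of motif sites
#'
#' Scans at `min_cutoff`, deduplicates, and returns the largest cutoff whose
#' deduplicated site count reaches `target_count`, truncating to exactly
#' `target_count` sites by descending LR (ties broken by chromosome, start,
#' then `+` strand).  If even `min_cutoff` yields fewer sites, all of them
#' are returned and the shortfall is flagged (this mirrors the situation
#' where a sparse motif cannot reach the target count at the minimum
#' recommended cutoff).
#'
#' @inheritParams scan_motif
#' @param target_count desired number of deduplicated sites (>= 1).
#' @param min_cutoff smallest admissible LR cutoff (default 100).
#' @param ... passed on to [scan_motif()].
#' @return list with `cutoff`, `sites` (coordinate-sorted `GRanges`),
#'   `shortfall` (logical) and `n` (number of sites returned).
#' @export
cutoff_for_count <- function(genome, motif, background, target_count,
                             min_cutoff = 100, ...) {
  if (!is.numeric(target_count) || target_count < 1)
    stop("target_count must be >= 1")
  target_count <- as.integer(target_count)
  raw <- scan_motif(genome, motif, background, lr_cutoff = min_cutoff, ...)
  dd <- deduplicate_sites(raw)
  if (length(dd) < target_count) {
    warning("only ", length(dd), " deduplicated sites at the minimum cutoff ",
            min_cutoff, " (target ", target_count, "); returning all")
    return(list(cutoff = min_cutoff, sites = dd, shortfall = TRUE,
                n = length(dd)))
  }
  o <- order(-dd$lr, as.integer(seqnames(dd)), start(dd),
             as.vector(strand(dd)) != "+")
  sel <- o[seq_len(target_count)]
  list(cutoff = dd$lr[o[target_count]],
       sites = sort(dd[sel], ignore.strand = TRUE),
       shortfall = FALSE,
       n = target_count)
}

#' Write motif sites as BED
#'
#' BED6 with the likelihood ratio in the score column and the motif name in
#' the name column.  Coordinates follow the BED convention (0-based,
#' half-open).
#'
#' @param sites `GRanges` with `lr` column.
#' @param path output path.
#' @param name site name (recycled).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, name = "site") {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   start = start(sites) - 1L,
                   end = end(sites),
                   name = name,
                   score = if (is.null(sites$lr)) 0 else sites$lr,
                   strand = as.character(strand(sites)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
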