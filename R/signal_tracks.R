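#' Construct a per-base or binned signal track
#'
#' A signal track stores one numeric vector per chromosome.  With
#' `binsize = 1` element `i` is the value at base `i` (1-based); with
#' `binsize = b` element `j` covers bases `(j-1)*b + 1` to `j*b`.  Positions
#' beyond the stored vectors are undefined (extraction returns `NA` there so
#' truncated windows contribute only defined positions); `NA` entries inside
#' a vector are read as 0, matching the sparse-track convention that absent
#' positions carry no signal.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param binsize bin width in bp (default 1).
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(values, binsize = 1L) {
  if (!is.list(values) || is.null(names(values)) ||
      any(!nzchar(names(values))))
    stop("values must be a named list of numeric vectors")
  values <- lapply(values, function(v) {
    v <- as.numeric(v)
    v[is.na(v)] <- 0
    v
  })
  binsize <- as.integer(binsize)
  if (binsize < 1L) stop("binsize must be >= 1")
  structure(list(values = values, binsize = binsize),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track: ", length(x$values), " chromosome(s), binsize ",
      x$binsize, "\n", sep = "")
  invisible(x)
}

#' Chromosome lengths covered by a track (bp)
#' @param track a `signal_track`.
#' @return named integer vector.
#' @export
track_lengths <- function(track) {
  setNames(lengths(track$values) * track$binsize, names(track$values))
}

# values at 1-based base positions on one chromosome; NA outside the track
.track_extract <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  out <- rep(NA_real_, length(pos))
  if (is.null(v)) return(out)
  idx <- (pos - 1L) %/% track$binsize + 1L
  ok <- pos >= 1L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Read a bedGraph file into a signal track
#'
#' Interval values are painted into dense per-bin vectors.  For
#' `binsize > 1` intervals must be aligned to the bin grid.
#'
#' @param path bedGraph file (4 columns).
#' @param binsize bin width of the track (default 1).
#' @param seqlengths optional named chromosome lengths; defaults to the
#'   largest end seen per chromosome.
#' @return a `signal_track`.
#' @export
read_bedgraph <- function(path, binsize = 1L, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(unique(seqnames(gr)))
  if (is.null(seqlengths))
    seqlengths <- vapply(chroms, function(ch)
      max(end(gr[seqnames(gr) == ch])), numeric(1))
  vals <- lapply(chroms, function(ch) {
    n <- ceiling(seqlengths[[ch]] / binsize)
    v <- numeric(n)
    sub <- gr[seqnames(gr) == ch]
    s <- (start(sub) - 1L) %/% binsize + 1L
    e <- (end(sub) - 1L) %/% binsize + 1L
    for (r in seq_along(sub)) v[s[r]:e[r]] <- sub$score[r]
    v
  })
  names(vals) <- chroms
  signal_track(vals, binsize = binsize)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal values are collapsed; zero runs are omitted.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  pieces <- lapply(names(track$values), function(ch) {
    r <- S4Vectors::Rle(track$values[[ch]])
    rl <- S4Vectors::runLength(r); rv <- S4Vectors::runValue(r)
    en <- cumsum(rl); st <- en - rl + 1L
    keep <- rv != 0
    if (!any(keep)) return(NULL)
    GRanges(ch, IRanges((st[keep] - 1L) * track$binsize + 1L,
                        en[keep] * track$binsize),
            score = rv[keep])
  })
  gr <- do.call(c, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(gr)) gr <- GRanges(score = numeric(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Scale raw conservation scores to the 0-255 byte range
#'
#' Raw per-base conservation probabilities in \[0, 1\] are scaled linearly
#' so that 255 corresponds to the most conserved state.  Values are kept as
#' real numbers; the one-byte storage that motivates the 0-255 range is an
#' encoding detail, not part of the arithmetic.
#'
#' @param raw a `signal_track` with values in \[0, 1\].
#' @return a `signal_track` with values in \[0, 255\].
#' @export
scale_conservation <- function(raw) {
  stopifnot(inherits(raw, "signal_track"))
  rng <- range(unlist(lapply(raw$values, range), use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 1)
    stop("raw conservation values must lie in [0, 1]; range seen: ",
         paste(signif(rng, 4), collapse = " .. "))
  signal_track(lapply(raw$values, function(v) v * 255),
               binsize = raw$binsize)
}

#' Average signal profile around motif sites
#'
#' Each site is extended by `flank` bp on both sides and the track value at
#' each offset is averaged across sites.  Offsets are relative to the motif
#' 5' start: minus-strand sites are reversed so that offset 0 is always the
#' first motif position.  Sites truncated by chromosome edges contribute
#' only their defined positions.
#'
#' @param sites `GRanges` of equal-width motif sites.
#' @param track a `signal_track`.
#' @param flank flank size in bp (default 1000).
#' @return An object of class `profile_result`: data frame with columns
#'   `offset` (`-flank .. L+flank-1`), `mean_score` and `n` (sites
#'   contributing at that offset); attribute `n_sites`.
#' @export
conservation_profile <- function(sites, track, flank = 1000) {
  if (length(sites) == 0L) stop("empty site list")
  L <- unique(width(sites))
  if (length(L) != 1L) stop("sites must have equal width")
  offs <- seq.int(-flank, L + flank - 1L)
  acc <- numeric(length(offs))
  cnt <- numeric(length(offs))
  chr <- as.character(seqnames(sites))
  st <- start(sites); en <- end(sites)
  minus <- as.vector(strand(sites)) == "-"
  for (i in seq_along(sites)) {
    pos <- if (minus[i]) en[i] - offs else st[i] + offs
    v <- .track_extract(track, chr[i], pos)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  res <- data.frame(offset = offs,
                    mean_score = ifelse(cnt > 0, acc / cnt, NA_real_),
                    n = cnt)
  attr(res, "n_sites") <- length(sites)
  class(res) <- c("profile_result", "data.frame")
  res
}

#' Overall conservation of a motif
#'
#' The conservation score of one motif site is the average track value
#' across the positions inside the site; the overall conservation of the
#' motif is the average of these site scores across all sites.
#'
#' @param sites `GRanges` of motif sites.
#' @param track a `signal_track`.
#' @return single numeric score.
#' @export
overall_conservation <- function(sites, track) {
  if (length(sites) == 0L) stop("empty site list")
  chr <- as.character(seqnames(sites))
  st <- start(sites); en <- end(sites)
  per_site <- vapply(seq_along(sites), function(i) {
    v <- .track_extract(track, chr[i], st[i]:en[i])
    mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.nan(per_site))) stop("no site overlaps the track")
  mean(per_site, na.rm = TRUE)
}

#' Normalize DNase-seq read-count tracks and average replicates
#'
#' Each sample's counts are normalized by its total read count and
#' multiplied by the median total across samples, giving `y`; the
#' transformed value is `log2(y + 1)`.  Transformed tracks from replicate
#' samples of the same cell line are averaged.
#'
#' @param samples named list of `signal_track` objects holding raw counts
#'   (all with the same binsize and chromosomes).
#' @param cell_lines character vector parallel to `samples` giving the cell
#'   line of each replicate.
#' @return named list of `signal_track`s, one per cell line, in log2 units;
#'   attribute `totals` holds the per-sample totals.
#' @export
normalize_dhs <- function(samples, cell_lines) {
  if (length(samples) == 0L) stop("need at least one sample")
  if (length(cell_lines) != length(samples))
    stop("cell_lines must be parallel to samples")
  totals <- vapply(samples, function(s)
    sum(unlist(s$values, use.names = FALSE)), numeric(1))
  if (any(totals <= 0)) stop("every sample must have a positive total count")
  med <- stats::median(totals)
  trans <- lapply(seq_along(samples), function(i) {
    f <- med / totals[i]
    lapply(samples[[i]]$values, function(v) log2(v * f + 1))
  })
  bs <- samples[[1]]$binsize
  out <- lapply(split(seq_along(samples), cell_lines), function(idx) {
    chroms <- names(trans[[idx[1]]])
    avg <- lapply(chroms, function(ch) {
      m <- Reduce(`+`, lapply(idx, function(i) trans[[i]][[ch]]))
      m / length(idx)
    })
    names(avg) <- chroms
    signal_track(avg, binsize = bs)
  })
  attr(out, "totals") <- totals
  out
}

#' DNase I hypersensitivity signal at motif sites
#'
#' For every site a window of `window` bp centered on the site midpoint
#' (floor of `(start + end) / 2` in 0-based coordinates) is extracted and
#' the mean signal within it computed, windows at chromosome edges being
#' clipped to their defined part.
#'
#' @param sites `GRanges` of motif sites.
#' @param track a normalized DHS `signal_track` (see [normalize_dhs()]).
#' @param window window size in bp (default 200).
#' @return list with `values` (per-site means) and `mean` (group mean).
#' @export
dhs_at_sites <- function(sites, track, window = 200) {
  if (length(sites) == 0L) stop("empty site list")
  if (window < 1) stop("window must be positive")
  half <- window %/% 2L
  chr <- as.character(seqnames(sites))
  start0 <- start(sites) - 1L
  end0 <- end(sites)
  center <- (start0 + end0) %/% 2L
  vals <- vapply(seq_along(sites), function(i) {
    pos <- (center[i] - half + 1L):(center[i] + (window - half))
    v <- .track_extract(track, chr[i], pos)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  list(values = vals, mean = mean(vals, na.rm = TRUE), window = window)
}

#' Compare DHS between two groups of sites (Welch t-test)
#'
#' One-sided Welch two-sample t-test of the hypothesis that group A's mean
#' signal exceeds group B's, with Bonferroni correction over `n_tests`
#' cell lines.  When both groups are constant with equal means the test is
#' degenerate and `t = 0`, `p = 0.5` is returned.
#'
#' @param group_a,group_b numeric vectors of per-site values (length >= 2
#'   each).
#' @param n_tests number of tests being corrected for (default 1).
#' @return list with `t`, `p_one_sided`, `p_bonferroni`, group means and
#'   sizes.
#' @export
compare_dhs_groups <- function(group_a, group_b, n_tests = 1) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    d <- mean(group_a) - mean(group_b)
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 0.5 else if (d > 0) 0 else 1
  } else {
    tt <- stats::t.test(group_a, group_b, alternative = "greater",
                        var.equal = FALSE)
    t <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(t = t, p_one_sided = p, p_bonferroni = min(1, p * n_tests),
       mean_a = mean(group_a), mean_b = mean(group_b),
       n_a = length(group_a), n_b = length(group_b), n_tests = n_tests)
}
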