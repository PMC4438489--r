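# Independent brute-force reference implementations used to validate the
# vectorized code paths.  These deliberately share no code with R/.

# per-window likelihood ratios by direct probability products
oracle_scan <- function(seq_string, motif, bg, strands = "both",
                        pseudocount = 1e-4) {
  codes_of <- function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    match(v, c("A", "C", "G", "T")) - 1L   # NA for N
  }
  revcomp <- function(s) {
    v <- rev(strsplit(toupper(s), "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v], collapse = "")
  }
  pm <- motif$probs + pseudocount
  pm <- pm / rowSums(pm)
  L <- nrow(pm)
  k <- bg$order
  score_orientation <- function(s) {
    cd <- codes_of(s)
    n <- length(cd)
    if (n < L) return(data.frame(start = integer(0), lr = numeric(0)))
    out_start <- integer(0); out_lr <- numeric(0)
    for (st in seq_len(n - L + 1)) {
      w <- cd[st:(st + L - 1)]
      if (anyNA(w)) next
      pmot <- prod(pm[cbind(seq_len(L), w + 1L)])
      pbg <- 1
      for (t in st:(st + L - 1)) {
        if (k == 0) {
          pbg <- pbg * bg$trans[1, cd[t] + 1L]
        } else if (t - k >= 1 && !anyNA(cd[(t - k):(t - 1)])) {
          ctx <- paste(c("A", "C", "G", "T")[cd[(t - k):(t - 1)] + 1L],
                       collapse = "")
          pbg <- pbg * bg$trans[ctx, cd[t] + 1L]
        } else {
          pbg <- pbg * bg$marginal[cd[t] + 1L]
        }
      }
      out_start <- c(out_start, st)
      out_lr <- c(out_lr, pmot / pbg)
    }
    data.frame(start = out_start, lr = out_lr)
  }
  fw <- score_orientation(seq_string)
  fw$strand <- rep("+", nrow(fw))
  if (strands == "forward") return(fw)
  n <- nchar(seq_string)
  rv <- score_orientation(revcomp(seq_string))
  rv$start <- n - rv$start - L + 2L
  rv$strand <- rep("-", nrow(rv))
  out <- rbind(fw, rv)
  out[order(out$start, out$strand), ]
}

# O(n^2) greedy deduplication by descending LR
oracle_dedup <- function(chrom, start, end, strand, lr) {
  o <- order(-lr, chrom, start, strand != "+")
  kept <- integer(0)
  for (i in o) {
    clash <- any(chrom[kept] == chrom[i] &
                 start[kept] <= end[i] & end[kept] >= start[i])
    if (!clash) kept <- c(kept, i)
  }
  sort(kept)
}

# transitive closure of the pairwise gap relation, then size filter
oracle_clusters <- function(chrom, start, end, window, min_sites,
                            metric = "edge") {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || chrom[i] != chrom[j]) next
    gap <- if (metric == "edge") {
      if (start[j] > end[i]) start[j] - end[i] - 1
      else if (start[i] > end[j]) start[i] - end[j] - 1
      else 0
    } else {
      abs(start[j] - start[i])
    }
    adj[i, j] <- gap <= window
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  keep <- names(sizes)[sizes >= min_sites]
  m <- ifelse(comp %in% as.integer(keep), comp, NA_integer_)
  m
}

# same-partition predicate from a membership vector (cluster ids may differ)
same_partition <- function(a, b) {
  ok_na <- identical(is.na(a), is.na(b))
  if (!ok_na) return(FALSE)
  ia <- which(!is.na(a))
  all(outer(a[ia], a[ia], "==") == outer(b[ia], b[ia], "=="))
}

# per-offset profile averaging by explicit loops
oracle_profile <- function(sites_df, values_by_chrom, L, flank) {
  offs <- seq.int(-flank, L + flank - 1)
  acc <- numeric(length(offs)); cnt <- numeric(length(offs))
  for (i in seq_len(nrow(sites_df))) {
    v <- values_by_chrom[[sites_df$chrom[i]]]
    for (oi in seq_along(offs)) {
      pos <- if (sites_df$strand[i] == "-")
        sites_df$end[i] - offs[oi] else sites_df$start[i] + offs[oi]
      if (pos >= 1 && pos <= length(v)) {
        acc[oi] <- acc[oi] + v[pos]
        cnt[oi] <- cnt[oi] + 1
      }
    }
  }
  ifelse(cnt > 0, acc / cnt, NA_real_)
}

# Welch two-sample t by the textbook formula (one-sided upper tail)
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = pt(t, df, lower.tail = FALSE))
}
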