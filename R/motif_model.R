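#' @importFrom methods is
#' @importFrom stats pnorm rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

.NUCS <- c("A", "C", "G", "T")

#' Construct a position-specific probability matrix motif
#'
#' A motif is modelled as an `L x 4` matrix of probabilities, one row per
#' motif position and one column per nucleotide (order A, C, G, T).  Row `i`
#' gives the probability of observing each nucleotide at position `i` of the
#' motif.  Rows must each sum to 1; probabilities of exactly 0 are allowed
#' (the genome scanner applies its own pseudocount, so the information
#' content of the published matrix is unaffected).
#'
#' @param probs numeric matrix with 4 columns (A, C, G, T) and `L >= 1` rows.
#'   Rows summing to 1 within `1e-3` are renormalized exactly; anything
#'   further off is rejected.
#' @param name motif identifier.
#' @return An object of class `motif_matrix` with elements `name` and
#'   `probs`.
#' @examples
#' m <- motif_matrix(rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)), "toy")
#' information_content(m)
#' @export
motif_matrix <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L)
    stop("motif matrix must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L)
    stop("motif must have at least one position")
  storage.mode(probs) <- "double"
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("motif probabilities must be finite values in [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-3))
    stop("motif rows must sum to 1 (within 1e-3); row sums: ",
         paste(signif(rs, 4), collapse = ", "))
  # renormalize only when needed: keeps already-normalized matrices
  # bit-identical, so row permutation preserves IC exactly
  if (any(abs(rs - 1) > 1e-12)) probs <- probs / rs
  dimnames(probs) <- list(NULL, .NUCS)
  m <- structure(list(name = as.character(name)[1], probs = probs),
                 class = "motif_matrix")
  validate_motif_matrix(m)
  m
}

#' Validate a motif matrix
#'
#' Checks the class invariants: probabilities in \[0, 1\], every row summing
#' to 1 within `tol`, and length at least 1.
#'
#' @param m a `motif_matrix`.
#' @param tol row-sum tolerance (default `1e-6`).
#' @return `m`, invisibly; errors if invalid.
#' @export
validate_motif_matrix <- function(m, tol = 1e-6) {
  if (!inherits(m, "motif_matrix")) stop("not a motif_matrix")
  p <- m$probs
  if (!is.matrix(p) || ncol(p) != 4L || nrow(p) < 1L)
    stop("motif probabilities must be an L x 4 matrix with L >= 1")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("motif probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > tol))
    stop("motif rows must sum to 1 within ", tol)
  invisible(m)
}

#' Motif length in base pairs
#' @param m a `motif_matrix`.
#' @return integer number of positions.
#' @export
motif_length <- function(m) nrow(m$probs)

#' @export
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix '", x$name, "': ", motif_length(x), " positions\n",
      sep = "")
  ic <- information_content(x)
  cat(sprintf("  total IC %.2f bits (%.3f bits/position)\n",
              ic$total, ic$per_nucleotide))
  invisible(x)
}

#' Information content of a motif
#'
#' The information content of one motif position is two minus its Shannon
#' entropy in bits, with the convention `0 * log2(0) = 0`: a position where
#' all four nucleotides are equiprobable carries 0 bits, a position where a
#' single nucleotide has probability 1 carries the maximum of 2 bits.  The
#' total information content is the sum over positions, and the
#' per-nucleotide information content is the total divided by the motif
#' length.
#'
#' @param m a `motif_matrix`.
#' @return An object of class `motif_ic`: list with `total` (bits),
#'   `per_position` (numeric vector of length L) and `per_nucleotide`
#'   (`total / L`).
#' @export
information_content <- function(m) {
  validate_motif_matrix(m)
  p <- m$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  per_pos <- 2 + rowSums(plogp)
  structure(list(total = sum(per_pos),
                 per_position = per_pos,
                 per_nucleotide = sum(per_pos) / nrow(p)),
            class = "motif_ic")
}

#' @export
print.motif_ic <- function(x, ...) {
  cat(sprintf("total IC: %.4f bits; per-nucleotide IC: %.4f bits (%d positions)\n",
              x$total, x$per_nucleotide, length(x$per_position)))
  invisible(x)
}

#' Reverse complement of a motif
#'
#' Reverses the position order and swaps A with T and C with G within each
#' position, producing the matrix describing the same motif read on the
#' opposite strand.  Applying the operation twice returns the original
#' matrix.
#'
#' @param m a `motif_matrix`.
#' @return a `motif_matrix`.
#' @export
reverse_complement <- function(m) {
  validate_motif_matrix(m)
  # complement: A<->T, C<->G == reverse the ACGT column order
  p <- m$probs[rev(seq_len(nrow(m$probs))), c(4L, 3L, 2L, 1L), drop = FALSE]
  dimnames(p) <- list(NULL, .NUCS)
  motif_matrix(p, name = m$name)
}

#' Read a motif matrix from a text file
#'
#' The format is a header line `>name` followed by L whitespace-delimited
#' rows of four numbers in A C G T order.  Rows of probabilities must sum to
#' 1 within `1e-3` (and are renormalized exactly on read).  Integer count
#' matrices are also accepted: when every entry is a non-negative whole
#' number and the rows do not already sum to 1, each row is normalized by
#' its sum.
#'
#' @param path file path.
#' @return a `motif_matrix`.
#' @export
read_motif <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty motif file: ", path)
  name <- "motif"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop("motif file has no matrix rows: ", path)
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
    if (length(v) != 4L || anyNA(v))
      stop("malformed motif row (need 4 numeric fields): '", l, "'")
    v
  })
  p <- do.call(rbind, rows)
  if (any(p < 0)) stop("negative entries in motif file")
  rs <- rowSums(p)
  if (any(rs == 0)) stop("motif row sums to 0")
  counts <- all(abs(p - round(p)) < 1e-9) && any(abs(rs - 1) > 1e-3)
  if (counts) {
    p <- p / rs
  } else if (any(abs(rs - 1) > 1e-3)) {
    stop("motif rows must sum to 1 within 1e-3 (or be integer counts); ",
         "row sums: ", paste(signif(rs, 4), collapse = ", "))
  }
  motif_matrix(p, name = name)
}

#' Write a motif matrix to a text file
#'
#' @param m a `motif_matrix`.
#' @param path output file path.
#' @param digits decimal places written (default 6; a write/read round trip
#'   reproduces the matrix to this precision).
#' @return `path`, invisibly.
#' @export
write_motif <- function(m, path, digits = 6) {
  validate_motif_matrix(m)
  fmt <- paste0("%.", digits, "f")
  rows <- apply(m$probs, 1L, function(r) paste(sprintf(fmt, r), collapse = "\t"))
  writeLines(c(paste0(">", m$name), rows), path)
  invisible(path)
}

#' Bundled example motif
#'
#' A synthetic 21-bp position-specific probability matrix shipped with the
#' package (`inst/extdata/novel_motif_synthetic.mat`).  It is an artificial
#' stand-in constructed for testing and simulation, not a published matrix:
#' a GC-rich core (consensus `GCGCAC` followed by a degenerate N, a C/T
#' pyrimidine position and `G`) flanked by moderately specific positions.
#'
#' @return a `motif_matrix`.
#' @export
example_motif <- function() {
  read_motif(system.file("extdata", "novel_motif_synthetic.mat",
                         package = "cismotifs", mustWork = TRUE))
}
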