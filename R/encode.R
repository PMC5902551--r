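#' One-hot encode a nucleotide sequence
#'
#' Encodes each base of `seq` as a length-4 indicator vector using the fixed
#' channel order A, T, C, G: A -> (1,0,0,0), T -> (0,1,0,0), C -> (0,0,1,0),
#' G -> (0,0,0,1). `N` (used for window padding beyond contig ends) encodes
#' as the all-zero row, which keeps the input dimensionality fixed while
#' contributing no signal.
#'
#' @param seq A single nucleotide string over `{A, C, G, T, N}` (uppercase).
#' @return A `nchar(seq)` x 4 binary matrix with column names A, T, C, G.
#' @examples
#' one_hot_encode("ACGT")
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(BASES, "N"))
  if (length(bad) > 0) {
    stop_("sequence contains characters outside {A,C,G,T,N}: ",
          paste(bad, collapse = ", "))
  }
  idx <- match(chars, BASES)
  m <- matrix(0L, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, BASES))
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1L
  m
}

#' Decode a one-hot matrix back to a nucleotide string
#'
#' Inverse of [one_hot_encode()]; all-zero rows decode to `N`.
#'
#' @param mat A binary matrix with 4 columns in channel order A, T, C, G.
#' @return A nucleotide string.
#' @export
decode_one_hot <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4)
  rs <- rowSums(mat)
  if (any(!rs %in% c(0, 1))) stop_("matrix rows must sum to 0 or 1")
  idx <- max.col(mat, ties.method = "first")
  out <- ifelse(rs == 0, "N", BASES[idx])
  paste(out, collapse = "")
}

# Batch-encode equal-length window sequences into the model's input matrix:
# one row per window, columns in row-major position order
# (pos1:A,T,C,G, pos2:A,T,C,G, ...). N and padding rows stay all-zero.
encode_windows <- function(seqs) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0) return(matrix(0, nrow = 0, ncol = 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop_("all window sequences must have equal length")
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  idx <- match(chars, BASES)  # n x L positions into the 4 channels, NA for N
  if (any(is.na(idx) & chars != "N")) {
    stop_("window sequences contain characters outside {A,C,G,T,N}")
  }
  X <- matrix(0, nrow = n, ncol = 4L * L)
  keep <- which(!is.na(idx))
  rows <- ((keep - 1L) %% n) + 1L
  poss <- ((keep - 1L) %/% n) + 1L
  cols <- (poss - 1L) * 4L + idx[keep]
  X[cbind(rows, cols)] <- 1
  X
}

# Centre-anchored crop of window strings from flank `from` down to flank `to`;
# the candidate base stays at the midpoint of every scale.
crop_windows <- function(seqs, from, to) {
  stopifnot(to <= from)
  if (to == from) return(seqs)
  substr(seqs, from - to + 1L, from + to + 1L)
}
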