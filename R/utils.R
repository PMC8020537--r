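# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
BASE_BYTES <- c(65L, 67L, 71L, 84L)  # utf8 codes of A,C,G,T

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; summary tables here use the
#' conventional half-up rule (e.g. 3.1585 -> 3.159 at 3 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Codon position of each alignment column
#'
#' @param length fragment length in nucleotides.
#' @param frame_offset codon position (1, 2 or 3) of the first nucleotide.
#'   Columns in a trailing partial codon follow the same cyclic rule.
#' @return integer vector of length `length` with values in 1:3.
#' @export
codon_positions <- function(length, frame_offset = 3) {
  stopifnot(length >= 1, frame_offset %in% 1:3)
  ((frame_offset - 1 + seq_len(length) - 1) %% 3) + 1
}

# 1-based column of the first complete codon given the frame convention
translation_start <- function(frame_offset) {
  stopifnot(frame_offset %in% 1:3)
  c(1L, 3L, 2L)[frame_offset]
}

# L x n integer matrix of utf8 byte codes, one column per sequence
seq_byte_matrix <- function(sequences) {
  L <- nchar(sequences[1])
  vapply(sequences, utf8ToInt, integer(L), USE.NAMES = FALSE)
}

# Hamming distances from column i of byte matrix m to columns idx
hamming_to <- function(m, i, idx) {
  dif <- m[, idx, drop = FALSE] != m[, i]
  colSums(dif)
}

# full pairwise Hamming distance matrix (positional metric, equal lengths)
hamming_matrix <- function(sequences) {
  n <- length(sequences)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  m <- seq_byte_matrix(sequences)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    D[i, j] <- colSums(m[, j, drop = FALSE] != m[, i])
  }
  D + t(D)
}

pairwise_distance_matrix <- function(sequences, metric = c("positional", "levenshtein")) {
  metric <- match.arg(metric)
  if (metric == "levenshtein") {
    D <- utils::adist(sequences)
    dimnames(D) <- NULL
    storage.mode(D) <- "double"
    return(D)
  }
  if (length(unique(nchar(sequences))) > 1) {
    stop("positional metric requires equal-length sequences")
  }
  hamming_matrix(sequences)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
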