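# Independent reference implementations: plain loops over precomputed
# structures, no sharing of code paths with the package internals.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# literal first-fit skew-precedence denoiser over a full distance matrix
oracle_classic_denoise <- function(seqs, alpha) {
  seqs <- seqs[order(-seqs$count, seqs$sequence), ]
  n <- nrow(seqs)
  chars <- strsplit(seqs$sequence, "")
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) D[i, j] <- D[j, i] <- sum(chars[[i]] != chars[[j]])
  }
  mother <- rep(NA_integer_, n)
  cent <- integer(0)
  for (i in seq_len(n)) {
    hit <- NA_integer_
    for (cc in cent) {
      beta <- 1 / 2^(alpha * D[i, cc] + 1)
      if (seqs$count[i] / seqs$count[cc] <= beta) { hit <- cc; break }
    }
    if (is.na(hit)) cent <- c(cent, i) else mother[i] <- hit
  }
  total <- seqs$count
  for (i in rev(seq_len(n))) {
    if (!is.na(mother[i])) {
      total[mother[i]] <- total[mother[i]] + total[i]
      total[i] <- 0
    }
  }
  list(esv_ids = seqs$id[cent],
       totals = stats::setNames(total[cent], seqs$id[cent]),
       mothers = stats::setNames(seqs$id[mother[!is.na(mother)]],
                                 seqs$id[!is.na(mother)]))
}

# union-find single-linkage clustering over the full distance matrix
oracle_cluster <- function(seqs, d) {
  n <- nrow(seqs)
  chars <- strsplit(seqs$sequence, "")
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sum(chars[[i]] != chars[[j]]) <= d) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# per-column Shannon entropy averaged within codon-position classes
oracle_entropy <- function(seqs, frame_offset = 3, weights = NULL) {
  chars <- do.call(rbind, strsplit(seqs$sequence, ""))
  L <- ncol(chars)
  if (is.null(weights)) weights <- rep(1, nrow(chars))
  H <- vapply(seq_len(L), function(k) {
    f <- tapply(weights, chars[, k], sum)
    p <- f / sum(f)
    -sum(p * log(p))
  }, numeric(1))
  pos <- ((frame_offset - 1 + seq_len(L) - 1) %% 3) + 1
  vapply(1:3, function(k) mean(H[pos == k]), numeric(1))
}
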