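# Per-codon-position Shannon entropies and the entropy-ratio diagnostic.
#
# Protein-coding amplicons concentrate natural variation in third codon
# positions, while sequencing/PCR errors hit all positions uniformly. The
# per-position entropies quantify this structure; their ratio Er = e2/e3
# (least over most variable position) tracks how much error-like variation
# remains in a dataset, and drives the distance correction in the denoiser.

#' Construct an entropy profile
#'
#' @param e1,e2,e3 entropies of codon positions 1-3, each in
#'   `[0, log(4)]` in the chosen base.
#' @param frame_offset codon position (1-3) of the first nucleotide of the
#'   fragment; default 3, the usual convention for the 313-nt Leray COI
#'   fragment (the first complete codon then starts at nucleotide 2 and the
#'   fragment contains 104 whole codons).
#' @param log_base `"natural"` (default) or `"base2"`.
#' @param weighting `"unique"` (each dereplicated sequence counted once;
#'   default) or `"read_weighted"` (weighted by read count).
#' @return object of class `entropy_profile`.
#' @export
entropy_profile <- function(e1, e2, e3, frame_offset = 3,
                            log_base = c("natural", "base2"),
                            weighting = c("unique", "read_weighted")) {
  log_base <- match.arg(log_base)
  weighting <- match.arg(weighting)
  emax <- if (log_base == "natural") log(4) else 2
  e <- c(e1, e2, e3)
  if (any(is.na(e)) || any(e < 0) || any(e > emax + 1e-9)) {
    stop("entropies must lie in [0, log(4)] in the chosen base")
  }
  structure(list(e1 = e1, e2 = e2, e3 = e3, frame_offset = frame_offset,
                 log_base = log_base, weighting = weighting),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy profile (%s log, %s weighting, frame offset %d)\n",
              x$log_base, x$weighting, x$frame_offset))
  cat(sprintf("  e1 = %.4f  e2 = %.4f  e3 = %.4f\n", x$e1, x$e2, x$e3))
  invisible(x)
}

#' Per-codon-position Shannon entropy of a dataset
#'
#' For every alignment column, computes the Shannon entropy of its base
#' frequencies (optionally read-weighted), then averages columns within
#' each codon-position class given the frame convention. A dataset of
#' identical sequences therefore has zero entropy at every position.
#'
#' @param seqs dataset data.frame (equal-length sequences, non-empty).
#' @inheritParams entropy_profile
#' @return an [entropy_profile()].
#' @export
positional_entropy <- function(seqs, frame_offset = 3,
                               log_base = c("natural", "base2"),
                               weighting = c("unique", "read_weighted")) {
  log_base <- match.arg(log_base)
  weighting <- match.arg(weighting)
  validate_dataset(seqs, equal_length = TRUE, context = "entropy input")
  if (nrow(seqs) == 0) stop("cannot compute entropy of an empty dataset")
  L <- nchar(seqs$sequence[1])
  if (L < 1) stop("zero-length sequences")
  m <- seq_byte_matrix(seqs$sequence)
  w <- if (weighting == "read_weighted") as.numeric(seqs$count) else rep(1, nrow(seqs))
  cnt <- vapply(BASE_BYTES, function(b) as.vector((m == b) %*% w), numeric(L))
  p <- cnt / rowSums(cnt)
  H <- -rowSums(ifelse(p > 0, p * log(p), 0))
  if (log_base == "base2") H <- H / log(2)
  pos <- codon_positions(L, frame_offset)
  e <- vapply(1:3, function(k) {
    if (any(pos == k)) mean(H[pos == k]) else 0
  }, numeric(1))
  entropy_profile(e[1], e[2], e[3], frame_offset = frame_offset,
                  log_base = log_base, weighting = weighting)
}

#' Entropy ratio Er = e2 / e3
#'
#' The ratio of the least variable (position 2) to the most variable
#' (position 3) codon-position entropy. High Er indicates residual
#' error-like variation; Er drops as denoising stringency increases.
#'
#' @param profile an [entropy_profile()].
#' @return non-negative number.
#' @export
entropy_ratio <- function(profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  if (profile$e3 == 0) stop("entropy ratio undefined: e3 = 0")
  profile$e2 / profile$e3
}

#' Entropy-ratio curve over denoising stringencies
#'
#' Denoises the dataset at each value of `alpha` and reports the number of
#' ESVs retained and the entropy ratio of the retained set. Used to choose
#' alpha by inspection: Er falls with decreasing alpha until a plateau.
#' No automatic knee detection is performed.
#'
#' @param seqs dataset data.frame.
#' @param alphas numeric vector of stringency values.
#' @param params a [denoise_params()] object; its `alpha` is overridden by
#'   each curve point. Entropy conventions (frame, log base, weighting) are
#'   taken from `params$profile` when present, defaults otherwise.
#' @return data.frame with columns `alpha`, `n_esv`, `er`, rows ordered by
#'   decreasing alpha. `er` is `NA` when the retained set has zero
#'   third-position entropy (e.g. a single sequence).
#' @export
er_curve <- function(seqs, alphas, params = denoise_params()) {
  stopifnot(length(alphas) > 0)
  alphas <- sort(unique(alphas), decreasing = TRUE)
  fo <- if (!is.null(params$profile)) params$profile$frame_offset else 3
  lb <- if (!is.null(params$profile)) params$profile$log_base else "natural"
  wt <- if (!is.null(params$profile)) params$profile$weighting else "unique"
  rows <- lapply(alphas, function(a) {
    p <- params
    p$alpha <- a
    res <- denoise(seqs, p)
    esvs <- esv_dataset(res)
    er <- NA_real_
    if (nrow(esvs) > 0) {
      prof <- positional_entropy(esvs, frame_offset = fo, log_base = lb, weighting = wt)
      if (prof$e3 > 0) er <- prof$e2 / prof$e3
    }
    data.frame(alpha = a, n_esv = nrow(esvs), er = er)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
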