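# The denoising core: merge putatively erroneous "daughter" sequences into
# more abundant "mother" ESVs.
#
# A daughter at distance d from a more abundant mother may be merged when
# its abundance skew (daughter reads / mother reads) does not exceed the
# threshold beta(d) = 1 / 2^(alpha*d + 1). With the entropy correction, d
# is replaced by d_corr, which reweights the per-codon-position difference
# counts by the positional entropies so that third-position differences
# (naturally variable) count more than second-position differences and the
# former are preferentially kept as real haplotypes.
#
# Two processing modes:
#   classic   - sequences in decreasing abundance; each merges into the
#               FIRST already-seen centroid satisfying the skew condition
#               (abundance-skew precedence by construction).
#   two_phase - phase 1 stores every eligible mother per daughter; phase 2
#               picks one via a criterion (skew, distance, or the ratio
#               skew/beta(d)); chains daughter->mother->... resolve to the
#               terminal motherless sequence, which receives all reads.
#
# Skews are always computed from the original dereplicated counts, never
# from accumulated cluster totals, and the merge condition is non-strict
# (skew <= beta). Equal-abundance pairs can never merge (skew = 1 > 1/2).

#' Abundance-skew threshold beta(d)
#'
#' `beta(d) = 1 / 2^(alpha * d + 1)`. Accepts real-valued `d` (needed for
#' entropy-corrected distances). Vectorised over `d`.
#'
#' @param alpha positive stringency parameter; lower values merge more
#'   aggressively. Default in the package is 5, the value supported for COI.
#' @param d non-negative distance(s).
#' @return threshold skew(s) in (0, 0.5].
#' @export
beta_threshold <- function(alpha, d) {
  stopifnot(alpha > 0, all(d >= 0))
  1 / 2^(alpha * d + 1)
}

#' Count sequence differences per codon position
#'
#' @param a,b equal-length nucleotide strings.
#' @param frame_offset codon position of the first nucleotide.
#' @return named integer vector `c(d1, d2, d3)`; the sum is the Hamming
#'   distance.
#' @export
count_positional_differences <- function(a, b, frame_offset = 3) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  xa <- utf8ToInt(a)
  xb <- utf8ToInt(b)
  dif <- xa != xb
  pos <- codon_positions(length(xa), frame_offset)
  d <- vapply(1:3, function(k) sum(dif & pos == k), integer(1))
  names(d) <- c("d1", "d2", "d3")
  d
}

#' Entropy-corrected distance
#'
#' `d_corr = sum_i d_i * e_i * 3 / (e1 + e2 + e3)`. A pair differing once
#' at each codon position keeps d_corr = 3 under any profile; a single
#' difference weighs more (less) than 1 when it sits at a position of
#' above- (below-) average entropy.
#'
#' @param d1,d2,d3 non-negative difference counts per codon position.
#' @param profile an [entropy_profile()] with `e1 + e2 + e3 > 0`.
#' @return non-negative real distance.
#' @export
corrected_distance <- function(d1, d2, d3, profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  s <- profile$e1 + profile$e2 + profile$e3
  if (s <= 0) stop("total entropy is zero; corrected distance undefined")
  (d1 * profile$e1 + d2 * profile$e2 + d3 * profile$e3) * 3 / s
}

#' Denoising parameters
#'
#' @param alpha positive stringency parameter (default 5).
#' @param mode `"classic"` (first-fit, abundance-skew precedence) or
#'   `"two_phase"` (store all candidate mothers, then select).
#' @param criterion mother-selection criterion for `two_phase` mode:
#'   `"skew"` (minimum abundance skew, the classic precedence), `"distance"`
#'   (minimum d) or `"ratio"` (minimum skew/beta(d)). Ignored in classic
#'   mode.
#' @param entropy_correction reweight distances by codon-position entropy;
#'   requires the positional metric.
#' @param profile [entropy_profile()] used for the correction; when `NULL`
#'   and `entropy_correction = TRUE`, the profile is computed from the
#'   input dataset.
#' @param distance_metric `"positional"` (per-column differences on aligned
#'   equal-length sequences; default) or `"levenshtein"` (edit distance,
#'   usable on variable-length input, incompatible with the correction).
#' @return object of class `denoise_params`.
#' @export
denoise_params <- function(alpha = 5,
                           mode = c("classic", "two_phase"),
                           criterion = c("skew", "distance", "ratio"),
                           entropy_correction = FALSE,
                           profile = NULL,
                           distance_metric = c("positional", "levenshtein")) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  distance_metric <- match.arg(distance_metric)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  if (entropy_correction && distance_metric == "levenshtein") {
    stop("entropy correction requires the positional metric ",
         "(codon positions of differences must be tracked)")
  }
  if (!is.null(profile) && !inherits(profile, "entropy_profile")) {
    stop("profile must be an entropy_profile")
  }
  structure(list(alpha = alpha, mode = mode, criterion = criterion,
                 entropy_correction = entropy_correction, profile = profile,
                 distance_metric = distance_metric),
            class = "denoise_params")
}

#' Distance between two sequences under the configured metric
#'
#' @param a,b nucleotide strings.
#' @param params a [denoise_params()]; with `entropy_correction` the
#'   profile must be supplied in `params$profile`.
#' @return non-negative real.
#' @export
pair_distance <- function(a, b, params = denoise_params()) {
  if (params$distance_metric == "levenshtein") {
    return(as.numeric(utils::adist(a, b)))
  }
  d <- count_positional_differences(a, b,
    frame_offset = if (!is.null(params$profile)) params$profile$frame_offset else 3)
  if (params$entropy_correction) {
    if (is.null(params$profile)) stop("entropy correction requires a profile")
    unname(corrected_distance(d[1], d[2], d[3], params$profile))
  } else {
    as.numeric(sum(d))
  }
}

#' Select one mother among stored candidates
#'
#' @param candidates data.frame of merge candidates with columns
#'   `mother_id`, `mother_count`, `mother_sequence`, `d`, `skew`, `ratio`
#'   (skew / beta(d); at most 1 for a valid candidate).
#' @param criterion `"skew"`, `"distance"` or `"ratio"` (minimised).
#'   Ties break towards the larger mother abundance, then the
#'   lexicographically smaller mother sequence.
#' @return the selected candidate row.
#' @export
select_mother <- function(candidates, criterion = c("skew", "distance", "ratio")) {
  criterion <- match.arg(criterion)
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("empty candidate list")
  }
  val <- switch(criterion,
                skew = candidates$skew,
                distance = candidates$d,
                ratio = candidates$ratio)
  ord <- order(val, -candidates$mother_count, candidates$mother_sequence)
  candidates[ord[1], , drop = FALSE]
}

#' Denoise a dereplicated dataset
#'
#' @param seqs dataset data.frame (dereplicated; equal-length sequences for
#'   the positional metric).
#' @param params a [denoise_params()].
#' @return object of class `denoise_result` with components:
#'   \describe{
#'     \item{esvs}{data.frame of retained ESVs: `id`, `sequence`, `count`
#'       (original reads of the centroid), `total_reads` (accumulated),
#'       `n_members`; canonical order (total reads desc, then sequence).}
#'     \item{members}{named list mapping each ESV id to the ids of all
#'       sequences it absorbed (centroid first).}
#'     \item{merge_map}{data.frame `daughter_id`, `mother_id` (immediate
#'       mother), `d`, `skew`, `criterion_value`.}
#'     \item{params}{the parameters used (with the realised profile).}
#'   }
#'   Reads are conserved: `sum(total_reads) == sum(seqs$count)`.
#' @export
denoise <- function(seqs, params = denoise_params()) {
  validate_dataset(seqs, equal_length = params$distance_metric == "positional",
                   context = "denoise input")
  seqs <- canonical_sort(seqs)
  n <- nrow(seqs)
  if (n == 0) {
    return(structure(list(
      esvs = data.frame(id = character(), sequence = character(),
                        count = integer(), total_reads = integer(),
                        n_members = integer()),
      members = list(),
      merge_map = empty_merge_map(),
      params = params), class = "denoise_result"))
  }
  counts <- as.numeric(seqs$count)
  positional <- params$distance_metric == "positional"
  wcol <- NULL
  if (params$entropy_correction) {
    prof <- params$profile %||% positional_entropy(seqs)
    s <- prof$e1 + prof$e2 + prof$e3
    if (s <= 0) stop("entropy correction requires e1 + e2 + e3 > 0")
    params$profile <- prof
    L <- nchar(seqs$sequence[1])
    pos <- codon_positions(L, prof$frame_offset)
    wcol <- (c(prof$e1, prof$e2, prof$e3) * 3 / s)[pos]
  }
  m <- if (positional) seq_byte_matrix(seqs$sequence) else NULL

  dist_to <- function(i, idx) {
    if (!positional) {
      return(as.numeric(utils::adist(seqs$sequence[idx], seqs$sequence[i])))
    }
    dif <- m[, idx, drop = FALSE] != m[, i]
    if (is.null(wcol)) colSums(dif) else colSums(dif * wcol)
  }

  mother <- rep(NA_integer_, n)
  mm_d <- mm_skew <- mm_val <- rep(NA_real_, n)

  if (params$mode == "classic") {
    cent <- integer(0)
    for (i in seq_len(n)) {
      hit <- NA_integer_
      hd <- NA_real_
      if (length(cent)) {
        dd <- dist_to(i, cent)
        sk <- counts[i] / counts[cent]
        w <- which(sk <= beta_threshold(params$alpha, dd))
        if (length(w)) {
          hit <- cent[w[1]]
          hd <- dd[w[1]]
        }
      }
      if (is.na(hit)) {
        cent <- c(cent, i)  # processing order is decreasing abundance
      } else {
        mother[i] <- hit
        mm_d[i] <- hd
        mm_skew[i] <- counts[i] / counts[hit]
        mm_val[i] <- mm_skew[i]  # classic = skew precedence
      }
    }
  } else {
    for (i in seq_len(n)[-1]) {
      prev <- which(counts[seq_len(i - 1)] > counts[i])
      if (!length(prev)) next
      dd <- dist_to(i, prev)
      sk <- counts[i] / counts[prev]
      bb <- beta_threshold(params$alpha, dd)
      ok <- sk <= bb
      if (!any(ok)) next
      cand <- data.frame(idx = prev[ok],
                         mother_id = seqs$id[prev[ok]],
                         mother_count = counts[prev[ok]],
                         mother_sequence = seqs$sequence[prev[ok]],
                         d = dd[ok], skew = sk[ok], ratio = sk[ok] / bb[ok],
                         stringsAsFactors = FALSE)
      sel <- select_mother(cand, params$criterion)
      mother[i] <- sel$idx
      mm_d[i] <- sel$d
      mm_skew[i] <- sel$skew
      mm_val[i] <- switch(params$criterion,
                          skew = sel$skew, distance = sel$d, ratio = sel$ratio)
    }
  }

  # chain resolution: a mother is always strictly more abundant, hence
  # earlier in canonical order, so one ascending pass reaches the terminal
  root <- seq_len(n)
  for (i in seq_len(n)) {
    if (!is.na(mother[i])) root[i] <- root[mother[i]]
  }
  total <- as.vector(rowsum(counts, root))
  roots <- sort(unique(root))
  members <- split(seqs$id, root)  # ascending index order: centroid first
  names(members) <- seqs$id[roots]
  esvs <- data.frame(id = seqs$id[roots],
                     sequence = seqs$sequence[roots],
                     count = seqs$count[roots],
                     total_reads = as.integer(total),
                     n_members = lengths(members),
                     stringsAsFactors = FALSE)
  ord <- order(-esvs$total_reads, esvs$sequence)
  esvs <- esvs[ord, , drop = FALSE]
  rownames(esvs) <- NULL
  members <- members[esvs$id]
  merged <- which(!is.na(mother))
  merge_map <- if (length(merged)) {
    data.frame(daughter_id = seqs$id[merged],
               mother_id = seqs$id[mother[merged]],
               d = mm_d[merged], skew = mm_skew[merged],
               criterion_value = mm_val[merged],
               stringsAsFactors = FALSE)
  } else {
    empty_merge_map()
  }
  structure(list(esvs = esvs, members = members, merge_map = merge_map,
                 params = params),
            class = "denoise_result")
}

empty_merge_map <- function() {
  data.frame(daughter_id = character(), mother_id = character(),
             d = numeric(), skew = numeric(), criterion_value = numeric(),
             stringsAsFactors = FALSE)
}

#' ESVs of a denoise result as a dataset
#'
#' Counts are the accumulated total reads, so the result can feed any
#' operation that takes a dataset (clustering, entropy, writing).
#'
#' @param result a `denoise_result`.
#' @return dataset data.frame `id`, `count`, `sequence`.
#' @export
esv_dataset <- function(result) {
  stopifnot(inherits(result, "denoise_result"))
  data.frame(id = result$esvs$id, count = result$esvs$total_reads,
             sequence = result$esvs$sequence, stringsAsFactors = FALSE)
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("denoise result: %d ESVs from %d input sequences (%s mode, alpha = %g%s)\n",
              nrow(x$esvs), nrow(x$esvs) + nrow(x$merge_map), x$params$mode,
              x$params$alpha,
              if (x$params$entropy_correction) ", entropy-corrected" else ""))
  cat(sprintf("  total reads: %d\n", sum(x$esvs$total_reads)))
  invisible(x)
}
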