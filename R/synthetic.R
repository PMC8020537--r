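# Seeded synthetic COI-like communities with ground truth.
#
# The generator emulates the structure of a protein-coding metabarcoding
# dataset: several species with divergent centroid haplotypes, intra-species
# haplotypes varying preferentially at third codon positions, skewed
# (lognormal) species abundances, uniform per-base error injection across
# positions, and dereplication. All haplotypes are kept translatable (no
# stop codons, conserved residues intact), so the error benchmark flags
# exactly the injected noise. A single seed fixes the full output.

#' Simulation parameters
#'
#' @param n_species number of species.
#' @param fragment_length amplicon length in nt (default 313).
#' @param frame_offset codon position of the first nucleotide (default 3).
#' @param inter_species_divergence expected substitutions separating a
#'   species centroid from the common ancestral sequence; also the minimum
#'   pairwise centroid distance enforced by rejection sampling (default 30,
#'   ~10% of the Leray fragment).
#' @param haplotypes_per_species expected haplotypes per species (>= 1);
#'   drawn as 1 + Poisson(mean - 1).
#' @param intra_species_substitutions expected substitutions separating a
#'   non-centroid haplotype from its species centroid (>= 1).
#' @param codon_position_weights probabilities of placing a *natural*
#'   substitution at codon positions 1-3. The default (0.15, 0.10, 0.75)
#'   favours third positions; it is a modelling choice, not an empirical
#'   estimate.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of the
#'   species abundance distribution.
#' @param within_species_skew fraction of a species' reads carried by its
#'   dominant haplotype; the remainder decays geometrically over the other
#'   haplotypes.
#' @param error_rate per-base substitution probability of a read, uniform
#'   across positions (errors ignore codon structure).
#' @param n_reads total reads in the community.
#' @param seed integer seed fixing the full output.
#' @param denoise_safe when `TRUE`, haplotype abundances are drawn within a
#'   factor < 2 of each other, so every true-haplotype pair has abundance
#'   skew > 1/2 >= beta(d) and no true haplotype is merge-eligible at any
#'   alpha, metric or correction.
#' @param genetic_code NCBI translation table used to keep haplotypes
#'   coding (default 5, invertebrate mitochondrial).
#' @param n_conserved number of conserved amino-acid positions planted in
#'   every species (default 5).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_species = 50, fragment_length = 313, frame_offset = 3,
                       inter_species_divergence = 30,
                       haplotypes_per_species = 5,
                       intra_species_substitutions = 2,
                       codon_position_weights = c(0.15, 0.10, 0.75),
                       abundance_meanlog = 0, abundance_sdlog = 1,
                       within_species_skew = 0.6,
                       error_rate = 0, n_reads = 1e5, seed = 1,
                       denoise_safe = FALSE, genetic_code = 5,
                       n_conserved = 5) {
  stopifnot(n_species >= 1, fragment_length >= 9, frame_offset %in% 1:3,
            haplotypes_per_species >= 1, intra_species_substitutions >= 1,
            length(codon_position_weights) == 3,
            all(codon_position_weights >= 0),
            abs(sum(codon_position_weights) - 1) < 1e-8,
            error_rate >= 0, error_rate <= 1,
            within_species_skew > 0, within_species_skew <= 1,
            n_reads >= 1, n_conserved >= 0)
  if (inter_species_divergence > fragment_length / 2) {
    stop("inter-species divergence infeasible for this fragment length")
  }
  structure(as.list(environment()), class = "sim_params")
}

# substitute k positions of seqstr, sampling columns by codon-position
# weight, rejecting substitutions that create a stop codon or alter a
# conserved residue; returns the mutated string
safe_mutate <- function(seqstr, k, weights, frame_offset, code, conserved_idx,
                        max_tries = 2000) {
  x <- strsplit(seqstr, "")[[1]]
  L <- length(x)
  pos <- codon_positions(L, frame_offset)
  wcol <- weights[pos]
  start <- translation_start(frame_offset)
  ncod <- (L - start + 1) %/% 3
  used <- integer(0)
  tries <- 0
  while (length(used) < k) {
    tries <- tries + 1
    if (tries > max_tries) stop("could not place substitutions under coding constraints")
    p <- sample.int(L, 1, prob = wcol)
    if (p %in% used) next
    old <- x[p]
    new <- sample(setdiff(BASES, old), 1)
    # columns outside the complete codons are unconstrained
    ci <- if (p >= start && p < start + 3 * ncod) (p - start) %/% 3 + 1 else NA
    if (!is.na(ci)) {
      cod <- x[(start + 3 * (ci - 1)):(start + 3 * ci - 1)]
      cod[(p - start) %% 3 + 1] <- new
      aa <- code[paste(cod, collapse = "")]
      if (aa == "*") next
      if (ci %in% conserved_idx) {
        old_aa <- code[paste(x[(start + 3 * (ci - 1)):(start + 3 * ci - 1)],
                             collapse = "")]
        if (aa != old_aa) next
      }
    }
    x[p] <- new
    used <- c(used, p)
  }
  paste(x, collapse = "")
}

# lookup matrix: other_bases[current base, offset 1..3] = a different base
other_bases_matrix <- function() {
  m <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  rownames(m) <- BASES
  m
}

#' Simulate a dereplicated amplicon community with ground truth
#'
#' @param params a [sim_params()].
#' @return list with:
#'   \describe{
#'     \item{seqs}{dereplicated dataset data.frame (`id`, `count`,
#'       `sequence`) in canonical order; read totals equal
#'       `params$n_reads`.}
#'     \item{truth}{list with `haplotypes` (data.frame `species_id`,
#'       `hap_id`, `sequence`, `true_count`) and `provenance` (data.frame
#'       `id`, `sequence`, `source_hap`, `species_id`, `is_error`,
#'       `count`, one row per observed unique sequence).}
#'     \item{error_config}{an [error_check_config()] matching the planted
#'       conserved residues, for the error benchmark.}
#'   }
#' @export
simulate_community <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$fragment_length
  fo <- params$frame_offset
  start <- translation_start(fo)
  ncod <- (L - start + 1) %/% 3
  code <- Biostrings::getGeneticCode(as.character(params$genetic_code))
  sense <- names(code)[code != "*"]

  # conserved amino-acid positions, identical across species
  n_cons <- min(params$n_conserved, max(ncod - 8, 0))
  cons_idx <- if (n_cons > 0) {
    unique(round(seq(5, ncod - 4, length.out = n_cons)))
  } else integer(0)

  # ancestral coding sequence
  anc <- character(L)
  if (start > 1) anc[seq_len(start - 1)] <- sample(BASES, start - 1, replace = TRUE)
  codons <- sample(sense, ncod, replace = TRUE)
  anc[start:(start + 3 * ncod - 1)] <- unlist(strsplit(codons, ""))
  tail_from <- start + 3 * ncod
  if (tail_from <= L) anc[tail_from:L] <- sample(BASES, L - tail_from + 1, replace = TRUE)
  ancestor <- paste(anc, collapse = "")
  cons_res <- vapply(cons_idx, function(ci) {
    code[substring(ancestor, start + 3 * (ci - 1), start + 3 * ci - 1)]
  }, character(1))

  cfg <- error_check_config(
    genetic_codes = unique(c(params$genetic_code, 1, 2)),
    frame_offset = fo,
    conserved_positions = data.frame(aa_index = cons_idx, allowed = cons_res,
                                     stringsAsFactors = FALSE))

  # species centroids: rejection-sampled to stay mutually distant
  centroids <- character(params$n_species)
  for (s in seq_len(params$n_species)) {
    repeat {
      k <- max(1, stats::rpois(1, params$inter_species_divergence))
      cand <- safe_mutate(ancestor, k, params$codon_position_weights, fo, code, cons_idx)
      if (s == 1) { centroids[s] <- cand; break }
      dmin <- min(vapply(centroids[seq_len(s - 1)], function(cc) {
        sum(utf8ToInt(cand) != utf8ToInt(cc))
      }, numeric(1)))
      if (dmin >= params$inter_species_divergence) { centroids[s] <- cand; break }
    }
  }

  # haplotypes per species, unique across the whole community
  hap_species <- integer(0)
  hap_seq <- character(0)
  for (s in seq_len(params$n_species)) {
    h <- 1 + stats::rpois(1, max(params$haplotypes_per_species - 1, 0))
    seqs_s <- centroids[s]
    guard <- 0
    while (length(seqs_s) < h) {
      guard <- guard + 1
      if (guard > 200) break
      k <- max(1, stats::rpois(1, params$intra_species_substitutions))
      cand <- safe_mutate(centroids[s], k, params$codon_position_weights,
                          fo, code, cons_idx)
      if (!(cand %in% c(hap_seq, seqs_s))) seqs_s <- c(seqs_s, cand)
    }
    hap_species <- c(hap_species, rep(s, length(seqs_s)))
    hap_seq <- c(hap_seq, seqs_s)
  }
  n_hap <- length(hap_seq)
  hap_id <- sprintf("sp%03d_h%02d", hap_species,
                    unlist(lapply(rle(hap_species)$lengths, seq_len)))

  # true read counts
  if (params$denoise_safe) {
    base <- params$n_reads / n_hap
    counts <- pmax(1, floor(base * stats::runif(n_hap, 0.55, 0.95)))
    rem <- params$n_reads - sum(counts)
    # distribute the remainder one read at a time to the smallest counts,
    # preserving the factor-<2 spread
    while (rem > 0) {
      take <- min(rem, n_hap)
      idx <- order(counts)[seq_len(take)]
      counts[idx] <- counts[idx] + 1
      rem <- rem - take
    }
  } else {
    sp_w <- stats::rlnorm(params$n_species, params$abundance_meanlog,
                          params$abundance_sdlog)
    sp_reads <- floor(params$n_reads * sp_w / sum(sp_w))
    counts <- numeric(n_hap)
    for (s in seq_len(params$n_species)) {
      idx <- which(hap_species == s)
      h <- length(idx)
      w <- if (h == 1) 1 else {
        rest <- 0.55^(seq_len(h - 1) - 1)
        c(params$within_species_skew,
          (1 - params$within_species_skew) * rest / sum(rest))
      }
      counts[idx] <- pmax(1, round(sp_reads[s] * w))
    }
    counts[which.max(counts)] <- counts[which.max(counts)] +
      (params$n_reads - sum(counts))
    if (any(counts < 1)) {  # dominant adjustment can only grow; guard anyway
      stop("internal: abundance allocation failed")
    }
  }
  counts <- as.integer(counts)

  truth_h <- data.frame(species_id = hap_species, hap_id = hap_id,
                        sequence = hap_seq, true_count = counts,
                        stringsAsFactors = FALSE)

  # uniform per-base error injection, vectorised per haplotype
  other <- other_bases_matrix()
  obs_seq <- character(0); obs_cnt <- integer(0); obs_src <- integer(0)
  e <- params$error_rate
  p_any <- if (e > 0) 1 - (1 - e)^L else 0
  for (hh in seq_len(n_hap)) {
    c0 <- counts[hh]
    m_err <- if (p_any > 0) stats::rbinom(1, c0, p_any) else 0L
    clean <- c0 - m_err
    if (clean > 0) {
      obs_seq <- c(obs_seq, hap_seq[hh]); obs_cnt <- c(obs_cnt, clean)
      obs_src <- c(obs_src, hh)
    }
    if (m_err == 0) next
    p1 <- stats::dbinom(1, L, e) / p_any
    p2 <- stats::dbinom(2, L, e) / p_any
    kk <- sample(1:3, m_err, replace = TRUE,
                 prob = c(p1, p2, max(1 - p1 - p2, 0)))
    hap_chars <- strsplit(hap_seq[hh], "")[[1]]
    # single-error reads: tabulate (position, replacement) variants
    n1 <- sum(kk == 1)
    if (n1 > 0) {
      pos <- sample.int(L, n1, replace = TRUE)
      off <- sample.int(3, n1, replace = TRUE)
      key <- (pos - 1) * 3 + off
      tab <- table(key)
      kpos <- (as.integer(names(tab)) - 1) %/% 3 + 1
      koff <- (as.integer(names(tab)) - 1) %% 3 + 1
      newb <- other[cbind(match(hap_chars[kpos], BASES), koff)]
      v <- rep(hap_seq[hh], length(tab))
      substr(v, kpos, kpos) <- newb
      obs_seq <- c(obs_seq, v); obs_cnt <- c(obs_cnt, as.integer(tab))
      obs_src <- c(obs_src, rep(hh, length(tab)))
    }
    # multi-error reads (rarer): constructed read by read, appended per hap
    for (k in 2:3) {
      nk <- sum(kk == k)
      if (nk == 0) next
      v <- vapply(seq_len(nk), function(r) {
        pos <- sample.int(L, k)
        ch <- hap_chars
        for (p in pos) ch[p] <- other[match(ch[p], BASES), sample.int(3, 1)]
        paste(ch, collapse = "")
      }, character(1))
      tab <- table(v)
      obs_seq <- c(obs_seq, names(tab))
      obs_cnt <- c(obs_cnt, as.integer(tab))
      obs_src <- c(obs_src, rep(hh, length(tab)))
    }
  }

  # dereplicate: merge identical observed sequences (error collisions and
  # errors landing on another true haplotype included)
  agg_cnt <- rowsum(obs_cnt, obs_seq)
  uniq <- rownames(agg_cnt)
  # provenance: dominant contributing haplotype per unique sequence
  o <- order(-obs_cnt)
  first <- o[!duplicated(obs_seq[o])]
  src_hap <- obs_src[first][match(uniq, obs_seq[first])]
  is_err <- !(uniq %in% hap_seq)
  ds <- canonical_sort(data.frame(id = NA_character_, count = as.integer(agg_cnt),
                                  sequence = uniq, stringsAsFactors = FALSE))
  ds$id <- sprintf("obs_%05d", seq_len(nrow(ds)))
  prov_ord <- match(ds$sequence, uniq)
  provenance <- data.frame(id = ds$id, sequence = ds$sequence,
                           source_hap = hap_id[src_hap[prov_ord]],
                           species_id = hap_species[src_hap[prov_ord]],
                           is_error = is_err[prov_ord], count = ds$count,
                           stringsAsFactors = FALSE)
  stopifnot(sum(ds$count) == params$n_reads)
  list(seqs = ds,
       truth = list(haplotypes = truth_h, provenance = provenance,
                    params = params),
       error_config = cfg)
}

#' Score recovery of the simulated ground truth
#'
#' @param result a `denoise_result` or a dataset data.frame of retained
#'   sequences.
#' @param truth the `truth` component of [simulate_community()].
#' @param motus optional `motu_set` built on the retained sequences; when
#'   supplied, species-level MOTU recall is also reported.
#' @return list with `recall` (fraction of true haplotypes recovered
#'   verbatim), `precision` (fraction of retained sequences that are true
#'   haplotypes; `NA` when nothing was retained) and `motu_recall`
#'   (fraction of species whose haplotypes land in a single MOTU containing
#'   no other species' sequences; `NA` when `motus` is absent).
#' @export
score_recovery <- function(result, truth, motus = NULL) {
  got <- if (inherits(result, "denoise_result")) result$esvs$sequence
         else result$sequence
  true_seqs <- truth$haplotypes$sequence[truth$haplotypes$true_count > 0]
  recall <- mean(true_seqs %in% got)
  precision <- if (length(got)) mean(got %in% true_seqs) else NA_real_
  motu_recall <- NA_real_
  if (!is.null(motus)) {
    stopifnot(inherits(motus, "motu_set"))
    sp_of_seq <- stats::setNames(truth$provenance$species_id, truth$provenance$sequence)
    ok <- vapply(sort(unique(truth$haplotypes$species_id)), function(s) {
      hs <- truth$haplotypes$sequence[truth$haplotypes$species_id == s &
                                      truth$haplotypes$true_count > 0]
      mids <- unique(motus$membership$motu_id[motus$membership$sequence %in% hs])
      if (length(mids) != 1 || length(hs) == 0) return(FALSE)
      if (!all(hs %in% motus$membership$sequence)) return(FALSE)
      members <- motus$membership$sequence[motus$membership$motu_id == mids]
      all(sp_of_seq[members] == s, na.rm = FALSE)
    }, logical(1))
    motu_recall <- mean(ok)
  }
  list(recall = recall, precision = precision, motu_recall = motu_recall)
}
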