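# Dataset comparison and quality benchmarks.
#
# Two families of checks: (1) symmetric comparison of two cleaned datasets
# (shared ESVs / MOTUs, reads carried by shared units, match indices);
# (2) intrinsic quality of a MOTU-structured dataset — a genetic-code scan
# for stop codons and substitutions at amino-acid positions conserved
# across metazoans, and the closed/open/hybrid classification of MOTUs
# against a species-level assignment table.

#' Symmetric match index between two sets
#'
#' `(N_match_A / N_A + N_match_B / N_B) / 2`, where `N_match` counts the
#' elements of one set whose key also occurs in the other. Symmetric,
#' bounded in `[0, 1]`, 1 for identical sets, 0 for disjoint ones.
#'
#' @param a,b character vectors of keys (exact sequences for ESVs,
#'   representative sequences for MOTUs). Duplicates are collapsed.
#' @return number in `[0, 1]`.
#' @export
match_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) {
    stop("match index undefined for an empty set")
  }
  shared <- length(intersect(a, b))
  (shared / length(a) + shared / length(b)) / 2
}

#' Compare two cleaned datasets at the ESV or MOTU level
#'
#' ESV identity is exact sequence equality; MOTU identity is exact equality
#' of the representative sequence. Reports shared/unshared unit counts,
#' reads carried by shared units on each side, the number of shared units
#' with identical read totals, and match indices for units and for reads.
#'
#' @param ds_a,ds_b for `level = "esv"`: dataset data.frames (or
#'   `denoise_result` objects, coerced via [esv_dataset()]); for
#'   `level = "motu"`: `motu_set` objects.
#' @param level `"esv"` or `"motu"`.
#' @return list of class `dataset_comparison`.
#' @export
compare_datasets <- function(ds_a, ds_b, level = c("esv", "motu")) {
  level <- match.arg(level)
  if (level == "esv") {
    if (inherits(ds_a, "denoise_result")) ds_a <- esv_dataset(ds_a)
    if (inherits(ds_b, "denoise_result")) ds_b <- esv_dataset(ds_b)
    key_a <- ds_a$sequence; reads_a <- ds_a$count
    key_b <- ds_b$sequence; reads_b <- ds_b$count
  } else {
    stopifnot(inherits(ds_a, "motu_set"), inherits(ds_b, "motu_set"))
    key_a <- ds_a$motus$representative_sequence; reads_a <- ds_a$motus$total_reads
    key_b <- ds_b$motus$representative_sequence; reads_b <- ds_b$motus$total_reads
  }
  mi_units <- match_index(key_a, key_b)  # errors on an empty side
  in_b <- key_a %in% key_b
  in_a <- key_b %in% key_a
  shared <- intersect(key_a, key_b)
  eq_reads <- sum(reads_a[match(shared, key_a)] == reads_b[match(shared, key_b)])
  mi_reads <- (sum(reads_a[in_b]) / sum(reads_a) +
               sum(reads_b[in_a]) / sum(reads_b)) / 2
  structure(list(
    level = level,
    n_a = length(key_a), n_b = length(key_b), n_shared = length(shared),
    reads_a = sum(reads_a), reads_b = sum(reads_b),
    reads_shared_a = sum(reads_a[in_b]), reads_shared_b = sum(reads_b[in_a]),
    n_shared_equal_reads = eq_reads,
    match_index_units = mi_units, match_index_reads = mi_reads
  ), class = "dataset_comparison")
}

#' @export
print.dataset_comparison <- function(x, ...) {
  cat(sprintf("%s-level comparison: %d vs %d units, %d shared (%d with equal reads)\n",
              x$level, x$n_a, x$n_b, x$n_shared, x$n_shared_equal_reads))
  cat(sprintf("  match index (units) = %.4f, match index (reads) = %.4f\n",
              x$match_index_units, x$match_index_reads))
  invisible(x)
}

#' Error-check configuration for the genetic-code scan
#'
#' @param genetic_codes NCBI translation table identifiers to evaluate
#'   (default: standard plus the metazoan mitochondrial variants
#'   2, 4, 5, 9, 13, 14).
#' @param frame_offset codon position of the first nucleotide (default 3).
#' @param conserved_positions data.frame with columns `aa_index` (1-based
#'   position within the translated fragment) and `allowed` (string of
#'   allowed one-letter residues, e.g. `"H"` or `"HQ"`). Required: the set
#'   of conserved metazoan residues depends on the amplified fragment and
#'   must be supplied by the caller (the synthetic community generator
#'   emits a matching configuration for its own communities).
#' @return object of class `error_check_config`.
#' @export
error_check_config <- function(genetic_codes = c(1, 2, 4, 5, 9, 13, 14),
                               frame_offset = 3,
                               conserved_positions) {
  stopifnot(length(genetic_codes) >= 1, frame_offset %in% 1:3)
  if (missing(conserved_positions) || is.null(conserved_positions)) {
    conserved_positions <- data.frame(aa_index = integer(), allowed = character(),
                                      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(conserved_positions),
            all(c("aa_index", "allowed") %in% names(conserved_positions)))
  if (nrow(conserved_positions) && any(conserved_positions$aa_index < 1)) {
    stop("conserved positions must be 1-based indices into the translation")
  }
  for (id in genetic_codes) {
    Biostrings::getGeneticCode(as.character(id))  # errors on unknown ids
  }
  structure(list(genetic_codes = as.character(genetic_codes),
                 frame_offset = frame_offset,
                 conserved_positions = conserved_positions),
            class = "error_check_config")
}

# translate equal-length sequences from the first complete codon of the
# frame; trailing partial codon ignored; returns character vector of AA
translate_frame <- function(sequences, frame_offset, code_id) {
  L <- nchar(sequences[1])
  start <- translation_start(frame_offset)
  ncod <- (L - start + 1) %/% 3
  if (ncod < 1) stop("fragment too short to translate in this frame")
  sub <- substring(sequences, start, start + 3 * ncod - 1)
  gc <- Biostrings::getGeneticCode(as.character(code_id))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(sub),
                                     genetic.code = gc))
}

#' Flag putatively erroneous ESVs by stop codons and conserved residues
#'
#' For each MOTU, every member is translated under each configured genetic
#' code; the code(s) yielding the smallest total number of stop codons over
#' the MOTU are selected (the conservative choice), and an ESV is flagged
#' erroneous only if under every selected code it shows at least one stop
#' codon or at least one mismatch at a conserved amino-acid position.
#'
#' @param motus a `motu_set` (caller-filtered to the taxa of interest;
#'   equal-length members).
#' @param config an [error_check_config()].
#' @return list with `flags` (data.frame `motu_id`, `id`, `erroneous`,
#'   `min_stops`, `min_conserved_mismatches`), `n_esvs`, `n_erroneous` and
#'   `fraction`.
#' @export
detect_erroneous_esvs <- function(motus, config) {
  stopifnot(inherits(motus, "motu_set"), inherits(config, "error_check_config"))
  mem <- motus$membership
  if (nrow(mem) == 0) {
    return(list(flags = data.frame(motu_id = character(), id = character(),
                                   erroneous = logical(), min_stops = integer(),
                                   min_conserved_mismatches = integer()),
                n_esvs = 0L, n_erroneous = 0L, fraction = NA_real_))
  }
  if (length(unique(nchar(mem$sequence))) > 1) {
    stop("error scan requires equal-length member sequences")
  }
  codes <- config$genetic_codes
  cons <- config$conserved_positions
  # translate everything once per code
  aa_by_code <- lapply(codes, function(cd) translate_frame(mem$sequence,
                                                           config$frame_offset, cd))
  names(aa_by_code) <- codes
  naa <- nchar(aa_by_code[[1]][1])
  if (nrow(cons) && any(cons$aa_index > naa)) {
    stop("conserved position beyond the translated length (", naa, " aa)")
  }
  stops <- vapply(aa_by_code, function(aa) {
    vapply(gregexpr("*", aa, fixed = TRUE),
           function(g) if (g[1] == -1) 0L else length(g), integer(1))
  }, integer(nrow(mem)))
  mism <- vapply(aa_by_code, function(aa) {
    if (!nrow(cons)) return(integer(length(aa)))
    bad <- vapply(seq_len(nrow(cons)), function(r) {
      res <- substring(aa, cons$aa_index[r], cons$aa_index[r])
      !vapply(res, grepl, logical(1), pattern = sprintf("[%s]", cons$allowed[r]))
    }, logical(length(aa)))
    if (is.null(dim(bad))) bad <- matrix(bad, nrow = length(aa))
    as.integer(rowSums(bad))
  }, integer(nrow(mem)))
  stops <- matrix(stops, nrow = nrow(mem), dimnames = list(NULL, codes))
  mism <- matrix(mism, nrow = nrow(mem), dimnames = list(NULL, codes))

  err <- logical(nrow(mem))
  min_stops <- min_mism <- integer(nrow(mem))
  for (mid in unique(mem$motu_id)) {
    rows <- which(mem$motu_id == mid)
    totals <- colSums(stops[rows, , drop = FALSE])
    sel <- codes[totals == min(totals)]
    bad <- stops[rows, sel, drop = FALSE] >= 1 | mism[rows, sel, drop = FALSE] >= 1
    err[rows] <- rowSums(bad) == length(sel)  # bad under every selected code
    min_stops[rows] <- apply(stops[rows, sel, drop = FALSE], 1, min)
    min_mism[rows] <- apply(mism[rows, sel, drop = FALSE], 1, min)
  }
  flags <- data.frame(motu_id = mem$motu_id, id = mem$id, erroneous = err,
                      min_stops = min_stops, min_conserved_mismatches = min_mism,
                      stringsAsFactors = FALSE)
  list(flags = flags, n_esvs = nrow(mem), n_erroneous = sum(err),
       fraction = sum(err) / nrow(mem))
}

#' Classify MOTUs against species-level assignments
#'
#' Assignments below `min_identity` are treated as unassigned. Categories:
#' \describe{
#'   \item{closed}{the MOTU contains all ESVs assigned to one species and
#'     only those.}
#'   \item{open}{a proper nonempty subset of one species' assigned ESVs and
#'     nothing else.}
#'   \item{hybrid}{members assigned to two or more species, or a mix of
#'     assigned and unassigned members.}
#'   \item{unassigned}{no assigned members; excluded from the
#'     closed/open/hybrid denominators.}
#' }
#'
#' @param motus a `motu_set`.
#' @param assignments data.frame with columns `esv_id`, `species`,
#'   `best_identity` (fraction in `[0, 1]`).
#' @param min_identity minimum best identity for an assignment to count
#'   (default 0.97).
#' @return list with `categories` (data.frame `motu_id`, `category`) and
#'   `counts` (named integer vector over the four categories).
#' @export
classify_motus <- function(motus, assignments, min_identity = 0.97) {
  stopifnot(inherits(motus, "motu_set"))
  need <- c("esv_id", "species", "best_identity")
  stopifnot(is.data.frame(assignments), all(need %in% names(assignments)))
  kept <- assignments[assignments$best_identity >= min_identity, , drop = FALSE]
  missing_ids <- setdiff(kept$esv_id, motus$membership$id)
  if (length(missing_ids)) {
    warning(length(missing_ids), " assigned ESV id(s) absent from all MOTUs (e.g. '",
            missing_ids[1], "')")
  }
  species_of <- stats::setNames(kept$species, kept$esv_id)
  full_sets <- split(kept$esv_id, kept$species)
  cat_of <- vapply(motus$motus$motu_id, function(mid) {
    mids <- motus$membership$id[motus$membership$motu_id == mid]
    asg <- species_of[mids[mids %in% names(species_of)]]
    if (!length(asg)) return("unassigned")
    spp <- unique(asg)
    if (length(spp) > 1) return("hybrid")
    if (length(asg) < length(mids)) return("hybrid")  # assigned + unassigned mix
    if (setequal(mids, full_sets[[spp]])) "closed" else "open"
  }, character(1))
  categories <- data.frame(motu_id = motus$motus$motu_id, category = unname(cat_of),
                           stringsAsFactors = FALSE)
  counts <- table(factor(categories$category,
                         levels = c("closed", "open", "hybrid", "unassigned")))
  list(categories = categories, counts = stats::setNames(as.integer(counts),
                                                         names(counts)))
}
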