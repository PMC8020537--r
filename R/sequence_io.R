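# Reading, writing and pre-filtering of dereplicated amplicon datasets.
#
# A dataset is a plain data.frame with columns id (character), count
# (integer reads) and sequence (uppercase ACGT string). Records are kept in
# canonical order: decreasing count, ties broken lexicographically by
# sequence, so that every downstream operation is deterministic.

#' Sort a dataset into canonical order
#'
#' Canonical order is decreasing read count, ties broken lexicographically
#' by sequence. All functions in the package emit datasets in this order.
#'
#' @param seqs dataset data.frame with columns `id`, `count`, `sequence`.
#' @return the same data.frame, reordered, row names reset.
#' @export
canonical_sort <- function(seqs) {
  seqs <- seqs[order(-seqs$count, seqs$sequence), , drop = FALSE]
  rownames(seqs) <- NULL
  seqs
}

# shared validity checks; `context` labels error messages
validate_dataset <- function(seqs, equal_length = FALSE, context = "dataset") {
  need <- c("id", "count", "sequence")
  if (!is.data.frame(seqs) || !all(need %in% names(seqs))) {
    stop(context, " must be a data.frame with columns id, count, sequence")
  }
  if (nrow(seqs) == 0) return(invisible(seqs))
  if (any(is.na(seqs$count)) || any(seqs$count < 1) ||
      any(seqs$count != floor(seqs$count))) {
    stop(context, ": counts must be integers >= 1")
  }
  bad <- grep("[^ACGT]", seqs$sequence)
  if (length(bad)) {
    stop(context, ": non-ACGT characters in record ", bad[1],
         " (id '", seqs$id[bad[1]], "')")
  }
  dup <- which(duplicated(seqs$sequence))
  if (length(dup)) {
    stop(context, " not dereplicated: duplicate sequence at record ", dup[1],
         " (id '", seqs$id[dup[1]], "')")
  }
  if (equal_length && length(unique(nchar(seqs$sequence))) > 1) {
    stop(context, ": sequences must all have the same length")
  }
  invisible(seqs)
}

#' Read a dereplicated amplicon dataset
#'
#' Supports the USEARCH-style size-annotated FASTA dialect (headers of the
#' form `id;size=N` or `id;size=N;`) and a tabular CSV with columns
#' `id,count,sequence`. Sequences are uppercased and must contain only
#' A/C/G/T; duplicate sequences (a non-dereplicated file) are an error.
#'
#' @param path input file.
#' @param format `"fasta_size"` or `"tabular"`.
#' @return dataset data.frame in canonical order (count desc, then sequence).
#' @export
read_dataset <- function(path, format = c("fasta_size", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta_size") {
    ss <- Biostrings::readDNAStringSet(path)
    heads <- names(ss)
    m <- regmatches(heads, regexec("^(.*?);size=([0-9]+);?[[:space:]]*$", heads))
    bad <- which(lengths(m) != 3L | vapply(m, function(x) length(x) == 3 && x[2] == "", FALSE))
    if (length(bad)) {
      stop("malformed size annotation in record ", bad[1], ": '", heads[bad[1]], "'")
    }
    seqs <- data.frame(
      id = vapply(m, `[`, "", 2L),
      count = as.integer(vapply(m, `[`, "", 3L)),
      sequence = toupper(as.character(ss)),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    need <- c("id", "count", "sequence")
    if (!all(need %in% names(tab))) {
      stop("tabular input must have columns id, count, sequence")
    }
    cnt <- suppressWarnings(as.integer(tab$count))
    bad <- which(is.na(cnt))
    if (length(bad)) stop("malformed count at record ", bad[1], ": '", tab$count[bad[1]], "'")
    seqs <- data.frame(id = tab$id, count = cnt,
                       sequence = toupper(tab$sequence), stringsAsFactors = FALSE)
  }
  rownames(seqs) <- NULL
  validate_dataset(seqs, context = basename(path))
  canonical_sort(seqs)
}

#' Write a dataset
#'
#' Round-trips losslessly with [read_dataset()]. FASTA headers always carry
#' the trailing semicolon form `id;size=N;`. Records are written in
#' canonical order.
#'
#' @param seqs dataset data.frame.
#' @param path output file.
#' @param format `"fasta_size"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(seqs, path, format = c("fasta_size", "tabular")) {
  format <- match.arg(format)
  validate_dataset(seqs)
  seqs <- canonical_sort(seqs)
  if (format == "fasta_size") {
    ss <- Biostrings::DNAStringSet(seqs$sequence)
    if (length(ss)) names(ss) <- paste0(seqs$id, ";size=", seqs$count, ";")
    Biostrings::writeXStringSet(ss, filepath = path)
  } else {
    utils::write.csv(seqs[, c("id", "count", "sequence")], path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Apply the standard pre-filters
#'
#' Keeps sequences of exactly `length` nucleotides with at least `minsize`
#' reads (the defaults drop off-length fragments and singletons). The
#' number of records removed by each rule is attached as attribute
#' `"removed"`.
#'
#' @param seqs dataset data.frame.
#' @param length required fragment length (default 313, the Leray COI
#'   fragment).
#' @param minsize minimum read count (default 2: singletons removed).
#' @return filtered dataset in canonical order, with attribute `removed`
#'   (named integer vector: `length`, `minsize`).
#' @export
filter_dataset <- function(seqs, length = 313L, minsize = 2L) {
  stopifnot(length >= 3, minsize >= 1)
  validate_dataset(seqs)
  ok_len <- nchar(seqs$sequence) == length
  ok_min <- seqs$count >= minsize
  out <- canonical_sort(seqs[ok_len & ok_min, , drop = FALSE])
  attr(out, "removed") <- c(length = sum(!ok_len),
                            minsize = sum(ok_len & !ok_min))
  out
}
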