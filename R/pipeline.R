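# Composition of denoising and clustering, plus dataset summary tables.

#' Run a denoise/cluster pipeline
#'
#' Composes the two cleaning steps in either order:
#' \describe{
#'   \item{denoise_then_cluster}{denoise the whole dataset, then cluster
#'     the retained ESVs (carrying their accumulated reads).}
#'   \item{cluster_then_denoise}{cluster first, then denoise independently
#'     within each MOTU — the MOTU is the natural sequence neighbourhood in
#'     which errors and their mothers co-occur. When the entropy correction
#'     is on, the profile is computed once on the whole dataset (most MOTUs
#'     are far too small for a reliable per-MOTU estimate).}
#'   \item{denoise_only / cluster_only}{a single step.}
#' }
#' Read totals are conserved through every order.
#'
#' @param seqs dataset data.frame.
#' @param order one of `"denoise_then_cluster"`, `"cluster_then_denoise"`,
#'   `"denoise_only"`, `"cluster_only"`.
#' @param params a [denoise_params()] for the denoising step(s).
#' @param d clustering distance (default 13).
#' @param metric clustering distance metric.
#' @return object of class `coi_pipeline`: list with `order`, `esvs`
#'   (dataset of retained ESVs, `NULL` for cluster_only), `motus`
#'   (`motu_set`, `NULL` for denoise_only), `denoise` (the `denoise_result`
#'   or a list of per-MOTU results), and `summary` (see
#'   [summarize_dataset()]).
#' @export
run_pipeline <- function(seqs,
                         order = c("denoise_then_cluster", "cluster_then_denoise",
                                   "denoise_only", "cluster_only"),
                         params = denoise_params(), d = 13,
                         metric = c("positional", "levenshtein")) {
  order <- match.arg(order)
  metric <- match.arg(metric)
  validate_dataset(seqs, context = "pipeline input")
  out <- list(order = order, esvs = NULL, motus = NULL, denoise = NULL)

  if (order == "denoise_only") {
    res <- denoise(seqs, params)
    out$denoise <- res
    out$esvs <- esv_dataset(res)
  } else if (order == "cluster_only") {
    out$motus <- cluster_motus(seqs, d = d, metric = metric)
  } else if (order == "denoise_then_cluster") {
    res <- denoise(seqs, params)
    out$denoise <- res
    out$esvs <- esv_dataset(res)
    out$motus <- if (nrow(out$esvs)) cluster_motus(out$esvs, d = d, metric = metric)
                 else new_motu_set(out$esvs, integer(0))
  } else {
    ms <- cluster_motus(seqs, d = d, metric = metric)
    if (params$entropy_correction && is.null(params$profile) && nrow(seqs) > 0) {
      params$profile <- positional_entropy(seqs)  # whole-dataset profile
    }
    per_motu <- lapply(ms$motus$motu_id, function(mid) {
      sub <- ms$membership[ms$membership$motu_id == mid,
                           c("id", "count", "sequence"), drop = FALSE]
      denoise(sub, params)
    })
    names(per_motu) <- ms$motus$motu_id
    out$denoise <- per_motu
    if (length(per_motu)) {
      # same components, members replaced by the denoised ESVs
      flat <- canonical_sort(do.call(rbind, lapply(seq_along(per_motu), function(k) {
        cbind(esv_dataset(per_motu[[k]]), .comp = k)
      })))
      out$esvs <- flat[, c("id", "count", "sequence")]
      out$motus <- new_motu_set(out$esvs, flat$.comp)
    } else {
      out$esvs <- data.frame(id = character(), count = integer(),
                             sequence = character(), stringsAsFactors = FALSE)
      out$motus <- ms
    }
  }
  out$summary <- summarize_pipeline(out, total_reads = sum(seqs$count))
  structure(out, class = "coi_pipeline")
}

summarize_pipeline <- function(out, total_reads) {
  n_esvs <- if (!is.null(out$esvs)) nrow(out$esvs)
            else nrow(out$motus$membership)
  if (!is.null(out$motus)) {
    summary_row(n_esvs, nrow(out$motus$motus),
                sum(out$motus$motus$n_members == 1), total_reads)
  } else {
    summary_row(n_esvs, NA_integer_, NA_integer_, total_reads)
  }
}

summary_row <- function(n_esvs, n_motus, n_single, total_reads) {
  r <- if (!is.na(n_motus) && n_motus > 0) motu_ratios(n_esvs, n_motus, total_reads)
       else list(esvs_per_motu = NA_real_, reads_per_motu = NA_real_)
  data.frame(n_esvs = n_esvs, n_motus = n_motus, n_single_esv_motus = n_single,
             esvs_per_motu = r$esvs_per_motu, reads_per_motu = r$reads_per_motu,
             total_reads = total_reads)
}

#' Per-MOTU ratio columns of a summary table
#'
#' ESVs per MOTU and reads per MOTU, rounded half-up to 3 decimals, the
#' presentation used in dataset summary tables (e.g. 60,198 ESVs in 19,058
#' MOTUs is 3.159 ESVs/MOTU).
#'
#' @param n_esvs,n_motus,total_reads dataset counts.
#' @return list with `esvs_per_motu` and `reads_per_motu`.
#' @export
motu_ratios <- function(n_esvs, n_motus, total_reads) {
  stopifnot(n_motus >= 1)
  list(esvs_per_motu = round_half_up(n_esvs / n_motus, 3),
       reads_per_motu = round_half_up(total_reads / n_motus, 3))
}

#' Percent increase between two counts
#'
#' @param from,to counts.
#' @param digits decimals of the half-up rounding (default 0).
#' @return `100 * (to - from) / from`, rounded.
#' @export
percent_increase <- function(from, to, digits = 0) {
  stopifnot(from > 0)
  round_half_up(100 * (to - from) / from, digits)
}

#' Summarise a dataset, denoise result, MOTU set or pipeline result
#'
#' Reports ESV and MOTU counts, single-ESV MOTUs, and the ESVs/MOTU and
#' reads/MOTU ratios (half-up, 3 decimals). MOTU columns are `NA` for
#' ESV-only inputs.
#'
#' @param x a dataset data.frame, `denoise_result`, `motu_set` or
#'   `coi_pipeline`.
#' @param ... unused.
#' @return one-row data.frame: `n_esvs`, `n_motus`, `n_single_esv_motus`,
#'   `esvs_per_motu`, `reads_per_motu`, `total_reads`.
#' @export
summarize_dataset <- function(x, ...) UseMethod("summarize_dataset")

#' @export
summarize_dataset.data.frame <- function(x, ...) {
  summary_row(nrow(x), NA_integer_, NA_integer_, sum(x$count))
}

#' @export
summarize_dataset.denoise_result <- function(x, ...) {
  summary_row(nrow(x$esvs), NA_integer_, NA_integer_, sum(x$esvs$total_reads))
}

#' @export
summarize_dataset.motu_set <- function(x, ...) {
  summary_row(nrow(x$membership), nrow(x$motus), sum(x$motus$n_members == 1),
              sum(x$motus$total_reads))
}

#' @export
summarize_dataset.coi_pipeline <- function(x, ...) x$summary

#' @export
print.coi_pipeline <- function(x, ...) {
  cat(sprintf("pipeline (%s)\n", x$order))
  print(x$summary)
  invisible(x)
}
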