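# fixtures are built in code; no files on disk

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# a random dereplicated dataset with unique sequences
random_dataset <- function(n, L = 60, max_count = 1000) {
  seqs <- character(0)
  while (length(seqs) < n) {
    seqs <- unique(c(seqs, replicate(n - length(seqs), random_sequence(L))))
  }
  canonical_sort(data.frame(id = sprintf("s%04d", seq_len(n)),
                            count = sample.int(max_count, n, replace = TRUE),
                            sequence = seqs, stringsAsFactors = FALSE))
}

# substitute the base at 1-based column `pos`
mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# replace with a different base at column `pos`
mutate_other <- function(seq, pos) {
  cur <- substr(seq, pos, pos)
  mutate_at(seq, pos, setdiff(c("A", "C", "G", "T"), cur)[1])
}

make_ds <- function(counts, sequences, ids = sprintf("q%02d", seq_along(counts))) {
  canonical_sort(data.frame(id = ids, count = as.integer(counts),
                            sequence = sequences, stringsAsFactors = FALSE))
}

# the entropy profile printed for a large benthic COI dataset; used as a
# representative fixed profile in correction tests
coi_profile <- function(frame_offset = 3) {
  entropy_profile(0.473, 0.227, 1.021, frame_offset = frame_offset)
}
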