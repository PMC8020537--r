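Package: coidenoise
Title: Entropy-Aware Denoising and Single-Linkage Clustering for COI Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning protein-coding amplicon (COI) metabarcoding
    datasets. Implements the UNOISE3 abundance-skew merge rule with an
    optional correction that reweights sequence distances by the Shannon
    entropy of each codon position, a two-phase mother-selection scheme with
    three precedence criteria, single-linkage MOTU clustering that retains
    all member sequences, pipeline composition in either order (denoise then
    cluster, or cluster then denoise within MOTUs), parameter-selection
    diagnostics (entropy-ratio curves, clustering-distance curves), dataset
    comparison and quality benchmarks (stop-codon and conserved-residue
    scans, closed/open/hybrid MOTU classification), and a seeded synthetic
    community generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
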