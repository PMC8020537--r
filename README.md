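# coidenoise

Denoising and clustering for protein-coding (COI) amplicon metabarcoding,
with codon-position entropy awareness.

## The problem

Metabarcoding pipelines for the 313-nt Leray fragment of COI must separate
true haplotypes from PCR/sequencing artefacts. Two steps do complementary
work and should be combined, not chosen between: **denoising** merges
putatively erroneous "daughter" sequences into their correct "mother",
yielding exact sequence variants (ESVs, a proxy for haplotypes), and
**single-linkage clustering** groups sequences into MOTUs (a proxy for
species) while retaining every member sequence, so intra-species
variation stays available for downstream analyses (haplotype diversity,
metaphylogeography).

The merge rule: a daughter at distance *d* from a more abundant mother is
merged when its abundance skew does not exceed

```
beta(d) = 1 / 2^(alpha * d + 1)
```

with stringency `alpha` (default 5, the value supported for COI). Because
COI is a coding gene, natural variation concentrates at third codon
positions while errors fall uniformly; the optional entropy correction
reweights the distance,

```
d_corr = sum_p d_p * e_p * 3 / (e1 + e2 + e3)
```

where `d_p` counts differences at codon position *p* and `e_p` is that
position's Shannon entropy. Third-position differences then weigh more
(variants kept as plausible haplotypes) and second-position differences
weigh less (merged as likely errors). A pair differing once at each
position keeps `d_corr = 3`.

The toolkit also provides: two processing modes (classic first-fit and a
two-phase mode with skew / distance / ratio mother-selection criteria and
chain resolution), the entropy-ratio diagnostic `Er = e2/e3` and its
`alpha`-selection curve, single-linkage MOTU clustering at distance `d`
(default 13 ≈ 4.15% of the fragment) with `d`-selection diagnostics,
pipeline composition in either order (denoising within MOTUs when
clustering comes first), dataset comparison (match indices, shared
ESVs/MOTUs), quality benchmarks (stop-codon and conserved-residue scans
across genetic codes; closed/open/hybrid MOTU classification), and a
seeded synthetic community generator with full ground truth.

## Worked example

Simulate a noisy 12-species community, clean it, and benchmark the result
(all numbers below are the script's actual output):

```r
library(coidenoise)

sim <- simulate_community(sim_params(n_species = 12, haplotypes_per_species = 4,
                                     n_reads = 2e5, error_rate = 5e-4, seed = 42))
reads <- filter_dataset(sim$seqs, length = 313, minsize = 2)
nrow(reads)
#> [1] 6142

prof <- positional_entropy(reads)
prof
#> entropy profile (natural log, unique weighting, frame offset 3)
#>   e1 = 0.1393  e2 = 0.1298  e3 = 0.5479
entropy_ratio(prof)
#> [1] 0.2369

er_curve(reads, alphas = c(10, 7, 5, 3, 1), denoise_params(profile = prof))
#>   alpha n_esv     er
#> 1    10  1137 0.2275
#> 2     7    68 0.1970
#> 3     5    56 0.1955
#> 4     3    50 0.1947
#> 5     1    32 0.1807

plain <- denoise(reads, denoise_params(alpha = 5))
corr  <- denoise(reads, denoise_params(alpha = 5, entropy_correction = TRUE,
                                       profile = prof))
c(plain = nrow(plain$esvs), corrected = nrow(corr$esvs))
#>     plain corrected
#>        56       451
```

The Er curve drops sharply from `alpha` 10 to 7 and levels off around 5 —
the usual basis for choosing `alpha = 5` on this marker. The plain run
recovers 56 ESVs; the entropy-corrected run additionally retains
third-position variants (451 ESVs). Scoring against the simulator's truth
(59 planted haplotypes):

```r
score_recovery(plain, sim$truth)[c("recall", "precision")]
#> $recall    [1] 0.949
#> $precision [1] 1
score_recovery(corr, sim$truth)[c("recall", "precision")]
#> $recall    [1] 0.932
#> $precision [1] 0.122
```

so at this uniform error rate the correction trades precision for
retained third-position variation. Clustering and the erroneous-ESV scan
(stop codons + planted conserved residues, genetic-code-aware):

```r
ms <- cluster_motus(esv_dataset(corr), d = 13)
summarize_dataset(ms)
#>   n_esvs n_motus n_single_esv_motus esvs_per_motu reads_per_motu total_reads
#> 1    451      12                  0        37.583       15764.42      189173

detect_erroneous_esvs(cluster_motus(reads, d = 13), sim$error_config)$fraction
#> [1] 0.0679   # raw dataset: 6.79% flagged
detect_erroneous_esvs(ms, sim$error_config)$fraction
#> [1] 0.0355   # after denoising: 3.55% flagged

compare_datasets(plain, corr, level = "esv")
#> esv-level comparison: 56 vs 451 units, 54 shared (16 with equal reads)
#>   match index (units) = 0.5420, match index (reads) = 0.9948
```

The shared ESVs carry essentially all reads (read match index 0.995), as
expected when the extra retained variants are rare.

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/coidenoise`:

```sh
Rscript inst/cli/coidenoise simulate --seed 4 --n-species 12 --out sim.fasta
Rscript inst/cli/coidenoise denoise --input sim.fasta --alpha 5 --entropy-correction --out-prefix dn
Rscript inst/cli/coidenoise cluster --input dn_esvs.fasta --d 13 --out-prefix cl
Rscript inst/cli/coidenoise pipeline --input sim.fasta --order cluster_then_denoise --out-prefix pl
```

Flags mirror a flat `key=value` config file (`--config`); flags override
the config. Identical invocations produce bit-identical outputs.

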