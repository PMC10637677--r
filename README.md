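# barcodegap

Barcoding-gap analysis and threshold-based species identification for DNA
barcode data (COI, ITS2, or any aligned marker).

DNA barcoding identifies specimens by comparing a query sequence against a
reference set of species-labelled sequences. It works when a *barcoding
gap* exists: the distribution of intraspecific distances sits clearly below
the distribution of interspecific distances, so a distance threshold *t*
can separate "same species" from "different species". `barcodegap`
implements the complete analysis a barcoding study runs to test this for a
marker and a community sample:

- **Distances.** Kimura 2-parameter distances with pairwise deletion,
  `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`, where `P` and `Q` are the
  transition- and transversion-difference proportions among comparable
  sites; plus raw p-distances. Saturated pairs are flagged, never clamped.
- **Thresholds**, three ways: local minima of a Gaussian kernel density
  over all pairwise distances (no labels needed); minimisation of the
  cumulative identification error (false negatives + false positives) over
  a threshold grid (default 0.1%–2% in 0.1% steps); and the 95% rule — the
  smallest intraspecific distance below-or-at which 95% of intraspecific
  distances fall.
- **Best-close-match identification.** Each sequence is assigned the
  species of its nearest neighbour if that neighbour lies within *t*:
  `correct`, `incorrect`, `ambiguous` (nearest-neighbour tie across
  species), or `no_id` (nothing within *t*), with per-species summaries.
- **Diversity.** Haplotype count, haplotype diversity
  `Hd = n(1 − Σpᵢ²)/(n−1)`, segregating sites `S`, and nucleotide
  diversity `π` (mean pairwise p-distance).
- **Gap tables.** Per-sequence maximum-intraspecific / minimum-
  interspecific distances and per-species mean/range tables.
- **A synthetic community generator** (star phylogeny, tunable intra- and
  interspecific divergence, transition:transversion ratio κ, optional
  shared-haplotype "overlap" regime) so the whole pipeline is testable with
  no downloads.

## Worked example

```r
library(barcodegap)

# a clean-gap community: 4 species x 10 sequences, 600 bp,
# intraspecific divergence 0.01, interspecific 0.15
sim <- simulate_community(community_spec(seed = 7))
aln <- apply_filter(sim$alignment)          # drop unknowns/outgroups/singletons
dm  <- pairwise_distance_matrix(aln, "K2P")

gap_table(dm, aln$labels)
#> gap_table: 40 sequences, 4 species
#>   max intra: mean +/- SD = 1.32% +/- 0.29%
#>   min inter: mean +/- SD = 17.05% +/- 1.43%
#>   barcoding gap present: (0.0186, 0.1530)

optimize_threshold(dm, aln$labels)
#> threshold_estimate [THRESH_OPT]
#>   value: 0.01200 (1.200%)
#>   candidates: 0.01200, 0.01300, ..., 0.02000

percentile_threshold(dm, aln$labels)
#> threshold_estimate [PERCENTILE_95]
#>   value: 0.01515 (1.515%)

best_close_match(dm, aln$labels, t = 0.05)
#> best-close-match identification at t = 0.05000 (5.000%), n = 40
#>   correct     40 (1.00)
#>   incorrect    0 (0.00)
#>   ambiguous    0 (0.00)
#>   no_id        0 (0.00)

diversity_summary(aln)
#> diversity_summary (synthetic): n = 40, L = 600
#>   haplotypes: 40, Hd = 1.000
#>   segregating sites: 260, pi = 0.1325
```

Reading: every intraspecific distance (max 1.86%) sits below every
interspecific distance (min 15.30%), so the gap exists; any threshold
inside `(0.0186, 0.1530)` — including all three estimates above — yields
100% correct identifications. In the overlap regime
(`community_spec(overlap_mode = TRUE)`) a haplotype is shared across two
species and some sequences are necessarily `ambiguous`/`incorrect` at
*every* threshold — the failure mode that makes a mitochondrial marker
unreliable for recently diverged species.

On real data, start from an aligned FASTA plus a two-column label table
(`id<TAB>species`, with `OUTGROUP`/`UNIDENTIFIED` as reserved labels) and
run the whole workflow in one call:

```r
res <- run_pipeline(run_config("coi_aligned.fasta", "coi_labels.tsv",
                               locus = "COI", trim = c(1, 632),
                               out_dir = "coi_report"))
```

which writes the distance matrix, all three threshold estimates with
diagnostics (density curve / error grid), per-sequence identifications at
each threshold, diversity JSON, the per-species gap table and a manifest
itemising every excluded sequence. A command-line front end with
`simulate` and `run` subcommands is installed at `inst/cli/barcodegap.R`.

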