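# bdptools

Identification and chromatin analysis of **bidirectional promoters (BDPs)** —
the intergenic regions between two divergently transcribed, head-to-head
genes — with the rice genome as the motivating system. The package bundles the
full analysis chain used to characterize such promoters:

- **Pair identification.** Head-to-head gene pairs are called from a GFF3
  annotation when a `-` strand gene's TSS lies left of a `+` strand gene's TSS
  on the same chromosome, no third gene's TSS falls between them, the gene
  bodies do not overlap, and the TSS distance is ≤ 1 kb. Pairs are classed by
  TSS distance: type I (0–250 bp), II (250–500 bp), III (500–1000 bp),
  boundaries assigned to the smaller class.
- **Promoter sequence features.** GC content, TATA-box presence and degenerate
  (IUPAC) motif occurrences on both strands.
- **Motif overrepresentation.** For each motif, the mean abundance X̄ over the
  n inquiry promoters is standardized against 1000 resampled, length-matched
  unidirectional-promoter (UDP) lists:

  Z = (X̄ − μ) / (σ / √n)

  with μ the background mean and σ the per-sequence standard deviation of
  abundance (estimated from the spread of the 1000 replicate-list means);
  motifs with a one-sided p < 0.05 are reported as overrepresented.
- **Coexpression modes.** Per-pair Pearson correlations (PCC) across
  expression libraries; pairs are *coexpressed* above the mean of all positive
  PCCs, *antiexpressed* below the mean of all negative PCCs, *independent* in
  between and *null* when undefined — thresholds derived from the data (or
  pinned, e.g. at the 0.38 / −0.20 of the original eleven-library rice
  matrix). Random adjacent gene duos serve as controls.
- **Chromatin metaprofiles.** TSS-anchored, orientation-aware profiles of
  normalized read counts (reads per bp per genomic window per million mapped,
  20 windows per kb) for histone-mark ChIP and MNase read midpoints;
  pair-oriented profiles place the higher-FPKM gene of each pair on the right.
  Phased-nucleosome amplitudes (the highest window downstream of the TSS) give
  percent occupancy changes between groups.
- **Statistics.** Two-sample, two-sided Kolmogorov–Smirnov tests on per-gene
  signals, and drought-responsive pair calls (both genes with fold change
  > 2, pseudocount 0.1 FPKM).
- **Synthetic data.** A first-class generator (`sim_config()`,
  `simulate_bdp_data()`) plants head-to-head pairs at controlled distances,
  promoter GC and motifs, pair correlations, drought fold changes, promoter
  NDRs and ~200 bp phased nucleosome arrays — so every stage is testable with
  known truth and no downloads.

## Worked example

```r
library(bdptools)
library(tibble)

cfg  <- sim_config(seed = 7, n_pairs = c(I = 20, II = 20, III = 20),
                   n_udp = 80, chromosome_length = 1.2e6)
sim  <- simulate_bdp_data(cfg)

pairs <- find_bidirectional_pairs(sim$genes)
dplyr::count(pairs, bdp_type)
#>   bdp_type     n
#> 1 I           20
#> 2 II          20
#> 3 III         20

cx <- coexpression_modes(sim$expression, pairs)
cx$thresholds
#> <bdp_thresholds> coexpressed > 0.746, antiexpressed < -0.592
mode_summary(cx$pairs)[1:3, ]
#>   bdp_type mode          n_pairs fraction
#> 1 I        antiexpressed       1     0.05
#> 2 I        coexpressed        14     0.7
#> 3 I        independent         5     0.25

tg   <- sim$truth$genes
anch <- tibble(chrom = "chr1", tss = tg$tss[tg$role != "udp"],
               strand = tg$strand[tg$role != "udp"])
prof <- meta_profile(sim$reads$mnase, anch)
prof
#> <bdp_profile> mnase (single): 40 windows of 50 bp over 120 loci
phased_amplitude(prof)
#> [1] 9.54
autoplot(prof)   # NDR dip over the promoter, phased peaks into the gene body
```

All 60 planted pairs are recovered with their distance classes; the derived
coexpression thresholds bracket zero and most type-I pairs come out
coexpressed (the planted majority mode); the MNase metaprofile shows the
promoter nucleosome-depleted region just upstream of the TSS and the decaying
~200 bp phased array downstream, whose tallest peak (9.54 normalized reads)
is the phased-nucleosome amplitude used for occupancy comparisons.

`run_pipeline()` chains every stage (simulate → identify → seqfeat → motifs →
coexpr → profile → stats) from a YAML or list configuration, writes one TSV
per result table plus a `manifest.json`, and is byte-reproducible under a
fixed seed.

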