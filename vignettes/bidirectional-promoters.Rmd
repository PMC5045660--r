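---
title: "Methods: identifying and profiling bidirectional promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and profiling bidirectional promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdptools)
```

# The analysis in one paragraph

A bidirectional promoter (BDP) is the intergenic stretch between the
transcription start sites (TSSs) of two genes transcribed head-to-head on
opposite strands. `bdptools` identifies such pairs from a gene annotation,
classes them by TSS distance — type I (0–250 bp), II (250–500 bp),
III (500–1000 bp) — and then asks three questions about them: what their
sequence looks like (GC, TATA boxes, overrepresented cis-regulatory motifs
against a resampled unidirectional-promoter background), how the two genes of
a pair behave across expression libraries (Pearson correlation, a four-way
expression-mode classification, drought fold-change calls), and what
chromatin sits on them (TSS-anchored metaprofiles of histone-mark ChIP and
MNase midpoints, phased-nucleosome amplitudes, two-sample Kolmogorov–Smirnov
contrasts). A synthetic-data generator plants all of these features with
known truth, so every stage is tested end to end.

# Pair identification

`find_bidirectional_pairs()` demands, for a candidate pair: opposite strands
with the `-` gene's TSS left of the `+` gene's TSS (divergent transcription);
the same chromosome; TSS distance at most 1 kb; no third gene's TSS strictly
between the two TSSs; and disjoint gene bodies, so the promoter is genuinely
intergenic. TSSs come from the `gene` records (start for `+`, end for `-`);
no isoform-level refinement is attempted because annotations differ in how
they report isoform 5' ends.

Three conventions had to be fixed where the biology alone does not decide:

* **Bin boundaries.** The class intervals are closed on the right at the
  smaller class: `[0,250]`, `(250,500]`, `(500,1000]`. This is deterministic
  and treats 1000 bp (the stated inclusive cutoff) as type III.
* **Multiple candidate partners.** A gene flanked by two eligible partners is
  paired with the nearer one; exact ties break lexicographically on gene id.
  Every gene appears in at most one pair.
* **Overlapping divergent genes** (TSSs divergent but bodies overlapping)
  are excluded: they have no intergenic promoter to analyse.

Both the unit tests and the acceptance suite check the finder against an
O(n²) brute-force oracle on randomly generated annotations (100 annotations
of 20–120 genes, overlaps and tandem arrangements allowed) and against the
generator's truth tables.

# Motif overrepresentation: the Z statistic

For a motif and an inquiry set of $n$ promoter sequences, the abundance of
the motif in a sequence is its occurrence count (both strands, overlaps
counted). Writing $\bar X$ for the mean abundance over the inquiry set, the
statistic is

$$Z = \frac{\bar X - \mu}{\sigma/\sqrt{n}},$$

where $\mu$ and $\sigma$ are the mean and the *per-sequence* standard
deviation of the motif's abundance in the background: 1000 random lists of
$n$ unidirectional promoters of the matching length class (250, 500 or
1000 bp; an inquiry set is routed to the shortest class that covers its
longest sequence). Because each background list has exactly $n$ sequences,
the standard deviation of the 1000 list means estimates $\sigma/\sqrt{n}$,
so `motif_zscore()` recovers $\sigma$ as $\mathrm{sd}(\text{list means})
\cdot \sqrt{n}$ and the statistic reduces to the classic one-sample z-score
of $\bar X$ against the resampled null. This reading is what makes the
$\sqrt n$ in the formula meaningful: with it, the test is calibrated — the
acceptance suite draws inquiry sets *from* the background pool for 200 null
motifs and observes a significant fraction statistically compatible with the
nominal 5% — whereas reading $\sigma$ as the standard deviation *of the list
means themselves* would double-count the $\sqrt n$ and reject ~40% of null
motifs. A degenerate background (every replicate identical, $\sigma = 0$)
is reported explicitly: $z = 0, p = 0.5$ if $\bar X = \mu$, otherwise
$p = 0$ with a `sigma_zero` flag.

Two open choices and their resolutions:

* **Counts, not presence.** Abundance is the occurrence count per sequence
  rather than a presence/absence indicator; counts subsume presence and are
  the natural unit for short promoters where multiple occurrences matter.
* **One-sided p, no multiplicity correction by default.** Only
  overrepresentation is of interest, and the conventional filter is a plain
  p < 0.05; `adjust = "BH"` is available but off by default.

Background lists are drawn without replacement within a list, independently
across the 1000 lists, under a caller-supplied seed.

# Coexpression modes

Per-pair Pearson correlations are computed on raw FPKM across libraries
(`log = TRUE` switches to log2(FPKM+1); raw is the default because absolute
expression values are the conventional input here). Genes with FPKM 0 in
every library, or with zero variance, make the correlation undefined and the
pair `null`. Thresholds are derived from the data — the mean of all strictly
positive PCCs and the mean of all strictly negative PCCs — because those
numbers are dataset-specific; `coexpression_thresholds(0.38, -0.20)` pins
the values reported for the original eleven-library rice matrix when exact
replication is wanted. A pair is `coexpressed` strictly above the positive
threshold, `antiexpressed` strictly below the negative one, `independent`
between them (boundaries inclusive).

Controls are genomically adjacent gene duos regardless of orientation,
excluding duos that would themselves qualify as head-to-head pairs and genes
already in a pair.

# Normalized read counts and metaprofiles

All read data enter as single-base midpoints with a library size
(`total_mapped`). The unit throughout is *reads per bp of genomic window per
million mapped reads*: an interval is tiled by equal-width, half-open
windows (20 per kb, i.e. 50 bp; a read on a boundary belongs to the
downstream window), and each window's count is divided by its width in bp
and by `total_mapped`/10⁶. "Sliding" here means tiling, not overlapping: the
windows partition the interval, which yields an exact conservation identity
— summing `value × width × total/10⁶` over windows returns the raw read
count — that the tests enforce to machine precision. Normalization makes
profiles invariant under duplicating every read and doubling the library.

`meta_profile()` averages per-locus window vectors over `[TSS − 1 kb,
TSS + 1 kb)`, reversing the vector for leftward-transcribed anchors so +x is
always downstream; anchors whose flank leaves the chromosome are dropped and
counted. `pair_profile()` renders a pair-centred view: the gene with the
higher mean FPKM anchors the right half (its downstream is +x), the
lower-FPKM gene the left half, each half being the downstream 1 kb from its
own TSS. Joining two TSS-anchored half-profiles avoids rescaling promoters
of different widths onto a common axis, which would interpolate counts;
the cost is that the promoter interior itself is not displayed on this
axis. FPKM ties break lexicographically, so the profile is deterministic.

`phased_amplitude()` is the highest window value downstream of the anchor
(the +1-nucleosome region); `occupancy_change(a, b)` is the percent change
of amplitudes, `100·(A − B)/B`. Gene-level scalars (`gene_signal()`) use
either the whole gene body or the 50 bp window 100–150 bp downstream of the
TSS, the region of the promoter-proximal peak.

# Statistics

K-S comparisons use the two-sided two-sample test with the asymptotic
p-value (no exact small-sample correction), matching the convention for
windowed count data where ties are ubiquitous; the D statistic itself is
tie-exact and is checked against a brute-force sup-difference oracle.
Drought calls compute, per gene, `(mean drought FPKM + 0.1) /
(mean control FPKM + 0.1)`; the pseudocount (0.1 FPKM) stabilizes ratios at
zero expression. A pair is called up only if *both* genes exceed the
fold-change threshold (down if both fall below its reciprocal): the
both-genes rule is the stricter reading of pair-level regulation, and
`rule = "either"` is available where a laxer call is wanted.

# What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the package is designed
around:

| parameter | default | reading |
|---|---|---|
| class distances | uniform in 1–250 / 251–500 / 501–1000 bp | type I/II/III definitions |
| promoter GC | 54 / 50 / 45% (I/II/III), 40% UDP, 43% background | GC falls with BDP size and exceeds UDP controls |
| TATA planting | 18 / 52 / 82% (I/II/III), 48% UDP | TATA content rises with BDP size; type I TATA-poor |
| libraries | 11 | the expression-matrix design |
| planted correlations | 0.9 / −0.8 / 0 by mode | coexpressed / antiexpressed / independent pairs |
| mode mix | 50 / 20 / 30% | type-I pairs are mostly coexpressed |
| library noise | SD 0.3 on log FPKM | ≈2-fold spread; keeps raw-FPKM PCC near the planted log-scale correlation |
| drought fold changes | eight pairs ×4, eight ×0.25 | planted up-/down-regulated pairs, exact ratios |
| nucleosome array | 200 bp spacing, SD 40 bp, 5 peaks, decay 0.85 | phased array into the gene body |
| NDR | flat depletion ×0.1 over the promoter interval | promoter nucleosome depletion |
| mark enrichment | per class, e.g. MNase 1.3× at BDPs | class-specific occupancy contrasts |

Noteworthy generator decisions:

* **Arrays run downstream only.** Each TSS seeds one Gaussian array into its
  gene body. In a head-to-head pair the two arrays flank the shared promoter
  from both sides, reproducing the flanking-array phenotype; emitting a
  second, upstream array per TSS would stack two arrays at every BDP and
  distort the planted per-class enrichment (the planted 1.3× contrast would
  measure ≈1.9×), making the truth tables unusable for calibration checks.
* **Flat NDR over the promoter interval.** Depletion multiplies the
  intensity by `ndr_depth` exactly between the two TSSs (or over the
  `ndr_width` bp upstream of a UDP TSS). A smooth well of fixed width was
  rejected because it bleeds into the +1 nucleosome of short type-I
  promoters and biases the recovered enrichment downward.
* **Exact drought ratios.** Drought replicates are the control replicates
  multiplied by the planted fold change, so the planted ratio is recovered
  exactly before any statistical thresholding.
* **Per-file RNG streams.** Every output draws from its own stream (`seed +
  stable index`), so adding a mark to the configuration never changes the
  annotation, the expression matrices or other marks; regeneration under the
  same seed is byte-identical on disk.

The generator does **not** model sequencing error, mappability, isoforms,
diploidy, replicate-level ChIP variability, or a realistic rice karyotype
(one synthetic chromosome stands in). Passing tests therefore demonstrate
that the *methods* recover planted structure at realistic scales and noise
levels — they do not certify genome-scale numbers on real rice data, which
additionally depend on annotation quality and alignment pipelines outside
this package's scope.

# Numerical and degenerate-input conventions

* IUPAC matching treats the pattern as degenerate and the subject as
  literal, so `N` in a sequence never matches — conservative for masked
  bases. GC content excludes `N` from numerator and denominator and warns
  on an all-ambiguous sequence.
* Match positions are 1-based; reverse-strand matches are reported at their
  forward-strand start coordinate.
* Empty promoter intervals (TSS distance ≤ 1) yield empty sequences and are
  skipped by sequence-feature routines.
* `window_counts()` demands interval length ≥ window count and a positive
  library size; fractional window widths are allowed and conserve counts.
* A zero reference amplitude makes an occupancy change undefined and is an
  explicit error, as is an all-positive (or all-negative) correlation set
  when deriving thresholds.

# Problem sizes

The test suite runs the oracle comparison on 100 random annotations of
20–120 genes; coexpression recovery on 1500 pairs (500 per planted mode)
across 11 libraries; Z-statistic calibration on 200 null motifs against a
400-promoter pool with 1000 background lists of 100; chromatin recovery on
60 type-I pairs and 120 UDP genes at 4×10⁵ MNase reads; and K-S calibration
on 1000 replicate pairs of n = 100 samples. `scripts/acceptance.R` uses a
245-pair genome (60/60/125 by class, mirroring type III as the largest
class) with 400 UDP genes on a 4 Mb chromosome. These sizes were chosen so
each statistical check has enough resolution for 3-standard-error bounds
while staying comfortably desk-scale.

# Known limitations

* The measured TATA fraction of simulated promoters slightly exceeds the
  planting rate because AT-rich promoters also contain chance TATA matches;
  the planting rates are therefore lower bounds on the realized fractions.
* Expression-mode recovery depends on the library noise level; at noise SD
  well above ~0.5 on log FPKM, raw-scale correlations of antiexpressed pairs
  compress towards zero (a property of the lognormal, not of the
  estimator) and recovery degrades.
* `select_udp_controls()` stratifies over the FPKM deciles of the
  bidirectional genes and refuses (with the decile named) when a stratum has
  too few candidates; small gene pools need either more candidates or a
  smaller multiplier.
* The pipeline's motif stage scans the full catalogue per class; with very
  large catalogues the 1000-list resampling dominates runtime — reduce
  `reps` for exploratory runs.
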