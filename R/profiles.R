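# positions (sorted or not) falling in [lo, hi] (1-based inclusive), binned
# into n half-open equal-width windows; boundary positions go to the right
# (downstream) window.
bin_positions <- function(pos, lo, hi, n) {
  len <- hi - lo + 1
  w <- len / n
  p <- pos[pos >= lo & pos <= hi]
  if (!length(p)) return(numeric(n))
  b <- pmin(floor((p - lo) / w) + 1, n)
  tabulate(b, n)
}

#' Windowed normalized read counts over an interval
#'
#' Divides the interval into `n_windows` equal-width half-open windows tiling
#' it left to right and reports, per window, reads per bp per million mapped:
#' `count / window_width / (total_mapped / 1e6)`. Reads on a window boundary
#' belong to the right (downstream) window.
#'
#' @param reads A [read_set()].
#' @param chrom,start,end Interval (1-based inclusive); length must be at
#'   least `n_windows`.
#' @param n_windows Number of windows (default 20).
#' @return Tibble with `window`, `start`, `width`, `count` and `value`
#'   (normalized reads count). The conservation identity
#'   `sum(value * width * total_mapped/1e6) == sum(count)` holds exactly.
#' @export
window_counts <- function(reads, chrom, start, end, n_windows = 20) {
  stopifnot(inherits(reads, "bdp_read_set"))
  if (reads$total_mapped <= 0) abort("zero total_mapped reads")
  len <- end - start + 1
  if (len < n_windows) abort("interval shorter than the number of windows")
  pos <- reads$midpoints$pos[reads$midpoints$chrom == chrom]
  counts <- bin_positions(pos, start, end, n_windows)
  w <- len / n_windows
  tibble(window = seq_len(n_windows),
         start = start + w * (seq_len(n_windows) - 1),
         width = w,
         count = counts,
         value = counts / w / (reads$total_mapped / 1e6))
}

new_profile <- function(df, mark, n_loci, window_width, orientation) {
  structure(df, class = c("bdp_profile", class(tibble())),
            mark = mark, n_loci = n_loci, window_width = window_width,
            orientation = orientation)
}

#' TSS-anchored metaprofile of normalized read counts
#'
#' For each anchor (a TSS and its transcription direction) the flanking
#' `[-flank, +flank)` region is divided into equal windows, counts are
#' normalized to reads per bp per million mapped, the window vector is
#' reversed for leftward-transcribed anchors so that positive x always points
#' downstream, and windows are averaged over anchors.
#'
#' @param reads A [read_set()].
#' @param anchors Tibble with `chrom`, `tss` and `strand` (`+`/`-`,
#'   transcription direction).
#' @param flank Flank size in bp on each side of the TSS (default 1000).
#' @param n_windows_per_kb Windows per 1000 bp (default 20, i.e. 50 bp).
#' @param chrom_sizes Optional named vector of chromosome lengths; anchors
#'   whose flanks leave the chromosome are dropped (count reported in the
#'   `n_dropped` attribute).
#' @return Tibble of class `bdp_profile`: `window_center` (bp relative to the
#'   TSS, negative = upstream), `value` (mean normalized reads count),
#'   `n_loci`.
#' @export
meta_profile <- function(reads, anchors, flank = 1000, n_windows_per_kb = 20,
                         chrom_sizes = NULL) {
  stopifnot(inherits(reads, "bdp_read_set"), nrow(anchors) >= 1)
  n <- as.integer(round(2 * flank * n_windows_per_kb / 1000))
  w <- 2 * flank / n
  keep <- rep(TRUE, nrow(anchors))
  keep <- keep & (anchors$tss - flank >= 1)
  if (!is.null(chrom_sizes))
    keep <- keep & (anchors$tss + flank - 1 <=
                      unname(chrom_sizes[anchors$chrom]))
  dropped <- sum(!keep)
  anchors <- anchors[keep, ]
  if (!nrow(anchors)) abort("no anchor with a complete flanking window")
  acc <- numeric(n)
  bychrom <- split(seq_len(nrow(anchors)), anchors$chrom)
  for (ch in names(bychrom)) {
    pos <- sort(reads$midpoints$pos[reads$midpoints$chrom == ch])
    for (i in bychrom[[ch]]) {
      lo <- anchors$tss[i] - flank
      v <- bin_positions(pos, lo, lo + 2 * flank - 1, n)
      if (anchors$strand[i] == "-") v <- rev(v)
      acc <- acc + v
    }
  }
  values <- (acc / nrow(anchors)) / w / (reads$total_mapped / 1e6)
  out <- new_profile(
    tibble(window_center = -flank + w * (seq_len(n) - 0.5),
           value = values, n_loci = nrow(anchors)),
    mark = reads$mark, n_loci = nrow(anchors), window_width = w,
    orientation = "single")
  attr(out, "n_dropped") <- dropped
  out
}

#' Orientation-aware profile across bidirectional pairs
#'
#' For each pair, the gene with the higher mean FPKM anchors the right side
#' (its transcription direction is +x) and the lower-FPKM gene the left side
#' (its direction is -x): each half is the downstream `flank` bp from the
#' respective TSS, so the profile is symmetric under swapping the two genes'
#' expression. FPKM ties are broken towards the lexicographically smaller
#' gene id on the right.
#'
#' @param reads A [read_set()].
#' @param pairs Pairs from [find_bidirectional_pairs()].
#' @param expression Expression tibble covering all pair genes.
#' @param flank Half-width in bp (default 1000).
#' @param n_windows_per_kb Windows per 1000 bp (default 20).
#' @return Tibble of class `bdp_profile` with `window_center` in
#'   `[-flank, flank]` (negative = downstream of the lower-FPKM gene).
#' @export
pair_profile <- function(reads, pairs, expression, flank = 1000,
                         n_windows_per_kb = 20) {
  stopifnot(nrow(pairs) >= 1)
  fpkm <- expression_means(expression)
  fp <- setNames(fpkm$mean_fpkm, fpkm$gene_id)
  missing <- setdiff(c(pairs$minus_gene, pairs$plus_gene), names(fp))
  if (length(missing))
    abort(paste0("expression missing for gene(s): ",
                 paste(missing, collapse = ", ")))
  tss <- setNames(c(pairs$tss_minus, pairs$tss_plus),
                  c(pairs$minus_gene, pairs$plus_gene))
  strand <- setNames(rep(c("-", "+"), each = nrow(pairs)),
                     c(pairs$minus_gene, pairs$plus_gene))

  hi_is_minus <- fp[pairs$minus_gene] > fp[pairs$plus_gene] |
    (fp[pairs$minus_gene] == fp[pairs$plus_gene] &
       pairs$minus_gene < pairs$plus_gene)
  hi <- ifelse(hi_is_minus, pairs$minus_gene, pairs$plus_gene)
  lo <- ifelse(hi_is_minus, pairs$plus_gene, pairs$minus_gene)

  half <- function(gene_ids) {
    n <- as.integer(round(flank * n_windows_per_kb / 1000))
    acc <- numeric(n)
    for (ch in unique(pairs$chrom)) {
      pos <- sort(reads$midpoints$pos[reads$midpoints$chrom == ch])
      for (gid in gene_ids[pairs$chrom == ch]) {
        t <- tss[gid]
        if (strand[gid] == "+") {
          acc <- acc + bin_positions(pos, t, t + flank - 1, n)
        } else {
          acc <- acc + rev(bin_positions(pos, t - flank + 1, t, n))
        }
      }
    }
    (acc / length(gene_ids)) / (flank / n) / (reads$total_mapped / 1e6)
  }
  right <- half(hi)
  left <- half(lo)
  n <- length(right)
  w <- flank / n
  new_profile(
    tibble(window_center = c(-rev(w * (seq_len(n) - 0.5)), w * (seq_len(n) - 0.5)),
           value = c(rev(left), right), n_loci = nrow(pairs)),
    mark = reads$mark, n_loci = nrow(pairs), window_width = w,
    orientation = "pair")
}

#' Normalized read count of one gene
#'
#' `scope = "gene_body"`: reads in the gene body per bp per million mapped.
#' `scope = "peak_window"`: the same normalization over the 50 bp window 100
#' to 150 bp downstream of the TSS (in the transcription direction), the
#' region of the highest promoter-proximal peak.
#'
#' @param reads A [read_set()].
#' @param genes Tibble of gene models (vectorized).
#' @param scope `"gene_body"` or `"peak_window"`.
#' @return Tibble with `gene_id`, `mark`, `scope`, `value`.
#' @export
gene_signal <- function(reads, genes, scope = c("gene_body", "peak_window")) {
  scope <- match.arg(scope)
  g <- gene_tss(genes)
  per_m <- reads$total_mapped / 1e6
  vals <- vapply(seq_len(nrow(g)), function(i) {
    if (scope == "gene_body") {
      lo <- g$start[i]; hi <- g$end[i]
    } else if (g$strand[i] == "+") {
      lo <- g$tss[i] + 100; hi <- g$tss[i] + 149
    } else {
      lo <- g$tss[i] - 149; hi <- g$tss[i] - 100
    }
    if (hi < lo) abort("zero-length signal window")
    pos <- reads$midpoints$pos[reads$midpoints$chrom == g$chrom[i]]
    sum(pos >= lo & pos <= hi) / (hi - lo + 1) / per_m
  }, numeric(1))
  tibble(gene_id = g$gene_id, mark = reads$mark, scope = scope, value = vals)
}

#' Phased-nucleosome amplitude and occupancy change
#'
#' The phased amplitude is the highest window value downstream of the anchor
#' (positive window centers, the +1 nucleosome region). The occupancy change
#' between two profiles on identical axes is `100 * (amp_a - amp_b) / amp_b`
#' percent.
#'
#' @param profile,profile_a,profile_b `bdp_profile` objects.
#' @return `phased_amplitude()`: a number. `occupancy_change()`: a percentage.
#' @export
phased_amplitude <- function(profile) {
  v <- profile$value[profile$window_center > 0]
  if (!length(v)) abort("profile has no downstream windows")
  max(v)
}

#' @rdname phased_amplitude
#' @export
occupancy_change <- function(profile_a, profile_b) {
  if (!isTRUE(all.equal(profile_a$window_center, profile_b$window_center)))
    abort("profiles are not on identical axes")
  amp_a <- phased_amplitude(profile_a)
  amp_b <- phased_amplitude(profile_b)
  if (amp_b == 0) abort("reference amplitude is zero: change undefined")
  100 * (amp_a - amp_b) / amp_b
}

#' @export
print.bdp_profile <- function(x, ...) {
  cat(sprintf("<bdp_profile> %s (%s): %d windows of %g bp over %d loci\n",
              attr(x, "mark"), attr(x, "orientation"), nrow(x),
              attr(x, "window_width"), attr(x, "n_loci")))
  NextMethod()
}
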