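as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) x
  else if (inherits(x, "DNAString")) Biostrings::DNAStringSet(x)
  else Biostrings::DNAStringSet(toupper(as.character(x)))
}

check_iupac <- function(pattern) {
  syms <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(syms, names(IUPAC_MAP))
  if (length(bad))
    abort(paste0("invalid IUPAC symbol(s) in pattern '", pattern, "': ",
                 paste(unique(bad), collapse = ", ")))
  toupper(pattern)
}

#' GC content of sequences
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param seqs Character vector, `DNAString` or `DNAStringSet`.
#' @return Numeric vector of GC fractions; `NA` (with a warning) for a
#'   sequence containing no unambiguous base.
#' @export
#' @examples
#' gc_content(c("GGCC", "ATATGC"))
gc_content <- function(seqs) {
  s <- as_dna_set(seqs)
  if (!length(s) || any(Biostrings::width(s) == 0))
    abort("gc_content needs nonempty sequences")
  fr <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  denom <- rowSums(fr)
  out <- ifelse(denom > 0, (fr[, "C"] + fr[, "G"]) / denom, NA_real_)
  if (anyNA(out)) warning("GC content undefined for all-ambiguous sequence(s)")
  unname(out)
}

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Reports every offset where the degenerate pattern matches the forward
#' sequence, plus every match of the pattern against the reverse complement,
#' the latter reported as the forward-strand start coordinate of the matched
#' window. Overlapping matches are all reported. An `N` in the sequence never
#' matches (the pattern is degenerate, the subject is literal).
#'
#' @param seq A single sequence (character or `DNAString`).
#' @param pattern IUPAC pattern.
#' @param both_strands Scan the reverse complement too?
#' @return Tibble with `start` (1-based forward coordinate) and `strand`.
#' @export
#' @examples
#' scan_motif("TGGGCC", "TGGGCY")
scan_motif <- function(seq, pattern, both_strands = TRUE) {
  pattern <- check_iupac(pattern)
  subject <- as_dna_set(seq)[[1]]
  fixedness <- c(pattern = FALSE, subject = TRUE)
  fwd <- Biostrings::matchPattern(pattern, subject, fixed = fixedness)
  out <- tibble(start = BiocGenerics::start(fwd),
                strand = rep("+", length(fwd)))
  if (both_strands) {
    rcpat <- Biostrings::reverseComplement(Biostrings::DNAString(pattern))
    rev <- Biostrings::matchPattern(rcpat, subject, fixed = fixedness)
    out <- bind_rows(out, tibble(start = BiocGenerics::start(rev),
                                 strand = rep("-", length(rev))))
  }
  arrange(out, .data$start, .data$strand)
}

#' Count motif occurrences per sequence
#'
#' Vectorized over sequences: total matches of a degenerate pattern on the
#' forward strand plus (optionally) the reverse complement.
#'
#' @param seqs `DNAStringSet` or character vector.
#' @inheritParams scan_motif
#' @return Integer vector of occurrence counts, one per sequence.
#' @export
count_motif <- function(seqs, pattern, both_strands = TRUE) {
  pattern <- check_iupac(pattern)
  s <- as_dna_set(seqs)
  fixedness <- c(pattern = FALSE, subject = TRUE)
  n <- Biostrings::vcountPattern(pattern, s, fixed = fixedness)
  if (both_strands) {
    rcpat <- Biostrings::reverseComplement(Biostrings::DNAString(pattern))
    n <- n + Biostrings::vcountPattern(rcpat, s, fixed = fixedness)
  }
  n
}

#' Canonical TATA-box patterns
#'
#' A small set of PLACE-style TATA-box consensus variants used by default for
#' promoter TATA screening.
#' @export
bdp_tata_patterns <- c("TATAAAT", "TATATAA", "TATTAAT")

#' Fraction of promoters containing a TATA box
#'
#' @param promoters `DNAStringSet` (or character vector) of promoter
#'   sequences.
#' @param patterns Character vector of IUPAC TATA patterns.
#' @return Fraction of promoters with at least one match to any pattern.
#' @export
tata_fraction <- function(promoters, patterns = bdp_tata_patterns) {
  if (!length(patterns)) abort("empty TATA pattern list")
  s <- as_dna_set(promoters)
  if (!length(s)) abort("empty promoter set")
  hit <- rep(FALSE, length(s))
  for (p in patterns) hit <- hit | (count_motif(s, p) > 0)
  mean(hit)
}

#' Extract promoter sequences from a genome
#'
#' @param genome `DNAStringSet` of chromosome sequences (names = chromosome).
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `strand`; intervals on the `-` strand are
#'   reverse-complemented so sequences read 5' to 3' for the owning gene.
#' @param names Optional character vector naming the output sequences.
#' @return `DNAStringSet`; zero-width intervals (`end < start`) give empty
#'   sequences.
#' @export
extract_promoters <- function(genome, intervals, names = NULL) {
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e < s) return("")
    x <- Biostrings::subseq(genome[[intervals$chrom[i]]], start = s, end = e)
    if ("strand" %in% names(intervals) && identical(intervals$strand[i], "-"))
      x <- Biostrings::reverseComplement(x)
    as.character(x)
  }, character(1)))
  if (!is.null(names)) names(out) <- names
  out
}

#' Promoter sequences of bidirectional pairs
#'
#' The BDP promoter is the intergenic region strictly between the two TSSs.
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param pairs Pairs from [find_bidirectional_pairs()].
#' @return `DNAStringSet` named by `pair_id`.
#' @export
pair_promoter_seqs <- function(genome, pairs) {
  extract_promoters(genome,
                    tibble(chrom = pairs$chrom, start = pairs$prom_start,
                           end = pairs$prom_end),
                    names = pairs$pair_id)
}

#' Per-promoter sequence feature table
#'
#' GC content, length and TATA presence for a set of promoter sequences.
#'
#' @param promoters Named `DNAStringSet`.
#' @param tata_patterns Patterns passed to [count_motif()] for TATA presence.
#' @return Tibble with `owner_id`, `length`, `gc`, `has_tata`.
#' @export
promoter_features <- function(promoters, tata_patterns = bdp_tata_patterns) {
  s <- as_dna_set(promoters)
  keep <- Biostrings::width(s) > 0
  s <- s[keep]
  hit <- rep(FALSE, length(s))
  for (p in tata_patterns) hit <- hit | (count_motif(s, p) > 0)
  tibble(owner_id = if (is.null(names(s))) as.character(seq_along(s)) else names(s),
         length = Biostrings::width(s),
         gc = gc_content(s),
         has_tata = hit)
}
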