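# Independent oracles used to cross-check the implementation.

# Brute-force all-pairs head-to-head scan with the same contract as
# find_bidirectional_pairs: O(n^2) over every gene pair, no sorting tricks.
oracle_find_pairs <- function(genes, max_dist = 1000) {
  g <- genes
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  cand <- list()
  n <- nrow(g)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- g[i, ]; b <- g[j, ]
    if (a$strand != "-" || b$strand != "+") next
    if (a$chrom != b$chrom) next
    if (!(a$tss < b$tss)) next
    if (b$tss - a$tss > max_dist) next
    if (!(a$end < b$start)) next
    between <- g$chrom == a$chrom & g$tss > a$tss & g$tss < b$tss
    if (any(between)) next
    cand[[length(cand) + 1]] <- data.frame(
      minus_gene = a$gene_id, plus_gene = b$gene_id,
      tss_minus = a$tss, tss_plus = b$tss, distance = b$tss - a$tss)
  }
  if (!length(cand)) return(data.frame(minus_gene = character(),
                                       plus_gene = character(),
                                       distance = numeric()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$distance, cand$minus_gene, cand$plus_gene), ]
  used <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$minus_gene[i] %in% used) && !(cand$plus_gene[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, cand$minus_gene[i], cand$plus_gene[i])
    }
  }
  cand[keep, ]
}

# Regex-based IUPAC scanner (overlapping matches via lookahead).
iupac_class <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")
iupac_regex <- function(pattern) {
  paste(iupac_class[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}
revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}
oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  hits <- function(pat, strand) {
    m <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m), strand = strand)
  }
  out <- hits(pattern, "+")
  if (both_strands) out <- rbind(out, hits(revcomp_chr(pattern), "-"))
  if (is.null(out)) return(data.frame(start = integer(), strand = character()))
  out[order(out$start, out$strand), ]
}

# Brute-force two-sample K-S statistic: sup |F1 - F2| over pooled points.
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Per-base window counting oracle for normalized counts.
oracle_window_values <- function(pos, lo, hi, n, total) {
  len <- hi - lo + 1
  w <- len / n
  per_base <- tabulate(pos[pos >= lo & pos <= hi] - lo + 1, len)
  vapply(seq_len(n), function(k) {
    b0 <- (k - 1) * w; b1 <- k * w
    idx <- which(seq_len(len) - 1 >= b0 & seq_len(len) - 1 < b1)
    sum(per_base[idx]) / w / (total / 1e6)
  }, numeric(1))
}

# Random (possibly messy) annotation for property tests: overlaps allowed.
random_annotation <- function(n, seed, span = 60000) {
  set.seed(seed)
  start <- sort(sample.int(span, n))
  len <- sample(200:1500, n, replace = TRUE)
  data.frame(gene_id = sprintf("r%04d", sample(seq_len(n))),
             chrom = sample(c("c1", "c2"), n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

random_dna <- function(n, len, gc = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), character(1))
}
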