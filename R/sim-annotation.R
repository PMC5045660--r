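# IUPAC degenerate nucleotide codes -> base sets (shared with the scanner)
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_instantiate <- function(pattern) {
  syms <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(syms, names(IUPAC_MAP))
  if (length(bad)) abort(paste0("invalid IUPAC symbol(s): ", paste(bad, collapse = ", ")))
  paste(vapply(syms, function(s) {
    b <- IUPAC_MAP[[s]]
    if (length(b) == 1) b else sample(b, 1)
  }, character(1)), collapse = "")
}

random_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Uniform TSS-distance draw inside a class interval: I [1,250], II (250,500],
# III (500,1000].
class_distance <- function(class) {
  switch(class,
         I = sample(1:250, 1),
         II = sample(251:500, 1),
         III = sample(501:1000, 1),
         abort(paste0("unknown BDP class: ", class)))
}

#' Simulate a genome with planted bidirectional promoters
#'
#' Lays out head-to-head gene pairs (with TSS distances drawn uniformly within
#' each class interval) and unidirectional genes along one chromosome, with
#' inter-locus gaps large enough that no accidental head-to-head pair can
#' arise. Emits the genome sequence (promoters at their configured GC, planted
#' TATA boxes and motifs at recorded positions) and a truth table for every
#' downstream check.
#'
#' @param config A [sim_config()].
#' @return An object of class `bdp_sim`: a list with `genome` (a
#'   [Biostrings::DNAStringSet]), `genes` (tibble of gene models), `truth`
#'   (list of tibbles: `pairs`, `genes`, `motifs`, `udp_promoters`) and
#'   `config`.
#' @export
simulate_annotation <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed + 0L, sim_annotation_impl(config))
}

sim_annotation_impl <- function(cfg) {
  chrom <- "chr1"
  glen <- function() round(runif(1, cfg$gene_length[1], cfg$gene_length[2]))
  ggap <- function() round(runif(1, cfg$gap[1], cfg$gap[2]))

  loci <- c(rep("I", cfg$n_pairs[["I"]]), rep("II", cfg$n_pairs[["II"]]),
            rep("III", cfg$n_pairs[["III"]]), rep("udp", cfg$n_udp))
  loci <- if (length(loci)) sample(loci) else character(0)

  genes <- list(); pairs <- list(); udp_prom <- list()
  cursor <- 1 + ggap()
  gi <- 0L; pi <- 0L
  for (cl in loci) {
    if (cl == "udp") {
      gi <- gi + 1L
      len <- glen(); strand <- sample(c("+", "-"), 1)
      start <- cursor; end <- start + len - 1
      id <- sprintf("gene_%04d", gi)
      tss <- if (strand == "+") start else end
      genes[[length(genes) + 1]] <- tibble(
        gene_id = id, chrom = chrom, start = start, end = end,
        strand = strand, biotype = "protein_coding",
        role = "udp", class = "udp", pair_id = NA_character_, tss = tss)
      ps <- if (strand == "+") start - cfg$udp_promoter_length else end + 1
      pe <- ps + cfg$udp_promoter_length - 1
      udp_prom[[length(udp_prom) + 1]] <- tibble(
        gene_id = id, chrom = chrom,
        start = max(1, ps), end = pe, strand = strand)
      cursor <- end + 1 + ggap()
    } else {
      pi <- pi + 1L
      d <- class_distance(cl)
      len1 <- glen(); len2 <- glen()
      m_start <- cursor; m_end <- m_start + len1 - 1      # minus gene, TSS = end
      p_start <- m_end + d; p_end <- p_start + len2 - 1    # plus gene, TSS = start
      id_m <- sprintf("gene_%04d", gi + 1L)
      id_p <- sprintf("gene_%04d", gi + 2L)
      gi <- gi + 2L
      pid <- sprintf("pair_%03d", pi)
      genes[[length(genes) + 1]] <- tibble(
        gene_id = c(id_m, id_p), chrom = chrom,
        start = c(m_start, p_start), end = c(m_end, p_end),
        strand = c("-", "+"), biotype = "protein_coding",
        role = c("bdp_minus", "bdp_plus"), class = cl, pair_id = pid,
        tss = c(m_end, p_start))
      pairs[[length(pairs) + 1]] <- tibble(
        pair_id = pid, minus_gene = id_m, plus_gene = id_p, chrom = chrom,
        tss_minus = m_end, tss_plus = p_start, distance = d,
        bdp_type = cl, prom_start = m_end + 1, prom_end = p_start - 1)
      cursor <- p_end + 1 + ggap()
    }
  }
  genes <- if (length(genes)) bind_rows(genes) else
    tibble(gene_id = character(), chrom = character(), start = numeric(),
           end = numeric(), strand = character(), biotype = character(),
           role = character(), class = character(), pair_id = character(),
           tss = numeric())
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(pair_id = character(), minus_gene = character(),
           plus_gene = character(), chrom = character(), tss_minus = numeric(),
           tss_plus = numeric(), distance = numeric(), bdp_type = character(),
           prom_start = numeric(), prom_end = numeric())
  udp_prom <- if (length(udp_prom)) bind_rows(udp_prom) else
    tibble(gene_id = character(), chrom = character(), start = numeric(),
           end = numeric(), strand = character())

  need <- cursor - 1
  if (need > cfg$chromosome_length) {
    abort(sprintf(paste0(
      "infeasible packing: layout of %d genes needs %d bp but ",
      "chromosome_length is %d; increase chromosome_length or reduce ",
      "gene counts/lengths/gaps"), nrow(genes), need, cfg$chromosome_length))
  }

  seq <- random_bases(cfg$chromosome_length, cfg$background_gc)

  # Promoter GC overwrites first (all UDP promoters share one GC, and BDP
  # promoters never overlap anything, so overwrite order is immaterial).
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      s <- pairs$prom_start[i]; e <- pairs$prom_end[i]
      if (e >= s) seq[s:e] <- random_bases(e - s + 1,
                                           cfg$promoter_gc[[pairs$bdp_type[i]]])
    }
  }
  if (nrow(udp_prom)) {
    for (i in seq_len(nrow(udp_prom))) {
      s <- udp_prom$start[i]; e <- udp_prom$end[i]
      seq[s:e] <- random_bases(e - s + 1, cfg$udp_promoter_gc)
    }
  }

  # Motif planting with a global occupancy set so no plant overwrites another.
  occupied <- integer(0)
  motif_rows <- list()
  plant <- function(ps, pe, pattern, owner, owner_type, motif_name) {
    w <- nchar(pattern)
    if (pe - ps + 1 < w) return(NULL)
    for (try in 1:25) {
      pos <- sample(ps:(pe - w + 1), 1)
      span <- pos:(pos + w - 1)
      if (!any(span %in% occupied)) {
        inst <- iupac_instantiate(pattern)
        seq[span] <<- strsplit(inst, "")[[1]]
        occupied <<- c(occupied, span)
        return(tibble(owner = owner, owner_type = owner_type,
                      motif = motif_name, pattern = pattern,
                      instance = inst, start = pos, strand = "+"))
      }
    }
    NULL
  }
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ps <- pairs$prom_start[i]; pe <- pairs$prom_end[i]
      if (pe < ps) next
      cl <- pairs$bdp_type[i]
      if (runif(1) < cfg$tata_rate[[cl]]) {
        motif_rows[[length(motif_rows) + 1]] <-
          plant(ps, pe, cfg$tata_pattern, pairs$pair_id[i], "pair", "TATA")
      }
      if (!is.null(cfg$planted_motifs)) {
        for (j in seq_len(nrow(cfg$planted_motifs))) {
          if (runif(1) < cfg$planted_motifs$rate[j]) {
            motif_rows[[length(motif_rows) + 1]] <-
              plant(ps, pe, cfg$planted_motifs$pattern[j], pairs$pair_id[i],
                    "pair", cfg$planted_motifs$name[j])
          }
        }
      }
    }
  }
  if (nrow(udp_prom)) {
    for (i in seq_len(nrow(udp_prom))) {
      if (runif(1) < cfg$udp_tata_rate) {
        motif_rows[[length(motif_rows) + 1]] <-
          plant(udp_prom$start[i], udp_prom$end[i], cfg$tata_pattern,
                udp_prom$gene_id[i], "gene", "TATA")
      }
    }
  }
  motifs <- if (length(motif_rows)) bind_rows(motif_rows) else
    tibble(owner = character(), owner_type = character(), motif = character(),
           pattern = character(), instance = character(), start = numeric(),
           strand = character())

  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- chrom

  structure(list(
    genome = genome,
    genes = genes %>% select("gene_id", "chrom", "start", "end", "strand",
                             "biotype"),
    truth = list(pairs = pairs,
                 genes = genes %>% select("gene_id", "role", "class",
                                          "pair_id", "tss", "strand"),
                 motifs = motifs,
                 udp_promoters = udp_prom),
    config = cfg
  ), class = "bdp_sim")
}

#' @export
print.bdp_sim <- function(x, ...) {
  cat("<bdp_sim>\n")
  cat("  chromosome:", names(x$genome), sprintf("(%d bp)\n", Biostrings::width(x$genome)))
  cat("  genes:", nrow(x$genes), " planted pairs:", nrow(x$truth$pairs), "\n")
  if (!is.null(x$expression))
    cat("  expression:", ncol(x$expression) - 1, "libraries\n")
  if (!is.null(x$reads))
    cat("  read sets:", paste(names(x$reads), collapse = ", "), "\n")
  invisible(x)
}
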