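#' Transcription start sites of gene models
#'
#' The TSS is the 5'-most transcribed base: `start` for a `+` strand gene,
#' `end` for a `-` strand gene.
#'
#' @param genes Tibble of gene models (see [read_gene_models()]).
#' @return `genes` with an added `tss` column.
#' @export
#' @examples
#' gene_tss(tibble::tibble(gene_id = "g", chrom = "chr1", start = 100,
#'                         end = 500, strand = "-", biotype = "protein_coding"))
gene_tss <- function(genes) {
  stopifnot(all(genes$strand %in% c("+", "-")), all(genes$end >= genes$start))
  mutate(genes, tss = ifelse(.data$strand == "+", .data$start, .data$end))
}

#' Classify a bidirectional promoter by TSS distance
#'
#' Distance bins are assigned so boundary values fall in the smaller class:
#' type I for distances in `[0, 250]`, II for `(250, 500]`, III for
#' `(500, 1000]`.
#'
#' @param tss_distance Numeric vector of TSS distances in bp.
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @export
#' @examples
#' classify_bdp(c(100, 250, 251, 500, 501, 1000))
classify_bdp <- function(tss_distance) {
  if (any(tss_distance < 0 | tss_distance > 1000))
    abort("tss_distance outside [0, 1000] has no BDP class")
  dplyr::case_when(tss_distance <= 250 ~ "I",
                   tss_distance <= 500 ~ "II",
                   TRUE ~ "III")
}

#' Identify head-to-head bidirectional gene pairs
#'
#' A bidirectional pair is a `-` strand gene and a `+` strand gene on the same
#' chromosome, transcribed divergently (TSS of the `-` gene left of the TSS of
#' the `+` gene), with no third gene's TSS strictly between the two TSSs, TSS
#' distance at most `max_dist`, and non-overlapping gene bodies (the promoter
#' must be intergenic). When a gene has several candidate partners the closest
#' pair wins, ties broken by lexicographic gene ids; every gene appears in at
#' most one pair.
#'
#' @param genes Tibble of gene models.
#' @param max_dist Maximum TSS distance in bp (default 1000).
#' @return Tibble with one row per pair: `pair_id`, `minus_gene`, `plus_gene`,
#'   `chrom`, `tss_minus`, `tss_plus`, `distance`, `bdp_type`, `prom_start`,
#'   `prom_end` (the intergenic interval strictly between the TSSs).
#' @export
find_bidirectional_pairs <- function(genes, max_dist = 1000) {
  stopifnot(max_dist > 0)
  empty <- tibble(pair_id = character(), minus_gene = character(),
                  plus_gene = character(), chrom = character(),
                  tss_minus = numeric(), tss_plus = numeric(),
                  distance = numeric(), bdp_type = character(),
                  prom_start = numeric(), prom_end = numeric())
  if (!nrow(genes)) return(empty)
  g <- gene_tss(genes)

  # Candidates: a (-) gene and a (+) gene at consecutive *distinct* TSS
  # values, so no third gene's TSS lies strictly between the two TSSs.
  cand <- g %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      ts <- sort(unique(df$tss))
      rows <- list()
      if (length(ts) >= 2) {
        for (k in seq_len(length(ts) - 1)) {
          t1 <- ts[k]; t2 <- ts[k + 1]
          if (t2 - t1 > max_dist) next
          left <- df[df$tss == t1 & df$strand == "-", ]
          right <- df[df$tss == t2 & df$strand == "+", ]
          if (!nrow(left) || !nrow(right)) next
          grid <- tidyr::expand_grid(i = seq_len(nrow(left)),
                                     j = seq_len(nrow(right)))
          ok <- left$end[grid$i] < right$start[grid$j]  # intergenic promoter
          grid <- grid[ok, ]
          if (nrow(grid)) rows[[length(rows) + 1]] <- tibble(
            minus_gene = left$gene_id[grid$i],
            plus_gene = right$gene_id[grid$j],
            tss_minus = t1, tss_plus = t2, distance = t2 - t1)
        }
      }
      if (length(rows)) bind_rows(rows) else
        tibble(minus_gene = character(), plus_gene = character(),
               tss_minus = numeric(), tss_plus = numeric(),
               distance = numeric())
    }) %>%
    ungroup()
  if (!nrow(cand)) return(empty)

  # greedy matching: closest distance first, lexicographic tie-break
  cand <- arrange(cand, .data$distance, .data$minus_gene, .data$plus_gene)
  used <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$minus_gene[i] %in% used) && !(cand$plus_gene[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, cand$minus_gene[i], cand$plus_gene[i])
    }
  }
  cand <- cand[keep, ] %>%
    arrange(.data$chrom, .data$tss_minus) %>%
    mutate(pair_id = sprintf("bdp_%04d", row_number()),
           bdp_type = classify_bdp(.data$distance),
           prom_start = .data$tss_minus + 1,
           prom_end = .data$tss_plus - 1)
  cand[c("pair_id", "minus_gene", "plus_gene", "chrom", "tss_minus",
         "tss_plus", "distance", "bdp_type", "prom_start", "prom_end")]
}

#' Select expression-matched unidirectional control genes
#'
#' Unidirectional candidates are genes in no pair and with no opposite-strand
#' divergent neighbour within `max_dist` bp. `multiplier * 2 * nrow(pairs)`
#' of them are drawn, stratified over the FPKM deciles of the bidirectional
#' genes so the control expression distribution matches.
#'
#' @param genes Tibble of gene models.
#' @param pairs Pairs from [find_bidirectional_pairs()].
#' @param expression Expression tibble (`gene_id` + library columns); genes
#'   are matched on mean FPKM across libraries.
#' @param multiplier Integer in 1..5: controls per bidirectional gene.
#' @param promoter_length Control promoter length in bp (250, 500 or 1000),
#'   matching the BDP class compared against.
#' @param seed Integer seed; the same seed reproduces the same control set.
#' @param max_dist Divergent-neighbour exclusion distance (default 1000).
#' @return Tibble of control genes with `tss`, `prom_start`, `prom_end`
#'   (the `promoter_length` bp upstream of the TSS) and `fpkm`.
#' @export
select_udp_controls <- function(genes, pairs, expression, multiplier = 1,
                                promoter_length = 1000, seed = 1,
                                max_dist = 1000) {
  stopifnot(multiplier %in% 1:5, promoter_length > 0)
  cand <- unidirectional_genes(genes, pairs, max_dist = max_dist)
  fpkm <- expression_means(expression)
  bdp_ids <- c(pairs$minus_gene, pairs$plus_gene)
  bdp_fpkm <- fpkm$mean_fpkm[match(bdp_ids, fpkm$gene_id)]
  if (anyNA(bdp_fpkm)) abort("expression missing for some bidirectional genes")
  cand <- cand %>%
    left_join(fpkm, by = "gene_id") %>%
    filter(!is.na(.data$mean_fpkm))

  n_target <- multiplier * 2 * nrow(pairs)
  qs <- stats::quantile(bdp_fpkm, probs = seq(0, 1, 0.1), names = FALSE)
  qs[1] <- -Inf; qs[11] <- Inf
  bdp_decile <- findInterval(bdp_fpkm, qs, rightmost.closed = TRUE)
  cand_decile <- findInterval(cand$mean_fpkm, qs, rightmost.closed = TRUE)
  # per-decile targets proportional to BDP gene counts, remainder to the
  # earliest deciles
  base <- floor(n_target * tabulate(bdp_decile, 10) / length(bdp_decile))
  rem <- n_target - sum(base)
  if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1
  picked <- withr::with_seed(seed, {
    idx <- integer(0)
    for (d in 1:10) {
      pool <- which(cand_decile == d)
      if (length(pool) < base[d])
        abort(sprintf(
          "insufficient unidirectional candidates in FPKM decile %d: need %d, have %d",
          d, base[d], length(pool)))
      if (base[d] > 0) idx <- c(idx, sample(pool, base[d]))
    }
    idx
  })
  out <- gene_tss(cand[picked, ]) %>% arrange(.data$chrom, .data$start)
  out %>%
    mutate(prom_start = ifelse(.data$strand == "+",
                               .data$tss - promoter_length, .data$tss + 1),
           prom_end = ifelse(.data$strand == "+",
                             .data$tss - 1, .data$tss + promoter_length),
           fpkm = .data$mean_fpkm) %>%
    select(-"mean_fpkm")
}

#' Unidirectional genes (no divergent partner within a distance cutoff)
#'
#' @inheritParams select_udp_controls
#' @return Tibble of gene models restricted to unidirectional genes.
#' @export
unidirectional_genes <- function(genes, pairs, max_dist = 1000) {
  g <- gene_tss(genes)
  paired <- c(pairs$minus_gene, pairs$plus_gene)
  has_partner <- rep(FALSE, nrow(g))
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    df <- g[idx, ]
    for (i in seq_along(idx)) {
      if (df$strand[i] == "-") {
        hit <- df$strand == "+" & df$tss > df$tss[i] &
          df$tss - df$tss[i] <= max_dist
      } else {
        hit <- df$strand == "-" & df$tss < df$tss[i] &
          df$tss[i] - df$tss <= max_dist
      }
      has_partner[idx[i]] <- any(hit)
    }
  }
  g[!has_partner & !(g$gene_id %in% paired), ] %>% select(-"tss")
}
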