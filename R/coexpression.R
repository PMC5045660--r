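expr_matrix <- function(expression) {
  stopifnot("gene_id" %in% names(expression))
  m <- as.matrix(expression[setdiff(names(expression), "gene_id")])
  if (any(m < 0, na.rm = TRUE)) abort("negative FPKM values")
  rownames(m) <- expression$gene_id
  m
}

expression_means <- function(expression) {
  m <- expr_matrix(expression)
  tibble(gene_id = rownames(m), mean_fpkm = rowMeans(m))
}

#' Pearson correlation of a gene pair across libraries
#'
#' Computed on raw FPKM values (set `log = TRUE` for log2(FPKM + 1)). The
#' correlation is undefined (`NA`) when either gene has FPKM 0 across all
#' libraries — such genes are treated as unexpressed — or when either vector
#' has zero variance.
#'
#' @param expression Expression tibble (`gene_id` + library columns).
#' @param gene_a,gene_b Gene ids (vectorized; recycled pairwise).
#' @param log Correlate log2(FPKM + 1) instead of raw FPKM.
#' @return Numeric vector of correlations (`NA` where undefined).
#' @export
pair_pcc <- function(expression, gene_a, gene_b, log = FALSE) {
  m <- expr_matrix(expression)
  missing <- setdiff(unique(c(gene_a, gene_b)), rownames(m))
  if (length(missing))
    abort(paste0("gene(s) absent from expression matrix: ",
                 paste(missing, collapse = ", ")))
  if (log) m <- log2(m + 1)
  all_zero <- rowSums(expr_matrix(expression)) == 0
  vapply(seq_along(gene_a), function(i) {
    a <- m[gene_a[i], ]; b <- m[gene_b[i], ]
    if (all_zero[gene_a[i]] || all_zero[gene_b[i]]) return(NA_real_)
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
}

#' Per-pair correlations for a pair table
#'
#' @param expression Expression tibble.
#' @param pairs Pairs from [find_bidirectional_pairs()] (or any tibble with
#'   `pair_id`, `minus_gene`, `plus_gene`).
#' @inheritParams pair_pcc
#' @return `pairs` with an added `pcc` column.
#' @export
pair_correlations <- function(expression, pairs, log = FALSE) {
  mutate(pairs, pcc = pair_pcc(expression, pairs$minus_gene, pairs$plus_gene,
                               log = log))
}

#' Data-derived coexpression thresholds
#'
#' The positive threshold is the mean of all strictly positive pair
#' correlations, the negative threshold the mean of all strictly negative
#' ones. (On the original eleven-library rice matrix these come out at 0.38
#' and -0.20; with other data they are recomputed, or can be pinned with
#' `coexpression_thresholds()`.)
#'
#' @param pccs Numeric vector of pair correlations (`NA`s ignored).
#' @return List of class `bdp_thresholds` with `pos_mean` and `neg_mean`.
#' @export
#' @examples
#' derive_thresholds(c(0.2, 0.6, -0.1, -0.3))
derive_thresholds <- function(pccs) {
  pccs <- pccs[!is.na(pccs)]
  pos <- pccs[pccs > 0]; neg <- pccs[pccs < 0]
  if (!length(pos)) abort("no positive correlations: pos_mean undefined")
  if (!length(neg)) abort("no negative correlations: neg_mean undefined")
  coexpression_thresholds(mean(pos), mean(neg))
}

#' @rdname derive_thresholds
#' @param pos_mean,neg_mean Fixed threshold values (`neg_mean < 0 < pos_mean`).
#' @export
coexpression_thresholds <- function(pos_mean = 0.38, neg_mean = -0.20) {
  stopifnot(pos_mean > 0, neg_mean < 0)
  structure(list(pos_mean = pos_mean, neg_mean = neg_mean),
            class = "bdp_thresholds")
}

#' @export
print.bdp_thresholds <- function(x, ...) {
  cat(sprintf("<bdp_thresholds> coexpressed > %.3f, antiexpressed < %.3f\n",
              x$pos_mean, x$neg_mean))
  invisible(x)
}

#' Four-way expression-mode classification
#'
#' A pair is `coexpressed` when its correlation exceeds the positive
#' threshold, `antiexpressed` when below the negative threshold,
#' `independent` in between, and `null` when the correlation is undefined.
#'
#' @param pcc Numeric vector of pair correlations (`NA` = undefined).
#' @param thresholds A `bdp_thresholds` object.
#' @return Character vector of modes.
#' @export
#' @examples
#' classify_mode(c(0.5, 0, -0.4, NA), coexpression_thresholds(0.38, -0.20))
classify_mode <- function(pcc, thresholds) {
  stopifnot(inherits(thresholds, "bdp_thresholds"))
  dplyr::case_when(is.na(pcc) ~ "null",
                   pcc > thresholds$pos_mean ~ "coexpressed",
                   pcc < thresholds$neg_mean ~ "antiexpressed",
                   TRUE ~ "independent")
}

#' Classify the coexpression mode of every pair
#'
#' Convenience wrapper: correlations, thresholds (derived from the data
#' unless supplied) and modes in one call.
#'
#' @inheritParams pair_correlations
#' @param thresholds `NULL` (derive from the data) or a `bdp_thresholds`.
#' @return List with `pairs` (input + `pcc` + `mode`) and `thresholds`.
#' @export
coexpression_modes <- function(expression, pairs, thresholds = NULL,
                               log = FALSE) {
  tab <- pair_correlations(expression, pairs, log = log)
  if (is.null(thresholds)) thresholds <- derive_thresholds(tab$pcc)
  tab$mode <- classify_mode(tab$pcc, thresholds)
  list(pairs = tab, thresholds = thresholds)
}

#' Randomly sampled adjacent unidirectional gene pairs
#'
#' Control pairs for the coexpression comparison: genomically adjacent gene
#' duos, regardless of transcription direction, excluding duos that would
#' themselves qualify as head-to-head pairs within `max_dist` bp and genes
#' already in a bidirectional pair.
#'
#' @param genes Tibble of gene models.
#' @param pairs Bidirectional pairs to exclude (may be `NULL`).
#' @param n Number of adjacent duos to draw (default 1000); `NULL` draws
#'   `min(1000, available)`.
#' @param seed Integer seed.
#' @param max_dist Head-to-head exclusion distance.
#' @return Tibble with `gene_a`, `gene_b` (adjacent along the chromosome).
#' @export
random_adjacent_pairs <- function(genes, pairs = NULL, n = 1000, seed = 1,
                                  max_dist = 1000) {
  g <- gene_tss(genes) %>% arrange(.data$chrom, .data$start, .data$gene_id)
  duos <- g %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) return(tibble(gene_a = character(),
                                      gene_b = character(),
                                      head_to_head = logical()))
      a <- df[-nrow(df), ]; b <- df[-1, ]
      tibble(gene_a = a$gene_id, gene_b = b$gene_id,
             head_to_head = a$strand == "-" & b$strand == "+" &
               a$tss < b$tss & (b$tss - a$tss) <= max_dist)
    }) %>%
    ungroup() %>%
    filter(!.data$head_to_head) %>%
    select("gene_a", "gene_b")
  if (!is.null(pairs) && nrow(pairs)) {
    in_bdp <- c(pairs$minus_gene, pairs$plus_gene)
    duos <- filter(duos, !(.data$gene_a %in% in_bdp),
                   !(.data$gene_b %in% in_bdp))
  }
  if (is.null(n)) n <- min(1000, nrow(duos))
  if (nrow(duos) < n)
    abort(sprintf("only %d adjacent unidirectional duos available, need %d",
                  nrow(duos), n))
  withr::with_seed(seed, duos[sample.int(nrow(duos), n), ]) %>%
    arrange(.data$gene_a)
}

#' Coexpressed fraction by TSS distance
#'
#' Bins pairs by TSS distance over `[0, 1000]` and reports the fraction of
#' coexpressed pairs per bin. Bins are left-closed, the last bin closed on
#' both ends, so the bins tile `[0, 1000]` exactly.
#'
#' @param pairs Classified pair tibble (needs `distance` and `mode`).
#' @param bin_width Bin width in bp (must divide 1000).
#' @return Tibble with `bin_start`, `bin_end`, `n_pairs`, `coexpressed_frac`
#'   (`NA` for empty bins).
#' @export
coexpression_by_distance <- function(pairs, bin_width = 100) {
  stopifnot(1000 %% bin_width == 0)
  edges <- seq(0, 1000, by = bin_width)
  bin <- pmin(findInterval(pairs$distance, edges), length(edges) - 1)
  tibble(bin_start = edges[-length(edges)], bin_end = edges[-1]) %>%
    mutate(n_pairs = vapply(row_number(), function(b) sum(bin == b), numeric(1)),
           coexpressed_frac = vapply(row_number(), function(b) {
             if (!any(bin == b)) return(NA_real_)
             mean(pairs$mode[bin == b] == "coexpressed")
           }, numeric(1)))
}

#' Mode summary by BDP type
#'
#' Counts of pairs per expression mode within each BDP distance class.
#'
#' @param pairs Classified pair tibble (needs `bdp_type` and `mode`).
#' @return Tibble with one row per type and mode, plus the within-type
#'   fraction.
#' @export
mode_summary <- function(pairs) {
  pairs %>%
    dplyr::count(.data$bdp_type, .data$mode, name = "n_pairs") %>%
    group_by(.data$bdp_type) %>%
    mutate(fraction = .data$n_pairs / sum(.data$n_pairs)) %>%
    ungroup()
}
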