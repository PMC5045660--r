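#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Wraps [stats::ks.test()] with the two-sided alternative and the asymptotic
#' p-value (no exact small-sample correction), the convention used for
#' comparing normalized read counts or expression between groups. Ties (which
#' are common in windowed count data) only affect the p-value approximation,
#' not the D statistic, so the tie warning is suppressed.
#'
#' @param x,y Numeric samples (each nonempty).
#' @return One-row tibble: `d` (sup-difference of the empirical CDFs),
#'   `p_value`, `n1`, `n2`, `alternative`.
#' @export
#' @examples
#' ks_compare(rnorm(50), rnorm(50, 1))
ks_compare <- function(x, y) {
  if (!length(x) || !length(y)) abort("empty sample in K-S comparison")
  ht <- suppressWarnings(ks.test(x, y, alternative = "two.sided",
                                 exact = FALSE))
  tibble(d = unname(ht$statistic), p_value = ht$p.value,
         n1 = length(x), n2 = length(y), alternative = "two.sided")
}

#' K-S tests of per-gene signal between groups
#'
#' Compares the normalized read counts of two gene groups (e.g. bidirectional
#' versus unidirectional genes) for each mark.
#'
#' @param signals Tibble from [gene_signal()] rows for both groups, with an
#'   added `group` column.
#' @param group_a,group_b The two group labels to compare.
#' @return Tibble with one row per `mark` and `scope`: the K-S `d`,
#'   `p_value` and group sizes.
#' @export
ks_signal_tests <- function(signals, group_a, group_b) {
  signals %>%
    group_by(.data$mark, .data$scope) %>%
    dplyr::group_modify(function(df, key) {
      ks_compare(df$value[df$group == group_a],
                 df$value[df$group == group_b])
    }) %>%
    ungroup() %>%
    mutate(group_a = group_a, group_b = group_b)
}

#' Drought-responsive gene pairs
#'
#' Per gene, the response is `(mean drought FPKM + pseudocount) /
#' (mean control FPKM + pseudocount)`. With `rule = "both"` (default) a pair
#' is called up-regulated when both genes exceed the fold-change threshold
#' and down-regulated when both fall below its reciprocal; `rule = "either"`
#' requires only one gene to pass (and the other not to pass in the opposite
#' direction).
#'
#' @param expr_control,expr_drought Expression tibbles (`gene_id` + replicate
#'   columns) for the two conditions.
#' @param pairs Pair tibble (`pair_id`, `minus_gene`, `plus_gene`).
#' @param fc Fold-change threshold (default 2).
#' @param pseudocount Added to both numerator and denominator (default 0.1
#'   FPKM).
#' @param rule `"both"` or `"either"`.
#' @return Tibble with `pair_id`, per-gene fold changes and `call`
#'   (`up`/`down`/`unchanged`).
#' @export
drought_de_pairs <- function(expr_control, expr_drought, pairs, fc = 2,
                             pseudocount = 0.1, rule = c("both", "either")) {
  rule <- match.arg(rule)
  stopifnot(fc > 1)
  mc <- expr_matrix(expr_control)
  md <- expr_matrix(expr_drought)
  need <- c(pairs$minus_gene, pairs$plus_gene)
  missing <- setdiff(need, intersect(rownames(mc), rownames(md)))
  if (length(missing))
    abort(paste0("pair gene(s) missing from condition matrices: ",
                 paste(missing, collapse = ", ")))
  ratio <- (rowMeans(md)[need] + pseudocount) /
    (rowMeans(mc)[need] + pseudocount)
  r1 <- ratio[pairs$minus_gene]; r2 <- ratio[pairs$plus_gene]
  up1 <- r1 > fc; up2 <- r2 > fc
  dn1 <- r1 < 1 / fc; dn2 <- r2 < 1 / fc
  call <- if (rule == "both") {
    dplyr::case_when(up1 & up2 ~ "up", dn1 & dn2 ~ "down", TRUE ~ "unchanged")
  } else {
    dplyr::case_when((up1 | up2) & !dn1 & !dn2 ~ "up",
                     (dn1 | dn2) & !up1 & !up2 ~ "down",
                     TRUE ~ "unchanged")
  }
  tibble(pair_id = pairs$pair_id,
         fc_minus = unname(r1), fc_plus = unname(r2), call = call)
}
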