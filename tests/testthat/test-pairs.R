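mk_genes <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(gene_id = r[[1]], chrom = r[[2]], start = as.numeric(r[[3]]),
                   end = as.numeric(r[[4]]), strand = r[[5]],
                   biotype = "protein_coding")))
}

test_that("TSS follows the strand convention and mirrors under strand flip", {
  g <- mk_genes(list("a", "c1", 100, 500, "+"), list("b", "c1", 100, 500, "-"))
  expect_equal(gene_tss(g)$tss, c(100, 500))
  # flipping the strand mirrors the TSS about the interval midpoint
  flipped <- dplyr::mutate(g, strand = ifelse(strand == "+", "-", "+"))
  mid <- (g$start + g$end) / 2
  expect_equal(gene_tss(flipped)$tss, 2 * mid - gene_tss(g)$tss)
})

test_that("distance bins assign boundaries to the smaller class", {
  expect_equal(classify_bdp(c(0, 100, 250)), c("I", "I", "I"))
  expect_equal(classify_bdp(c(251, 500)), c("II", "II"))
  expect_equal(classify_bdp(c(501, 1000)), c("III", "III"))
  expect_error(classify_bdp(1001))
  expect_error(classify_bdp(-1))
})

test_that("orientation and distance filters reject non-divergent configurations", {
  # tail-to-tail (+ then -): no pair
  expect_equal(nrow(find_bidirectional_pairs(
    mk_genes(list("a", "c1", 100, 500, "+"), list("b", "c1", 900, 1300, "-")))), 0)
  # divergent but 1001 bp apart: no pair
  expect_equal(nrow(find_bidirectional_pairs(
    mk_genes(list("a", "c1", 100, 500, "-"), list("b", "c1", 1501, 1900, "+")))), 0)
  # divergent at exactly 1000: a pair
  p <- find_bidirectional_pairs(
    mk_genes(list("a", "c1", 100, 500, "-"), list("b", "c1", 1500, 1900, "+")))
  expect_equal(p$distance, 1000)
  expect_equal(p$bdp_type, "III")
  # overlapping gene bodies: excluded
  expect_equal(nrow(find_bidirectional_pairs(
    mk_genes(list("a", "c1", 100, 800, "-"), list("b", "c1", 700, 1600, "+")))), 0)
  # a third gene's TSS strictly between the two TSSs breaks the (a, b) pair
  p3 <- find_bidirectional_pairs(
    mk_genes(list("a", "c1", 100, 500, "-"), list("b", "c1", 900, 1300, "+"),
             list("c", "c1", 700, 710, "-")))
  expect_false("a" %in% p3$minus_gene)
  # ... though the intervening gene itself may pair divergently (c, b)
  expect_equal(p3$minus_gene, "c")
  expect_equal(p3$plus_gene, "b")
})

test_that("pair finding matches the brute-force all-pairs oracle", {
  for (seed in 1:30) {
    g <- random_annotation(sample(20:120, 1), seed = seed)
    got <- find_bidirectional_pairs(g)
    want <- oracle_find_pairs(g)
    expect_equal(nrow(got), nrow(want), label = paste("n pairs, seed", seed))
    key <- function(d) sort(paste(d$minus_gene, d$plus_gene, d$distance))
    expect_equal(key(got), key(want), label = paste("pair set, seed", seed))
  }
})

test_that("planted synthetic pairs are recovered exactly", {
  sim <- shared_sim()
  got <- find_bidirectional_pairs(sim$genes)
  tp <- sim$truth$pairs
  expect_equal(nrow(got), nrow(tp))
  key <- function(d) sort(paste(d$minus_gene, d$plus_gene, d$distance))
  expect_equal(key(got), key(tp))
  expect_equal(sort(got$bdp_type), sort(tp$bdp_type))
})

test_that("no gene occurs in two pairs and reflection preserves the pairing", {
  g <- random_annotation(80, seed = 99)
  p <- find_bidirectional_pairs(g)
  expect_equal(anyDuplicated(c(p$minus_gene, p$plus_gene)), 0)
  # genome-wide reflection: mirror coordinates, flip strands
  M <- max(g$end) + 1000
  gref <- dplyr::mutate(g, start2 = M - end, end2 = M - start,
                        strand = ifelse(strand == "+", "-", "+"),
                        start = start2, end = end2) %>%
    dplyr::select(-start2, -end2)
  pref <- find_bidirectional_pairs(gref)
  expect_equal(nrow(pref), nrow(p))
  expect_equal(sort(pref$distance), sort(p$distance))
  # roles swap under reflection
  expect_equal(sort(pref$minus_gene), sort(p$plus_gene))
})

test_that("UDP controls are stratified, sized and reproducible", {
  # 20 planted pairs plus a large same-strand UDP pool, uniform expression
  n_pairs <- 20; n_udp <- 400
  pair_rows <- lapply(seq_len(n_pairs), function(i) {
    base <- i * 10000
    mk_genes(list(sprintf("m%02d", i), "c1", base, base + 900, "-"),
             list(sprintf("p%02d", i), "c1", base + 1100, base + 2000, "+"))
  })
  udp_rows <- lapply(seq_len(n_udp), function(i) {
    base <- 300000 + i * 5000
    mk_genes(list(sprintf("u%03d", i), "c1", base, base + 900, "+"))
  })
  genes <- dplyr::bind_rows(c(pair_rows, udp_rows))
  pairs <- find_bidirectional_pairs(genes)
  expect_equal(nrow(pairs), n_pairs)
  set.seed(4)
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                           tibble::as_tibble(matrix(runif(nrow(genes) * 3, 1, 100),
                                                    ncol = 3,
                                                    dimnames = list(NULL, paste0("l", 1:3)))))
  ctl1 <- select_udp_controls(genes, pairs, expr, multiplier = 2,
                              promoter_length = 500, seed = 9)
  expect_equal(nrow(ctl1), 2 * 2 * n_pairs)
  expect_true(all(ctl1$prom_end - ctl1$prom_start + 1 == 500))
  expect_identical(ctl1, select_udp_controls(genes, pairs, expr, multiplier = 2,
                                             promoter_length = 500, seed = 9))
  # no control gene is part of a pair
  expect_equal(length(intersect(ctl1$gene_id,
                                c(pairs$minus_gene, pairs$plus_gene))), 0)
  # with uniform expression the per-decile allocation differs by <= 1
  bdp_fpkm <- rowMeans(expr[match(c(pairs$minus_gene, pairs$plus_gene),
                                  expr$gene_id), -1])
  qs <- stats::quantile(bdp_fpkm, probs = seq(0, 1, 0.1), names = FALSE)
  # allocation follows the BDP deciles: 10 equal groups of 2*2*20/10 = 8
  dec <- findInterval(ctl1$fpkm, c(-Inf, qs[2:10], Inf), rightmost.closed = TRUE)
  expect_true(max(table(dec)) - min(table(dec)) <= 1)
  # an impossible request names the failing decile
  few <- dplyr::bind_rows(c(pair_rows, udp_rows[1:10]))
  expr_few <- expr[expr$gene_id %in% few$gene_id, ]
  expect_error(select_udp_controls(few, pairs, expr_few, multiplier = 5, seed = 1),
               "decile")
})
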