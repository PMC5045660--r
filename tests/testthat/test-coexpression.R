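test_that("pair correlations follow the Pearson definition and its guards", {
  e <- mk_expr(list("a", c(1, 2, 3, 4)), list("b", c(1, 2, 3, 4)),
               list("c", c(4, 3, 2, 1)), list("d", c(2, 1, 4, 3)),
               list("z", c(0, 0, 0, 0)), list("k", c(5, 5, 5, 5)))
  expect_equal(pair_pcc(e, "a", "b"), 1)
  expect_equal(pair_pcc(e, "a", "c"), -1)    # y = -x + c
  expect_equal(pair_pcc(e, "a", "d"), 0.6)   # frozen from the closed form
  expect_true(is.na(pair_pcc(e, "a", "z")))  # all-zero gene excluded
  expect_true(is.na(pair_pcc(e, "a", "k")))  # zero variance
  expect_error(pair_pcc(e, "a", "missing"), "absent")
  # invariance under positive affine rescaling of each gene
  e2 <- e
  e2[e2$gene_id == "a", -1] <- e2[e2$gene_id == "a", -1] * 7 + 2
  e2[e2$gene_id == "d", -1] <- e2[e2$gene_id == "d", -1] * 0.3 + 11
  expect_equal(pair_pcc(e2, "a", "d"), 0.6)
})

test_that("thresholds are the means of the signed correlation halves", {
  th <- derive_thresholds(c(0.2, 0.6, -0.1, -0.3))
  expect_equal(th$pos_mean, 0.4)
  expect_equal(th$neg_mean, -0.2)
  expect_error(derive_thresholds(c(0.1, 0.5)), "negative")
  expect_error(derive_thresholds(c(-0.1, -0.5)), "positive")
  expect_error(coexpression_thresholds(-0.1, -0.2))
})

test_that("mode classification partitions every pair exactly once", {
  th <- coexpression_thresholds(0.38, -0.20)
  expect_equal(classify_mode(c(0.5, 0, -0.4, NA), th),
               c("coexpressed", "independent", "antiexpressed", "null"))
  # boundary values are independent (strict inequalities outside)
  expect_equal(classify_mode(c(0.38, -0.20), th),
               c("independent", "independent"))
  set.seed(2)
  pcc <- c(runif(200, -1, 1), NA)
  modes <- classify_mode(pcc, th)
  expect_true(all(modes %in% c("coexpressed", "antiexpressed", "independent",
                               "null")))
  expect_equal(sum(is.na(pcc)), sum(modes == "null"))
})

test_that("planted expression modes are recovered from the data", {
  sim <- shared_sim()
  pairs <- sim$truth$pairs
  cx <- coexpression_modes(sim$expression, pairs)
  expect_true(cx$thresholds$pos_mean > 0, )
  expect_true(cx$thresholds$neg_mean < 0)
  truth <- sim$truth$expression
  m <- dplyr::inner_join(cx$pairs[, c("pair_id", "mode")], truth, by = "pair_id")
  expect_gt(mean(m$mode.x == m$mode.y), 0.7)  # small-sample fixture
})

test_that("random adjacent duos avoid head-to-head pairs and reproduce", {
  sim <- shared_sim()
  pairs <- sim$truth$pairs
  duos <- random_adjacent_pairs(sim$genes, pairs, n = 10, seed = 5)
  expect_equal(nrow(duos), 10)
  expect_identical(duos, random_adjacent_pairs(sim$genes, pairs, n = 10, seed = 5))
  g <- gene_tss(sim$genes)
  for (i in seq_len(nrow(duos))) {
    a <- g[g$gene_id == duos$gene_a[i], ]
    b <- g[g$gene_id == duos$gene_b[i], ]
    h2h <- a$strand == "-" && b$strand == "+" && a$tss < b$tss &&
      (b$tss - a$tss) <= 1000
    expect_false(h2h)
  }
  expect_error(random_adjacent_pairs(sim$genes, pairs, n = 10000), "available")
})

test_that("coexpressed fraction by distance bins [0,1000] without gaps", {
  pairs <- tibble::tibble(distance = c(10, 150, 420, 980),
                          mode = rep("coexpressed", 4))
  tab <- coexpression_by_distance(pairs)
  expect_equal(tab$bin_start, seq(0, 900, 100))
  expect_equal(tab$bin_end, seq(100, 1000, 100))
  expect_true(all(tab$coexpressed_frac[tab$n_pairs > 0] == 1))
  expect_true(all(is.na(tab$coexpressed_frac[tab$n_pairs == 0])))
  # distance-decaying coexpression shows up as a decreasing trend
  set.seed(9)
  d <- runif(4000, 0, 1000)
  co <- rbinom(4000, 1, 0.9 - 0.7 * d / 1000) == 1
  tab2 <- coexpression_by_distance(tibble::tibble(
    distance = d, mode = ifelse(co, "coexpressed", "independent")))
  expect_lt(cor(tab2$bin_start, tab2$coexpressed_frac, method = "spearman"), -0.8)
})

test_that("mode summaries count pairs per type and mode", {
  pairs <- tibble::tibble(bdp_type = c("I", "I", "II"),
                          mode = c("coexpressed", "independent", "coexpressed"))
  ms <- mode_summary(pairs)
  expect_equal(sum(ms$n_pairs), 3)
  expect_equal(ms$fraction[ms$bdp_type == "I"], c(0.5, 0.5))
})
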