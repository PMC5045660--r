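test_that("window values follow the normalization and conservation identity", {
  rs <- mk_reads(rep(25, 10))     # 10 midpoints in the first 50-bp window
  wc <- window_counts(rs, "c1", 1, 1000, 20)
  expect_equal(wc$value[1], 10 / 50 / 1)   # total 1e6 -> per-million factor 1
  expect_equal(wc$value[-1], rep(0, 19))
  # empty read set
  wc0 <- window_counts(mk_reads(numeric(0)), "c1", 1, 1000, 20)
  expect_equal(wc0$value, rep(0, 20))
  # conservation, including intervals whose length is not divisible by 20
  set.seed(5)
  rs2 <- mk_reads(sample.int(5000, 800, replace = TRUE), total = 3e5)
  for (iv in list(c(1, 1000), c(37, 3101), c(400, 4399))) {
    wc2 <- window_counts(rs2, "c1", iv[1], iv[2], 20)
    raw <- sum(rs2$midpoints$pos >= iv[1] & rs2$midpoints$pos <= iv[2])
    expect_equal(sum(wc2$value * wc2$width * (rs2$total_mapped / 1e6)), raw,
                 tolerance = 1e-12)
    expect_equal(wc2$value,
                 oracle_window_values(rs2$midpoints$pos, iv[1], iv[2], 20,
                                      rs2$total_mapped))
  }
  # a midpoint exactly on a boundary belongs to the right window
  wcb <- window_counts(mk_reads(51), "c1", 1, 1000, 20)
  expect_equal(which(wcb$count == 1), 2)
  expect_error(window_counts(rs, "c1", 1, 10, 20), "shorter")
  expect_error(window_counts(mk_reads(1, total = 0), "c1", 1, 1000), "total_mapped")
})

test_that("metaprofiles average oriented per-locus windows", {
  set.seed(11)
  pos <- sample.int(10000, 500, replace = TRUE)
  rs <- mk_reads(pos, total = 1e5)
  a1 <- tibble::tibble(chrom = "c1", tss = 5000, strand = "+")
  prof <- meta_profile(rs, a1, flank = 1000)
  wc <- window_counts(rs, "c1", 4000, 5999, 40)
  expect_equal(prof$value, wc$value)
  # duplicating anchors leaves the mean unchanged
  prof2 <- meta_profile(rs, dplyr::bind_rows(a1, a1), flank = 1000)
  expect_equal(prof2$value, prof$value)
  # a minus-strand anchor reverses the axis
  am <- tibble::tibble(chrom = "c1", tss = 5000, strand = "-")
  profm <- meta_profile(rs, am, flank = 1000)
  expect_equal(profm$value, rev(prof$value))
  # normalization: duplicating every read and doubling the library cancels
  rs2 <- mk_reads(c(pos, pos), total = 2e5)
  expect_equal(meta_profile(rs2, a1, flank = 1000)$value, prof$value)
  # anchors too close to the contig edge are dropped and counted
  prof3 <- meta_profile(rs, dplyr::bind_rows(a1, tibble::tibble(
    chrom = "c1", tss = 300, strand = "+")), flank = 1000)
  expect_equal(attr(prof3, "n_dropped"), 1)
  expect_equal(prof3$value, prof$value)
})

test_that("pair profiles orient by expression and mirror under swaps", {
  # two pairs on one chromosome; reads enriched downstream of specific genes
  pairs <- tibble::tibble(pair_id = c("p1", "p2"),
                          minus_gene = c("m1", "m2"), plus_gene = c("p1g", "p2g"),
                          chrom = "c1",
                          tss_minus = c(10000, 30000), tss_plus = c(10200, 30200),
                          distance = 200, bdp_type = "I",
                          prom_start = c(10001, 30001), prom_end = c(10199, 30199))
  set.seed(21)
  # enrichment downstream of the plus genes (right of tss_plus)
  pos <- c(sample(10200:11199, 400, replace = TRUE),
           sample(30200:31199, 400, replace = TRUE),
           sample(9000:9999, 200, replace = TRUE),
           sample(29000:29999, 200, replace = TRUE))
  rs <- mk_reads(pos, total = 1e6)
  e_hi_plus <- mk_expr(list("m1", c(1, 1, 1)), list("p1g", c(9, 9, 9)),
                       list("m2", c(1, 1, 1)), list("p2g", c(9, 9, 9)))
  e_hi_minus <- mk_expr(list("m1", c(9, 9, 9)), list("p1g", c(1, 1, 1)),
                        list("m2", c(9, 9, 9)), list("p2g", c(1, 1, 1)))
  pr1 <- pair_profile(rs, pairs, e_hi_plus)
  pr2 <- pair_profile(rs, pairs, e_hi_minus)
  # swapping which gene is higher mirrors the profile about x = 0
  expect_equal(pr1$value, rev(pr2$value))
  # the 2x-enriched side: right/left mass ratio ~ 2 when the higher-FPKM
  # genes carry twice the reads
  expect_equal(sum(pr1$value[pr1$window_center > 0]) /
                 sum(pr1$value[pr1$window_center < 0]), 2, tolerance = 0.15)
  # FPKM ties break deterministically (lexicographic id on the right)
  e_tie <- mk_expr(list("m1", c(5, 5, 5)), list("p1g", c(5, 5, 5)),
                   list("m2", c(5, 5, 5)), list("p2g", c(5, 5, 5)))
  t1 <- pair_profile(rs, pairs, e_tie)
  t2 <- pair_profile(rs, pairs, e_tie)
  expect_equal(t1$value, t2$value)
})

test_that("gene signals normalize reads per bp per million in both scopes", {
  g <- tibble::tibble(gene_id = "g", chrom = "c1", start = 1001, end = 2000,
                      strand = "+", biotype = "protein_coding")
  rs <- mk_reads(sample(1001:2000, 100, replace = TRUE))
  expect_equal(gene_signal(rs, g, "gene_body")$value, 100 / 1000 / 1)
  expect_equal(gene_signal(mk_reads(5000), g, "gene_body")$value, 0)
  # peak window covers the 50 bp from +100 to +149 downstream of the TSS
  rsp <- mk_reads(c(1101, 1150, 1151))  # tss+100 in, tss+149 in, tss+150 out
  expect_equal(gene_signal(rsp, g, "peak_window")$value, 2 / 50 / 1)
  gm <- dplyr::mutate(g, strand = "-")
  rsm <- mk_reads(c(2000 - 100, 2000 - 149, 2000 - 150))
  expect_equal(gene_signal(rsm, gm, "peak_window")$value, 2 / 50 / 1)
  # strand flip leaves the gene-body value unchanged
  expect_equal(gene_signal(rs, gm, "gene_body")$value,
               gene_signal(rs, g, "gene_body")$value)
})

test_that("phased amplitude and occupancy change compare profile peaks", {
  prof <- structure(tibble::tibble(window_center = seq(-975, 975, by = 50),
                                   value = c(rep(1, 20), rep(2, 10), rep(1, 10)),
                                   n_loci = 5),
                    class = c("bdp_profile", class(tibble::tibble())))
  expect_equal(phased_amplitude(prof), 2)
  expect_equal(occupancy_change(prof, prof), 0)
  prof2 <- prof; prof2$value <- prof$value * 1.33
  expect_equal(occupancy_change(prof2, prof), 33, tolerance = 1e-9)
  prof0 <- prof; prof0$value <- 0
  expect_error(occupancy_change(prof, prof0), "zero")
})
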