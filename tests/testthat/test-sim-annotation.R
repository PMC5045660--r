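test_that("planted pairs land in their class distance intervals", {
  sim <- shared_sim()
  tp <- sim$truth$pairs
  expect_equal(nrow(tp), 18)
  expect_true(all(tp$distance[tp$bdp_type == "I"] >= 1 &
                    tp$distance[tp$bdp_type == "I"] <= 250))
  expect_true(all(tp$distance[tp$bdp_type == "II"] >= 251 &
                    tp$distance[tp$bdp_type == "II"] <= 500))
  expect_true(all(tp$distance[tp$bdp_type == "III"] >= 501 &
                    tp$distance[tp$bdp_type == "III"] <= 1000))
  expect_equal(tp$distance, tp$tss_plus - tp$tss_minus)
})

test_that("a pair-free simulation yields only unidirectional genes", {
  sim <- simulate_annotation(sim_config(seed = 5, n_pairs = c(I = 0, II = 0, III = 0),
                                        n_udp = 10, chromosome_length = 1e5))
  expect_equal(nrow(sim$genes), 10)
  expect_equal(nrow(sim$truth$pairs), 0)
})

test_that("pooled promoter GC matches the configured fraction within 3 s.e.", {
  cfg <- sim_config(seed = 7, n_pairs = c(I = 200, II = 0, III = 0), n_udp = 0,
                    chromosome_length = 2.5e6,
                    tata_rate = c(I = 0, II = 0, III = 0), udp_tata_rate = 0,
                    promoter_gc = c(I = 0.54, II = 0.50, III = 0.45))
  sim <- simulate_annotation(cfg)
  proms <- pair_promoter_seqs(sim$genome, sim$truth$pairs)
  proms <- proms[Biostrings::width(proms) > 0]
  total_bp <- sum(Biostrings::width(proms))
  pooled_gc <- sum(gc_content(proms) * Biostrings::width(proms)) / total_bp
  se <- sqrt(0.54 * 0.46 / total_bp)
  expect_lt(abs(pooled_gc - 0.54), 3 * se)
})

test_that("planted motifs are recorded and recoverable with zero misses", {
  cfg <- tiny_config(seed = 301, planted_motifs = tibble::tibble(
    name = c("GBOX", "ABRE"), pattern = c("CACGTG", "ACGTGKC"),
    rate = c(0.8, 0.6)))
  sim <- simulate_annotation(cfg)
  tm <- sim$truth$motifs
  expect_gt(nrow(tm[tm$motif != "TATA", ]), 0)
  pairs <- sim$truth$pairs
  for (i in seq_len(nrow(tm))) {
    if (tm$owner_type[i] != "pair") next
    pr <- pairs[pairs$pair_id == tm$owner[i], ]
    seq <- as.character(pair_promoter_seqs(sim$genome, pr)[[1]])
    rel <- tm$start[i] - pr$prom_start + 1
    hits <- scan_motif(seq, tm$pattern[i])
    expect_true(rel %in% hits$start[hits$strand == "+"],
                label = sprintf("planted %s at %d recovered", tm$motif[i], rel))
  }
})

test_that("regeneration under the same seed is bit-identical on disk", {
  cfg <- tiny_config(seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_bdp_data(cfg), d1)
  p2 <- write_simulation(simulate_bdp_data(cfg), d2)
  expect_equal(names(p1), names(p2))
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])),
                     label = paste("identical bytes for", k))
  }
})

test_that("infeasible packing fails with an explicit constraint error", {
  cfg <- sim_config(seed = 1, n_pairs = c(I = 50, II = 50, III = 50),
                    n_udp = 200, chromosome_length = 1e4)
  expect_error(simulate_annotation(cfg), "infeasible packing")
})

test_that("gene models round-trip through GFF3 with line-level validation", {
  sim <- shared_sim()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(sim$genes, path)
  back <- read_gene_models(path)
  expect_equal(
    dplyr::arrange(back, gene_id),
    dplyr::arrange(sim$genes, gene_id) %>%
      dplyr::mutate(start = as.integer(start), end = as.integer(end)))

  # empty file
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_gene_models(empty)), 0)

  # malformed line reported with its line number
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tx\tgene\t1\t10"), bad)
  expect_error(read_gene_models(bad), "line 2")

  # unknown strand
  bad2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("chr1\tsrc\tgene\t1\t10\t.\t*\t.\tID=g1"), bad2)
  expect_error(read_gene_models(bad2), "strand")

  # protein-coding filter drops non-coding genes
  nc <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1;biotype=protein_coding",
               "chr1\tsrc\tgene\t2001\t3000\t.\t+\t.\tID=g2;biotype=lncRNA"), nc)
  expect_equal(read_gene_models(nc, protein_coding = TRUE)$gene_id, "g1")
})
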