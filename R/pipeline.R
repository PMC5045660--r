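default_pipeline_params <- function() {
  list(max_dist = 1000, n_windows = 20, flank = 1000, reps = 1000,
       alpha = 0.05, fc = 2, seed = 1, multiplier = 1, bin_width = 100,
       n_adjacent = NULL, protein_coding = TRUE)
}

default_pipeline_stages <- function() {
  list(simulate = FALSE, identify = TRUE, seqfeat = TRUE, motifs = TRUE,
       coexpr = TRUE, profile = TRUE, stats = TRUE)
}

#' Read and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list with elements `paths` (gff, fasta,
#' expression, control, drought, motif_catalogue, reads: a named list of BED
#' paths, out_dir), `params` and `stages`; missing params/stages take their
#' defaults, and `sim_config` may hold [sim_config()] arguments for the
#' simulate stage.
#'
#' @param config Path to a YAML file or a list.
#' @return Normalized configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$paths <- config$paths %||% list()
  config$params <- utils::modifyList(default_pipeline_params(),
                                     config$params %||% list())
  config$stages <- utils::modifyList(default_pipeline_stages(),
                                     config$stages %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need_path <- function(config, field, stage) {
  p <- config$paths[[field]]
  if (is.null(p))
    abort(sprintf("stage '%s' is enabled but config$paths$%s is missing",
                  stage, field))
  p
}

#' Run the full bidirectional-promoter pipeline
#'
#' Executes the enabled stages in order — simulate (optional), identify,
#' sequence features, motif enrichment, coexpression, chromatin profiles,
#' statistics — writing every result table to `out_dir` together with a
#' `manifest.json` recording inputs, parameters and seed. Rerunning with an
#' identical configuration reproduces the tables byte for byte.
#'
#' @param config A YAML path or list, see [read_pipeline_config()].
#' @return Named list of written output paths (also in the manifest),
#'   invisibly; the loaded results are attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  params <- config$params
  stages <- config$stages
  out_dir <- config$paths$out_dir %||% abort("config$paths$out_dir is missing")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  results <- list()
  ran <- character(0)
  stage_msg <- function(s) message("[bdptools] stage: ", s)

  if (isTRUE(stages$simulate)) {
    stage_msg("simulate")
    sc <- do.call(sim_config, utils::modifyList(list(seed = params$seed),
                                                config$sim_config %||% list()))
    sim <- simulate_bdp_data(sc)
    simdir <- file.path(out_dir, "sim")
    paths <- write_simulation(sim, simdir)
    config$paths$gff <- paths[["annotation"]]
    config$paths$fasta <- paths[["genome"]]
    config$paths$expression <- paths[["expression"]]
    config$paths$control <- paths[["control"]]
    config$paths$drought <- paths[["drought"]]
    config$paths$reads <- as.list(paths[grep("^reads_", names(paths))])
    names(config$paths$reads) <- sub("^reads_", "", names(config$paths$reads))
    outputs$sim <- unname(paths)
    ran <- c(ran, "simulate")
  }

  genes <- NULL; pairs <- NULL; genome <- NULL; expr <- NULL
  if (isTRUE(stages$identify)) {
    stage_msg("identify")
    genes <- read_gene_models(need_path(config, "gff", "identify"),
                              protein_coding = params$protein_coding)
    pairs <- find_bidirectional_pairs(genes, max_dist = params$max_dist)
    outputs$pairs <- file.path(out_dir, "pairs.tsv")
    readr::write_tsv(pairs, outputs$pairs)
    # promoter intervals exported as BED (0-based half-open)
    outputs$promoters <- file.path(out_dir, "promoters.bed")
    readr::write_tsv(tibble(chrom = pairs$chrom,
                            start = pairs$prom_start - 1L,
                            end = pairs$prom_end,
                            name = pairs$pair_id),
                     outputs$promoters, col_names = FALSE)
    results$pairs <- pairs
    ran <- c(ran, "identify")
  }

  if (isTRUE(stages$seqfeat)) {
    stage_msg("seqfeat")
    if (is.null(pairs)) abort("stage 'seqfeat' needs stage 'identify'")
    genome <- Biostrings::readDNAStringSet(need_path(config, "fasta", "seqfeat"))
    names(genome) <- sub("\\s.*$", "", names(genome))
    proms <- pair_promoter_seqs(genome, pairs)
    feats <- promoter_features(proms) %>%
      left_join(select(pairs, owner_id = "pair_id", "bdp_type", "distance"),
                by = "owner_id")
    outputs$promoter_features <- file.path(out_dir, "promoter_features.tsv")
    readr::write_tsv(feats, outputs$promoter_features)
    results$promoter_features <- feats
    ran <- c(ran, "seqfeat")
  }

  if (isTRUE(stages$motifs)) {
    stage_msg("motifs")
    if (is.null(pairs) || is.null(genome))
      abort("stage 'motifs' needs stages 'identify' and 'seqfeat'")
    catalogue <- read_motif_catalogue(
      need_path(config, "motif_catalogue", "motifs"))
    udp <- unidirectional_genes(genes, pairs, max_dist = params$max_dist)
    enr <- purrr::map_dfr(c(I = 250, II = 500, III = 1000), function(len) {
      cls <- names(which(c(I = 250, II = 500, III = 1000) == len))
      inquiry_pairs <- filter(pairs, .data$bdp_type == cls)
      if (!nrow(inquiry_pairs)) return(tibble())
      inquiry <- pair_promoter_seqs(genome, inquiry_pairs)
      inquiry <- inquiry[Biostrings::width(inquiry) > 0]
      pool <- udp_promoter_pool(genome, udp, len)
      res <- enriched_motifs(inquiry, catalogue, pool, alpha = params$alpha,
                             reps = params$reps, seed = params$seed,
                             keep_all = TRUE)
      mutate(tidy(res), bdp_type = cls)
    })
    outputs$motif_enrichment <- file.path(out_dir, "motif_enrichment.tsv")
    readr::write_tsv(enr, outputs$motif_enrichment)
    results$motif_enrichment <- enr
    ran <- c(ran, "motifs")
  }

  if (isTRUE(stages$coexpr)) {
    stage_msg("coexpr")
    if (is.null(pairs)) abort("stage 'coexpr' needs stage 'identify'")
    expr <- read_expression_matrix(need_path(config, "expression", "coexpr"))
    cx <- coexpression_modes(expr, pairs)
    by_dist <- coexpression_by_distance(cx$pairs, bin_width = params$bin_width)
    outputs$coexpression <- file.path(out_dir, "coexpression.tsv")
    readr::write_tsv(select(cx$pairs, "pair_id", "pcc", "mode", "distance",
                            "bdp_type"), outputs$coexpression)
    outputs$coexpression_summary <- file.path(out_dir, "coexpression_summary.tsv")
    readr::write_tsv(mode_summary(cx$pairs), outputs$coexpression_summary)
    outputs$coexpression_by_distance <- file.path(out_dir,
                                                  "coexpression_by_distance.tsv")
    readr::write_tsv(by_dist, outputs$coexpression_by_distance)
    # adjacent unidirectional duos as the correlation control
    in_expr <- genes[genes$gene_id %in% expr$gene_id, ]
    duos <- random_adjacent_pairs(in_expr, pairs, n = params$n_adjacent,
                                  seed = params$seed,
                                  max_dist = params$max_dist)
    duos$pcc <- pair_pcc(expr, duos$gene_a, duos$gene_b)
    outputs$adjacent_pccs <- file.path(out_dir, "adjacent_pccs.tsv")
    readr::write_tsv(duos, outputs$adjacent_pccs)
    results$coexpression <- cx
    results$coexpression_by_distance <- by_dist
    results$adjacent <- duos
    ran <- c(ran, "coexpr")
  }

  controls <- NULL
  if ((isTRUE(stages$profile) || isTRUE(stages$stats)) && !is.null(expr) &&
      !is.null(pairs) && nrow(pairs)) {
    controls <- select_udp_controls(genes, pairs, expr,
                                    multiplier = params$multiplier,
                                    promoter_length = 1000,
                                    seed = params$seed,
                                    max_dist = params$max_dist)
  }

  readsets <- NULL
  if (isTRUE(stages$profile) || isTRUE(stages$stats)) {
    rp <- need_path(config, "reads", "profile/stats")
    readsets <- lapply(rp, read_read_set)
  }

  if (isTRUE(stages$profile)) {
    stage_msg("profile")
    if (is.null(pairs)) abort("stage 'profile' needs stage 'identify'")
    anchors_bdp <- tibble(chrom = rep(pairs$chrom, 2),
                          tss = c(pairs$tss_minus, pairs$tss_plus),
                          strand = rep(c("-", "+"), each = nrow(pairs)))
    prof <- purrr::map_dfr(names(readsets), function(mark) {
      rs <- readsets[[mark]]
      p_bdp <- meta_profile(rs, anchors_bdp, flank = params$flank)
      rows <- mutate(as_tibble(p_bdp), mark = mark, set = "bdp_tss")
      if (!is.null(controls) && nrow(controls)) {
        p_udp <- meta_profile(rs, select(gene_tss(controls), "chrom", "tss",
                                         "strand"), flank = params$flank)
        rows <- bind_rows(rows, mutate(as_tibble(p_udp), mark = mark,
                                       set = "udp_tss"))
      }
      if (!is.null(expr)) {
        p_pair <- pair_profile(rs, pairs, expr, flank = params$flank)
        rows <- bind_rows(rows, mutate(as_tibble(p_pair), mark = mark,
                                       set = "pair_oriented"))
      }
      rows
    })
    outputs$profiles <- file.path(out_dir, "profiles.tsv")
    readr::write_tsv(prof, outputs$profiles)
    results$profiles <- prof
    ran <- c(ran, "profile")
  }

  if (isTRUE(stages$stats)) {
    stage_msg("stats")
    if (is.null(pairs)) abort("stage 'stats' needs stage 'identify'")
    bdp_genes <- filter(genes, .data$gene_id %in%
                          c(pairs$minus_gene, pairs$plus_gene))
    ks <- purrr::map_dfr(names(readsets), function(mark) {
      rs <- readsets[[mark]]
      sig <- bind_rows(
        mutate(gene_signal(rs, bdp_genes, "gene_body"), group = "bdp"),
        if (!is.null(controls) && nrow(controls))
          mutate(gene_signal(rs, controls, "gene_body"), group = "udp"))
      if (!all(c("bdp", "udp") %in% sig$group)) return(tibble())
      ks_signal_tests(sig, "bdp", "udp")
    })
    outputs$ks_tests <- file.path(out_dir, "ks_tests.json")
    jsonlite::write_json(ks, outputs$ks_tests, digits = NA, pretty = TRUE)
    results$ks_tests <- ks
    if (!is.null(config$paths$control) && !is.null(config$paths$drought)) {
      ctl <- read_expression_matrix(config$paths$control)
      drt <- read_expression_matrix(config$paths$drought)
      de <- drought_de_pairs(ctl, drt, pairs, fc = params$fc)
      outputs$drought_pairs <- file.path(out_dir, "drought_pairs.tsv")
      readr::write_tsv(de, outputs$drought_pairs)
      results$drought <- de
    }
    ran <- c(ran, "stats")
  }

  manifest <- list(package = "bdptools",
                   version = as.character(utils::packageVersion("bdptools")),
                   seed = params$seed,
                   params = params,
                   stages_run = ran,
                   inputs = config$paths[setdiff(names(config$paths), "out_dir")],
                   outputs = lapply(outputs, unname))
  outputs$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, outputs$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  out <- outputs
  attr(out, "results") <- results
  invisible(out)
}

#' Background pool of unidirectional promoters of one length class
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param udp_genes Unidirectional gene models (see [unidirectional_genes()]).
#' @param length_class Promoter length in bp (250, 500 or 1000).
#' @return `DNAStringSet` of upstream promoter sequences (genes too close to
#'   a chromosome end are skipped).
#' @export
udp_promoter_pool <- function(genome, udp_genes, length_class) {
  g <- gene_tss(udp_genes)
  lens <- setNames(Biostrings::width(genome), names(genome))
  iv <- tibble(chrom = g$chrom,
               start = ifelse(g$strand == "+", g$tss - length_class, g$tss + 1),
               end = ifelse(g$strand == "+", g$tss - 1, g$tss + length_class),
               strand = g$strand)
  ok <- iv$start >= 1 & iv$end <= lens[iv$chrom]
  extract_promoters(genome, iv[ok, ], names = g$gene_id[ok])
}
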