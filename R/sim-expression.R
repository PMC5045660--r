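#' Simulate FPKM expression matrices with planted pair correlations
#'
#' Draws, for every planted head-to-head pair, log-FPKM values from a
#' bivariate normal with the correlation configured for the pair's planted
#' coexpression mode, then exponentiates; unidirectional genes get independent
#' draws. Also produces paired control/drought condition matrices in which the
#' planted fold changes multiply the control values exactly, so the
#' drought/control ratio equals the planted fold change by construction.
#'
#' @param sim A `bdp_sim` from [simulate_annotation()].
#' @param noise_free If `TRUE`, the per-library noise of the two genes of a
#'   pair is forced perfectly dependent (useful with `pair_correlation = 1` to
#'   check degenerate-correlation behaviour).
#' @return `sim` augmented with `expression` (tibble: `gene_id` + one column
#'   per library), `condition` (list of `control` and `drought` tibbles) and
#'   `truth$expression` (pair_id, planted mode, planted r, fold_change).
#' @export
simulate_expression <- function(sim, noise_free = FALSE) {
  stopifnot(inherits(sim, "bdp_sim"))
  cfg <- sim$config
  if (any(abs(cfg$pair_correlation) > 1)) abort("|r| > 1 is not a correlation")
  withr::with_seed(cfg$seed + 1L, sim_expression_impl(sim, noise_free))
}

# One bivariate-normal noise matrix (n_lib x 2) with correlation r, unit sd.
bivn_noise <- function(n_lib, r, sd) {
  z1 <- rnorm(n_lib)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(n_lib)
  cbind(z1, z2) * sd
}

sim_expression_impl <- function(sim, noise_free) {
  cfg <- sim$config
  pairs <- sim$truth$pairs
  tg <- sim$truth$genes
  n_lib <- cfg$n_libraries
  lib_ids <- sprintf("lib_%02d", seq_len(n_lib))
  sdn <- if (noise_free) 0 else cfg$library_noise_sd

  modes <- names(cfg$mode_probs)
  pair_mode <- if (nrow(pairs)) sample(modes, nrow(pairs), replace = TRUE,
                                       prob = cfg$mode_probs) else character(0)
  pair_r <- unname(cfg$pair_correlation[pair_mode])

  expr <- matrix(NA_real_, nrow = nrow(tg), ncol = n_lib,
                 dimnames = list(tg$gene_id, lib_ids))
  base_mu <- rnorm(nrow(tg), cfg$log_fpkm_mean, cfg$log_fpkm_sd)
  names(base_mu) <- tg$gene_id

  for (i in seq_len(nrow(pairs))) {
    g <- c(pairs$minus_gene[i], pairs$plus_gene[i])
    r <- pair_r[i]
    noise <- if (noise_free) {
      z <- rnorm(n_lib)
      cbind(z, sign(r) * z) * cfg$library_noise_sd
    } else bivn_noise(n_lib, r, sdn)
    expr[g[1], ] <- exp(base_mu[g[1]] + noise[, 1])
    expr[g[2], ] <- exp(base_mu[g[2]] + noise[, 2])
  }
  udp_ids <- tg$gene_id[tg$role == "udp"]
  for (g in udp_ids) expr[g, ] <- exp(base_mu[g] + rnorm(n_lib, 0, sdn))

  # Paired condition matrices: control replicates with fresh noise, drought =
  # control x planted fold change (exact ratio).
  n_rep <- cfg$n_condition_reps
  ctl <- matrix(exp(base_mu[tg$gene_id] +
                      rnorm(nrow(tg) * n_rep, 0, sdn)),
                nrow = nrow(tg), ncol = n_rep,
                dimnames = list(tg$gene_id, sprintf("ctl_%02d", seq_len(n_rep))))
  fc_gene <- setNames(rep(1, nrow(tg)), tg$gene_id)
  fcs <- cfg$drought_fold_changes
  fc_pairs <- character(0)
  if (length(fcs) && nrow(pairs)) {
    n_fc <- min(length(fcs), nrow(pairs))
    fc_pairs <- sample(pairs$pair_id, n_fc)
    for (k in seq_len(n_fc)) {
      pr <- pairs[pairs$pair_id == fc_pairs[k], ]
      fc_gene[c(pr$minus_gene, pr$plus_gene)] <- fcs[k]
    }
  }
  drt <- ctl * fc_gene[rownames(ctl)]
  colnames(drt) <- sprintf("drt_%02d", seq_len(n_rep))

  pair_fc <- setNames(rep(1, nrow(pairs)), pairs$pair_id)
  if (length(fc_pairs)) pair_fc[fc_pairs] <- fcs[seq_along(fc_pairs)]

  sim$expression <- as_tibble(expr, rownames = "gene_id")
  sim$condition <- list(control = as_tibble(ctl, rownames = "gene_id"),
                        drought = as_tibble(drt, rownames = "gene_id"))
  sim$truth$expression <- tibble(pair_id = pairs$pair_id,
                                 mode = pair_mode, r = pair_r,
                                 fold_change = unname(pair_fc))
  sim
}
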