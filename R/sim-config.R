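#' Configuration for the synthetic BDP genome generator
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' The defaults encode the study conditions the generator emulates: three BDP
#' distance classes (type I 1-250 bp, II 251-500 bp, III 501-1000 bp between
#' TSSs), promoter GC falling with BDP size (54/50/45%), TATA-box frequency
#' rising with size (18/52/82%), eleven expression libraries, ~200 bp phased
#' nucleosome arrays flanking a promoter nucleosome-depleted region (NDR), and
#' per-class enrichment of chromatin marks.
#'
#' @param seed Integer seed. Every output file draws from its own RNG stream
#'   seeded as `seed + <stable file index>`, so adding a mark never perturbs
#'   the other outputs.
#' @param n_pairs Named integer vector `c(I=, II=, III=)`: number of planted
#'   head-to-head pairs per distance class.
#' @param n_udp Number of unidirectional (control) genes.
#' @param chromosome_length Length in bp of the single simulated chromosome.
#' @param gene_length Length range (bp) genes are drawn from, uniformly.
#' @param gap Range (bp) of the gap between successive loci; its minimum must
#'   exceed `max_dist` used downstream (default > 1000 bp) so no accidental
#'   head-to-head pair arises between loci.
#' @param promoter_gc Named fractions `c(I=, II=, III=)`: expected GC of the
#'   intergenic promoter of each BDP class.
#' @param udp_promoter_gc,background_gc Expected GC of UDP promoters and of
#'   the rest of the chromosome.
#' @param udp_promoter_length Length (bp) of the upstream region treated as a
#'   UDP promoter.
#' @param tata_rate Named fractions `c(I=, II=, III=)`: probability that a BDP
#'   promoter receives one planted TATA box.
#' @param udp_tata_rate Same for UDP promoters.
#' @param tata_pattern IUPAC pattern planted as the TATA box.
#' @param planted_motifs `NULL` or a data frame with columns `name`, `pattern`
#'   (IUPAC) and `rate` (per-promoter planting probability in BDP promoters).
#' @param pair_correlation Named reals in `[-1, 1]`: the log-scale expression
#'   correlation planted for each coexpression mode.
#' @param mode_probs Named probabilities summing to 1: how planted pairs are
#'   allocated to coexpression modes.
#' @param n_libraries Number of expression libraries (columns of the FPKM
#'   matrix).
#' @param log_fpkm_mean,log_fpkm_sd Mean and SD of per-gene baseline natural
#'   log FPKM.
#' @param library_noise_sd SD of the per-library log-FPKM fluctuation around
#'   the gene baseline (about a two-fold typical spread at 0.3).
#' @param n_condition_reps Replicate libraries per condition in the paired
#'   control/drought matrices.
#' @param drought_fold_changes Numeric vector of fold changes; each is planted
#'   on one randomly chosen pair (both genes), applied multiplicatively to the
#'   control replicates. Values > 1 are up-regulation, < 1 down-regulation.
#' @param marks Named list describing read sets to simulate. Each element is a
#'   list with `assay` (`"chip"` or `"mnase"`) and `enrichment`, a named
#'   positive vector over classes `c(I=, II=, III=, udp=)` scaling the peak
#'   intensity at loci of that class.
#' @param reads_per_mark Total midpoints emitted per mark (the library size).
#' @param nucleosome_spacing Nucleosome repeat length in bp (default 200).
#' @param nucleosome_sd SD (bp) of each nucleosome's Gaussian footprint.
#' @param n_nucleosomes Nucleosomes per array on each side of a TSS.
#' @param nucleosome_decay Multiplicative amplitude decay per nucleosome into
#'   the gene body.
#' @param ndr_width Width parameter of the NDR: the depletion well is a
#'   Gaussian of sigma `ndr_width/2` centred on the promoter midpoint.
#' @param ndr_depth Intensity multiplier at the bottom of the NDR well
#'   (1 = no depletion).
#' @param baseline Flat background intensity relative to unit peak amplitude.
#'
#' @return A validated list of class `bdp_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_pairs = c(I = 5, II = 5, III = 5), n_udp = 20)
#' sim <- simulate_annotation(cfg)
#' nrow(sim$truth$pairs)
sim_config <- function(seed = 1,
                       n_pairs = c(I = 30L, II = 30L, III = 30L),
                       n_udp = 120L,
                       chromosome_length = 2e6,
                       gene_length = c(1000, 2000),
                       gap = c(1200, 3000),
                       promoter_gc = c(I = 0.54, II = 0.50, III = 0.45),
                       udp_promoter_gc = 0.40,
                       background_gc = 0.43,
                       udp_promoter_length = 1000,
                       tata_rate = c(I = 0.18, II = 0.52, III = 0.82),
                       udp_tata_rate = 0.48,
                       tata_pattern = "TATAAAT",
                       planted_motifs = NULL,
                       pair_correlation = c(coexpressed = 0.9,
                                            antiexpressed = -0.8,
                                            independent = 0),
                       mode_probs = c(coexpressed = 0.5,
                                      antiexpressed = 0.2,
                                      independent = 0.3),
                       n_libraries = 11L,
                       log_fpkm_mean = 2,
                       log_fpkm_sd = 1,
                       library_noise_sd = 0.3,
                       n_condition_reps = 3L,
                       drought_fold_changes = c(rep(4, 8), rep(0.25, 8)),
                       marks = default_sim_marks(),
                       reads_per_mark = 2e5,
                       nucleosome_spacing = 200,
                       nucleosome_sd = 40,
                       n_nucleosomes = 5L,
                       nucleosome_decay = 0.85,
                       ndr_width = 150,
                       ndr_depth = 0.1,
                       baseline = 0.02) {
  cfg <- as.list(environment())
  class(cfg) <- "bdp_sim_config"
  validate_sim_config(cfg)
}

#' Default simulated read sets
#'
#' One MNase library with uniformly higher occupancy at BDPs (1.3x) and two
#' ChIP marks: an active acetylation mark enriched most in type I BDPs and a
#' repressive mark depleted at BDPs.
#'
#' @return Named list suitable for the `marks` field of [sim_config()].
#' @export
default_sim_marks <- function() {
  list(
    mnase = list(assay = "mnase",
                 enrichment = c(I = 1.3, II = 1.3, III = 1.3, udp = 1)),
    H3K4ac = list(assay = "chip",
                  enrichment = c(I = 2, II = 1.5, III = 1.2, udp = 1)),
    H3K27me3 = list(assay = "chip",
                    enrichment = c(I = 0.5, II = 0.7, III = 0.8, udp = 1))
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "bdp_sim_config"))
  # tolerate YAML round-trips that turn named vectors into lists
  for (f in c("n_pairs", "promoter_gc", "tata_rate", "pair_correlation",
              "mode_probs", "gene_length", "gap", "drought_fold_changes"))
    cfg[[f]] <- unlist(cfg[[f]])
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid sim_config: ", msg))
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be a single number")
  chk(all(c("I", "II", "III") %in% names(cfg$n_pairs)),
      "n_pairs needs names I, II, III")
  chk(all(cfg$n_pairs >= 0) && cfg$n_udp >= 0, "counts must be >= 0")
  chk(all(cfg$promoter_gc >= 0 & cfg$promoter_gc <= 1) &&
        cfg$udp_promoter_gc >= 0 && cfg$udp_promoter_gc <= 1 &&
        cfg$background_gc >= 0 && cfg$background_gc <= 1,
      "GC fractions must lie in [0, 1]")
  chk(all(cfg$tata_rate >= 0 & cfg$tata_rate <= 1) &&
        cfg$udp_tata_rate >= 0 && cfg$udp_tata_rate <= 1,
      "TATA rates must lie in [0, 1]")
  chk(all(cfg$pair_correlation >= -1 & cfg$pair_correlation <= 1),
      "pair_correlation must lie in [-1, 1]")
  chk(abs(sum(cfg$mode_probs) - 1) < 1e-8, "mode_probs must sum to 1")
  chk(cfg$nucleosome_spacing > 0, "nucleosome_spacing must be > 0")
  chk(cfg$ndr_depth >= 0, "ndr_depth must be >= 0")
  chk(cfg$n_libraries >= 2, "need at least 2 libraries")
  for (m in names(cfg$marks)) {
    enr <- cfg$marks[[m]]$enrichment
    chk(all(enr > 0), sprintf("mark_enrichment for '%s' must be positive", m))
  }
  if (!is.null(cfg$planted_motifs)) {
    pm <- cfg$planted_motifs
    chk(all(c("name", "pattern", "rate") %in% names(pm)),
        "planted_motifs needs columns name, pattern, rate")
    chk(all(pm$rate >= 0 & pm$rate <= 1), "motif rates must lie in [0, 1]")
  }
  cfg
}
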