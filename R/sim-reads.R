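#' Construct a read set of midpoint positions
#'
#' Light container for single-base read midpoints of one sequencing library
#' (ChIP of a histone mark, or MNase for nucleosome occupancy) together with
#' its library size, the denominator of all per-million normalizations.
#'
#' @param mark Mark/library name.
#' @param midpoints Tibble with columns `chrom` and `pos` (1-based midpoint).
#' @param total_mapped Total mapped reads of the library (>= `nrow(midpoints)`).
#' @param assay `"chip"` or `"mnase"`.
#' @return An object of class `bdp_read_set`.
#' @export
read_set <- function(mark, midpoints, total_mapped = nrow(midpoints),
                     assay = c("chip", "mnase")) {
  assay <- match.arg(assay)
  stopifnot(all(c("chrom", "pos") %in% names(midpoints)),
            total_mapped >= nrow(midpoints))
  structure(list(mark = mark, assay = assay,
                 midpoints = as_tibble(midpoints)[c("chrom", "pos")],
                 total_mapped = as.numeric(total_mapped)),
            class = "bdp_read_set")
}

#' @export
print.bdp_read_set <- function(x, ...) {
  cat(sprintf("<bdp_read_set> %s (%s): %d midpoints, %g total mapped\n",
              x$mark, x$assay, nrow(x$midpoints), x$total_mapped))
  invisible(x)
}

# Per-base sampling intensity for one mark over the simulated chromosome.
# Nucleosome Gaussians at (spacing/2 + k*spacing) downstream of each TSS,
# amplitude decaying into the gene body and scaled by the class enrichment;
# a Gaussian NDR well over each promoter midpoint multiplies the whole
# intensity. Arrays run into the gene body only: in a head-to-head pair the
# upstream flank of each promoter is provided by the partner gene, so
# emitting a second upstream array would stack two arrays at BDPs and break
# the configured per-class enrichment contrast.
sim_mark_intensity <- function(sim, enrichment) {
  cfg <- sim$config
  L <- cfg$chromosome_length
  peaks <- numeric(L)
  sdn <- cfg$nucleosome_sd
  half <- cfg$nucleosome_spacing / 2
  add_gauss <- function(center, amp, sdv) {
    lo <- max(1, floor(center - 4 * sdv)); hi <- min(L, ceiling(center + 4 * sdv))
    if (hi < lo) return(invisible())
    xs <- lo:hi
    peaks[xs] <<- peaks[xs] + amp * exp(-(xs - center)^2 / (2 * sdv^2))
  }
  tg <- sim$truth$genes
  for (i in seq_len(nrow(tg))) {
    enr <- enrichment[[tg$class[i]]]
    dir <- if (tg$strand[i] == "+") 1 else -1
    tss <- tg$tss[i]
    if (cfg$n_nucleosomes > 0) {
      for (k in 0:(cfg$n_nucleosomes - 1)) {
        amp <- enr * cfg$nucleosome_decay^k
        off <- half + k * cfg$nucleosome_spacing
        add_gauss(tss + dir * off, amp, sdn)   # into the gene body
      }
    }
  }
  intensity <- cfg$baseline + peaks
  # NDR: flat depletion over the promoter interval itself (between the two
  # TSSs for a pair; ndr_width bp upstream of the TSS for a UDP gene), so the
  # +1 nucleosome just downstream is untouched and the planted per-class
  # enrichment of the peaks stays exactly recoverable.
  well <- function(lo, hi) {
    lo <- max(1, lo); hi <- min(L, hi)
    if (hi >= lo) intensity[lo:hi] <<- intensity[lo:hi] * cfg$ndr_depth
  }
  prs <- sim$truth$pairs
  for (i in seq_len(nrow(prs))) well(prs$tss_minus[i], prs$tss_plus[i])
  udp <- tg[tg$role == "udp", ]
  for (i in seq_len(nrow(udp))) {
    if (udp$strand[i] == "+") well(udp$tss[i] - cfg$ndr_width, udp$tss[i] - 1)
    else well(udp$tss[i] + 1, udp$tss[i] + cfg$ndr_width)
  }
  intensity
}

#' Simulate read sets with planted nucleosome arrays and mark enrichment
#'
#' For every mark configured in `config$marks`, samples `reads_per_mark`
#' single-base read midpoints from a per-base intensity with a depleted NDR
#' over each promoter, a ~`nucleosome_spacing` bp phased Gaussian nucleosome
#' array running from each TSS into its gene body (amplitude decaying with
#' distance; in a head-to-head pair the two genes' arrays flank the shared
#' promoter from both sides) and per-class enrichment of the peaks. Each mark uses its own RNG stream
#' (`seed + 10 + mark index`), so adding a mark never changes the others.
#'
#' @param sim A `bdp_sim` from [simulate_annotation()].
#' @return `sim` augmented with `reads`, a named list of [read_set()] objects.
#' @export
simulate_reads <- function(sim) {
  stopifnot(inherits(sim, "bdp_sim"))
  cfg <- sim$config
  chrom <- names(sim$genome)
  out <- list()
  for (mi in seq_along(cfg$marks)) {
    mark <- names(cfg$marks)[mi]
    spec <- cfg$marks[[mi]]
    if (any(spec$enrichment <= 0)) abort("mark_enrichment must be > 0")
    out[[mark]] <- withr::with_seed(cfg$seed + 10L + mi, {
      intensity <- sim_mark_intensity(sim, spec$enrichment)
      cum <- cumsum(intensity)
      u <- runif(cfg$reads_per_mark) * cum[length(cum)]
      pos <- findInterval(u, cum) + 1L
      read_set(mark, tibble(chrom = chrom, pos = sort(pos)),
               total_mapped = cfg$reads_per_mark, assay = spec$assay)
    })
  }
  sim$reads <- out
  sim
}

#' Run the whole synthetic-data generator
#'
#' Convenience wrapper: [simulate_annotation()] then [simulate_expression()]
#' then [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @return A complete `bdp_sim` object.
#' @export
simulate_bdp_data <- function(config) {
  simulate_annotation(config) %>%
    simulate_expression() %>%
    simulate_reads()
}
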