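#' Resample background promoter lists
#'
#' Draws `reps` lists of `n_sequences` promoters each (without replacement
#' within a list) from a pool of unidirectional promoters of the matching
#' length class. These are the negative controls against which motif
#' abundances are standardized.
#'
#' @param pool `DNAStringSet` of background promoters (one length class), or
#'   an integer pool size.
#' @param n_sequences Sequences per replicate list (match the inquiry set).
#' @param reps Number of replicate lists (default 1000).
#' @param seed Integer seed.
#' @return List of `reps` integer index vectors into the pool.
#' @export
sample_background <- function(pool, n_sequences, reps = 1000, seed = 1) {
  n_pool <- if (is.numeric(pool)) pool else length(pool)
  if (n_pool < n_sequences)
    abort(sprintf("background pool too small: %d sequences, need %d",
                  n_pool, n_sequences))
  withr::with_seed(seed,
    lapply(seq_len(reps), function(i) sample.int(n_pool, n_sequences)))
}

#' The motif overrepresentation Z statistic
#'
#' `motif_z()` applies the formula `z = (x_bar - mu) / (sigma / sqrt(n))`,
#' where `x_bar` is the mean motif abundance per inquiry sequence, `mu` the
#' mean abundance in the resampled background, `sigma` the per-sequence
#' standard deviation of abundance in the background, and `n` the number of
#' inquiry sequences. `motif_zscore()` computes the inputs from data: since
#' each of the `reps` background lists holds `n` sequences, the standard
#' deviation of the replicate means estimates `sigma / sqrt(n)`, so `sigma`
#' is recovered as `sd(replicate_means) * sqrt(n)`.
#'
#' The p-value is the one-sided upper-tail standard-normal probability
#' (overrepresentation only). A degenerate background (`sigma = 0`) gives
#' `z = 0, p = 0.5` when `x_bar == mu` and `p = 0` with `sigma_zero = TRUE`
#' otherwise.
#'
#' @param x_bar,mu,sigma,n Components of the formula.
#' @return `motif_z()`: the z value. `motif_zscore()`: a one-row tibble with
#'   `x_bar`, `mu`, `sigma`, `n`, `z`, `p`, `sigma_zero`.
#' @export
#' @examples
#' motif_z(x_bar = 2, mu = 1, sigma = 0.5, n = 3)  # 3.4641
motif_z <- function(x_bar, mu, sigma, n) {
  stopifnot(n >= 1, sigma >= 0)
  if (sigma == 0) {
    if (x_bar == mu) return(0)
    return(sign(x_bar - mu) * Inf)
  }
  (x_bar - mu) / (sigma / sqrt(n))
}

#' @rdname motif_z
#' @param inquiry_abundances Occurrence count of the motif in each inquiry
#'   sequence.
#' @param background_replicate_means Mean abundance of the motif in each
#'   background replicate list.
#' @export
motif_zscore <- function(inquiry_abundances, background_replicate_means) {
  n <- length(inquiry_abundances)
  stopifnot(n >= 1, length(background_replicate_means) >= 2)
  x_bar <- mean(inquiry_abundances)
  mu <- mean(background_replicate_means)
  sigma <- sd(background_replicate_means) * sqrt(n)
  z <- motif_z(x_bar, mu, sigma, n)
  p <- if (is.infinite(z)) { if (z > 0) 0 else 1 } else pnorm(z, lower.tail = FALSE)
  tibble(x_bar = x_bar, mu = mu, sigma = sigma, n = n, z = z, p = p,
         sigma_zero = sigma == 0)
}

#' Length class of a promoter set
#'
#' Inquiry sets are routed to the background of the matching promoter length:
#' sets whose sequences are at most 250 bp use the 250 bp background, at most
#' 500 bp the 500 bp background, and anything longer the 1000 bp background.
#'
#' @param lengths Sequence lengths in bp.
#' @return One of 250, 500, 1000.
#' @export
promoter_length_class <- function(lengths) {
  m <- max(lengths)
  if (m <= 250) 250 else if (m <= 500) 500 else 1000
}

#' Overrepresented motifs in an inquiry promoter set
#'
#' Scans every catalogue motif over every inquiry sequence (both strands,
#' occurrence counts) and over a pool of unidirectional promoters, resamples
#' `reps` background lists of the inquiry size from the pool, and standardizes
#' each motif's inquiry abundance with [motif_zscore()]. Motifs with
#' `p < alpha` are reported as overrepresented.
#'
#' @param inquiry `DNAStringSet` of inquiry promoter sequences.
#' @param catalogue Motif catalogue tibble (`name`, `pattern`; see
#'   [read_motif_catalogue()]).
#' @param udp_pool Background promoters: a `DNAStringSet`, or a named list of
#'   `DNAStringSet`s keyed `"250"`, `"500"`, `"1000"` from which the class
#'   matching the inquiry lengths ([promoter_length_class()]) is selected.
#' @param alpha Significance cutoff on the (unadjusted, one-sided) p-value.
#' @param reps Background replicates (default 1000).
#' @param seed Integer seed for the background resampling.
#' @param adjust `"none"` (default, mirroring a plain p < alpha filter) or
#'   `"BH"` for Benjamini-Hochberg adjustment before filtering.
#' @param keep_all Return all motifs (with a `significant` flag) instead of
#'   only the significant ones.
#' @return Tibble of class `bdp_enrichment`, sorted by p: `name`, `pattern`,
#'   `x_bar`, `mu`, `sigma`, `n`, `z`, `p` (and `p_adj` if adjusted).
#' @export
enriched_motifs <- function(inquiry, catalogue, udp_pool, alpha = 0.05,
                            reps = 1000, seed = 1, adjust = c("none", "BH"),
                            keep_all = FALSE) {
  adjust <- match.arg(adjust)
  if (is.null(catalogue) || !nrow(catalogue)) abort("empty motif catalogue")
  inquiry <- as_dna_set(inquiry)
  if (!length(inquiry)) abort("empty inquiry set")
  if (is.list(udp_pool) && !inherits(udp_pool, "DNAStringSet")) {
    cls <- as.character(promoter_length_class(Biostrings::width(inquiry)))
    if (!cls %in% names(udp_pool))
      abort(sprintf("udp_pool has no background for length class %s bp", cls))
    udp_pool <- udp_pool[[cls]]
  }
  udp_pool <- as_dna_set(udp_pool)
  n <- length(inquiry)
  idx <- sample_background(udp_pool, n, reps = reps, seed = seed)

  inquiry_counts <- vapply(catalogue$pattern,
                           function(p) count_motif(inquiry, p),
                           integer(n))
  inquiry_counts <- matrix(inquiry_counts, nrow = n)
  pool_counts <- vapply(catalogue$pattern,
                        function(p) count_motif(udp_pool, p),
                        integer(length(udp_pool)))
  pool_counts <- matrix(pool_counts, nrow = length(udp_pool))
  rep_means <- vapply(idx, function(i)
    colMeans(pool_counts[i, , drop = FALSE]), numeric(ncol(pool_counts)))
  rep_means <- t(matrix(rep_means, nrow = ncol(pool_counts)))

  res <- purrr::map_dfr(seq_len(nrow(catalogue)), function(m) {
    motif_zscore(inquiry_counts[, m], rep_means[, m])
  })
  out <- dplyr::bind_cols(
    tibble(name = catalogue$name, pattern = catalogue$pattern), res)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  crit <- if (adjust == "BH") out$p_adj else out$p
  out$significant <- crit < alpha
  out <- arrange(out, .data$p, .data$name)
  if (!keep_all) out <- filter(out, .data$significant)
  structure(out, class = c("bdp_enrichment", class(tibble())),
            alpha = alpha, reps = reps, n_tested = nrow(catalogue))
}

#' @export
tidy.bdp_enrichment <- function(x, ...) {
  class(x) <- class(tibble())
  attr(x, "alpha") <- NULL; attr(x, "reps") <- NULL; attr(x, "n_tested") <- NULL
  x
}

#' @export
glance.bdp_enrichment <- function(x, ...) {
  tibble(n_motifs = attr(x, "n_tested"),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         reps = attr(x, "reps"))
}
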