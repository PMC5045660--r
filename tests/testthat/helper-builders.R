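# Small builders shared across test files.

mk_expr <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) r[[2]]))
  colnames(m) <- paste0("l", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(gene_id = vapply(rows, function(r) r[[1]], character(1))),
    tibble::as_tibble(m))
}

mk_reads <- function(pos, total = 1e6, chrom = "c1", mark = "m",
                     assay = "chip") {
  read_set(mark, tibble::tibble(chrom = chrom, pos = pos),
           total_mapped = total, assay = assay)
}
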