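#' Read gene models from a GFF3 annotation
#'
#' Returns the `gene` records of a GFF3 file as a tibble of gene models.
#' Lines are validated first so malformed input is reported with its line
#' number; parsing itself is done by [rtracklayer::import()].
#'
#' @param path Path to a GFF3 file.
#' @param protein_coding If `TRUE`, keep only genes whose `biotype` (or
#'   `gene_biotype`) attribute is `"protein_coding"`.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand` and `biotype`.
#' @export
read_gene_models <- function(path, protein_coding = FALSE) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                    i, length(f)))
    if (!f[7] %in% c("+", "-", ".", "?"))
      abort(sprintf("malformed GFF3 line %d: unknown strand '%s'", i, f[7]))
  }
  if (!length(body)) {
    return(tibble(gene_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), strand = character(), biotype = character()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (!length(gr)) {
    return(tibble(gene_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), strand = character(), biotype = character()))
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  biotype <- if ("biotype" %in% names(mc)) as.character(mc$biotype)
             else if ("gene_biotype" %in% names(mc)) as.character(mc$gene_biotype)
             else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(mc)) as.character(mc$ID)
        else if ("Name" %in% names(mc)) as.character(mc$Name)
        else as.character(seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    abort("gene record with unknown strand (expected + or -)")
  out <- tibble(gene_id = id,
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = BiocGenerics::start(gr),
                end = BiocGenerics::end(gr),
                strand = strand,
                biotype = biotype)
  if (protein_coding) out <- filter(out, .data$biotype %in% "protein_coding")
  out
}

#' Write gene models to GFF3
#'
#' @param genes Tibble of gene models (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$source <- "bdptools"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$biotype <- genes$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a read set as a BED file of single-base midpoints
#'
#' Midpoints are written as 1-bp intervals in 0-based half-open BED
#' coordinates. The first line is a header comment recording the mark, assay
#' and total mapped reads, which [read_read_set()] restores.
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_set <- function(reads, path) {
  stopifnot(inherits(reads, "bdp_read_set"))
  writeLines(sprintf("#mark=%s assay=%s total_mapped=%.0f",
                     reads$mark, reads$assay, reads$total_mapped), path)
  readr::write_tsv(
    tibble(chrom = reads$midpoints$chrom,
           start = reads$midpoints$pos - 1L,
           end = reads$midpoints$pos,
           name = reads$mark),
    path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a midpoint BED file written by [write_read_set()]
#'
#' @param path Path to the BED file.
#' @return A [read_set()].
#' @export
read_read_set <- function(path) {
  hdr <- readLines(path, n = 1)
  grab <- function(key, default = NA_character_) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
    if (length(m) == 2) m[2] else default
  }
  bed <- readr::read_tsv(path, comment = "#",
                         col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic", progress = FALSE)
  total <- suppressWarnings(as.numeric(grab("total_mapped")))
  if (!is.finite(total)) total <- nrow(bed)
  read_set(mark = grab("mark", "unknown"),
           midpoints = tibble(chrom = bed$chrom, pos = bed$end),
           total_mapped = total,
           assay = if (identical(grab("assay"), "mnase")) "mnase" else "chip")
}

#' Read/write an FPKM expression matrix TSV
#'
#' Rows are genes, the first column is `gene_id`, remaining columns are
#' libraries.
#'
#' @param path Path to a TSV file.
#' @return Tibble (for the reader) or `path` invisibly (for the writer).
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (any(as.matrix(x[-1]) < 0, na.rm = TRUE)) abort("negative FPKM values")
  x
}

#' @rdname read_expression_matrix
#' @param expr Expression tibble (`gene_id` + library columns).
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read a motif catalogue TSV
#'
#' Expects columns `name`, `pattern` (IUPAC) and optionally `annotation`.
#' A small curated plant catalogue ships with the package at
#' `system.file("extdata", "motif_catalogue.tsv", package = "bdptools")`.
#'
#' @param path Path to the TSV.
#' @return Tibble with `name`, `pattern`, `annotation`.
#' @export
read_motif_catalogue <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  stopifnot(all(c("name", "pattern") %in% names(x)))
  if (!"annotation" %in% names(x)) x$annotation <- NA_character_
  ok <- vapply(x$pattern, function(p)
    all(strsplit(toupper(p), "")[[1]] %in% names(IUPAC_MAP)), logical(1))
  if (any(!ok))
    abort(paste0("invalid IUPAC pattern(s) in catalogue: ",
                 paste(x$name[!ok], collapse = ", ")))
  x[c("name", "pattern", "annotation")]
}

#' Write every synthetic fixture of a simulation to disk
#'
#' Emits the genome FASTA, the GFF3 annotation, truth tables, expression and
#' condition matrices (TSV) and one midpoint BED per simulated mark.
#' Regenerating the same `bdp_sim` and re-writing gives byte-identical files.
#'
#' @param sim A `bdp_sim`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "bdp_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             pairs = file.path(dir, "truth_pairs.tsv"),
             genes = file.path(dir, "truth_genes.tsv"),
             motifs = file.path(dir, "truth_motifs.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write_gene_models(sim$genes, paths[["annotation"]])
  readr::write_tsv(sim$truth$pairs, paths[["pairs"]])
  readr::write_tsv(sim$truth$genes, paths[["genes"]])
  readr::write_tsv(sim$truth$motifs, paths[["motifs"]])
  if (!is.null(sim$expression)) {
    paths[["expression"]] <- file.path(dir, "expression.tsv")
    write_expression_matrix(sim$expression, paths[["expression"]])
    paths[["control"]] <- file.path(dir, "control.tsv")
    paths[["drought"]] <- file.path(dir, "drought.tsv")
    write_expression_matrix(sim$condition$control, paths[["control"]])
    write_expression_matrix(sim$condition$drought, paths[["drought"]])
    paths[["expression_truth"]] <- file.path(dir, "truth_expression.tsv")
    readr::write_tsv(sim$truth$expression, paths[["expression_truth"]])
  }
  for (mark in names(sim$reads)) {
    key <- paste0("reads_", mark)
    paths[[key]] <- file.path(dir, paste0("reads_", mark, ".bed"))
    write_read_set(sim$reads[[mark]], paths[[key]])
  }
  invisible(paths)
}
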