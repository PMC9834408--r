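#' Gene models
#'
#' A gene model table holds one record per gene: `gene_id`, `chrom`,
#' `start`, `end` (0-based half-open base pairs) and `strand` (`"+"` or
#' `"-"`). All region arithmetic in the package uses 0-based half-open
#' coordinates; BED input/output is native and GTF is converted on read.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end integer interval bounds, 0-based half-open, `start < end`.
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  g <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  validate_gene_models(g)
  g
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stopf("gene table must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stopf("duplicate gene_id in gene table")
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end]
    stopf("gene(s) with start >= end: %s", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  invisible(genes)
}

gene_lengths <- function(genes) genes$end - genes$start

#' Remove genes shorter than a minimum length
#'
#' Genes strictly shorter than `min_len` are removed; a gene of exactly
#' `min_len` bp is kept. Input order is preserved. The default of 500 bp is
#' the filter applied before TSS/gene-body quantification of nascent
#' transcription; ChIP-style quantification conventionally uses the same
#' operation with `min_len = 2000`.
#'
#' @param genes gene model table (see [gene_models()]).
#' @param min_len minimum gene length in bp; `0` is the identity filter.
#' @return The filtered gene table.
#' @export
filter_short_genes <- function(genes, min_len = 500) {
  validate_gene_models(genes)
  genes[gene_lengths(genes) >= min_len, , drop = FALSE]
}

#' Derive TSS and gene-body windows
#'
#' The TSS window is `flank` bp on each side of the TSS base (a 501 bp
#' window at the default `flank = 250`); the gene body runs from `flank + 1`
#' bp downstream of the TSS to the 3' end of the gene. The two windows are
#' disjoint and adjacent. For a `+` strand gene `[s, e)` the TSS base is `s`:
#' TSS window `[s - flank, s + flank + 1)`, body `[s + flank + 1, e)`. For a
#' `-` strand gene the TSS base is `e - 1` and the layout mirrors. TSS
#' windows may extend upstream beyond the gene; windows extending below
#' coordinate 0 are clipped at 0 with a warning.
#'
#' Genes too short for a non-empty body (length <= `flank + 1`) are
#' rejected with an error; apply [filter_short_genes()] first.
#'
#' @param genes gene model table.
#' @param flank half-width of the TSS window in bp (default 250).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `tss_start`, `tss_end`, `body_start`, `body_end` (0-based half-open).
#' @export
derive_region_pairs <- function(genes, flank = 250) {
  validate_gene_models(genes)
  flank <- as.integer(flank)
  if (flank < 0) stopf("flank must be >= 0")
  len <- gene_lengths(genes)
  short <- len <= flank + 1L
  if (any(short)) {
    stopf(
      "gene(s) too short for a non-empty gene body at flank %d (need length > %d): %s",
      flank, flank + 1L, paste(head(genes$gene_id[short], 5), collapse = ", ")
    )
  }
  plus <- genes$strand == "+"
  tss_start <- ifelse(plus, genes$start - flank, genes$end - 1L - flank)
  tss_end <- ifelse(plus, genes$start + flank + 1L, genes$end + flank)
  body_start <- ifelse(plus, genes$start + flank + 1L, genes$start)
  body_end <- ifelse(plus, genes$end, genes$end - 1L - flank)
  if (any(tss_start < 0)) {
    warning(sprintf(
      "%d TSS window(s) extended below coordinate 0 and were clipped",
      sum(tss_start < 0)
    ), call. = FALSE)
    tss_start <- pmax(tss_start, 0L)
  }
  data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss_start = as.integer(tss_start), tss_end = as.integer(tss_end),
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    stringsAsFactors = FALSE
  )
}

region_widths <- function(pairs) {
  data.frame(
    gene_id = pairs$gene_id,
    tss_width = pairs$tss_end - pairs$tss_start,
    body_width = pairs$body_end - pairs$body_start
  )
}
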