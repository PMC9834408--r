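#' Read and write BED6 gene models
#'
#' BED is 0-based half-open, matching the package's internal convention;
#' the `name` column carries the gene id, `score` is written as 0.
#'
#' @param path file path.
#' @param genes gene model table.
#' @return `read_bed6()` returns a gene model table.
#' @export
read_bed6 <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score", "strand"))
  bad <- which(x$start >= x$end | !(x$strand %in% c("+", "-")))
  if (length(bad)) stopf("malformed BED record at line %d of %s", bad[1], path)
  gene_models(x$name, x$chrom, x$start, x$end, x$strand)
}

#' @rdname read_bed6
#' @export
write_bed6 <- function(genes, path) {
  validate_gene_models(genes)
  write.table(
    data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
               genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read gene models from a minimal GTF
#'
#' Only `gene` feature lines are used; the `gene_id` attribute is required.
#' GTF coordinates are 1-based inclusive and converted to the package's
#' 0-based half-open convention (`start - 1`, `end` unchanged).
#'
#' @param path GTF file path.
#' @return A gene model table.
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  recs <- list()
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 9) stopf("malformed GTF line %d in %s", lineno[i], path)
    if (f[3] != "gene") next
    m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
    if (length(m) < 2) stopf("missing gene_id attribute at GTF line %d", lineno[i])
    recs[[length(recs) + 1]] <- data.frame(
      gene_id = m[2], chrom = f[1], start = as.integer(f[4]) - 1L,
      end = as.integer(f[5]), strand = f[7], stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) stopf("no gene lines found in %s", path)
  g <- do.call(rbind, recs)
  gene_models(g$gene_id, g$chrom, g$start, g$end, g$strand)
}

#' Write region pairs as BED6
#'
#' Each gene contributes two records named `geneid:tss` and `geneid:body`.
#'
#' @param pairs region pairs from [derive_region_pairs()].
#' @param path output path.
#' @export
write_region_pairs_bed <- function(pairs, path) {
  out <- rbind(
    data.frame(chrom = pairs$chrom, start = pairs$tss_start,
               end = pairs$tss_end, name = paste0(pairs$gene_id, ":tss"),
               score = 0L, strand = pairs$strand),
    data.frame(chrom = pairs$chrom, start = pairs$body_start,
               end = pairs$body_end, name = paste0(pairs$gene_id, ":body"),
               score = 0L, strand = pairs$strand)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write fragment BED6
#'
#' One BED with the sample id in the `name` column.
#'
#' @param frags fragment table.
#' @param path file path.
#' @export
write_fragments_bed <- function(frags, path) {
  validate_fragments(frags)
  write.table(
    data.frame(frags$chrom, frags$start, frags$end, frags$sample, 0L,
               frags$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score", "strand"))
  bad <- which(x$start >= x$end)
  if (length(bad)) stopf("malformed BED record at line %d of %s", bad[1], path)
  data.frame(chrom = x$chrom, start = x$start, end = x$end,
             strand = x$strand, sample = x$name, stringsAsFactors = FALSE)
}

#' Read and write count matrices as TSV
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write spike-in tables
#'
#' TSV with columns `species`, `labeled` (0/1), then one column per sample.
#'
#' @param spike a [spikein_counts()] object.
#' @param path file path.
#' @export
write_spikein_tsv <- function(spike, path) {
  df <- data.frame(species = rownames(spike$counts),
                   labeled = as.integer(spike$labeled),
                   spike$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikein_tsv
#' @export
read_spikein_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$species
  spikein_counts(m, labeled = df$labeled == 1)
}

#' Read and write the sample design table
#'
#' TSV with columns `sample`, `assay` (`TT`/`RNA`), `condition`,
#' `replicate`; sample ids must be unique and every (assay, condition)
#' cell non-empty.
#'
#' @param design design data.frame.
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "condition", "replicate")
  if (!all(need %in% names(d))) {
    stopf("design must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$sample)) stopf("duplicate sample ids in design")
  if (!all(d$assay %in% c("TT", "RNA"))) stopf("assay must be TT or RNA")
  d
}

#' Read and write titration CSV
#'
#' Columns `replicate`, `protein_uM`, `anisotropy`, preceded by a metadata
#' header line `# ligand_nM: <value>`.
#'
#' @param series a `titration_series`.
#' @param path file path.
#' @export
write_titration_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ligand_nM: %.10g", attr(series, "ligand_nM")), con)
  write.table(as.data.frame(series)[, c("replicate", "protein_uM", "anisotropy")],
              con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("ligand_nM:\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stopf("missing '# ligand_nM:' header in %s", path)
  d <- read.table(path, sep = ",", header = TRUE, skip = 1,
                  stringsAsFactors = FALSE)
  attr(d, "ligand_nM") <- as.numeric(m[2])
  class(d) <- c("titration_series", "data.frame")
  d
}

#' Read and write pipeline configuration (YAML or JSON by extension)
#'
#' @param config named list.
#' @param path `.yaml`/`.yml` or `.json` path.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
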