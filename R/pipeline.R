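default_params <- function() {
  list(flank = 250, min_len = 500, threshold = 5, lfc_min = 1, alpha = 0.05,
       pseudocount = 1, strand_mode = "same", ref_condition = NULL,
       disp_moderation = "common")
}

#' Build a pipeline configuration
#'
#' @param annotation path to a BED6 (or `.gtf`) gene annotation.
#' @param design path to the design TSV (see [read_design_tsv()]).
#' @param fragments path to the fragment BED6 (sample id in the name
#'   column).
#' @param spike_tt,spike_rna paths to the per-assay spike-in TSVs.
#' @param outdir output directory (created if missing).
#' @param ... parameter overrides among: `flank`, `min_len`, `threshold`,
#'   `lfc_min`, `alpha`, `pseudocount`, `strand_mode`, `ref_condition`,
#'   `disp_moderation`. Unknown names are rejected.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, design, fragments, spike_tt,
                            spike_rna, outdir, ...) {
  params <- default_params()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown)) {
    stopf("unknown config parameter(s): %s", paste(unknown, collapse = ", "))
  }
  params[names(dots)] <- dots
  structure(c(list(annotation = annotation, design = design,
                   fragments = fragments, spike_tt = spike_tt,
                   spike_rna = spike_rna, outdir = outdir), params),
            class = "pipeline_config")
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[ttstab] ", fmt), ...))

#' Run the full joint nascent / steady-state pipeline
#'
#' Executes regions -> quantification -> spike-in normalization ->
#' low-count filtering -> differential testing on both arms -> stalling
#' index -> stability shift, writes every result table plus a run manifest
#' (parameters and input MD5 checksums) to `cfg$outdir`, and returns the
#' result bundle invisibly. Reruns on identical inputs produce identical
#' outputs.
#'
#' The TT arm is tested on total nascent counts (TSS + body); the low-count
#' filter is applied per arm on raw counts before testing, per the quoted
#' ordering of the analysis.
#'
#' @param cfg a [pipeline_config()] (or a path to a YAML/JSON file of the
#'   same fields).
#' @return Invisibly, a list with `diff_rna`, `diff_tt`, `stalling`,
#'   `stability`, `size_factors`, `region_counts`, `gene_counts`,
#'   `filters`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    x <- read_config(cfg)
    cfg <- do.call(pipeline_config, x)
  }
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  genes <- if (grepl("\\.gtf$", cfg$annotation)) read_gtf_genes(cfg$annotation)
           else read_bed6(cfg$annotation)
  design <- read_design_tsv(cfg$design)
  frags <- read_fragments_bed(cfg$fragments)
  spike_tt <- read_spikein_tsv(cfg$spike_tt)
  spike_rna <- read_spikein_tsv(cfg$spike_rna)
  log_stage("inputs: %d genes, %d samples, %d fragments",
            nrow(genes), nrow(design), nrow(frags))

  extra <- setdiff(unique(frags$sample), design$sample)
  if (length(extra)) {
    stopf("fragment sample(s) not present in design: %s",
          paste(extra, collapse = ", "))
  }

  kept <- filter_short_genes(genes, min_len = cfg$min_len)
  pairs <- derive_region_pairs(kept, flank = cfg$flank)
  log_stage("regions: %d/%d genes pass the %d bp length filter",
            nrow(kept), nrow(genes), cfg$min_len)

  d_tt <- design[design$assay == "TT", , drop = FALSE]
  d_rna <- design[design$assay == "RNA", , drop = FALSE]
  rc <- count_fragments(frags[frags$sample %in% d_tt$sample, , drop = FALSE],
                        pairs, strand_mode = cfg$strand_mode, design = d_tt)
  gc <- count_gene_level(frags[frags$sample %in% d_rna$sample, , drop = FALSE],
                         kept, strand_mode = cfg$strand_mode, design = d_rna)
  log_stage("quantify: TT assigned %d TSS / %d body fragments, %d straddlers discarded",
            sum(rc$tally$assigned_tss), sum(rc$tally$assigned_body),
            sum(rc$tally$both_discarded))

  s_tt <- size_factors_tt(spike_tt)
  s_rna <- size_factors_rna(spike_rna)

  tt_total <- rc$tss + rc$body
  filt_tt <- low_count_filter(tt_total, d_tt, threshold = cfg$threshold)
  filt_rna <- low_count_filter(gc$gene, d_rna, threshold = cfg$threshold)
  log_stage("filter: %d/%d TT genes, %d/%d RNA genes kept",
            sum(filt_tt$keep), nrow(filt_tt), sum(filt_rna$keep), nrow(filt_rna))

  ref <- cfg$ref_condition %||% unique(design$condition)[1]
  diff_tt <- nb_wald(tt_total[filt_tt$keep, , drop = FALSE], d_tt, s_tt,
                     ref_condition = ref, disp_moderation = cfg$disp_moderation,
                     lfc_min = cfg$lfc_min, alpha = cfg$alpha)
  diff_rna <- nb_wald(gc$gene[filt_rna$keep, , drop = FALSE], d_rna, s_rna,
                      ref_condition = ref, disp_moderation = cfg$disp_moderation,
                      lfc_min = cfg$lfc_min, alpha = cfg$alpha)
  keep_rc <- list(tss = rc$tss[filt_tt$keep, , drop = FALSE],
                  body = rc$body[filt_tt$keep, , drop = FALSE])
  stalling <- diff_stalling(keep_rc, d_tt, s_tt, ref_condition = ref,
                            pseudocount = cfg$pseudocount,
                            disp_moderation = cfg$disp_moderation)
  stability <- stability_shift(diff_rna, diff_tt)
  log_stage("differential: %d/%d RNA and %d/%d TT genes called up/down",
            sum(diff_rna$call %in% c("up", "down"), na.rm = TRUE), nrow(diff_rna),
            sum(diff_tt$call %in% c("up", "down"), na.rm = TRUE), nrow(diff_tt))

  out <- function(f) file.path(cfg$outdir, f)
  write_region_pairs_bed(pairs, out("regions.bed"))
  write_count_matrix(rc$tss, out("counts_tss.tsv"))
  write_count_matrix(rc$body, out("counts_body.tsv"))
  write_count_matrix(gc$gene, out("counts_gene.tsv"))
  write.table(rc$tally, out("tally_tt.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = c(names(s_tt), names(s_rna)),
                         size_factor = c(s_tt, s_rna)),
              out("size_factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in c("diff_rna", "diff_tt")) {
    d <- get(nm)
    write.table(
      data.frame(gene = d$gene_id, baseMeanRef = d$mean_ref,
                 baseMeanAlt = d$mean_alt, log2FC = d$log2FC, se = d$se,
                 p = d$p, padj = d$padj, call = d$call),
      out(paste0(nm, ".tsv")), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(as.data.frame(stalling), out("stalling.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(stability), out("stability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ssum <- summary(stability)
  jsonlite::write_json(
    list(n = ssum$n, median = ssum$median, q25 = ssum$q25, q75 = ssum$q75),
    out("stability_summary.json"), auto_unbox = TRUE, digits = NA)

  inputs <- c(cfg$annotation, cfg$design, cfg$fragments, cfg$spike_tt,
              cfg$spike_rna)
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("annotation", "design", "fragments",
                                           "spike_tt", "spike_rna", "outdir"))],
    ref_condition = ref,
    inputs = setNames(as.list(unname(tools::md5sum(inputs))), basename(inputs))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(diff_rna = diff_rna, diff_tt = diff_tt, stalling = stalling,
                 stability = stability,
                 size_factors = list(TT = s_tt, RNA = s_rna),
                 region_counts = rc, gene_counts = gc,
                 filters = list(TT = filt_tt, RNA = filt_rna)))
}
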