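strand_pass <- function(frag_strand, region_strand, strand_mode) {
  switch(strand_mode,
    same = frag_strand == region_strand,
    opposite = frag_strand != region_strand,
    ignore = rep(TRUE, length(frag_strand)),
    stopf("unknown strand_mode '%s' (use same/opposite/ignore)", strand_mode)
  )
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2  # >=1 bp, half-open

validate_fragments <- function(frags) {
  need <- c("chrom", "start", "end", "strand", "sample")
  if (!all(need %in% names(frags))) {
    stopf("fragment table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(frags$start >= frags$end)) stopf("fragments must satisfy start < end")
  invisible(frags)
}

#' Classify one fragment against a TSS/body region pair
#'
#' A fragment overlapping (by at least 1 bp, half-open intervals) only the
#' TSS window is `"TSS"`, only the gene body `"BODY"`, both windows
#' `"BOTH"` — such boundary-straddling fragments are excluded from counting
#' — and neither (or failing the strand test) `"NONE"`.
#'
#' @param frag a one-row fragment (list or data.frame with `chrom`, `start`,
#'   `end`, `strand`).
#' @param pair a one-row region-pair record (see [derive_region_pairs()]).
#' @param strand_mode `"same"` (default: fragment strand must equal the
#'   gene's), `"opposite"`, or `"ignore"`.
#' @return One of `"TSS"`, `"BODY"`, `"BOTH"`, `"NONE"`.
#' @export
classify_fragment <- function(frag, pair, strand_mode = "same") {
  if (frag$chrom != pair$chrom ||
      !strand_pass(frag$strand, pair$strand, strand_mode)) {
    return("NONE")
  }
  in_tss <- overlaps(frag$start, frag$end, pair$tss_start, pair$tss_end)
  in_body <- overlaps(frag$start, frag$end, pair$body_start, pair$body_end)
  if (in_tss && in_body) "BOTH"
  else if (in_tss) "TSS"
  else if (in_body) "BODY"
  else "NONE"
}

# fast candidate (fragment, region) hits via GenomicRanges; coords are
# 0-based half-open -> GRanges is 1-based closed
gr_hits <- function(frags, chrom, start, end) {
  q <- GenomicRanges::GRanges(frags$chrom,
                              IRanges::IRanges(frags$start + 1L, frags$end))
  s <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, pmax(end, start + 1L)))
  hit <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  cbind(frag = S4Vectors::queryHits(hit), region = S4Vectors::subjectHits(hit))
}

#' Count fragments in TSS and gene-body windows
#'
#' Applies [classify_fragment()] to every fragment x gene pair (overlap
#' search via `GenomicRanges::findOverlaps`): fragments classified `TSS` or
#' `BODY` increment the respective gene x sample count, fragments
#' overlapping both windows of a gene are discarded for that gene, and a
#' fragment may count toward several genes when their regions overlap.
#' Per-sample tallies classify each fragment once (precedence: counted in a
#' TSS > counted in a body > both-only > unassigned) so that
#' `assigned_tss + assigned_body + both_discarded + unassigned` equals the
#' number of input fragments exactly. Results are order-independent.
#'
#' @param frags fragment table (`chrom`, `start`, `end`, `strand`,
#'   `sample`).
#' @param pairs region pairs from [derive_region_pairs()].
#' @param strand_mode see [classify_fragment()].
#' @param design optional design table; if given, fragment samples absent
#'   from it are an error and the output columns follow the design order.
#' @return A list of class `region_counts`: integer matrices `tss` and
#'   `body` (genes x samples) and a `tally` data.frame.
#' @export
count_fragments <- function(frags, pairs, strand_mode = "same", design = NULL) {
  validate_fragments(frags)
  strand_pass(character(0), character(0), strand_mode)  # validate mode
  samples <- if (!is.null(design)) {
    extra <- setdiff(unique(frags$sample), design$sample)
    if (length(extra)) {
      stopf("fragment sample(s) not in design: %s", paste(extra, collapse = ", "))
    }
    design$sample
  } else sort(unique(frags$sample))
  ng <- nrow(pairs)
  tss <- matrix(0L, ng, length(samples), dimnames = list(pairs$gene_id, samples))
  body <- tss
  n <- nrow(frags)
  frag_status <- rep("unassigned", n)
  if (n > 0 && ng > 0) {
    ht <- gr_hits(frags, pairs$chrom, pairs$tss_start, pairs$tss_end)
    hb <- gr_hits(frags, pairs$chrom, pairs$body_start, pairs$body_end)
    key_t <- paste(ht[, 1], ht[, 2])
    key_b <- paste(hb[, 1], hb[, 2])
    all_pairs <- rbind(ht, hb[!(key_b %in% key_t), , drop = FALSE])
    in_t <- c(rep(TRUE, nrow(ht)), rep(FALSE, sum(!(key_b %in% key_t))))
    in_b <- c(key_t %in% key_b, rep(TRUE, sum(!(key_b %in% key_t))))
    keep <- strand_pass(frags$strand[all_pairs[, 1]],
                        pairs$strand[all_pairs[, 2]], strand_mode)
    all_pairs <- all_pairs[keep, , drop = FALSE]
    in_t <- in_t[keep]; in_b <- in_b[keep]
    cat_tss <- in_t & !in_b
    cat_body <- in_b & !in_t
    cat_both <- in_t & in_b
    si <- match(frags$sample[all_pairs[, 1]], samples)
    add <- function(mat, sel) {
      if (!any(sel)) return(mat)
      idx <- cbind(all_pairs[sel, 2], si[sel])
      tab <- table(idx[, 1], idx[, 2])
      mat[cbind(as.integer(rownames(tab))[row(tab)],
                as.integer(colnames(tab))[col(tab)])] <-
        mat[cbind(as.integer(rownames(tab))[row(tab)],
                  as.integer(colnames(tab))[col(tab)])] + as.integer(tab)
      mat
    }
    tss <- add(tss, cat_tss)
    body <- add(body, cat_body)
    frag_status[unique(all_pairs[cat_both, 1])] <- "both"
    frag_status[unique(all_pairs[cat_body, 1])] <- "body"
    frag_status[unique(all_pairs[cat_tss, 1])] <- "tss"
  }
  tally <- do.call(rbind, lapply(samples, function(smp) {
    st <- frag_status[frags$sample == smp]
    data.frame(
      sample = smp,
      assigned_tss = sum(st == "tss"), assigned_body = sum(st == "body"),
      both_discarded = sum(st == "both"), unassigned = sum(st == "unassigned"),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(tss = tss, body = body, tally = tally),
            class = "region_counts")
}

#' Count fragments per gene (steady-state arm)
#'
#' A fragment counts toward a gene if it overlaps the gene interval by at
#' least 1 bp and passes the strand test; there is no boundary-exclusion
#' rule at gene level. A fragment may count toward several overlapping
#' genes.
#'
#' @param frags fragment table.
#' @param genes gene model table.
#' @inheritParams count_fragments
#' @return A list of class `gene_counts`: integer matrix `gene`
#'   (genes x samples) and a `tally` data.frame (`assigned`, `unassigned`).
#' @export
count_gene_level <- function(frags, genes, strand_mode = "same", design = NULL) {
  validate_fragments(frags)
  validate_gene_models(genes)
  strand_pass(character(0), character(0), strand_mode)
  samples <- if (!is.null(design)) {
    extra <- setdiff(unique(frags$sample), design$sample)
    if (length(extra)) {
      stopf("fragment sample(s) not in design: %s", paste(extra, collapse = ", "))
    }
    design$sample
  } else sort(unique(frags$sample))
  mat <- matrix(0L, nrow(genes), length(samples),
                dimnames = list(genes$gene_id, samples))
  n <- nrow(frags)
  assigned <- rep(FALSE, n)
  if (n > 0 && nrow(genes) > 0) {
    h <- gr_hits(frags, genes$chrom, genes$start, genes$end)
    keep <- strand_pass(frags$strand[h[, 1]], genes$strand[h[, 2]], strand_mode)
    h <- h[keep, , drop = FALSE]
    if (nrow(h)) {
      si <- match(frags$sample[h[, 1]], samples)
      tab <- table(h[, 2], si)
      mat[cbind(as.integer(rownames(tab))[row(tab)],
                as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
      assigned[unique(h[, 1])] <- TRUE
    }
  }
  tally <- do.call(rbind, lapply(samples, function(smp) {
    sel <- frags$sample == smp
    data.frame(sample = smp, assigned = sum(assigned[sel]),
               unassigned = sum(!assigned[sel]), stringsAsFactors = FALSE)
  }))
  structure(list(gene = mat, tally = tally), class = "gene_counts")
}
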