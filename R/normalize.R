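#' Spike-in count container
#'
#' @param counts integer matrix, species x samples, with dimnames.
#' @param labeled logical vector (optionally named by species) flagging
#'   metabolically labeled species; only these inform TT size factors.
#' @return An object of class `spikein_counts`.
#' @export
spikein_counts <- function(counts, labeled) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("spike-in counts need species rownames and sample colnames")
  }
  if (length(labeled) != nrow(counts)) {
    stopf("labeled flag length must equal the number of species")
  }
  if (any(counts < 0)) stopf("spike-in counts must be >= 0")
  labeled <- setNames(as.logical(labeled), rownames(counts))
  structure(list(counts = counts, labeled = labeled),
            class = "spikein_counts")
}

# rescale raw per-sample factors to geometric mean 1
anchor_factors <- function(r) {
  if (any(r <= 0)) {
    stopf("spike-in factor is zero/negative in sample(s): %s",
          paste(names(r)[r <= 0], collapse = ", "))
  }
  r / gmean(r)
}

#' Size factors for the steady-state (RNA) arm
#'
#' The raw per-sample factor is the total spike-in count (the
#' exogenous-transcriptome read share); factors are rescaled to geometric
#' mean 1, and normalized counts are raw counts divided by the factor, so a
#' sample with higher spike-in recovery is scaled down.
#'
#' @param spike a [spikein_counts()] object.
#' @return Named positive numeric vector of size factors (geometric mean 1).
#' @export
size_factors_rna <- function(spike) {
  stopifnot(inherits(spike, "spikein_counts"))
  r <- colSums(spike$counts)
  anchor_factors(setNames(r, colnames(spike$counts)))
}

#' Size factors for the nascent (TT) arm
#'
#' The raw per-sample factor is the median count over the labeled spike-in
#' species only (unlabeled species do not survive nascent-RNA enrichment
#' and carry no dosage information); factors are rescaled to geometric
#' mean 1.
#'
#' @param spike a [spikein_counts()] object with at least one labeled
#'   species.
#' @return Named positive numeric vector of size factors (geometric mean 1).
#' @export
size_factors_tt <- function(spike) {
  stopifnot(inherits(spike, "spikein_counts"))
  lab <- spike$counts[spike$labeled, , drop = FALSE]
  if (nrow(lab) == 0) stopf("no labeled spike-in species")
  r <- apply(lab, 2, median)
  anchor_factors(setNames(r, colnames(spike$counts)))
}

#' Apply size factors to a count matrix
#'
#' `normalized(g, j) = counts(g, j) / s_j`; columns are matched to factor
#' names.
#'
#' @param counts numeric matrix, genes x samples.
#' @param s named size-factor vector covering every sample column.
#' @return Numeric matrix of normalized counts.
#' @export
apply_size_factors <- function(counts, s) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || !all(colnames(counts) %in% names(s))) {
    stopf("count columns must be named and present in the size factors")
  }
  sweep(counts, 2, s[colnames(counts)], "/")
}

#' Low-count gene filter
#'
#' A gene is removed if there is a condition in which every biological
#' replicate has a raw count strictly below `threshold` ("less than 5
#' reads in all replicates of one condition" at the default). Filtering is
#' done on raw counts, before normalization and differential testing.
#'
#' @param counts raw integer matrix, genes x samples.
#' @param design data.frame with `sample` and `condition` covering the
#'   count columns; every condition must have at least one sample.
#' @param threshold strict lower bound (default 5).
#' @return A data.frame (`gene_id`, `keep`, `trigger_condition`): for
#'   removed genes `trigger_condition` names the first condition whose
#'   replicates are all below threshold, otherwise `NA`.
#' @export
low_count_filter <- function(counts, design, threshold = 5) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  conds <- unique(design$condition)
  miss <- setdiff(colnames(counts), design$sample)
  if (length(miss)) stopf("samples missing from design: %s", paste(miss, collapse = ", "))
  below <- vapply(conds, function(cond) {
    cols <- design$sample[design$condition == cond]
    cols <- intersect(cols, colnames(counts))
    if (length(cols) == 0) stopf("condition '%s' has no samples in the count matrix", cond)
    apply(counts[, cols, drop = FALSE] < threshold, 1, all)
  }, logical(nrow(counts)))
  below <- matrix(below, nrow = nrow(counts),
                  dimnames = list(rownames(counts), conds))
  trig <- apply(below, 1, function(b) if (any(b)) conds[which(b)[1]] else NA_character_)
  data.frame(
    gene_id = rownames(counts), keep = !apply(below, 1, any),
    trigger_condition = trig, row.names = NULL, stringsAsFactors = FALSE
  )
}
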