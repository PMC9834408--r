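#' Method-of-moments NB dispersion estimates
#'
#' Within each condition, for normalized counts with mean `m` and sample
#' variance `v`, the moment estimator of the NB dispersion is
#' `alpha = (v - m) / m^2` (Var = mu + alpha mu^2). Per-condition estimates
#' are averaged across conditions and clamped below at `floor`. Genes whose
#' mean is zero in every condition get the floor.
#'
#' Genewise moment estimates at 2-3 replicates are extremely noisy (a few
#' degrees of freedom); the Wald tests therefore moderate them toward the
#' across-gene mean by default — see [nb_wald()].
#'
#' @param counts raw integer matrix, genes x samples.
#' @param design data.frame with `sample` and `condition`; every condition
#'   needs >= 2 replicates.
#' @param s named size factors for the samples.
#' @param floor lower clamp for the estimate (default 1e-8).
#' @return data.frame (`gene_id`, `alpha`).
#' @export
estimate_dispersion <- function(counts, design, s, floor = 1e-8) {
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  norm <- apply_size_factors(counts, s)
  conds <- unique(design$condition)
  per_cond <- vapply(conds, function(cond) {
    cols <- design$sample[design$condition == cond]
    cols <- intersect(cols, colnames(norm))
    if (length(cols) < 2) stopf("condition '%s' has < 2 replicates", cond)
    x <- norm[, cols, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }, numeric(nrow(norm)))
  per_cond <- matrix(per_cond, nrow = nrow(norm))
  a <- rowMeans(per_cond, na.rm = TRUE)
  a[is.nan(a)] <- floor
  data.frame(gene_id = rownames(counts), alpha = pmax(a, floor),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled common NB dispersion
#'
#' Moment estimator of a single dispersion shared by all genes:
#' `alpha = sum(v_gc - m_gc) / sum(m_gc^2)` over genes g and conditions c,
#' where `m` and `v` are the per-condition mean and variance of normalized
#' counts; clamped below at `floor`. The `m^2` weighting makes high-count
#' genes — the ones that carry dispersion information — dominate, so the
#' estimate is stable where the genewise moment estimator is not.
#'
#' @inheritParams estimate_dispersion
#' @return A single dispersion value.
#' @export
common_dispersion <- function(counts, design, s, floor = 1e-8) {
  norm <- apply_size_factors(counts, s)
  num <- 0; den <- 0
  for (cond in unique(design$condition)) {
    cols <- intersect(design$sample[design$condition == cond], colnames(norm))
    if (length(cols) < 2) stopf("condition '%s' has < 2 replicates", cond)
    x <- norm[, cols, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  max(num / den, floor)
}

# resolve the dispersion vector used in the Wald variance: genewise
# estimates, or (default) the pooled common dispersion that calibrates the
# normal-reference test at small replicate number
resolve_dispersion <- function(dispersions, counts, design, s,
                               disp_moderation) {
  disp_moderation <- match.arg(disp_moderation, c("common", "genewise"))
  if (disp_moderation == "common") {
    return(rep(common_dispersion(counts, design, s), nrow(counts)))
  }
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, design, s)
  a <- dispersions$alpha[match(rownames(counts), dispersions$gene_id)]
  if (anyNA(a)) stopf("dispersion estimates missing for some genes")
  a
}

# delta-method variance of ln(mean normalized count) in one condition:
# Var(ln mu_hat) ~ 1/(n * mu_hat * s_bar) + alpha/n
var_log_mean <- function(mu_hat, n, s_bar, alpha) {
  1 / (n * mu_hat * s_bar) + alpha / n
}

cond_stats <- function(norm, design, s, cond) {
  cols <- intersect(design$sample[design$condition == cond], colnames(norm))
  list(
    mu = rowMeans(norm[, cols, drop = FALSE]),
    n = length(cols),
    s_bar = mean(s[cols])
  )
}

#' Moment-based negative-binomial Wald test
#'
#' For a two-condition design, estimates per-condition means of normalized
#' counts, forms `log2FC = log2(mu_alt / mu_ref)`, and tests it against a
#' normal reference using the delta-method standard error
#' `Var(ln mu_c) ~ 1/(n_c mu_c s_bar_c) + alpha/n_c` summed over the two
#' conditions. Genes with a zero mean in either condition get an infinite
#' `log2FC`, are flagged `tested = FALSE` and excluded from testing and BH
#' adjustment. P-values are BH-adjusted and calls made by [call_de()].
#'
#' By default the variance uses the pooled [common_dispersion()]
#' (`disp_moderation = "common"`): with 3 replicates the genewise moment
#' estimator has so few degrees of freedom that plugging it into a
#' normal-reference Wald statistic roughly doubles the nominal type-I
#' error, while the pooled value calibrates it (the same reasoning behind
#' common/trended dispersion in the established count-model packages).
#' `"genewise"` uses the per-gene estimates (supplied or internally
#' estimated) unmoderated.
#'
#' @param counts raw integer matrix (filtered genes), genes x samples.
#' @param design data.frame with `sample`, `condition` (exactly two
#'   conditions among the count columns).
#' @param s named size factors.
#' @param dispersions optional [estimate_dispersion()] output, used when
#'   `disp_moderation = "genewise"` (estimated internally when `NULL`);
#'   the `"common"` mode pools directly from the counts.
#' @param ref_condition the reference (denominator) condition; defaults to
#'   the first condition in `design`.
#' @param disp_moderation `"common"` (default) or `"genewise"`.
#' @param lfc_min,alpha thresholds passed to [call_de()].
#' @return data.frame of class `diff_expr_result`: `gene_id`, `mean_ref`,
#'   `mean_alt`, `log2FC`, `se`, `p`, `padj`, `call`, `tested`.
#' @export
nb_wald <- function(counts, design, s, dispersions = NULL,
                    ref_condition = NULL, disp_moderation = "common",
                    lfc_min = 1, alpha = 0.05) {
  design <- design[design$sample %in% colnames(counts), , drop = FALSE]
  conds <- unique(design$condition)
  if (length(conds) != 2) {
    stopf("nb_wald handles exactly two conditions (got %d); run pairwise calls",
          length(conds))
  }
  ref <- ref_condition %||% conds[1]
  if (!ref %in% conds) stopf("ref_condition '%s' not in design", ref)
  alt <- setdiff(conds, ref)
  a <- resolve_dispersion(dispersions, counts, design, s, disp_moderation)
  norm <- apply_size_factors(counts, s)
  st_r <- cond_stats(norm, design, s, ref)
  st_a <- cond_stats(norm, design, s, alt)
  lfc <- log2(st_a$mu / st_r$mu)
  tested <- is.finite(lfc)
  v <- var_log_mean(st_r$mu, st_r$n, st_r$s_bar, a) +
    var_log_mean(st_a$mu, st_a$n, st_a$s_bar, a)
  se <- sqrt(v) / log(2)
  se[!tested] <- NA_real_
  z <- lfc / se
  p <- ifelse(tested, 2 * pnorm(-abs(z)), NA_real_)
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])
  res <- data.frame(
    gene_id = rownames(counts), mean_ref = st_r$mu, mean_alt = st_a$mu,
    log2FC = lfc, se = se, p = p, padj = padj,
    call = call_de(lfc, padj, lfc_min = lfc_min, alpha = alpha),
    tested = tested, row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "ref_condition") <- ref
  attr(res, "alt_condition") <- alt
  class(res) <- c("diff_expr_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1,
#' returned in input order (delegates to `stats::p.adjust`, after
#' validating the input range).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Differential-expression calls
#'
#' `up` iff `log2FC >= lfc_min` and `padj < alpha` (strict); `down` iff
#' `log2FC <= -lfc_min` and `padj < alpha`; otherwise `ns`. `NA` padj
#' (untested genes) gives `NA`.
#'
#' @param log2FC,padj numeric vectors.
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param alpha adjusted-p threshold (default 0.05, strict `<`).
#' @return character vector of `"up"`, `"down"`, `"ns"`, or `NA`.
#' @export
call_de <- function(log2FC, padj, lfc_min = 1, alpha = 0.05) {
  ifelse(is.na(padj), NA_character_,
    ifelse(padj < alpha & log2FC >= lfc_min, "up",
      ifelse(padj < alpha & log2FC <= -lfc_min, "down", "ns")))
}

#' Stalling index per gene and condition
#'
#' `SI = (mean normalized TSS count + pc) / (mean normalized body count +
#' pc)`: the promoter-proximal to gene-body ratio of nascent signal; higher
#' values indicate promoter-proximal polymerase accumulation. With
#' `width_normalize = TRUE` each mean is divided by its region width
#' before the ratio (off by default).
#'
#' @param region_counts a `region_counts` object (see [count_fragments()])
#'   or a list with `tss` and `body` matrices.
#' @param design data.frame with `sample`, `condition` covering the count
#'   columns.
#' @param s named size factors.
#' @param pseudocount added to both means (default 1; must be > 0 if any
#'   mean can be zero).
#' @param width_normalize divide means by region widths first.
#' @param widths data.frame (`gene_id`, `tss_width`, `body_width`),
#'   required when `width_normalize = TRUE`.
#' @return data.frame: `gene_id`, `condition`, `si`.
#' @export
stalling_index <- function(region_counts, design, s, pseudocount = 1,
                           width_normalize = FALSE, widths = NULL) {
  tssn <- apply_size_factors(region_counts$tss, s)
  bodn <- apply_size_factors(region_counts$body, s)
  if (width_normalize) {
    if (is.null(widths)) stopf("width_normalize needs a widths table")
    wt <- widths$tss_width[match(rownames(tssn), widths$gene_id)]
    wb <- widths$body_width[match(rownames(bodn), widths$gene_id)]
    tssn <- tssn / wt
    bodn <- bodn / wb
  }
  conds <- unique(design$condition)
  out <- do.call(rbind, lapply(conds, function(cond) {
    cols <- intersect(design$sample[design$condition == cond], colnames(tssn))
    mt <- rowMeans(tssn[, cols, drop = FALSE]) + pseudocount
    mb <- rowMeans(bodn[, cols, drop = FALSE]) + pseudocount
    if (pseudocount <= 0 && any(mb <= 0)) {
      stopf("zero body signal with pseudocount <= 0")
    }
    data.frame(gene_id = rownames(tssn), condition = cond, si = mt / mb,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Differential stalling index
#'
#' `dSI = log2(SI_alt / SI_ref)` with `SI` from [stalling_index()]. The
#' standard error combines the four delta-method variances of the log mean
#' TSS/body signal in the two conditions (as in [nb_wald()]); z and
#' two-sided normal p-values, BH-adjusted over the tested genes. Genes with
#' a zero mean in any of the four cells are flagged untested (the
#' pseudocount keeps `dSI` itself defined).
#'
#' @inheritParams stalling_index
#' @param dispersions optional list with `tss` and `body` dispersion tables
#'   from [estimate_dispersion()]; estimated internally when `NULL`.
#' @param ref_condition reference condition (default: first in `design`).
#' @param disp_moderation `"common"` (default) or `"genewise"`, see
#'   [nb_wald()].
#' @return data.frame of class `stalling_result`: `gene_id`, `si_ref`,
#'   `si_alt`, `dsi`, `se`, `p`, `padj`, `tested`.
#' @export
diff_stalling <- function(region_counts, design, s, dispersions = NULL,
                          ref_condition = NULL, pseudocount = 1,
                          disp_moderation = "common") {
  design <- design[design$sample %in% colnames(region_counts$tss), , drop = FALSE]
  conds <- unique(design$condition)
  if (length(conds) != 2) stopf("diff_stalling handles exactly two conditions")
  ref <- ref_condition %||% conds[1]
  alt <- setdiff(conds, ref)
  a_t <- resolve_dispersion(dispersions$tss, region_counts$tss, design, s,
                            disp_moderation)
  a_b <- resolve_dispersion(dispersions$body, region_counts$body, design, s,
                            disp_moderation)
  tssn <- apply_size_factors(region_counts$tss, s)
  bodn <- apply_size_factors(region_counts$body, s)
  cs <- function(mat, cond) cond_stats(mat, design, s, cond)
  t_r <- cs(tssn, ref); t_a <- cs(tssn, alt)
  b_r <- cs(bodn, ref); b_a <- cs(bodn, alt)
  si_ref <- (t_r$mu + pseudocount) / (b_r$mu + pseudocount)
  si_alt <- (t_a$mu + pseudocount) / (b_a$mu + pseudocount)
  dsi <- log2(si_alt / si_ref)
  tested <- t_r$mu > 0 & t_a$mu > 0 & b_r$mu > 0 & b_a$mu > 0
  v <- var_log_mean(t_r$mu, t_r$n, t_r$s_bar, a_t) +
    var_log_mean(t_a$mu, t_a$n, t_a$s_bar, a_t) +
    var_log_mean(b_r$mu, b_r$n, b_r$s_bar, a_b) +
    var_log_mean(b_a$mu, b_a$n, b_a$s_bar, a_b)
  se <- sqrt(v) / log(2)
  se[!tested] <- NA_real_
  z <- dsi / se
  p <- ifelse(tested, 2 * pnorm(-abs(z)), NA_real_)
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])
  res <- data.frame(
    gene_id = rownames(region_counts$tss), si_ref = si_ref, si_alt = si_alt,
    dsi = dsi, se = se, p = p, padj = padj, tested = tested,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "ref_condition") <- ref
  attr(res, "alt_condition") <- alt
  class(res) <- c("stalling_result", "data.frame")
  res
}

#' mRNA-stability shift between steady-state and nascent fold changes
#'
#' For every gene present in both arms (inner join), `delta = log2FC(RNA) -
#' log2FC(TT)`, both computed against the same reference condition. A
#' positive delta means the steady-state pool changed more than nascent
#' synthesis — relative stabilization; a negative delta, destabilization. A
#' pure transcription change moves both arms equally (delta ~ 0).
#'
#' @param diff_rna,diff_tt [nb_wald()] results for the two arms.
#' @return data.frame of class `stability_result`: `gene_id`, `lfc_rna`,
#'   `lfc_tt`, `delta`. `summary()` reports the median, quartiles and a
#'   fixed-break histogram of delta.
#' @export
stability_shift <- function(diff_rna, diff_tt) {
  r1 <- attr(diff_rna, "ref_condition"); r2 <- attr(diff_tt, "ref_condition")
  if (!is.null(r1) && !is.null(r2) && !identical(r1, r2)) {
    stopf("arms were computed against different reference conditions (%s vs %s)",
          r1, r2)
  }
  common <- intersect(diff_rna$gene_id, diff_tt$gene_id)
  if (length(common) == 0) stopf("no genes shared between the two arms")
  lr <- diff_rna$log2FC[match(common, diff_rna$gene_id)]
  lt <- diff_tt$log2FC[match(common, diff_tt$gene_id)]
  res <- data.frame(gene_id = common, lfc_rna = lr, lfc_tt = lt,
                    delta = lr - lt, row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("stability_result", "data.frame")
  res
}

#' @param object a `stability_result`.
#' @param breaks histogram breaks passed to `hist()`.
#' @param ... unused.
#' @rdname stability_shift
#' @export
summary.stability_result <- function(object, breaks = seq(-5, 5, by = 0.25),
                                     ...) {
  d <- object$delta[is.finite(object$delta)]
  h <- graphics::hist(pmin(pmax(d, min(breaks)), max(breaks)),
                      breaks = breaks, plot = FALSE)
  list(
    n = length(d),
    median = median(d),
    q25 = unname(quantile(d, 0.25)),
    q75 = unname(quantile(d, 0.75)),
    hist = data.frame(mid = h$mids, count = h$counts)
  )
}
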