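#' Default spike-in specification
#'
#' Two exogenous control pools, one per assay. The steady-state (RNA) pool
#' emulates whole-transcriptome spike-in material from a second species
#' (e.g. Drosophila S2 cells added at ~20% of the lysate): twelve unlabeled
#' species with abundances spread over a 16-fold range and summing to 0.2 of
#' the gene-derived depth. The nascent (TT) pool emulates six in
#' vitro-transcribed ERCC-derived spike-ins of which three carry the
#' metabolic label (4sU) and therefore survive the nascent-RNA enrichment:
#' only labeled species inform TT size factors downstream.
#'
#' @return A `data.frame` with columns `species`, `assay` (`"TT"`/`"RNA"`),
#'   `labeled` (logical) and `abundance` (relative to the per-sample
#'   gene-derived depth).
#' @export
default_spikein_spec <- function() {
  tt <- data.frame(
    species = c("ERCC-00043", "ERCC-00136", "ERCC-00092",
                "ERCC-00170", "ERCC-00145", "ERCC-00002"),
    assay = "TT",
    labeled = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    abundance = 0.005,
    stringsAsFactors = FALSE
  )
  w <- 2^seq(-2, 2, length.out = 12)
  rna <- data.frame(
    species = sprintf("dmel_spike_%02d", seq_len(12)),
    assay = "RNA",
    labeled = FALSE,
    abundance = 0.2 * w / sum(w),
    stringsAsFactors = FALSE
  )
  rbind(tt, rna)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: gene layout, design, depth,
#' per-sample capture efficiency, count dispersion, and the three classes of
#' condition effects (transcription, stability, pausing) with their gene
#' fractions and fold changes. Effect classes are disjoint, so the fractions
#' must sum to at most 1. The reference condition (first in `conditions`)
#' always carries fold 1 for every effect.
#'
#' @param n_genes number of genes (>= 1).
#' @param gene_length_range integer pair, uniform gene length range in bp;
#'   the minimum must exceed `flank + 1` so every gene has a non-empty body.
#' @param gene_spacing bp of intergenic gap between consecutive genes.
#' @param n_replicates replicates per (assay, condition) cell.
#' @param conditions ordered condition labels, reference first.
#' @param depth expected total gene-derived fragments per sample.
#' @param capture_range positive pair; per-sample capture efficiency `c_j`
#'   is drawn uniformly from it and multiplies genes and spike-ins alike —
#'   the assumption spike-in normalization exploits.
#' @param dispersion NB dispersion `alpha >= 0` (Var = mu + alpha mu^2);
#'   0 means Poisson.
#' @param frac_txn_change,frac_stab_change,frac_pause_change fractions of
#'   genes in each effect class; must sum to <= 1.
#' @param effect_txn,effect_stab,effect_pause fold changes (> 0) applied in
#'   non-reference conditions: `effect_txn` multiplies the synthesis rate,
#'   `effect_stab` multiplies the degradation rate, `effect_pause`
#'   multiplies the pausing odds `pi/(1-pi)`.
#' @param pausing_range range from which the reference pausing fraction
#'   `pi` is drawn uniformly (strictly inside (0,1)).
#' @param spikein_spec spike-in table, see [default_spikein_spec()].
#' @param flank TSS window half-width used to split nascent signal (bp).
#' @param fragment_length simulated fragment length in bp (default 150,
#'   a paired-end-150 style insert).
#' @param seed integer seed; every generator is deterministic given it.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_genes = 200,
                       gene_length_range = c(1000L, 20000L),
                       gene_spacing = 2000L,
                       n_replicates = 3,
                       conditions = c("WT", "KO"),
                       depth = 2e6,
                       capture_range = c(0.5, 2),
                       dispersion = 0.05,
                       frac_txn_change = 0,
                       frac_stab_change = 0,
                       frac_pause_change = 0,
                       effect_txn = 1,
                       effect_stab = 1,
                       effect_pause = 1,
                       pausing_range = c(0.2, 0.6),
                       spikein_spec = default_spikein_spec(),
                       flank = 250,
                       fragment_length = 150,
                       seed = 1L) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  r <- as.integer(gene_length_range)
  if (length(r) != 2 || r[1] < 1 || r[1] > r[2]) {
    stopf("invalid gene_length_range: min must be >= 1 and <= max")
  }
  if (r[1] <= flank + 1) {
    stopf("minimum gene length (%d) must exceed flank + 1 = %d", r[1], flank + 1)
  }
  if (gene_spacing < 1) stopf("gene_spacing must be >= 1")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    stopf("conditions must be non-empty unique labels (reference first)")
  }
  if (any(capture_range <= 0) || capture_range[1] > capture_range[2]) {
    stopf("capture_range must be a positive increasing pair")
  }
  if (dispersion < 0) stopf("dispersion must be >= 0")
  fr <- c(frac_txn_change, frac_stab_change, frac_pause_change)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stopf("effect fractions must lie in [0,1] and sum to <= 1 (disjoint classes)")
  }
  if (any(c(effect_txn, effect_stab, effect_pause) <= 0)) {
    stopf("effect fold changes must be > 0")
  }
  if (any(pausing_range <= 0) || any(pausing_range >= 1) ||
      pausing_range[1] > pausing_range[2]) {
    stopf("pausing_range must lie strictly inside (0,1)")
  }
  if (fragment_length < 1) stopf("fragment_length must be >= 1")
  cfg <- list(
    n_genes = as.integer(n_genes), gene_length_range = r,
    gene_spacing = as.integer(gene_spacing),
    n_replicates = as.integer(n_replicates), conditions = conditions,
    depth = depth, capture_range = capture_range, dispersion = dispersion,
    frac_txn_change = frac_txn_change, frac_stab_change = frac_stab_change,
    frac_pause_change = frac_pause_change,
    effect_txn = effect_txn, effect_stab = effect_stab,
    effect_pause = effect_pause,
    pausing_range = pausing_range, spikein_spec = spikein_spec,
    flank = as.integer(flank), fragment_length = as.integer(fragment_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping genes on one synthetic chromosome,
#' separated by `gene_spacing` bp of intergenic gap, with lengths uniform
#' in `gene_length_range` and random strands (both strands are guaranteed
#' to be represented when `n_genes >= 2`). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A gene model table (see [gene_models()]).
#' @export
generate_genes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 11L, {
    n <- cfg$n_genes
    r <- cfg$gene_length_range
    len <- if (r[1] == r[2]) rep(r[1], n) else {
      as.integer(floor(runif(n, r[1], r[2] + 1)))
    }
    start <- cfg$gene_spacing + c(0L, cumsum(len[-n] + cfg$gene_spacing))
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    if (n >= 2 && length(unique(strand)) == 1) {
      strand[2] <- setdiff(c("+", "-"), strand[1])
    }
    gene_models(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = "chrS", start = start, end = start + len, strand = strand
    )
  })
}

#' Generate ground-truth transcriptional parameters
#'
#' Draws per-gene synthesis rates `kappa` (lognormal, normalized to sum 1 so
#' `depth * kappa_g` is the expected nascent fragment yield), degradation
#' rates `delta` (lognormal around 1) and pausing fractions `pi` (uniform in
#' `cfg$pausing_range`), then assigns disjoint effect-class gene sets of
#' sizes `round(frac * n_genes)`. In every non-reference condition, `txn`
#' genes have `kappa` multiplied by `effect_txn`, `stab` genes have `delta`
#' multiplied by `effect_stab`, and `pause` genes have their pausing odds
#' `pi/(1-pi)` multiplied by `effect_pause` (which keeps `pi` inside (0,1)
#' for any fold). Steady-state expected abundance is `kappa/delta`; nascent
#' expected abundance is `kappa`.
#'
#' @param genes gene table from [generate_genes()].
#' @param cfg a [sim_config()].
#' @return A long `data.frame`: `gene_id`, `condition`, `synthesis`,
#'   `degradation`, `pausing`, `class` (`none`/`txn`/`stab`/`pause`).
#' @export
generate_truth <- function(genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(genes)
  with_seed(cfg$seed + 23L, {
    kappa <- rlnorm(n, meanlog = 0, sdlog = 1)
    kappa <- kappa / sum(kappa)
    delta <- rlnorm(n, meanlog = 0, sdlog = 0.5)
    pii <- runif(n, cfg$pausing_range[1], cfg$pausing_range[2])
    n_txn <- round(cfg$frac_txn_change * n)
    n_stab <- round(cfg$frac_stab_change * n)
    n_pause <- round(cfg$frac_pause_change * n)
    if (n_txn + n_stab + n_pause > n) stopf("effect fractions sum > 1")
    perm <- sample.int(n)
    cls <- rep("none", n)
    cls[perm[seq_len(n_txn)]] <- "txn"
    cls[perm[n_txn + seq_len(n_stab)]] <- "stab"
    cls[perm[n_txn + n_stab + seq_len(n_pause)]] <- "pause"
    out <- lapply(seq_along(cfg$conditions), function(ci) {
      k <- kappa; d <- delta; p <- pii
      if (ci > 1) {
        k[cls == "txn"] <- k[cls == "txn"] * cfg$effect_txn
        d[cls == "stab"] <- d[cls == "stab"] * cfg$effect_stab
        odds <- p[cls == "pause"] / (1 - p[cls == "pause"]) * cfg$effect_pause
        p[cls == "pause"] <- odds / (1 + odds)
      }
      data.frame(
        gene_id = genes$gene_id, condition = cfg$conditions[ci],
        synthesis = k, degradation = d, pausing = p, class = cls,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Generate the sample sheet with latent per-sample parameters
#'
#' One sample per (assay, condition, replicate): capture efficiencies `c_j`
#' uniform in `cfg$capture_range`, depth scalar `d_j = cfg$depth`.
#'
#' @param cfg a [sim_config()].
#' @return A `data.frame`: `sample`, `assay`, `condition`, `replicate`,
#'   `capture`, `depth`.
#' @export
generate_samples <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- expand.grid(
    replicate = seq_len(cfg$n_replicates),
    condition = cfg$conditions,
    assay = c("TT", "RNA"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("assay", "condition", "replicate")]
  with_seed(cfg$seed + 31L, {
    data.frame(
      sample = sprintf("%s_%s_r%d", grid$assay, grid$condition, grid$replicate),
      grid,
      capture = runif(nrow(grid), cfg$capture_range[1], cfg$capture_range[2]),
      depth = cfg$depth,
      stringsAsFactors = FALSE
    )
  })
}

# expected count means under the generative model, per sample
# returns list(tss, body, gene, spike) of matrices
truth_means <- function(truth, samples, cfg) {
  ref <- cfg$conditions[1]
  genes <- unique(truth$gene_id)
  tt <- samples[samples$assay == "TT", , drop = FALSE]
  rna <- samples[samples$assay == "RNA", , drop = FALSE]
  get_par <- function(cond, col) {
    t2 <- truth[truth$condition == cond, , drop = FALSE]
    t2[match(genes, t2$gene_id), col]
  }
  mk <- function(samp, fun) {
    m <- vapply(seq_len(nrow(samp)), function(j) {
      fun(samp$depth[j] * samp$capture[j], samp$condition[j])
    }, numeric(length(genes)))
    dimnames(m) <- list(genes, samp$sample)
    m
  }
  tss <- mk(tt, function(dc, cond) dc * get_par(cond, "synthesis") * get_par(cond, "pausing"))
  body <- mk(tt, function(dc, cond) dc * get_par(cond, "synthesis") * (1 - get_par(cond, "pausing")))
  gene <- mk(rna, function(dc, cond) dc * get_par(cond, "synthesis") / get_par(cond, "degradation"))
  sp <- cfg$spikein_spec
  spike <- matrix(0, nrow(sp), nrow(samples),
                  dimnames = list(sp$species, samples$sample))
  for (j in seq_len(nrow(samples))) {
    idx <- sp$assay == samples$assay[j]
    spike[idx, j] <- samples$depth[j] * samples$capture[j] * sp$abundance[idx]
  }
  list(tss = tss, body = body, gene = gene, spike = spike)
}

#' Expected (noise-free) counts under the generative model
#'
#' Returns the exact expected values of every count the simulator draws:
#' for a TT sample `j` and gene `g`, the nascent yield is
#' `m = d_j * c_j * kappa_g`, split `m * pi_g` (TSS window) and
#' `m * (1 - pi_g)` (gene body); an RNA sample has gene mean
#' `d_j * c_j * kappa_g / delta_g`; spike-in species `i` has mean
#' `d_j * c_j * a_i` in every sample of its assay.
#'
#' @param truth truth table from [generate_truth()].
#' @param samples sample sheet from [generate_samples()].
#' @param cfg a [sim_config()].
#' @return A list of mean matrices `tss`, `body` (genes x TT samples),
#'   `gene` (genes x RNA samples) and `spike` (species x all samples).
#' @export
expected_counts <- function(truth, samples, cfg) {
  truth_means(truth, samples, cfg)
}

# shared NB draw of the gene-level counts; called under the same seed by
# simulate_counts and simulate_fragments so their totals agree exactly
draw_gene_counts <- function(mu, alpha) {
  list(
    tss = matrix(rnb(length(mu$tss), as.vector(mu$tss), alpha),
                 nrow(mu$tss), dimnames = dimnames(mu$tss)),
    body = matrix(rnb(length(mu$body), as.vector(mu$body), alpha),
                  nrow(mu$body), dimnames = dimnames(mu$body)),
    gene = matrix(rnb(length(mu$gene), as.vector(mu$gene), alpha),
                  nrow(mu$gene), dimnames = dimnames(mu$gene))
  )
}

#' Simulate count matrices with spike-ins
#'
#' Draws NB counts (mean/dispersion parameterization; `dispersion = 0`
#' gives Poisson) around the [expected_counts()] means. Capture efficiency
#' multiplies gene and spike-in means identically, which is what makes
#' spike-in size factors consistent estimators of it. Deterministic given
#' `cfg$seed`.
#'
#' @inheritParams expected_counts
#' @return A list of class `count_bundle`: integer matrices `tss`, `body`
#'   (genes x TT samples), `gene` (genes x RNA samples), a list `spike`
#'   with one [spikein_counts()] object per assay, and the `design`
#'   (sample sheet without latent columns).
#' @export
simulate_counts <- function(truth, samples, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mu <- truth_means(truth, samples, cfg)
  counts <- with_seed(cfg$seed + 47L, draw_gene_counts(mu, cfg$dispersion))
  spike <- with_seed(cfg$seed + 53L, {
    matrix(rnb(length(mu$spike), as.vector(mu$spike), cfg$dispersion),
           nrow(mu$spike), dimnames = dimnames(mu$spike))
  })
  sp <- cfg$spikein_spec
  spike_by_assay <- lapply(c(TT = "TT", RNA = "RNA"), function(a) {
    idx <- sp$assay == a
    cols <- samples$sample[samples$assay == a]
    spikein_counts(spike[idx, cols, drop = FALSE],
                   labeled = setNames(sp$labeled[idx], sp$species[idx]))
  })
  structure(
    list(tss = counts$tss, body = counts$body, gene = counts$gene,
         spike = spike_by_assay,
         design = samples[, c("sample", "assay", "condition", "replicate")]),
    class = "count_bundle"
  )
}

#' Simulate fragment intervals
#'
#' Draws the same per-region counts as [simulate_counts()] (identical RNG
#' stream, so quantifying the fragments reproduces those counts exactly when
#' `straddlers_per_gene` and `intergenic_per_sample` are 0), then places
#' each fragment uniformly inside its generating region — TSS window or
#' gene body for TT samples, the whole gene for RNA samples — on the gene's
#' strand. Fragment length is `cfg$fragment_length`, clipped to the region
#' width. Optionally adds, per TT sample and gene, fragments that straddle
#' the TSS/body boundary (the class the counting rule must discard), and
#' per sample a number of intergenic fragments placed clear of every TSS
#' window. True categories are recorded for oracle tests.
#'
#' @inheritParams expected_counts
#' @param straddlers_per_gene boundary-straddling fragments per (TT sample,
#'   gene); requires `cfg$fragment_length >= 2`.
#' @param intergenic_per_sample intergenic fragments per sample.
#' @return A `data.frame` of fragments: `chrom`, `start`, `end`, `strand`,
#'   `sample`, `truth_class` (`tss`/`body`/`gene`/`straddler`/`intergenic`),
#'   with the gene table attached as attribute `genes`.
#' @export
simulate_fragments <- function(truth, samples, cfg,
                               straddlers_per_gene = 0,
                               intergenic_per_sample = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$fragment_length < 1) stopf("fragment_length must be >= 1")
  if (straddlers_per_gene > 0 && cfg$fragment_length < 2) {
    stopf("straddling fragments require fragment_length >= 2")
  }
  genes <- generate_genes(cfg)
  pairs <- derive_region_pairs(genes, flank = cfg$flank)
  mu <- truth_means(truth, samples, cfg)
  counts <- with_seed(cfg$seed + 47L, draw_gene_counts(mu, cfg$dispersion))
  fl <- cfg$fragment_length

  # uniform placement of n[g] fragments per gene inside [rs, re), fragment
  # length fl clipped to the region width; vectorized over genes
  place_all <- function(n, rs, re) {
    w <- pmin(fl, re - rs)
    span <- rep(re - rs - w + 1, n)
    s <- rep(rs, n) + floor(runif(sum(n)) * span)
    cbind(start = s, end = s + rep(w, n))
  }

  with_seed(cfg$seed + 61L, {
    gi <- match(rownames(counts$tss), genes$gene_id)
    gs <- genes[order(genes$start), ]
    gap_lo <- head(gs$end, -1) + cfg$flank + 1L
    gap_hi <- gs$start[-1] - cfg$flank - 1L
    gap_ok <- which(gap_hi - gap_lo >= fl)
    out <- vector("list", 0)
    emit <- function(iv, gene_rep, smp, cls, strand = NULL) {
      if (nrow(iv) == 0) return()
      out[[length(out) + 1]] <<- data.frame(
        chrom = genes$chrom[1], start = iv[, "start"], end = iv[, "end"],
        strand = strand %||% rep(pairs$strand, gene_rep),
        sample = smp, truth_class = cls, stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(samples))) {
      smp <- samples$sample[j]
      if (samples$assay[j] == "TT") {
        nt <- counts$tss[, smp]
        nb <- counts$body[, smp]
        emit(place_all(nt, pairs$tss_start, pairs$tss_end), nt, smp, "tss")
        emit(place_all(nb, pairs$body_start, pairs$body_end), nb, smp, "body")
        if (straddlers_per_gene > 0) {
          # boundary base b: a fragment covering b-1 and b hits both windows
          b <- ifelse(pairs$strand == "+", pairs$body_start, pairs$body_end)
          ns <- rep(straddlers_per_gene, nrow(pairs))
          s <- rep(b, ns) - fl + 1 + floor(runif(sum(ns)) * (fl - 1))
          emit(cbind(start = s, end = s + fl), ns, smp, "straddler")
        }
      } else {
        ng <- counts$gene[, smp]
        emit(place_all(ng, genes$start[gi], genes$end[gi]), ng, smp, "gene",
             strand = rep(genes$strand[gi], ng))
      }
      if (intergenic_per_sample > 0) {
        # gaps between consecutive genes, shrunk by flank, miss every window
        if (length(gap_ok) == 0) {
          stopf("no intergenic gap wide enough for fragments")
        }
        pick <- gap_ok[1 + floor(runif(intergenic_per_sample) * length(gap_ok))]
        s <- gap_lo[pick] +
          floor(runif(intergenic_per_sample) * (gap_hi[pick] - gap_lo[pick] - fl + 1))
        emit(cbind(start = s, end = s + fl),
             rep(1L, intergenic_per_sample), smp, "intergenic",
             strand = ifelse(runif(intergenic_per_sample) < 0.5, "+", "-"))
      }
    }
    frags <- if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), sample = character(),
                 truth_class = character())
    rownames(frags) <- NULL
    attr(frags, "genes") <- genes
    frags
  })
}

#' Ground-truth size factors of a simulated sample sheet
#'
#' The generative scale of sample `j` is `d_j * c_j`; anchored to geometric
#' mean 1 within the chosen assay these are the size factors an ideal
#' spike-in normalization would recover. Useful for testing the
#' differential machinery in isolation from spike-in counting noise.
#'
#' @param samples sample sheet from [generate_samples()] (latent `capture`
#'   and `depth` columns required).
#' @param assay `"TT"` or `"RNA"`.
#' @return Named size-factor vector (geometric mean 1).
#' @export
true_size_factors <- function(samples, assay) {
  sel <- samples$assay == assay
  if (!any(sel)) stopf("no samples with assay '%s'", assay)
  r <- samples$depth[sel] * samples$capture[sel]
  setNames(r / gmean(r), samples$sample[sel])
}

#' Simulate a fluorescence-anisotropy titration series
#'
#' Generates anisotropy readings for a labeled peptide (ligand) held at a
#' fixed concentration while the protein concentration is titrated along
#' `conc_grid_uM`:
#' `r = r_free + (r_bound - r_free) * fraction_bound(P, L, Kd) + noise`,
#' with iid Gaussian noise of sd `noise_sd`. All replicate series share the
#' grid.
#'
#' @param kd dissociation constant in uM (> 0).
#' @param r_free,r_bound anisotropy of the free and fully bound ligand
#'   (`r_bound >= r_free`).
#' @param ligand_nM total ligand (peptide) concentration in nM (default 90).
#' @param conc_grid_uM ascending, non-negative protein concentrations (uM).
#' @param noise_sd Gaussian noise sd in anisotropy units.
#' @param n_reps number of replicate series.
#' @param seed integer seed.
#' @return A `data.frame` (`replicate`, `protein_uM`, `anisotropy`) of class
#'   `titration_series` with attribute `ligand_nM`.
#' @export
simulate_titration <- function(kd, r_free, r_bound, ligand_nM = 90,
                               conc_grid_uM, noise_sd = 0, n_reps = 1,
                               seed = 1L) {
  if (kd <= 0) stopf("kd must be > 0")
  if (r_bound < r_free) stopf("r_bound must be >= r_free")
  if (any(conc_grid_uM < 0)) stopf("protein concentrations must be non-negative")
  if (is.unsorted(conc_grid_uM, strictly = TRUE)) {
    stopf("conc_grid_uM must be strictly ascending")
  }
  L <- ligand_nM / 1000
  f <- fraction_bound(conc_grid_uM, L = L, kd = kd)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      data.frame(
        replicate = r, protein_uM = conc_grid_uM,
        anisotropy = r_free + (r_bound - r_free) * f +
          rnorm(length(f), 0, noise_sd)
      )
    }))
    attr(out, "ligand_nM") <- ligand_nM
    class(out) <- c("titration_series", "data.frame")
    out
  })
}
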