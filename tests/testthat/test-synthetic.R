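test_that("generators are deterministic given the seed", {
  cfg <- sim_config(n_genes = 10, depth = 2e4, seed = 7)
  expect_identical(generate_genes(cfg), generate_genes(cfg))
  genes <- generate_genes(cfg)
  truth <- generate_truth(genes, cfg)
  expect_identical(truth, generate_truth(genes, cfg))
  samples <- generate_samples(cfg)
  expect_identical(simulate_counts(truth, samples, cfg),
                   simulate_counts(truth, samples, cfg))
  expect_identical(simulate_fragments(truth, samples, cfg),
                   simulate_fragments(truth, samples, cfg))
})

test_that("gene layout honors the configured lengths and never overlaps", {
  cfg <- sim_config(n_genes = 10, gene_length_range = c(600, 600), seed = 3)
  g <- generate_genes(cfg)
  expect_true(all(g$end - g$start == 600))

  cfg2 <- sim_config(n_genes = 50, seed = 5)
  g2 <- generate_genes(cfg2)
  expect_setequal(unique(g2$strand), c("+", "-"))
  # brute-force all-pairs overlap check
  for (i in seq_len(49)) for (j in (i + 1):50) {
    expect_false(g2$start[i] < g2$end[j] && g2$end[i] > g2$start[j])
  }
  r <- cfg2$gene_length_range
  expect_true(all(g2$end - g2$start >= r[1] & g2$end - g2$start <= r[2]))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gene_length_range = c(2000, 1000)), "gene_length_range")
  expect_error(sim_config(gene_length_range = c(-5, 1000)), "gene_length_range")
  expect_error(sim_config(gene_length_range = c(200, 400)), "flank")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(frac_txn_change = 0.6, frac_stab_change = 0.6),
               "sum")
  expect_error(sim_config(effect_txn = 0), "fold")
  expect_error(sim_config(fragment_length = 0), "fragment_length")
})

test_that("effect classes are disjoint with the configured sizes", {
  cfg <- sim_config(n_genes = 100, seed = 9, frac_txn_change = 0.2,
                    frac_stab_change = 0.1, frac_pause_change = 0.05,
                    effect_txn = 0.5, effect_stab = 2, effect_pause = 3)
  truth <- generate_truth(generate_genes(cfg), cfg)
  cls <- truth[truth$condition == "WT", ]
  expect_equal(sum(cls$class == "txn"), 20)
  expect_equal(sum(cls$class == "stab"), 10)
  expect_equal(sum(cls$class == "pause"), 5)
  # disjoint by construction: one class label per gene
  expect_equal(length(unique(cls$gene_id)), 100)
})

test_that("a null design carries identical parameters across conditions", {
  cfg <- sim_config(n_genes = 40, seed = 2)
  truth <- generate_truth(generate_genes(cfg), cfg)
  wt <- truth[truth$condition == "WT", ]
  ko <- truth[truth$condition == "KO", ]
  expect_true(all(wt$class == "none"))
  expect_equal(wt$synthesis, ko$synthesis)
  expect_equal(wt$degradation, ko$degradation)
  expect_equal(wt$pausing, ko$pausing)
})

test_that("a pause-odds fold of 1 leaves the pausing fraction unchanged", {
  cfg <- sim_config(n_genes = 40, seed = 2, frac_pause_change = 0.5,
                    effect_pause = 1)
  truth <- generate_truth(generate_genes(cfg), cfg)
  wt <- truth[truth$condition == "WT", ]
  ko <- truth[truth$condition == "KO", ]
  expect_equal(wt$pausing, ko$pausing)
})

test_that("the pause effect acts on the odds scale and stays inside (0,1)", {
  cfg <- sim_config(n_genes = 50, seed = 4, frac_pause_change = 1,
                    effect_pause = 50, pausing_range = c(0.5, 0.9))
  truth <- generate_truth(generate_genes(cfg), cfg)
  wt <- truth[truth$condition == "WT", ]
  ko <- truth[truth$condition == "KO", ]
  expect_true(all(ko$pausing > 0 & ko$pausing < 1))
  odds_ratio <- (ko$pausing / (1 - ko$pausing)) / (wt$pausing / (1 - wt$pausing))
  expect_equal(odds_ratio, rep(50, 50))
})

test_that("Poisson simulation matches analytic means at large counts", {
  cfg <- sim_config(n_genes = 20, depth = 2e7, dispersion = 0, seed = 13)
  genes <- generate_genes(cfg)
  truth <- generate_truth(genes, cfg)
  samples <- generate_samples(cfg)
  mu <- expected_counts(truth, samples, cfg)
  cb <- simulate_counts(truth, samples, cfg)
  for (part in c("tss", "body", "gene")) {
    big <- mu[[part]] >= 1e5
    expect_gt(sum(big), 10)
    rel <- abs(cb[[part]][big] - mu[[part]][big]) / mu[[part]][big]
    expect_lt(max(rel), 0.01)
  }
})

test_that("a fully paused gene yields zero body counts under Poisson", {
  cfg <- sim_config(n_genes = 3, depth = 1e4, dispersion = 0, seed = 6)
  genes <- generate_genes(cfg)
  samples <- generate_samples(cfg)
  truth <- generate_truth(genes, cfg)
  truth$pausing <- 1  # boundary edge case
  mu <- expected_counts(truth, samples, cfg)
  expect_true(all(mu$body == 0))
  cb <- simulate_counts(truth, samples, cfg)
  expect_true(all(cb$body == 0))
})

test_that("quantifying simulated fragments reproduces the simulated counts", {
  cfg <- sim_config(n_genes = 25, depth = 3e4, seed = 21)
  genes <- generate_genes(cfg)
  truth <- generate_truth(genes, cfg)
  samples <- generate_samples(cfg)
  cb <- simulate_counts(truth, samples, cfg)
  frags <- simulate_fragments(truth, samples, cfg)
  pairs <- derive_region_pairs(genes, flank = cfg$flank)
  d_tt <- cb$design[cb$design$assay == "TT", ]
  d_rna <- cb$design[cb$design$assay == "RNA", ]
  rc <- count_fragments(frags[frags$sample %in% d_tt$sample, ], pairs,
                        design = d_tt)
  gc <- count_gene_level(frags[frags$sample %in% d_rna$sample, ], genes,
                         design = d_rna)
  expect_equal(rc$tss[rownames(cb$tss), colnames(cb$tss)], cb$tss,
               ignore_attr = TRUE)
  expect_equal(rc$body[rownames(cb$body), colnames(cb$body)], cb$body,
               ignore_attr = TRUE)
  expect_equal(gc$gene[rownames(cb$gene), colnames(cb$gene)], cb$gene,
               ignore_attr = TRUE)
  expect_true(all(rc$tally$both_discarded == 0))
  expect_true(all(rc$tally$unassigned == 0))
})

test_that("straddler fragments are discarded and intergenic ones unassigned", {
  cfg <- sim_config(n_genes = 8, depth = 2e3, seed = 33)
  genes <- generate_genes(cfg)
  truth <- generate_truth(genes, cfg)
  samples <- generate_samples(cfg)
  frags <- simulate_fragments(truth, samples, cfg, straddlers_per_gene = 2,
                              intergenic_per_sample = 5)
  pairs <- derive_region_pairs(genes, flank = cfg$flank)
  tt_samples <- samples$sample[samples$assay == "TT"]
  ft <- frags[frags$sample %in% tt_samples, ]
  rc <- count_fragments(ft, pairs)
  n_straddle <- sum(ft$truth_class == "straddler")
  n_inter <- sum(ft$truth_class == "intergenic")
  expect_equal(sum(rc$tally$both_discarded), n_straddle)
  expect_equal(sum(rc$tally$unassigned), n_inter)
  # per-gene counts are untouched by the extra fragment classes
  cb <- simulate_counts(truth, samples, cfg)
  expect_equal(rc$tss[rownames(cb$tss), colnames(cb$tss)], cb$tss,
               ignore_attr = TRUE)
})

test_that("titration series obey the binding model limits", {
  grid <- c(0, 10^seq(-2, 2, length.out = 11))
  ts <- simulate_titration(kd = 1, r_free = 0.05, r_bound = 0.25,
                           conc_grid_uM = grid, noise_sd = 0, n_reps = 1)
  expect_equal(ts$anisotropy[1], 0.05)  # no protein
  sat <- simulate_titration(kd = 1, r_free = 0.05, r_bound = 0.25,
                            conc_grid_uM = c(0, 1e4), noise_sd = 0)
  expect_lt(abs(sat$anisotropy[2] - 0.25), 1e-3 * 0.2)
  # ligand far below Kd at P = Kd: midpoint of the range within 1%
  mid <- simulate_titration(kd = 10, r_free = 0.1, r_bound = 0.3,
                            ligand_nM = 0.09 * 1000, conc_grid_uM = c(0, 10),
                            noise_sd = 0)
  expect_lt(abs(mid$anisotropy[2] - 0.2), 0.01 * 0.2)
  expect_error(simulate_titration(kd = 1, r_free = 0, r_bound = 1,
                                  conc_grid_uM = c(-1, 2)), "non-negative")
  expect_error(simulate_titration(kd = -1, r_free = 0, r_bound = 1,
                                  conc_grid_uM = c(0, 1)), "kd")
})
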