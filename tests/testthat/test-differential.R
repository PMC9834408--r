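design_3v3 <- function(prefix = "s") {
  data.frame(sample = paste0(prefix, 1:6),
             condition = rep(c("WT", "KO"), each = 3))
}
unit_s <- function(design) setNames(rep(1, nrow(design)), design$sample)

test_that("zero within-condition variance gives the dispersion floor", {
  design <- design_3v3()
  counts <- matrix(rep(c(10, 10, 10, 30, 30, 30), each = 4), 4, byrow = FALSE,
                   dimnames = list(paste0("g", 1:4), design$sample))
  d <- estimate_dispersion(counts, design, unit_s(design))
  expect_equal(d$alpha, rep(1e-8, 4))
})

test_that("moment dispersion recovers the simulating value", {
  withr::with_seed(101, {
    design <- design_3v3()
    G <- 4000
    pois <- matrix(rpois(G * 6, 1000), G, dimnames = list(NULL, design$sample))
    d0 <- estimate_dispersion(pois, design, unit_s(design))
    expect_lt(median(d0$alpha), 0.01)
    nb <- matrix(rnbinom(G * 6, mu = 1000, size = 10), G,
                 dimnames = list(NULL, design$sample))
    d1 <- estimate_dispersion(nb, design, unit_s(design))
    expect_gt(median(d1$alpha), 0.07)
    expect_lt(median(d1$alpha), 0.13)
    # pooled common dispersion is tighter still
    a <- common_dispersion(nb, design, unit_s(design))
    expect_gt(a, 0.08)
    expect_lt(a, 0.12)
  })
})

test_that("dispersion estimation demands two replicates per condition", {
  design <- data.frame(sample = c("a", "b", "c"),
                       condition = c("WT", "WT", "KO"))
  counts <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), design$sample))
  expect_error(estimate_dispersion(counts, design,
                                   unit_s(design)), "KO")
})

test_that("the Wald test is exact on degenerate contrasts", {
  design <- design_3v3()
  s <- unit_s(design)
  counts <- matrix(rep(c(40, 50, 60), 2), 1,
                   dimnames = list("g", design$sample))
  res <- nb_wald(rbind(counts, counts + 0), design, s)
  expect_equal(res$log2FC, c(0, 0))
  expect_equal(res$p, c(1, 1))
  doubled <- matrix(c(40, 50, 60, 80, 100, 120), 1,
                    dimnames = list("g", design$sample))
  filler <- matrix(rep(c(10, 12, 14, 10, 12, 14), 2), 2, byrow = TRUE,
                   dimnames = list(c("f1", "f2"), design$sample))
  res2 <- nb_wald(rbind(doubled, filler), design, s)
  expect_equal(res2$log2FC[1], 1)
})

test_that("swapping reference and alternative negates the fold change exactly", {
  withr::with_seed(102, {
    design <- design_3v3()
    s <- unit_s(design)
    counts <- matrix(rpois(60, 200), 10,
                     dimnames = list(paste0("g", 1:10), design$sample))
    a <- nb_wald(counts, design, s, ref_condition = "WT")
    b <- nb_wald(counts, design, s, ref_condition = "KO")
    expect_equal(a$log2FC, -b$log2FC)
    expect_equal(a$p, b$p)
    st_a <- diff_stalling(list(tss = counts, body = counts + 5L), design, s,
                          ref_condition = "WT")
    st_b <- diff_stalling(list(tss = counts, body = counts + 5L), design, s,
                          ref_condition = "KO")
    expect_equal(st_a$dsi, -st_b$dsi)
  })
})

test_that("genes with a zero mean are flagged and excluded from testing", {
  design <- design_3v3()
  counts <- matrix(c(0, 0, 0, 10, 12, 14,
                     20, 30, 25, 22, 28, 26), 2, byrow = TRUE,
                   dimnames = list(c("zero", "ok"), design$sample))
  res <- nb_wald(counts, design, unit_s(design))
  expect_false(res$tested[1])
  expect_true(is.infinite(res$log2FC[1]))
  expect_true(is.na(res$p[1]))
  expect_true(res$tested[2])
})

test_that("more than two conditions is an explicit error", {
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("A", "B", "C"), each = 2))
  counts <- matrix(rpois(30, 50), 5, dimnames = list(NULL, design$sample))
  expect_error(nb_wald(counts, design, unit_s(design)), "pairwise")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(103, {
    for (n in 1:12) {
      for (rep in 1:20) {
        p <- runif(n)
        expect_equal(bh_adjust(p), oracle_bh(p))
      }
    }
    p_big <- runif(500)
    expect_equal(bh_adjust(p_big), oracle_bh(p_big))
  })
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "finite")
})

test_that("DE calls apply both thresholds with a strict p cutoff", {
  expect_equal(call_de(1.2, 0.01), "up")
  expect_equal(call_de(0.9, 1e-6), "ns")
  expect_equal(call_de(-3, 0.05), "ns")   # padj not strictly below alpha
  expect_equal(call_de(-1, 0.049), "down")
  expect_equal(call_de(1, NA), NA_character_)
})

test_that("stalling index is the pseudocounted ratio of normalized means", {
  design <- design_3v3()
  s <- unit_s(design)
  rc <- list(
    tss = matrix(50, 1, 6, dimnames = list("g", design$sample)),
    body = matrix(100, 1, 6, dimnames = list("g", design$sample))
  )
  si <- stalling_index(rc, design, s, pseudocount = 0)
  expect_equal(si$si, c(0.5, 0.5))
  rc0 <- list(
    tss = matrix(0, 1, 6, dimnames = list("g", design$sample)),
    body = matrix(0, 1, 6, dimnames = list("g", design$sample))
  )
  expect_equal(stalling_index(rc0, design, s, pseudocount = 1)$si, c(1, 1))
  expect_error(stalling_index(rc0, design, s, pseudocount = 0), "pseudocount")
  # width normalization divides each mean by its region width
  widths <- data.frame(gene_id = "g", tss_width = 501, body_width = 1000)
  siw <- stalling_index(rc, design, s, pseudocount = 0,
                        width_normalize = TRUE, widths = widths)
  expect_equal(siw$si, rep(0.5 / (501 / 1000) / 1, 2) * c(1, 1))
})

test_that("identical counts across conditions give a zero stalling shift", {
  design <- design_3v3()
  s <- unit_s(design)
  base <- matrix(rep(c(30, 40, 50), 2), 2, 6, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), design$sample))
  st <- diff_stalling(list(tss = base, body = 2 * base), design, s)
  expect_equal(st$dsi, c(0, 0))
})

test_that("stability shift is the RNA minus TT fold-change difference", {
  mk <- function(g, lfc, ref = "WT") {
    d <- data.frame(gene_id = g, log2FC = lfc)
    attr(d, "ref_condition") <- ref
    d
  }
  ss <- stability_shift(mk(c("a", "b"), c(1, 2)), mk(c("b", "a"), c(1.5, 0)))
  expect_equal(ss$delta[ss$gene_id == "a"], 1)   # stabilization
  expect_equal(ss$delta[ss$gene_id == "b"], 0.5)
  expect_error(stability_shift(mk("a", 1), mk("b", 1)), "shared")
  expect_error(stability_shift(mk("a", 1), mk("a", 1, ref = "KO")),
               "reference")
  sm <- summary(stability_shift(mk(letters[1:4], c(1, 2, 3, 4)),
                                mk(letters[1:4], c(0, 0, 0, 0))))
  expect_equal(sm$median, 2.5)
  expect_equal(sm$n, 4)
  expect_equal(sum(sm$hist$count), 4)
})

test_that("pure effects move only their own readout", {
  # transcription halved: both arms drop ~1 log2; delta ~ 0
  cfg <- sim_config(n_genes = 300, depth = 1e6, dispersion = 0.02, seed = 31,
                    frac_txn_change = 0.3, effect_txn = 0.5)
  genes <- generate_genes(cfg)
  truth <- generate_truth(genes, cfg)
  samples <- generate_samples(cfg)
  cb <- simulate_counts(truth, samples, cfg)
  d_tt <- cb$design[cb$design$assay == "TT", ]
  d_rna <- cb$design[cb$design$assay == "RNA", ]
  s_tt <- true_size_factors(samples, "TT")
  s_rna <- true_size_factors(samples, "RNA")
  dtt <- nb_wald(cb$tss + cb$body, d_tt, s_tt)
  drn <- nb_wald(cb$gene, d_rna, s_rna)
  ss <- stability_shift(drn, dtt)
  cls <- setNames(truth$class[truth$condition == "WT"],
                  truth$gene_id[truth$condition == "WT"])
  txn <- cls[ss$gene_id] == "txn"
  expect_lt(abs(median(ss$delta[txn])), 0.1)
  expect_lt(median(ss$lfc_tt[txn]), -0.8)

  # degradation doubled: TT flat, RNA ~ -1, delta ~ -1
  cfg2 <- sim_config(n_genes = 300, depth = 1e6, dispersion = 0.02, seed = 32,
                     frac_stab_change = 0.3, effect_stab = 2)
  genes2 <- generate_genes(cfg2)
  truth2 <- generate_truth(genes2, cfg2)
  samples2 <- generate_samples(cfg2)
  cb2 <- simulate_counts(truth2, samples2, cfg2)
  dtt2 <- nb_wald(cb2$tss + cb2$body, cb2$design[cb2$design$assay == "TT", ],
                  true_size_factors(samples2, "TT"))
  drn2 <- nb_wald(cb2$gene, cb2$design[cb2$design$assay == "RNA", ],
                  true_size_factors(samples2, "RNA"))
  ss2 <- stability_shift(drn2, dtt2)
  cls2 <- setNames(truth2$class[truth2$condition == "WT"],
                   truth2$gene_id[truth2$condition == "WT"])
  stab <- cls2[ss2$gene_id] == "stab"
  expect_lt(abs(median(ss2$delta[stab]) + 1), 0.2)
  expect_lt(abs(median(ss2$lfc_tt[stab])), 0.2)
})
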