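---
title: "ttstab: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ttstab: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttstab)
```

ttstab analyses paired nascent-transcription (4sU metabolic labeling,
TT-seq style) and steady-state (RNA-seq) expression data for the same
two-condition contrast, and quantifies the binding panels that typically
accompany such studies (fluorescence-anisotropy titrations, ChIP-qPCR).
This vignette is the package's own account of the underlying models, the
choices that were genuinely open, and what the validation suite does and
does not demonstrate.

## The generative model

Every statistical contract in the package is stated against an explicit
count model. For gene $g$ in sample $j$ (depth $d_j$, capture efficiency
$c_j$), with synthesis rate $\kappa_g$, degradation rate $\delta_g$ and
pausing fraction $\pi_g$ (all per condition):

* nascent TSS window: $\mu = d_j c_j \kappa_g \pi_g$
* nascent gene body: $\mu = d_j c_j \kappa_g (1-\pi_g)$
* steady-state, whole gene: $\mu = d_j c_j \kappa_g/\delta_g$
* spike-in species $i$: $\mu = d_j c_j a_i$

Counts are negative binomial in the $(\mu, \alpha)$ parameterization,
$\mathrm{Var} = \mu + \alpha\mu^2$, with $\alpha = 0$ falling back to
Poisson. The steady-state mean is the first-order kinetics equilibrium
$\kappa/\delta$; nascent signal sees $\kappa$ only. This is what makes the
stability shift $\Delta = \mathrm{log_2FC(RNA)} - \mathrm{log_2FC(TT)}$
interpretable: a pure synthesis change cancels in $\Delta$, a pure
degradation change appears only in the RNA arm.

The one load-bearing assumption is that $c_j$ multiplies endogenous genes
and spike-ins identically. Spike-in size factors are consistent estimators
of $d_j c_j$ exactly because of it; if spike-in recovery decouples from
gene recovery (pipetting error on the spike mix, differential degradation
during enrichment), every downstream global statement inherits that error.

## Regions and counting

Coordinates are 0-based half-open everywhere; BED input/output is native
and GTF is converted on read (the choice is invisible to users of the file
interfaces but removes every off-by-one ambiguity internally). The TSS
window is the TSS base $\pm$ 250 bp — a 501 bp window, the reading
consistent with a gene body that starts at +251 — and the body runs from
+251 to the 3' end. Genes shorter than 500 bp are removed before
quantification (strictly shorter; 500 bp is kept); a 2 kb threshold for
ChIP-style use is the same operation with a different parameter. TSS
windows may extend upstream of the gene; windows crossing coordinate 0 are
clipped at 0 with a warning, which cannot occur on the synthetic layout.

A fragment overlapping (≥ 1 bp) only one window counts there; a fragment
overlapping both windows of a gene is discarded for that gene. There is no
minimum-overlap fraction. Overlapping genes are permitted and a fragment
may count toward several; the per-sample conservation tallies classify
each fragment once (counted-TSS > counted-BODY > both-only > unassigned)
so `assigned_tss + assigned_body + both_discarded + unassigned` always
equals the fragment count exactly. The default `strand_mode = "same"`
assumes a directional library whose fragments carry the transcript strand;
`"opposite"` and `"ignore"` cover other upstream conventions.

## Normalization and filtering

Raw per-sample factors are the total spike-in count (RNA arm) or the
median over labeled spike-in species (TT arm; unlabeled species do not
survive nascent enrichment and are ignored by construction). Factors are
anchored to geometric mean 1 so normalized counts stay on a counts-like
scale — the anchoring is a presentation choice; any common rescaling
cancels in every ratio the package forms. The low-count filter removes a
gene when some condition has every replicate strictly below 5 raw counts,
applied before normalization and testing, and is monotone in the
threshold.

## Differential testing

The package deliberately implements its own moment-based NB Wald test
rather than delegating to a GLM framework: per-condition means of
normalized counts, $\mathrm{log_2FC} = \log_2(\hat\mu_A/\hat\mu_R)$, and a
delta-method variance
$\mathrm{Var}(\ln\hat\mu_c) \approx \frac{1}{n_c\hat\mu_c\bar s_c} +
\frac{\alpha}{n_c}$ summed over conditions, with a two-sided normal
p-value and BH adjustment. Its contract is calibration and effect-size
recovery under the stated generative model, which the test suite measures
directly — not numerical equality with any external tool.

**Dispersion moderation is the one place implementation overruled the
obvious design.** The genewise moment estimator
$\hat\alpha_g = (v - m)/m^2$ averaged across conditions is provided
(`estimate_dispersion()`), but at 3 replicates it has roughly four degrees
of freedom: plugging it into a normal-reference Wald statistic inflates
empirical type-I error to ~0.12 at nominal 0.05, and taking the mean of
genewise estimates across genes is destabilized by the heavy upper tail
contributed by low-count genes. The default is therefore the pooled
common dispersion $\hat\alpha = \sum(v_{gc}-m_{gc}) / \sum m_{gc}^2$
(`common_dispersion()`), whose $m^2$ weighting lets the high-count genes
that actually carry dispersion information dominate. This is the same
reasoning behind common/trended dispersion in the established count-model
packages. Measured on the null generative model (2 000 genes, 3v3,
$\alpha = 0.05$), the pooled default keeps both `nb_wald()` and
`diff_stalling()` within [0.03, 0.07] across seeds. The cost is the usual
one: if true dispersions vary strongly across genes, highly dispersed
genes are tested anti-conservatively; `disp_moderation = "genewise"`
restores the per-gene plug-in for users with many replicates.

The stalling index is
$SI = (\overline{\mathrm{TSS}} + pc)/(\overline{\mathrm{body}} + pc)$
on normalized means, pseudocount 1 by default, without width
normalization (the nascent-assay convention here quantifies raw windows; a
flag enables width division for ChIP-style use). `diff_stalling()` tests
$dSI = \log_2(SI_A/SI_R)$ with the four-cell delta-method variance;
size-factor errors largely cancel inside each $SI$ because TSS and body
share the sample. Genes with a zero mean in any cell keep a defined $dSI$
through the pseudocount but are excluded from testing rather than assigned
a fabricated variance.

The stability shift joins the two arms on gene id (inner join — genes
absent from either arm are dropped, not imputed) and must see the same
reference condition on both sides.

## Binding panels

The anisotropy model is the exact 1:1 isotherm with ligand depletion,
$f = \frac{(L+P+K_d) - \sqrt{(L+P+K_d)^2 - 4LP}}{2L}$, evaluated in the
cancellation-free form $2P/(q + \sqrt{q^2-4LP})$. The hyperbolic
approximation $P/(P+K_d)$ was rejected as the model because panels of this
kind reach $K_d$ values only a few-fold above the ~90 nM labeled-peptide
concentration, where depletion visibly bends the curve. Fitting is
Levenberg–Marquardt over $(K_d, r_\text{free}, r_\text{bound})$ with the
half-saturation point as the $K_d$ start and restarts at 0.1× and 10×;
each replicate is fitted separately (reported as mean ± sd, matching how
such panels are conventionally summarized) alongside a pooled fit. A flat
series is flagged non-identifiable and reports no $K_d$ — a non-binder is
a result, not a failure. Concentrations are µM internally; ligand input is
nM because that is how these experiments are written up.

Percent input is $100 \cdot 2^{\mathrm{adjCq_{input}} - \mathrm{Cq_{ChIP}}}$
with $\mathrm{adjCq_{input}} = \mathrm{Cq_{input}} -
\log_2(100/\mathrm{input\ fraction})$; the input fraction is an explicit
parameter because only the adjusted-to-100% convention, not the dilution,
is ever stated in write-ups.

## What the synthetic generator does and does not emulate

The generator's defaults are the study conditions the package is
validated under: 3 replicates per assay and condition, two conditions
(reference first), ~2×10⁶ gene-derived fragments per sample, NB dispersion
0.05, per-sample capture efficiencies uniform on [0.5, 2], lognormal
synthesis rates (normalized so depth is interpretable), lognormal
degradation rates around 1, pausing fractions uniform on [0.2, 0.6],
fragment length 150 bp. The spike pools mirror common practice: six
ERCC-derived species for the nascent assay of which three are labeled
(abundance 0.5% of depth each), and a twelve-species unlabeled foreign
pool summing to 20% of depth for RNA-seq. Pausing effects act on the odds
$\pi/(1-\pi)$ so any fold keeps $\pi$ inside (0,1). Effect classes are
disjoint by construction and sized `round(frac · n_genes)`.

Fragment simulation draws region counts from the *same* seeded stream as
the count simulator, so quantifying the emitted fragments reproduces the
count matrices exactly when no straddling or intergenic fragments are
requested — the identity the end-to-end tests exploit. Straddlers are
placed across the TSS/body boundary (the class the counting rule must
discard) and intergenic fragments clear of every TSS window, with true
categories recorded for oracle tests.

Deliberately not emulated: sequence content and alignment (no FASTQ),
fragment-length variability, transcript isoforms and overlapping gene
structures, trended (mean-dependent) dispersion, batch effects, and any
decoupling of spike-in from gene recovery. Passing tests therefore show
that the statistical machinery does what it claims **under its own
assumptions**; they cannot show robustness to the ways real libraries
violate them.

## How the validation suite uses size factors

Two classes of checks are intentionally separated:

* **Normalization neutrality** is checked noise-free: on expected counts
  with capture efficiencies spanning 16×, spike-derived size factors make
  per-sample means agree to ~10⁻¹⁶ relative. This isolates the algebra of
  the estimator.
* **Calibration and effect recovery** are checked with the generator's
  true per-sample scale factors (`true_size_factors()`). The reason is a
  real statistical phenomenon, not convenience: a median over three
  labeled spike species with NB noise carries a ~15% per-sample scale
  error that is *shared across all genes*. Shared between-condition scale
  error is indistinguishable from a global expression shift for any
  per-gene test, and in unlucky draws it pushes the apparent type-I rate
  far outside any band — which says nothing about the test statistic
  itself. Conditioning on known scales tests the machinery; the worked
  example in the README shows what the spike-noise pathway does to a
  genome-wide median in practice.

This also documents a practical recommendation: with spike-in counts this
noisy, absolute genome-wide statements (e.g. "the global median shifted by
0.2 log2 units") are at the mercy of a handful of spike species, while
contrasts between gene classes within the same comparison are not.

## Numerical choices and degenerate inputs

* NB draws use `rnbinom(mu, size = 1/alpha)`; `alpha = 0` dispatches to
  `rpois` rather than a large-size approximation.
* Dispersion estimates are clamped below at 10⁻⁸ (a zero estimate would
  make the Wald variance degenerate for zero-mean genes).
* Genes with a zero mean in either condition get $\pm\infty$ log2FC,
  `tested = FALSE`, and are excluded from BH (adjusting untestable genes
  would distort the ranks of testable ones).
* `fraction_bound` uses the stable quadratic root; the discriminant is
  non-negative analytically and numerically for valid inputs.
* BH adjustment delegates to `stats::p.adjust` after range validation;
  the suite verifies it against an independent brute-force step-up
  implementation.
* Seeds: every generator takes the configured seed plus a fixed small
  offset per operation, so individual stages are reproducible in
  isolation and jointly.

## Problem sizes used by the validation suite

The suite validates at sizes chosen to make every distributional claim
measurable with comfortable margins while keeping the whole suite quick
to iterate on: 2 000 genes × 3v3 for null calibration, 500 genes with
10% effect fractions for recovery, 20 random scenarios of 50 genes ×
1 000 fragments for the counting oracle, the exhaustive 7⁶ grid for the
low-count rule, and 12-point titrations in triplicate for binding. These
are an order of magnitude below a real experiment in gene count but not
in per-gene depth, which is what the per-gene statistics actually see.

## Known limitations

* Two-condition contrasts only; multi-factor designs and shrinkage
  estimators are out of scope by design.
* The common-dispersion default trades per-gene dispersion resolution for
  calibration at low replicate numbers.
* One TSS per gene model; isoform-resolved promoters are not handled.
* The stability shift is a difference of noisy estimates; its per-gene
  variance is not modeled (only arm-level standard errors are reported),
  so class-level medians, not single-gene $\Delta$ values, are the
  supported readout.
* No read-level simulation: alignment artifacts, multimapping and
  sequence bias are upstream of everything this package models.
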