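#' Exact 1:1 equilibrium bound fraction
#'
#' Fraction of total ligand (labeled peptide) bound at total protein `P`,
#' total ligand `L` and dissociation constant `Kd`, from the mass-balance
#' quadratic (ligand depletion included):
#' `f = ((L + P + Kd) - sqrt((L + P + Kd)^2 - 4 L P)) / (2 L)`.
#' Evaluated in the cancellation-free form `2P / (q + sqrt(q^2 - 4LP))`
#' with `q = L + P + Kd`. For `L << Kd` this approaches the hyperbola
#' `P / (P + Kd)`. All concentrations must share one unit (uM throughout
#' the package).
#'
#' @param P total protein concentration(s), >= 0.
#' @param L total ligand concentration, > 0.
#' @param kd dissociation constant, > 0.
#' @return Bound fraction(s) in \[0, 1\].
#' @export
fraction_bound <- function(P, L, kd) {
  if (L <= 0) stopf("ligand concentration must be > 0")
  if (kd <= 0) stopf("kd must be > 0")
  if (any(P < 0)) stopf("protein concentrations must be >= 0")
  q <- L + P + kd
  2 * P / (q + sqrt(q^2 - 4 * L * P))
}

aniso_model <- function(P, L, kd, r_free, r_bound) {
  r_free + (r_bound - r_free) * fraction_bound(P, L, kd)
}

fit_one_series <- function(P, r, L) {
  rng <- diff(range(r))
  if (rng <= max(1e-12, 1e-6 * max(abs(r), 1))) {
    return(list(kd = NA_real_, r_free = NA_real_, r_bound = NA_real_,
                se_kd = NA_real_, converged = FALSE,
                reason = "flat series: binding not identifiable"))
  }
  # half-saturation initial guess by linear interpolation of the response
  half <- min(r) + rng / 2
  ord <- order(P)
  kd0 <- tryCatch(approx(r[ord], P[ord], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(P[P > 0])
  dat <- data.frame(P = P, r = r)
  starts <- lapply(c(1, 0.1, 10), function(m) {
    list(kd = kd0 * m, r_free = min(r), r_bound = max(r))
  })
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ aniso_model(P, L, kd, r_free, r_bound),
        data = dat, start = st,
        lower = c(kd = 1e-9, r_free = -Inf, r_bound = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit)))["kd"],
                     error = function(e) NA_real_)
      return(list(kd = unname(co["kd"]), r_free = unname(co["r_free"]),
                  r_bound = unname(co["r_bound"]), se_kd = unname(se),
                  converged = TRUE, reason = NA_character_))
    }
  }
  list(kd = NA_real_, r_free = NA_real_, r_bound = NA_real_,
       se_kd = NA_real_, converged = FALSE,
       reason = "nonlinear least squares did not converge")
}

#' Fit a 1:1 binding isotherm to anisotropy titrations
#'
#' Nonlinear least squares of
#' `r(P) = r_free + (r_bound - r_free) * fraction_bound(P, L, Kd)` over
#' `(Kd, r_free, r_bound)` (Levenberg-Marquardt, bounded `Kd > 0`, a few
#' restarts around the half-saturation initial guess). Each replicate
#' series is fitted separately and `Kd` reported as mean +/- sd across
#' replicates; a pooled fit over all points is also returned. Flat series
#' are flagged non-identifiable with no `Kd`, never silently defaulted.
#'
#' @param series a `titration_series` (see [simulate_titration()] /
#'   [read_titration_csv()]): columns `replicate`, `protein_uM`,
#'   `anisotropy`, attribute `ligand_nM`.
#' @param ligand_nM total ligand concentration in nM; defaults to the
#'   series attribute.
#' @return A list of class `binding_fit`: `kd_mean`, `kd_sd` (uM, across
#'   converged replicate fits), `replicates` (per-replicate data.frame),
#'   `pooled` (pooled-fit list), `converged` (any replicate converged).
#' @export
fit_kd <- function(series, ligand_nM = NULL) {
  ligand_nM <- ligand_nM %||% attr(series, "ligand_nM")
  if (is.null(ligand_nM)) stopf("ligand concentration not given")
  L <- ligand_nM / 1000
  need <- c("replicate", "protein_uM", "anisotropy")
  if (!all(need %in% names(series))) {
    stopf("titration series needs columns: %s", paste(need, collapse = ", "))
  }
  reps <- split(series, series$replicate)
  for (d in reps) {
    if (nrow(d) < 5) stopf("each replicate series needs >= 5 points")
    if (is.unsorted(d$protein_uM, strictly = TRUE)) {
      stopf("protein grid must be strictly ascending within a replicate")
    }
  }
  fits <- lapply(reps, function(d) fit_one_series(d$protein_uM, d$anisotropy, L))
  rep_df <- data.frame(
    replicate = names(reps),
    kd = vapply(fits, `[[`, numeric(1), "kd"),
    r_free = vapply(fits, `[[`, numeric(1), "r_free"),
    r_bound = vapply(fits, `[[`, numeric(1), "r_bound"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  kds <- rep_df$kd[rep_df$converged]
  pooled <- fit_one_series(series$protein_uM, series$anisotropy, L)
  structure(list(
    kd_mean = if (length(kds)) mean(kds) else NA_real_,
    kd_sd = if (length(kds) > 1) stats::sd(kds) else NA_real_,
    replicates = rep_df,
    pooled = pooled,
    ligand_nM = ligand_nM,
    converged = any(rep_df$converged)
  ), class = "binding_fit")
}

#' Assemble a domain x peptide affinity matrix
#'
#' @param fits data.frame with columns `domain`, `peptide`, `kd` (uM) and
#'   optionally `converged`; non-converged entries (non-binders) become
#'   `NA` cells.
#' @param transform `"kd"` (uM values, default) or `"neg_log10_M"`
#'   (`-log10(Kd in M)`, so 1 uM maps to 6).
#' @return Numeric matrix, domains x peptides.
#' @export
build_affinity_matrix <- function(fits, transform = c("kd", "neg_log10_M")) {
  transform <- match.arg(transform)
  if (!all(c("domain", "peptide", "kd") %in% names(fits))) {
    stopf("fits need columns domain, peptide, kd")
  }
  kd <- fits$kd
  if (!is.null(fits$converged)) kd[!fits$converged] <- NA_real_
  doms <- unique(fits$domain); peps <- unique(fits$peptide)
  m <- matrix(NA_real_, length(doms), length(peps),
              dimnames = list(doms, peps))
  m[cbind(match(fits$domain, doms), match(fits$peptide, peps))] <- kd
  if (transform == "neg_log10_M") m <- -log10(m * 1e-6)
  m
}

#' ChIP-qPCR percent input
#'
#' The input Cq is first adjusted to 100% chromatin:
#' `adjCq = Cq_input - log2(100 / input_fraction)`, then
#' `%input = 100 * 2^(adjCq - Cq_chip)`. One Cq cycle more in the ChIP
#' sample halves the result.
#'
#' @param cq_input input-sample Cq value(s).
#' @param cq_chip ChIP-sample Cq value(s).
#' @param input_fraction percent of chromatin reserved as input, in
#'   (0, 100\] (default 100 = input not diluted).
#' @return Percent input value(s).
#' @export
percent_input <- function(cq_input, cq_chip, input_fraction = 100) {
  if (any(!is.finite(cq_input)) || any(!is.finite(cq_chip))) {
    stopf("Cq values must be finite")
  }
  if (any(input_fraction <= 0) || any(input_fraction > 100)) {
    stopf("input_fraction must lie in (0, 100]")
  }
  adj <- cq_input - log2(100 / input_fraction)
  100 * 2^(adj - cq_chip)
}
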