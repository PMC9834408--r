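# Brute-force oracles kept deliberately independent of the package's
# vectorized / GenomicRanges-based implementations.

# half-open interval overlap by >= 1 bp
ov <- function(s1, e1, s2, e2) s1 < e2 && e1 > s2

oracle_classify <- function(frag, pair, strand_mode = "same") {
  pass <- switch(strand_mode,
                 same = frag$strand == pair$strand,
                 opposite = frag$strand != pair$strand,
                 ignore = TRUE)
  if (!pass || frag$chrom != pair$chrom) return("NONE")
  t <- ov(frag$start, frag$end, pair$tss_start, pair$tss_end)
  b <- ov(frag$start, frag$end, pair$body_start, pair$body_end)
  if (t && b) "BOTH" else if (t) "TSS" else if (b) "BODY" else "NONE"
}

# all-pairs counting: for every gene, plain comparison arithmetic against
# every fragment (no overlap-search machinery), with the tally precedence
# the package documents (counted-TSS > counted-BODY > both-only >
# unassigned)
oracle_count <- function(frags, pairs, strand_mode = "same",
                         samples = sort(unique(frags$sample))) {
  tss <- matrix(0L, nrow(pairs), length(samples),
                dimnames = list(pairs$gene_id, samples))
  body <- tss
  rank <- rep(0L, nrow(frags))  # 0 none, 1 both, 2 body, 3 tss
  si <- match(frags$sample, samples)
  for (g in seq_len(nrow(pairs))) {
    pass <- switch(strand_mode,
                   same = frags$strand == pairs$strand[g],
                   opposite = frags$strand != pairs$strand[g],
                   ignore = rep(TRUE, nrow(frags)))
    pass <- pass & frags$chrom == pairs$chrom[g]
    t <- pass & frags$start < pairs$tss_end[g] & frags$end > pairs$tss_start[g]
    b <- pass & frags$start < pairs$body_end[g] & frags$end > pairs$body_start[g]
    is_tss <- t & !b
    is_body <- b & !t
    is_both <- t & b
    tss[g, ] <- tss[g, ] + tabulate(si[is_tss], length(samples))
    body[g, ] <- body[g, ] + tabulate(si[is_body], length(samples))
    rank <- pmax(rank, is_tss * 3L, is_body * 2L, is_both * 1L)
  }
  tally <- do.call(rbind, lapply(seq_along(samples), function(k) {
    r <- rank[si == k]
    data.frame(sample = samples[k], assigned_tss = sum(r == 3),
               assigned_body = sum(r == 2),
               both_discarded = sum(r == 1),
               unassigned = sum(r == 0),
               stringsAsFactors = FALSE)
  }))
  list(tss = tss, body = body, tally = tally)
}

oracle_count_gene <- function(frags, genes, strand_mode = "same",
                              samples = sort(unique(frags$sample))) {
  m <- matrix(0L, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  si <- match(frags$sample, samples)
  for (g in seq_len(nrow(genes))) {
    pass <- switch(strand_mode,
                   same = frags$strand == genes$strand[g],
                   opposite = frags$strand != genes$strand[g],
                   ignore = rep(TRUE, nrow(frags)))
    hit <- pass & frags$chrom == genes$chrom[g] &
      frags$start < genes$end[g] & frags$end > genes$start[g]
    m[g, ] <- tabulate(si[hit], length(samples))
  }
  m
}

# textbook BH step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# random fragments spread over the span of a gene set (plus margins)
random_fragments <- function(n, genes, samples = c("s1", "s2"),
                             max_len = 400) {
  lo <- min(genes$start) - 500
  hi <- max(genes$end) + 500
  start <- floor(runif(n, lo, hi))
  len <- 1 + floor(runif(n, 0, max_len))
  data.frame(
    chrom = sample(unique(genes$chrom), n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    sample = sample(samples, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

random_gene_set <- function(n, chrom = "chrT") {
  len <- 600 + floor(runif(n, 0, 5000))
  gap <- 600 + floor(runif(n, 0, 2000))
  start <- cumsum(gap) + c(0, cumsum(len[-n]))
  gene_models(sprintf("t%03d", seq_len(n)), chrom, start, start + len,
              sample(c("+", "-"), n, replace = TRUE))
}
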