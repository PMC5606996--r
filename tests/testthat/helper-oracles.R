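# Independent brute-force oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# hypergeometric upper tail P(X >= k) by explicit pmf summation
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks) / choose(N, n))
}

# Benjamini-Hochberg from the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# quantile normalization from the definition (average-rank tie handling)
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    # mean of the reference values spanned by each (possibly tied) rank
    vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(ref[lo:hi])
    }, numeric(1))
  })
  dimnames(out) <- dimnames(m)
  out
}

# all-pairs half-open interval overlap of peaks with TSS windows
assign_oracle <- function(peaks, promoters, window = 10000) {
  out <- stats::setNames(rep(list(integer()), nrow(promoters)),
                         promoters$gene_id)
  for (g in seq_len(nrow(promoters))) {
    ws <- promoters$tss[g] - window
    we <- promoters$tss[g] + window
    hit <- which(peaks$chrom == promoters$chrom[g] &
                   peaks$start < we & peaks$end > ws)
    out[[g]] <- sort(hit)
  }
  out
}

# binary probit NLL from first principles (for the k = 1 reduction)
binary_probit_nll <- function(alpha, beta, x, y01) {
  p0 <- pnorm(alpha - beta * x)
  -sum(log(ifelse(y01 == 0L, p0, 1 - p0)))
}

# small deterministic cohort used by several screening tests
toy_cohort <- function(n_genes = 40, n_samples = 70, pag_fraction = 0.5,
                       seed = 101) {
  simulate_ordinal_cohort(n_genes, n_samples = n_samples,
                          pag_fraction = pag_fraction, seed = seed)
}
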