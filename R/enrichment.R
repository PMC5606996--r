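# Gene-set over-representation with enrichment scores

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the target list is enriched for the
#' set's members relative to the background, and reports the enrichment
#' score: the frequency of set members in the target divided by their
#' frequency in the background, `(k/n) / (K/N)`.  Sets are intersected with
#' the background before testing; terms with no target overlap (`k = 0`)
#' are excluded.
#'
#' @param target_genes Character vector; must be a subset of the background.
#' @param background_genes Character vector defining the universe `N`.
#' @param gene_sets Named list of character vectors (term -> members), e.g.
#'   from [read_gmt()].
#' @param p_cutoff Significance cutoff on the BH-adjusted p (default 0.01).
#' @return Data frame with one row per term with `k >= 1`: `term`, `k`
#'   (overlap), `n` (target size in background), `K` (term size in
#'   background), `N` (background size), `p` (hypergeometric upper tail),
#'   `p_adj` (BH), `enrichment_score`, `significant`.
#' @export
enrich <- function(target_genes, background_genes, gene_sets,
                   p_cutoff = 0.01) {
  bg <- unique(as.character(background_genes))
  tg <- unique(as.character(target_genes))
  if (!all(tg %in% bg)) {
    stop("target genes must be a subset of the background", call. = FALSE)
  }
  if (length(tg) == 0L) {
    warning("empty target gene list")
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), enrichment_score = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  N <- length(bg); n <- length(tg)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(as.character(gene_sets[[term]])), bg)
    K <- length(members)
    k <- length(intersect(members, tg))
    if (k < 1L) return(NULL)
    data.frame(term = term, k = k, n = n, K = K, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               enrichment_score = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), enrichment_score = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < p_cutoff
  out <- out[, c("term", "k", "n", "K", "N", "p", "p_adj",
                 "enrichment_score", "significant")]
  rownames(out) <- NULL
  out
}

#' Compare two enrichment-score distributions
#'
#' Welch two-sample two-tailed t-test on two score vectors, reporting means
#' and standard deviations alongside the test.  Degenerate inputs (both
#' vectors constant) yield `p = 1` when the means agree and `p = 0`
#' otherwise.
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 2.
#' @return List with `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `p`.
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 2L, length(scores_b) >= 2L)
  sda <- stats::sd(scores_a); sdb <- stats::sd(scores_b)
  if (sda == 0 && sdb == 0) {
    eq <- isTRUE(all.equal(mean(scores_a), mean(scores_b)))
    return(list(mean_a = mean(scores_a), mean_b = mean(scores_b),
                sd_a = sda, sd_b = sdb,
                t = if (eq) 0 else Inf, p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(mean_a = mean(scores_a), mean_b = mean(scores_b),
       sd_a = sda, sd_b = sdb,
       t = unname(tt$statistic), p = tt$p.value)
}
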