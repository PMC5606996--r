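# Binary disease-vs-control comparator: empirical-Bayes moderated t-test,
# BH adjustment and set-overlap statistics.

# Newton inversion of trigamma, used by the moments fit of the prior df.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes moderated two-group differential test
#'
#' Per gene, computes the pooled two-sample variance `s^2` on `d = n1 + n2
#' - 2` residual df, shrinks it toward a prior variance `s0^2` with prior df
#' `d0`, `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and forms the moderated
#' statistic `t = (mean1 - mean2) / (s_tilde * sqrt(1/n1 + 1/n2))` referred
#' to a t distribution on `d0 + d` df.  With `d0 = 0` this is exactly the
#' ordinary pooled t-test; as `d0 -> Inf` it approaches a z-like statistic
#' at the prior variance.
#'
#' When `d0`/`s0sq` are not supplied they are estimated from the ensemble of
#' per-gene variances by a method-of-moments fit on log variances: with
#' `e = log(s^2) - digamma(d/2) + log(d/2)`, the prior df solves
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.  If the observed
#' spread is no larger than the sampling spread, `d0 = Inf`.
#'
#' @param expr Genes x samples matrix, log scale.
#' @param labels Two-level factor/character vector over the columns (first
#'   level is the reference group; `logfc = mean(other) - mean(reference)`).
#' @param d0,s0sq Optional prior df and prior variance; estimated when `NULL`.
#' @param p_threshold DEG threshold on the BH-adjusted p-value (default
#'   `0.001`).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return Data frame with `gene_id`, `logfc`, `t_mod`, `df_total`, `p`,
#'   `p_adj`, `is_deg`, `zero_variance`; attributes `d0` and `s0sq` carry
#'   the prior used.  Zero-variance genes get `NA` statistics when no prior
#'   information is available and are excluded from DEG calls.
#' @export
moderated_two_group_test <- function(expr, labels, d0 = NULL, s0sq = NULL,
                                     p_threshold = 0.001,
                                     adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  expr <- as.matrix(expr)
  labels <- as.character(labels)
  stopifnot(ncol(expr) == length(labels))
  lv <- unique(labels)
  if (length(lv) != 2L) stop("exactly two label groups required", call. = FALSE)
  i1 <- labels == lv[1L]; i2 <- labels == lv[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2", call. = FALSE)
  d <- n1 + n2 - 2L

  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(expr[, i2, drop = FALSE], 1L, stats::var)
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  delta <- m2 - m1

  if (is.null(d0) || is.null(s0sq)) {
    pos <- s2 > 0
    e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
    ve <- stats::var(e)
    excess <- ve - trigamma(d / 2)
    if (is.na(excess) || excess <= 0) {
      d0_est <- Inf
      s0_est <- exp(mean(e))
    } else {
      d0_est <- 2 * .trigamma_inverse(excess)
      s0_est <- exp(mean(e) + digamma(d0_est / 2) - log(d0_est / 2))
    }
    if (is.null(d0)) d0 <- d0_est
    if (is.null(s0sq)) s0sq <- s0_est
  }

  if (is.infinite(d0)) {
    s2_tilde <- rep(s0sq, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- (d0 * s0sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- delta / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  zero_var <- s2_tilde <= 0 | !is.finite(t_mod)
  t_mod[zero_var] <- NA_real_
  p[zero_var] <- NA_real_

  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- if (adjust == "BH") bh_adjust(p[ok]) else
    stats::p.adjust(p[ok], method = "bonferroni")

  gene_ids <- rownames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(expr)))
  out <- data.frame(gene_id = gene_ids, logfc = delta, t_mod = t_mod,
                    df_total = df_total, p = p, p_adj = p_adj,
                    is_deg = !is.na(p_adj) & p_adj < p_threshold,
                    zero_variance = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotone enforcement, as implemented by
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, aligned with the input.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Overlap of two gene sets with a hypergeometric tail p-value
#'
#' @param set_a,set_b Character vectors (subsets of the universe).
#' @param universe_size Integer size of the gene universe.
#' @return List with `intersection` (character vector), `n_overlap`, and
#'   `p` = upper-tail hypergeometric probability of observing at least the
#'   realized overlap.
#' @export
overlap_stats <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(union(set_a, set_b)) > universe_size) {
    stop("universe smaller than the union of the two sets", call. = FALSE)
  }
  inter <- intersect(set_a, set_b)
  k <- length(inter)
  p <- stats::phyper(k - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(intersection = inter, n_overlap = k, p = p)
}
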