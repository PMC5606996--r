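# H3K9ac / expression integration: promoter-window peak assignment,
# summed-M score, interaction-effect statistic and gamma robustness.

#' Assign ChIP-seq peaks to promoter windows
#'
#' A peak `[start, end)` (0-based half-open) is assigned to a gene when it
#' overlaps the window `[tss - window, tss + window)` around the gene's
#' transcription start site.  The window is symmetric, so the recorded
#' strand does not change the assignment; a peak may serve several genes.
#' Interval overlap is resolved with `IRanges::findOverlaps()` per
#' chromosome.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`, `m_value`
#'   (0-based half-open coordinates).
#' @param promoters Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based), `strand`.
#' @param window Half-width of the promoter window in bp (default 10000).
#' @return Named list, gene id -> integer vector of row indices into
#'   `peaks` (possibly empty).
#' @export
assign_peaks <- function(peaks, promoters, window = 10000) {
  stopifnot(all(c("chrom", "start", "end", "m_value") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss") %in% names(promoters)))
  if (nrow(peaks) > 0L && any(peaks$start >= peaks$end)) {
    stop("peak intervals must satisfy start < end", call. = FALSE)
  }
  out <- stats::setNames(rep(list(integer()), nrow(promoters)),
                         promoters$gene_id)
  if (nrow(peaks) == 0L || nrow(promoters) == 0L) return(out)
  shared <- intersect(unique(peaks$chrom), unique(promoters$chrom))
  if (length(shared) == 0L) {
    warning("no chromosome names shared between peaks and promoters")
    return(out)
  }
  for (chr in shared) {
    pi <- which(peaks$chrom == chr)
    gi <- which(promoters$chrom == chr)
    # convert 0-based half-open [s, e) to 1-based closed [s + 1, e]
    pk <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    win <- IRanges::IRanges(start = promoters$tss[gi] - window + 1L,
                            end = promoters$tss[gi] + window)
    hits <- IRanges::findOverlaps(win, pk)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (j in seq_along(gi)) {
      out[[gi[j]]] <- sort(pi[sh[qh == j]])
    }
  }
  out
}

#' H3K9ac score: summed peak M-values in the promoter window
#'
#' The score of a gene is the sum of the M-values (log-ratio peak
#' intensities between conditions) of the peaks assigned to its promoter
#' window.  Genes with no assigned peak are dropped: they are not
#' candidates for the interaction-effect analysis.
#'
#' @param assignment Output of [assign_peaks()].
#' @param peaks The peak data frame the assignment indexes into.
#' @return Named numeric vector of scores for genes with >= 1 peak.
#' @export
h3k9ac_score <- function(assignment, peaks) {
  has <- vapply(assignment, length, integer(1)) > 0L
  vapply(assignment[has], function(idx) sum(peaks$m_value[idx]), numeric(1))
}

#' Interaction-effect statistic for epigenome/expression integration
#'
#' For candidate genes with promoter H3K9ac score `x1` and expression
#' log fold-change `x2`, computes the interaction-effect response
#' `ie = gamma0 + gamma1 x1 + gamma2 x2 + gamma3 x1 x2`, standardizes it
#' across the candidates to `ie_z` (z-score), and selects genes with
#' `ie_z > 0` (strictly; a gene sitting exactly at the mean is not
#' selected).  `gamma0` does not affect the ranking; the defaults set it to
#' 0 and the remaining coefficients to 1.
#'
#' @param x1 Numeric vector of H3K9ac scores over the candidate genes.
#' @param x2 Numeric vector of expression fold-changes (same length/order).
#' @param gammas Numeric length-4 vector `(gamma0, gamma1, gamma2, gamma3)`;
#'   default `c(0, 1, 1, 1)`.
#' @param gene_ids Optional gene identifiers.
#' @param sd_type `"population"` (default, divisor `n`) or `"sample"`
#'   (divisor `n - 1`) for the z-score.
#' @return Data frame (rows ordered by decreasing `ie_z`) with `gene_id`,
#'   `x1`, `x2`, `ie`, `ie_z`, `selected`, `rank`.
#' @examples
#' interaction_effect(x1 = c(0, 1, 2), x2 = c(0, 2, 3))
#' @export
interaction_effect <- function(x1, x2, gammas = c(0, 1, 1, 1),
                               gene_ids = NULL,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(x1) == length(x2), length(gammas) == 4L)
  n <- length(x1)
  if (n < 2L) stop("need at least 2 candidate genes to z-score", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  ie <- gammas[1L] + gammas[2L] * x1 + gammas[3L] * x2 + gammas[4L] * x1 * x2
  s <- stats::sd(ie)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  ie_z <- if (s == 0) rep(0, n) else (ie - mean(ie)) / s
  out <- data.frame(gene_id = as.character(gene_ids), x1 = x1, x2 = x2,
                    ie = ie, ie_z = ie_z, selected = ie_z > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ie_z, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Robustness of the selected gene set to the gamma coefficients
#'
#' Recomputes the interaction-effect selection (`ie_z > 0`) under randomly
#' drawn gamma coefficients (`gamma0` fixed at 0) and reports the fraction
#' of iterations whose selected set equals the default-gamma set.  The
#' default sampler draws `gamma1, gamma2, gamma3` independently from
#' U(0.5, 2).
#'
#' @inheritParams interaction_effect
#' @param n_iter Number of random draws (default 100).
#' @param sampler Function of no arguments returning `c(gamma1, gamma2,
#'   gamma3)`; `NULL` for the default uniform sampler.
#' @param seed RNG seed for reproducibility.
#' @return Fraction of iterations with an identical selected set, in
#'   `[0, 1]`.
#' @export
gamma_robustness <- function(x1, x2, n_iter = 100, sampler = NULL,
                             seed = NULL, gene_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sampler)) sampler <- function() stats::runif(3, 0.5, 2)
  base <- interaction_effect(x1, x2, gene_ids = gene_ids)
  base_set <- sort(base$gene_id[base$selected])
  same <- vapply(seq_len(n_iter), function(i) {
    g <- sampler()
    it <- interaction_effect(x1, x2, gammas = c(0, g), gene_ids = gene_ids)
    identical(sort(it$gene_id[it$selected]), base_set)
  }, logical(1))
  mean(same)
}
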