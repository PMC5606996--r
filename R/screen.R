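# Per-gene screening of an expression matrix against an ordinal phenotype

#' Screen genes for association with an ordinal phenotype
#'
#' Fits the cumulative-link model ([ordreg_fit()]) to every gene of an
#' expression matrix against a shared ordinal phenotype and calls
#' phenotype-associated genes (PAGs).  By default a gene is a PAG when the
#' two-tailed Wald p-values of *all* fitted parameters (the `k` intercepts
#' and the slope) fall below `p_threshold`; set `all_params = FALSE` to
#' require only the slope p-value.  Benjamini-Hochberg adjusted slope
#' p-values are emitted for transparency but play no part in the PAG call.
#'
#' Constant-expression genes are skipped (never counted as PAGs) and
#' non-converged or separated fits are excluded from PAG calling; both are
#' tallied in the `"screen_summary"` attribute and reported via `message()`.
#'
#' @param expr Numeric matrix, genes as rows (rownames = gene ids), samples
#'   as columns (colnames = sample ids).  Log-scale expression assumed.
#' @param phenotype An [ordinal_phenotype()] covering the same samples.
#' @param link Link name, `"probit"` (default) or `"logit"`.
#' @param p_threshold Significance threshold for PAG calling (default
#'   `1e-6`).
#' @param all_params If `TRUE` (default) every fitted parameter must pass
#'   `p_threshold`; if `FALSE` only the slope.
#' @param quiet Suppress the summary message.
#' @return A data frame of class `"pag_table"`, one row per fitted gene,
#'   with columns `gene_id`, `beta`, `se_beta`, `z_slope`, `p_slope`,
#'   `p_intercept_max`, `p_max`, `p_slope_adj` (BH), `converged`,
#'   `separated`, `direction` (`"up"`/`"down"`), `is_pag`, `rank` (global,
#'   1 = largest `|beta|` among PAGs, NA otherwise).  Attribute
#'   `"screen_summary"` carries the filter counts.
#' @export
screen_genes <- function(expr, phenotype, link = "probit",
                         p_threshold = 1e-6, all_params = TRUE,
                         quiet = FALSE) {
  stopifnot(inherits(phenotype, "ordinal_phenotype"))
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L) {
    out <- .empty_pag_table()
    attr(out, "screen_summary") <- list(n_genes = 0L, fitted = 0L,
                                        skipped_constant = 0L,
                                        skipped_na = 0L, not_converged = 0L,
                                        separated = 0L, n_pag = 0L)
    return(out)
  }
  if (is.null(colnames(expr))) {
    stop("expression matrix must carry sample ids as colnames", call. = FALSE)
  }
  idx <- match(phenotype$sample_ids, colnames(expr))
  if (anyNA(idx) || ncol(expr) != length(phenotype$sample_ids)) {
    stop("sample sets of expression matrix and phenotype differ", call. = FALSE)
  }
  expr <- expr[, idx, drop = FALSE]
  grades <- phenotype$grades
  if (length(unique(grades)) < 2L) {
    stop("phenotype has fewer than 2 observed levels", call. = FALSE)
  }
  gene_ids <- rownames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(expr)))

  n_const <- 0L; n_na <- 0L; n_nc <- 0L; n_sep <- 0L
  rows <- vector("list", nrow(expr))
  for (g in seq_len(nrow(expr))) {
    xg <- expr[g, ]
    if (anyNA(xg) || any(!is.finite(xg))) { n_na <- n_na + 1L; next }
    if (stats::sd(xg) == 0) { n_const <- n_const + 1L; next }
    fit <- ordreg_fit(xg, grades, link = link)
    if (!fit$converged) n_nc <- n_nc + 1L
    if (fit$separated) n_sep <- n_sep + 1L
    k <- fit$k
    rows[[g]] <- data.frame(
      gene_id = gene_ids[g],
      beta = fit$beta, se_beta = fit$se_beta,
      z_slope = unname(fit$z_values[k + 1L]),
      p_slope = unname(fit$p_values[k + 1L]),
      p_intercept_max = max(fit$p_values[seq_len(k)]),
      p_max = max(fit$p_values),
      converged = fit$converged, separated = fit$separated,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) tab <- .empty_pag_table()
  if (nrow(tab) > 0L) {
    tab$p_slope_adj <- stats::p.adjust(tab$p_slope, method = "BH")
    crit <- if (all_params) tab$p_max else tab$p_slope
    tab$is_pag <- crit < p_threshold & tab$converged & !tab$separated
    tab$direction <- ifelse(tab$beta > 0, "up", "down")
    tab$rank <- NA_integer_
    if (any(tab$is_pag)) {
      pag_idx <- which(tab$is_pag)
      ord <- pag_idx[order(-abs(tab$beta[pag_idx]), tab$p_slope[pag_idx],
                           tab$gene_id[pag_idx])]
      tab$rank[ord] <- seq_along(ord)
    }
    rownames(tab) <- NULL
  }
  smry <- list(n_genes = nrow(expr), fitted = nrow(tab),
               skipped_constant = n_const, skipped_na = n_na,
               not_converged = n_nc, separated = n_sep,
               n_pag = sum(tab$is_pag))
  if (!quiet) {
    message(sprintf(
      "screened %d genes: %d fitted, %d constant skipped, %d non-finite skipped, %d not converged, %d separated, %d PAGs",
      smry$n_genes, smry$fitted, smry$skipped_constant, smry$skipped_na,
      smry$not_converged, smry$separated, smry$n_pag))
  }
  attr(tab, "screen_summary") <- smry
  class(tab) <- c("pag_table", "data.frame")
  tab
}

.empty_pag_table <- function() {
  data.frame(gene_id = character(), beta = numeric(), se_beta = numeric(),
             z_slope = numeric(), p_slope = numeric(),
             p_intercept_max = numeric(), p_max = numeric(),
             converged = logical(), separated = logical(),
             p_slope_adj = numeric(), is_pag = logical(),
             direction = character(), rank = integer(),
             stringsAsFactors = FALSE)
}

#' Split called genes by direction and rank by slope magnitude
#'
#' Partitions the PAGs of a screen into consistently upregulated
#' (`beta > 0`) and downregulated (`beta < 0`) lists, each sorted by
#' decreasing `|beta|`.  Ties are broken by smaller slope p-value, then by
#' gene id.
#'
#' @param pag_table Output of [screen_genes()].
#' @return A list with data-frame components `up` and `down`.
#' @export
split_and_rank <- function(pag_table) {
  stopifnot(is.data.frame(pag_table))
  pag <- pag_table[pag_table$is_pag, , drop = FALSE]
  ord <- function(d) d[order(-abs(d$beta), d$p_slope, d$gene_id), ,
                       drop = FALSE]
  up <- ord(pag[pag$beta > 0, , drop = FALSE])
  down <- ord(pag[pag$beta < 0, , drop = FALSE])
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down)
}
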